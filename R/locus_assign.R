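# Scoring scheme shared by identity_score and the splice module: unit
# match/mismatch, affine gaps (open 2, extend 1, so a length-L gap costs
# 2 + L). N is scored as a mismatch against everything, including N, and is
# never counted as a match downstream.
assign_submat <- function() {
  m <- matrix(-1L, 5L, 5L,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- 1L
  m["N", "N"] <- -1L
  m
}

#' Local-alignment identity between a query and a target
#'
#' Best local (Smith–Waterman) alignment under unit match/mismatch scores
#' and affine gap penalties (open 2, extend 1). Identity is
#' `100 * matches / alignment columns`, where a match requires equal
#' non-`N` bases; gap columns and `N` columns count toward the denominator
#' only.
#'
#' @param query,target nucleotide strings over `{A,C,G,T,N}`.
#' @return list: `identity_pct`, `match_count`, `n_columns`, `score`,
#'   `aligned_query`, `aligned_target`, `query_range`/`target_range`
#'   (1-based inclusive aligned spans), `mismatches` (data.frame
#'   `query_pos`, `query_base`, `target_base`; substitution columns only).
#' @examples
#' identity_score("ACGTACGT", "ACGTACGT")$identity_pct  # 100
#' @export
identity_score <- function(query, target) {
  if (!nzchar(query) || !nzchar(target))
    stop("identity_score: empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target),
    type = "local", substitutionMatrix = assign_submat(),
    gapOpening = 2, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  real <- c("A", "C", "G", "T")
  is_match <- p == s & p %in% real
  qpos <- cumsum(p != "-") + Biostrings::start(Biostrings::pattern(aln)) - 1L
  sub_col <- p != "-" & s != "-" & !is_match
  list(identity_pct = 100 * sum(is_match) / length(p),
       match_count = sum(is_match),
       n_columns = length(p),
       score = Biostrings::score(aln),
       aligned_query = paste(p, collapse = ""),
       aligned_target = paste(s, collapse = ""),
       query_range = c(Biostrings::start(Biostrings::pattern(aln)),
                       Biostrings::end(Biostrings::pattern(aln))),
       target_range = c(Biostrings::start(Biostrings::subject(aln)),
                        Biostrings::end(Biostrings::subject(aln))),
       mismatches = data.frame(query_pos = qpos[sub_col],
                               query_base = p[sub_col],
                               target_base = s[sub_col],
                               stringsAsFactors = FALSE))
}

# k-mer-seeded alignment window on a long target: evenly spaced exact
# 16-mers from the query anchor the region worth aligning. Returns a
# 1-based c(start, end) on the target, or NULL when nothing seeds.
candidate_window <- function(query, target, k = 16L, margin = 150L) {
  n <- nchar(query)
  if (n < k) return(NULL)
  starts <- unique(pmax(1L, as.integer(seq(1L, n - k + 1L, length.out = 8L))))
  subj <- Biostrings::DNAString(target)
  lo <- Inf; hi <- -Inf
  for (st in starts) {
    pat <- substr(query, st, st + k - 1L)
    if (grepl("N", pat, fixed = TRUE)) next
    m <- Biostrings::matchPattern(pat, subj)
    if (length(m)) {
      o <- Biostrings::start(m) - st
      lo <- min(lo, min(o) + 1L)
      hi <- max(hi, max(o) + n)
    }
  }
  if (!is.finite(lo)) return(NULL)
  c(max(1L, lo - margin), min(nchar(target), hi + margin))
}

zero_score <- function() {
  list(identity_pct = 0, match_count = 0L, n_columns = 0L, score = -Inf,
       aligned_query = "", aligned_target = "", query_range = c(0L, 0L),
       target_range = c(0L, 0L),
       mismatches = data.frame(query_pos = integer(),
                               query_base = character(),
                               target_base = character(),
                               stringsAsFactors = FALSE))
}

#' Assign a cDNA clone to its locus of origin
#'
#' Scores the query (both orientations unless `try_revcomp = FALSE`)
#' against every candidate locus with [identity_score()] and applies the
#' highest-identity rule: the best locus is the argmax of integer match
#' count, then percent identity. An exact tie on both keys across >= 2
#' loci makes the call `ambiguous`; a best identity below
#' `min_identity_pct` makes it `below_threshold`.
#'
#' @param query nucleotide string (>= 30 nt).
#' @param candidates named character vector of candidate locus sequences
#'   (names are locus ids, unique).
#' @param min_identity_pct identity threshold in percent (default 99,
#'   after the observation that genuine clones match their locus by >99%).
#' @param try_revcomp also score the reverse complement and keep the
#'   better orientation (default TRUE).
#' @return list: `query_id` (NA here; set by callers), `status`
#'   (`assigned`/`ambiguous`/`below_threshold`), `best_locus`,
#'   `identity_pct`, `match_count`, `orientation` (`+`/`-`), `tied_loci`,
#'   `mismatches` (from the best alignment), `per_locus` (data.frame of
#'   all scores).
#' @export
assign_locus <- function(query, candidates, min_identity_pct = 99,
                         try_revcomp = TRUE) {
  if (length(candidates) < 1L) stop("assign_locus: no candidate loci")
  if (is.null(names(candidates)) || anyDuplicated(names(candidates)))
    stop("assign_locus: candidates must have unique names")
  if (nchar(query) < 30L) stop("assign_locus: query shorter than 30 nt")
  orientations <- if (try_revcomp) c("+", "-") else "+"
  qseq <- c("+" = query, "-" = unname(revcomp(query)))
  rows <- list(); best_aln <- list()
  for (id in names(candidates)) {
    target <- candidates[[id]]
    # seed-restricted windows on long targets; exhaustive otherwise
    use_windows <- nchar(target) > 2L * nchar(query) + 500L
    wins <- if (use_windows)
      lapply(qseq[orientations], candidate_window, target = target)
    else NULL
    seeded <- !is.null(wins) && any(!vapply(wins, is.null, TRUE))
    for (ori in orientations) {
      sc <- if (!use_windows || !seeded) {
        identity_score(qseq[[ori]], target)
      } else if (is.null(wins[[ori]])) {
        zero_score()  # no seed in this orientation, the other one seeded
      } else {
        identity_score(qseq[[ori]],
                       substr(target, wins[[ori]][1], wins[[ori]][2]))
      }
      rows[[paste(id, ori)]] <- data.frame(
        locus_id = id, orientation = ori,
        match_count = sc$match_count, identity_pct = sc$identity_pct,
        stringsAsFactors = FALSE)
      best_aln[[paste(id, ori)]] <- sc
    }
  }
  per <- do.call(rbind, rows); rownames(per) <- NULL
  # best orientation per locus, then rank loci
  per_locus <- do.call(rbind, lapply(split(per, per$locus_id), function(d) {
    d[order(-d$match_count, -d$identity_pct)[1], , drop = FALSE]
  }))
  per_locus <- per_locus[order(-per_locus$match_count,
                               -per_locus$identity_pct), , drop = FALSE]
  rownames(per_locus) <- NULL
  top <- per_locus[1, ]
  tied <- per_locus$locus_id[per_locus$match_count == top$match_count &
                             per_locus$identity_pct == top$identity_pct]
  status <- if (top$identity_pct < min_identity_pct) "below_threshold"
            else if (length(tied) >= 2L) "ambiguous"
            else "assigned"
  sc <- best_aln[[paste(top$locus_id, top$orientation)]]
  list(query_id = NA_character_, status = status,
       best_locus = if (status == "assigned") top$locus_id else NA_character_,
       identity_pct = top$identity_pct, match_count = top$match_count,
       orientation = top$orientation,
       tied_loci = if (length(tied) >= 2L) sort(tied) else character(),
       mismatches = sc$mismatches, per_locus = per_locus)
}

#' Assign a set of clones and tabulate the calls
#'
#' @param queries named character vector of clone sequences.
#' @param candidates named character vector of locus sequences.
#' @param min_identity_pct identity threshold (percent).
#' @return data.frame: `query_id`, `status`, `best_locus`, `identity_pct`,
#'   `match_count`, `orientation`, `tied_loci` (comma-joined),
#'   `mismatches` (`pos:ref>alt` semicolon-joined).
#' @export
assign_clones <- function(queries, candidates, min_identity_pct = 99) {
  # identical clone sequences get identical calls; compute each once
  cache <- new.env(parent = emptyenv())
  rows <- lapply(names(queries), function(id) {
    key <- queries[[id]]
    a <- if (!is.null(cache[[key]])) cache[[key]]
         else cache[[key]] <- assign_locus(key, candidates, min_identity_pct)
    mm <- a$mismatches
    data.frame(query_id = id, status = a$status,
               best_locus = a$best_locus,
               identity_pct = a$identity_pct, match_count = a$match_count,
               orientation = a$orientation,
               tied_loci = paste(a$tied_loci, collapse = ","),
               mismatches = paste(sprintf("%d:%s>%s", mm$query_pos,
                                          mm$target_base, mm$query_base),
                                  collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Diagnostic sites among near-identical paralogs
#'
#' Aligns every candidate globally to the first one (progressive pairwise;
#' candidates must be >= ~90% identical for this to be meaningful) and
#' reports the columns where at least two candidates carry different
#' bases. Insertions relative to the reference candidate are ignored.
#'
#' @param candidates named character vector (>= 2 sequences).
#' @return data.frame in long form: `site` (column index on the first
#'   candidate, 1-based), `locus_id`, `allele` (`-` for a gap), `pos`
#'   (1-based position in that candidate's own coordinates; NA at gaps).
#' @export
diagnostic_sites <- function(candidates) {
  if (length(candidates) < 2L) stop("diagnostic_sites: need >= 2 candidates")
  ref <- candidates[[1]]
  nref <- nchar(ref)
  mat <- matrix("-", nrow = length(candidates), ncol = nref,
                dimnames = list(names(candidates), NULL))
  pos <- matrix(NA_integer_, nrow = length(candidates), ncol = nref,
                dimnames = list(names(candidates), NULL))
  mat[1, ] <- strsplit(ref, "")[[1]]
  pos[1, ] <- seq_len(nref)
  for (i in seq_along(candidates)[-1]) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(candidates[[i]]), Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = assign_submat(),
      gapOpening = 2, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    refcol <- cumsum(s != "-")
    qpos <- cumsum(p != "-")
    keep <- s != "-"
    mat[i, refcol[keep]] <- p[keep]
    pos[i, refcol[keep]] <- ifelse(p[keep] == "-", NA_integer_, qpos[keep])
  }
  diff_col <- vapply(seq_len(nref), function(j) {
    a <- mat[, j]; a <- a[a %in% c("A", "C", "G", "T", "-")]
    length(unique(a)) >= 2L
  }, logical(1))
  sites <- which(diff_col)
  if (!length(sites))
    return(data.frame(site = integer(), locus_id = character(),
                      allele = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(sites, function(j) {
    data.frame(site = j, locus_id = rownames(mat),
               allele = mat[, j], pos = pos[, j],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
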