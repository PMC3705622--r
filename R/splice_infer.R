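#' Provirus model
#'
#' A provirus sequence with its landmark coordinates, all 0-based
#' half-open / 0-based positions on `seq`:
#' \itemize{
#'   \item `ltr5`, `ltr3`: LTR intervals `c(start, end)`;
#'   \item `r_region`: R-region interval relative to an LTR start
#'     (transcripts run R-to-R, hence two R copies per proviral mRNA);
#'   \item `canonical_5ss`: first intron base of the env-mRNA intron;
#'   \item `canonical_3ss`: first exon base after the intron;
#'   \item `type2_segment`: the 292-bp pol–env segment `c(start, end)`
#'     present in type II proviruses, `NULL` for type I;
#'   \item `provirus_type`: `"I"` or `"II"`.
#' }
#'
#' @param seq nucleotide string.
#' @param ltr5,ltr3 LTR intervals `c(start, end)`.
#' @param canonical_5ss,canonical_3ss splice-site positions.
#' @param type2_segment `c(start, end)` or `NULL`.
#' @param r_region R interval relative to LTR start.
#' @return object of class `provirus_model`.
#' @export
provirus_model <- function(seq, ltr5, ltr3, canonical_5ss, canonical_3ss,
                           type2_segment = NULL,
                           r_region = c(700L, 810L)) {
  stopifnot(ltr5[1] < ltr5[2], ltr3[1] < ltr3[2], ltr5[2] <= ltr3[1],
            canonical_5ss < canonical_3ss)
  if (!is.null(type2_segment) && diff(type2_segment) != 292L)
    stop("type2_segment must be exactly 292 bp when present")
  structure(list(seq = seq, ltr5 = as.integer(ltr5), ltr3 = as.integer(ltr3),
                 canonical_5ss = as.integer(canonical_5ss),
                 canonical_3ss = as.integer(canonical_3ss),
                 type2_segment = if (is.null(type2_segment)) NULL
                                 else as.integer(type2_segment),
                 provirus_type = if (is.null(type2_segment)) "I" else "II",
                 r_region = as.integer(r_region)),
            class = "provirus_model")
}

#' @export
print.provirus_model <- function(x, ...) {
  cat(sprintf("provirus_model: %d bp, type %s, LTRs [%d,%d)/[%d,%d), 5'SS %d, 3'SS %d\n",
              nchar(x$seq), x$provirus_type, x$ltr5[1], x$ltr5[2],
              x$ltr3[1], x$ltr3[2], x$canonical_5ss, x$canonical_3ss))
  invisible(x)
}

#' Write / read a model landmark sidecar (JSON)
#'
#' The sequence travels as FASTA; landmarks travel as a small JSON file.
#' @param model a `provirus_model`.
#' @param path JSON path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(model[setdiff(names(model), "seq")], path,
                       auto_unbox = FALSE, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @param seq the model sequence (read separately from FASTA).
#' @export
read_model_json <- function(path, seq) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  provirus_model(seq, ltr5 = j$ltr5, ltr3 = j$ltr3,
                 canonical_5ss = j$canonical_5ss,
                 canonical_3ss = j$canonical_3ss,
                 type2_segment = j$type2_segment,
                 r_region = j$r_region)
}

# --- junction inference ----------------------------------------------------

# Candidate offsets o such that cdna base i sits at model position o + i
# (1-based model position o+i, 0-based o+i-1). Seeds: 18-mers from the
# given end, allowing 1 mismatch, three staggered seeds to survive
# substitution noise.
seed_offsets <- function(cdna, model_seq, from_end = FALSE, k = 18L) {
  n <- nchar(cdna)
  starts <- if (!from_end) c(1L, k + 1L, 2L * k + 1L)
            else c(n - k + 1L, n - 2L * k + 1L, n - 3L * k + 1L)
  starts <- starts[starts >= 1L & starts + k - 1L <= n]
  offs <- integer()
  subj <- Biostrings::DNAString(model_seq)
  for (st in starts) {
    pat <- substr(cdna, st, st + k - 1L)
    if (grepl("N", pat, fixed = TRUE)) next
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = 1L)
    if (length(m)) offs <- c(offs, Biostrings::start(m) - st)
  }
  sort(unique(offs))
}

# matches of cdna placed ungapped at offset o (model pos of base i = o+i,
# 1-based); returns logical vector per cdna base, FALSE outside the model.
placement_matches <- function(cdna_chars, model_chars, o) {
  n <- length(cdna_chars); L <- length(model_chars)
  idx <- o + seq_len(n)
  ok <- idx >= 1L & idx <= L
  res <- logical(n)
  res[ok] <- cdna_chars[ok] == model_chars[idx[ok]] &
    cdna_chars[ok] %in% c("A", "C", "G", "T")
  res
}

#' Infer the splice junction of a cDNA against a provirus model
#'
#' Searches split placements of the cDNA: a prefix placed ungapped ending
#' at a donor (first intron base) and a suffix starting at an acceptor
#' (first exon base after the intron), with both sites restricted to
#' `search_window` nt around the model's canonical sites. Candidate
#' placements are anchored by 18-mer seeds from either end of the cDNA;
#' for every placement pair the exact best split point is found from
#' cumulative match counts. The spliced optimum must beat the best
#' contiguous placement by at least `min_margin` matches (default 8,
#' guards against spurious micro-introns), otherwise the cDNA is called
#' unspliced and `NULL` is returned.
#'
#' Ties on total matches are broken by intron dinucleotides
#' (`GT..AG` > `AT..AC` > other), then smallest
#' `|donor_offset| + |acceptor_offset|`, then leftmost donor.
#'
#' @param cdna cDNA sequence (>= 60 nt, sense orientation of the model).
#' @param model a [provirus_model()].
#' @param search_window window half-width around each canonical site
#'   (default 1000 nt).
#' @param min_margin spliced-vs-contiguous match margin (default 8).
#' @param min_intron smallest intron considered (default 20 nt).
#' @return `NULL` for unspliced cDNAs, else a list: `donor_pos`,
#'   `acceptor_pos` (0-based: first intron base / first exon base after),
#'   `donor_offset`, `acceptor_offset` (signed, downstream positive),
#'   `donor_dinuc`, `acceptor_dinuc`, `intron_len`, `matches`,
#'   `contiguous_matches`, `ss_class`.
#' @export
find_junction <- function(cdna, model, search_window = 1000L,
                          min_margin = 8L, min_intron = 20L) {
  if (is.null(model$canonical_5ss) || is.null(model$canonical_3ss))
    stop("model lacks canonical splice sites")
  if (nchar(cdna) < 60L) stop("cdna shorter than 60 nt")
  n <- nchar(cdna)
  cc <- strsplit(cdna, "")[[1]]
  mc <- strsplit(model$seq, "")[[1]]
  o1s <- seed_offsets(cdna, model$seq, from_end = FALSE)
  o2s <- seed_offsets(cdna, model$seq, from_end = TRUE)
  if (!length(o1s) && !length(o2s)) return(NULL)
  contig <- 0L
  for (o in unique(c(o1s, o2s)))
    contig <- max(contig, sum(placement_matches(cc, mc, o)))
  cand <- list()
  for (o1 in o1s) for (o2 in o2s) {
    if (o2 <= o1) next
    P <- cumsum(placement_matches(cc, mc, o1))
    S <- rev(cumsum(rev(placement_matches(cc, mc, o2))))
    k <- seq_len(n - 1L)                  # split after cdna base k
    total <- P[k] + S[k + 1L]
    d <- o1 + k                           # 0-based first intron base
    a <- o2 + k                           # 0-based first exon base after
    ok <- abs(d - model$canonical_5ss) <= search_window &
      abs(a - model$canonical_3ss) <= search_window &
      (a - d) >= min_intron & d >= 1L & a <= length(mc)
    if (!any(ok)) next
    best <- max(total[ok])
    sel <- which(ok & total == best)
    cand[[length(cand) + 1L]] <- data.frame(
      donor = d[sel], acceptor = a[sel], matches = total[sel])
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  cand <- cand[cand$matches == max(cand$matches), , drop = FALSE]
  cand <- cand[!duplicated(cand[c("donor", "acceptor")]), , drop = FALSE]
  if (cand$matches[1] < contig + min_margin) return(NULL)
  dd <- substring(model$seq, cand$donor + 1L, cand$donor + 2L)
  ad <- substring(model$seq, cand$acceptor - 1L, cand$acceptor)
  rank <- ifelse(dd == "GT" & ad == "AG", 0L,
                 ifelse(dd == "AT" & ad == "AC", 1L, 2L))
  offsum <- abs(cand$donor - model$canonical_5ss) +
    abs(cand$acceptor - model$canonical_3ss)
  ord <- order(rank, offsum, cand$donor)
  b <- cand[ord[1], ]
  jx <- list(donor_pos = b$donor, acceptor_pos = b$acceptor,
             donor_offset = b$donor - model$canonical_5ss,
             acceptor_offset = b$acceptor - model$canonical_3ss,
             donor_dinuc = substr0(model$seq, b$donor, b$donor + 2L),
             acceptor_dinuc = substr0(model$seq, b$acceptor - 2L, b$acceptor),
             intron_len = b$acceptor - b$donor,
             matches = b$matches, contiguous_matches = contig)
  jx$ss_class <- classify_sites(model, jx)
  jx
}

#' Classify the spliceosome class of an inferred junction
#'
#' Canonical when both offsets are 0; otherwise the donor decides:
#' an intron starting `GT` is a major-spliceosome (U2-type) alternative
#' site; a donor matching the U12-type consensus (`[GA]TATCC` at the
#' intron start; the minor-spliceosome pattern adopted here, configurable)
#' is `alt_minor`; anything else `non_canonical`. The acceptor
#' dinucleotide is reported alongside but does not decide the class.
#'
#' @param model a [provirus_model()].
#' @param junction junction list with `donor_pos`/`acceptor_pos` (or the
#'   offsets) as returned by [find_junction()].
#' @param minor_donor_pattern regex matched against the first 6 intron nt.
#' @return one of `"canonical"`, `"alt_major"`, `"alt_minor"`,
#'   `"non_canonical"`.
#' @export
classify_sites <- function(model, junction,
                           minor_donor_pattern = "^[GA]TATCC") {
  d <- junction$donor_pos; a <- junction$acceptor_pos
  if (d < 0 || a > nchar(model$seq))
    stop("junction positions outside the model")
  if (d == model$canonical_5ss && a == model$canonical_3ss)
    return("canonical")
  intron_start <- substr0(model$seq, d, min(d + 6L, nchar(model$seq)))
  if (substr(intron_start, 1L, 2L) == "GT") return("alt_major")
  if (grepl(minor_donor_pattern, intron_start)) return("alt_minor")
  "non_canonical"
}

# --- provirus typing -------------------------------------------------------

#' Deletions in a query relative to a reference sequence
#'
#' Global pairwise alignment (unit match/mismatch, affine gaps open 2
#' extend 1); returns gaps in the query, in reference coordinates.
#'
#' @param query,ref nucleotide strings.
#' @param min_len report deletions of at least this length.
#' @return data.frame `start`, `end` (0-based half-open on `ref`), `width`.
#' @export
find_deletions <- function(query, ref, min_len = 1L) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = assign_submat(),
    gapOpening = 2, gapExtension = 1)
  del <- Biostrings::deletion(aln)[[1]]  # ranges on the subject, 1-based
  df <- data.frame(start = Biostrings::start(del) - 1L,
                   end = Biostrings::end(del),
                   width = Biostrings::width(del))
  df[df$width >= min_len, , drop = FALSE]
}

#' Type a provirus by the 292-bp pol–env segment
#'
#' Aligns a locus sequence to a type II reference model and looks for a
#' deletion of 292 +/- `tol` bp overlapping the reference's
#' `type2_segment`: present -> type I; absent -> type II. Loci are never
#' typed I unless such a deletion actually overlaps the segment.
#'
#' @param locus_seq locus nucleotide sequence (alignable to the reference).
#' @param reference a type II [provirus_model()].
#' @param tol deletion-length tolerance (default 10 bp).
#' @return list: `provirus_type` (`"I"`/`"II"`), `deletion_len` (exact bp,
#'   0 for type II), `deletion_locus` (`c(start, end)` on the reference or
#'   `NULL`).
#' @export
detect_type <- function(locus_seq, reference, tol = 10L) {
  if (is.null(reference$type2_segment))
    stop("reference model must be type II (have a type2_segment)")
  seg <- reference$type2_segment
  dels <- find_deletions(locus_seq, reference$seq, min_len = 50L)
  if (nrow(dels)) {
    ov <- pmin(dels$end, seg[2]) - pmax(dels$start, seg[1])
    hit <- which(ov > 0L & abs(dels$width - 292L) <= tol)
    if (length(hit)) {
      h <- hit[which.max(ov[hit])]
      return(list(provirus_type = "I", deletion_len = dels$width[h],
                  deletion_locus = c(dels$start[h], dels$end[h])))
    }
  }
  list(provirus_type = "II", deletion_len = 0L, deletion_locus = NULL)
}

# --- in-silico PCR ---------------------------------------------------------

# primer binding sites on a template: forward primer as-is, reverse primer
# as its reverse complement; <= max_mismatch mismatches.
primer_sites <- function(template, primer, max_mismatch = 1L) {
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(template),
                                max.mismatch = max_mismatch)
  data.frame(start = Biostrings::start(m) - 1L, end = Biostrings::end(m))
}

#' Predict PCR amplicon sizes on a template
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer (each with at most `max_mismatch` mismatches) and returns every
#' in-order product up to `max_len`; products include both primers. On a
#' type II model versus its type I counterpart, a pair flanking the
#' pol–env segment yields products differing by exactly 292 bp.
#'
#' @param template template sequence (model sequence or transcript).
#' @param primer_pair list/row with elements `fwd` and `rev` (both 5'->3',
#'   `rev` on the antisense strand).
#' @param max_mismatch per-primer mismatch allowance (default 1).
#' @param max_len product length cap (default 5000 bp).
#' @return data.frame `start`, `end` (0-based half-open on the template),
#'   `length`; zero rows when a primer finds no site.
#' @export
predict_amplicon_sizes <- function(template, primer_pair, max_mismatch = 1L,
                                   max_len = 5000L) {
  fwd <- primer_sites(template, primer_pair$fwd, max_mismatch)
  rev <- primer_sites(template, unname(revcomp(primer_pair$rev)), max_mismatch)
  out <- data.frame(start = integer(), end = integer(), length = integer())
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
    if (rev$end[j] > fwd$start[i]) {
      len <- rev$end[j] - fwd$start[i]
      if (len <= max_len && rev$start[j] >= fwd$end[i])
        out <- rbind(out, data.frame(start = fwd$start[i], end = rev$end[j],
                                     length = len))
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}
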