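#' Parse a RepeatMasker-style repeat table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`ucsc_rmsk_tsv`}{UCSC Table Browser rmsk export: TSV with a header
#'     naming at least `genoName`, `genoStart`, `genoEnd`, `strand`,
#'     `repName`; `repClass` and `id` are carried when present.
#'     Coordinates are already 0-based half-open.}
#'   \item{`rm_out`}{native RepeatMasker `.out`: whitespace table after the
#'     three header lines, 1-based inclusive coordinates, strand `C` for
#'     the reverse strand, final column the fragment-joining ID.}
#' }
#'
#' @param path input file.
#' @param dialect `"ucsc_rmsk_tsv"` or `"rm_out"`.
#' @return data.frame of fragments in internal 0-based half-open
#'   coordinates, input order preserved: columns `chrom`, `start`, `end`,
#'   `strand`, `rep_name`, `rep_class`, `element_id`.
#' @export
parse_repeat_table <- function(path, dialect = c("ucsc_rmsk_tsv", "rm_out")) {
  dialect <- match.arg(dialect)
  if (dialect == "ucsc_rmsk_tsv") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) return(empty_fragments())
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (nrow(df) == 0L) return(empty_fragments())
    names(df) <- sub("^#", "", names(df))
    need <- c("genoName", "genoStart", "genoEnd", "strand", "repName")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("ucsc_rmsk_tsv input lacks column(s): ", paste(miss, collapse = ", "))
    starts <- suppressWarnings(as.integer(df$genoStart))
    ends <- suppressWarnings(as.integer(df$genoEnd))
    bad <- which(is.na(starts) | is.na(ends))
    if (length(bad))
      stop("non-integer coordinates at data line ", bad[1])
    out <- data.frame(chrom = as.character(df$genoName),
                      start = starts, end = ends,
                      strand = as.character(df$strand),
                      rep_name = as.character(df$repName),
                      rep_class = if ("repClass" %in% names(df))
                        as.character(df$repClass) else NA_character_,
                      element_id = if ("id" %in% names(df))
                        suppressWarnings(as.integer(df$id)) else NA_integer_,
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    # drop the two banner lines (start with "SW"/"score") if present
    lines <- lines[!grepl("^\\s*(SW|score)", lines)]
    if (length(lines) == 0L) return(empty_fragments())
    fields <- strsplit(trimws(lines), "\\s+")
    parse_row <- function(f, i) {
      if (length(f) < 14L)
        stop("rm_out line ", i, " has ", length(f), " fields; expected >= 14")
      beg <- suppressWarnings(as.integer(f[6])); en <- suppressWarnings(as.integer(f[7]))
      if (is.na(beg) || is.na(en))
        stop("non-integer coordinates at data line ", i)
      data.frame(chrom = f[5], start = beg - 1L, end = en,
                 strand = if (f[9] == "C") "-" else "+",
                 rep_name = f[10], rep_class = f[11],
                 element_id = suppressWarnings(as.integer(f[length(f)])),
                 stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, Map(parse_row, fields, seq_along(fields)))
  }
  rownames(out) <- NULL
  validate_intervals(out)
  out
}

empty_fragments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), rep_name = character(),
             rep_class = character(), element_id = integer(),
             stringsAsFactors = FALSE)
}

#' Default HERV-K RepeatMasker names
#'
#' The three human-specific HERV-K LTR subfamilies plus the internal
#' proviral segment name, as annotated by RepeatMasker/RepBase.
#' @export
hervk_ltr_names <- c("LTR5_Hs", "LTR5A", "LTR5B")

#' @rdname hervk_ltr_names
#' @export
hervk_internal_names <- "HERVK-int"

#' Filter fragments to HERV-K LTR and internal classes
#'
#' Partitions a fragment table by `rep_name`: LTR names on one side,
#' internal-segment names on the other; everything else dropped.
#'
#' @param fragments fragment data.frame from [parse_repeat_table()].
#' @param ltr_names,internal_names name sets; defaults are the HERV-K ones.
#' @return list with elements `ltr` and `internal` (fragment data.frames).
#' @export
filter_hervk <- function(fragments, ltr_names = hervk_ltr_names,
                         internal_names = hervk_internal_names) {
  list(ltr = fragments[fragments$rep_name %in% ltr_names, , drop = FALSE],
       internal = fragments[fragments$rep_name %in% internal_names, , drop = FALSE])
}

#' Fragment size histogram
#'
#' Bins fragment lengths into fixed-width windows: a fragment of length L
#' falls in bin `floor(L / window_bp)`, i.e. window `[k*w, (k+1)*w)`. The
#' paper-style views use 20-bp windows for LTR fragments and 200-bp windows
#' for internal segments.
#'
#' @param fragments fragment data.frame (or an integer vector of lengths).
#' @param window_bp positive window width in bp.
#' @return data.frame `bin_start`, `bin_end`, `count` (only occupied bins),
#'   with `sum(count) == n fragments`.
#' @export
size_histogram <- function(fragments, window_bp) {
  stopifnot(window_bp > 0)
  lens <- if (is.data.frame(fragments)) interval_length(fragments)
          else as.integer(fragments)
  k <- floor(lens / window_bp)
  tab <- table(k)
  idx <- as.integer(names(tab))
  data.frame(bin_start = idx * as.integer(window_bp),
             bin_end = (idx + 1L) * as.integer(window_bp),
             count = as.integer(tab))
}

#' Fragment catalog statistics
#'
#' Mean fragment length, the fraction of a full-length element it
#' represents, and the implied fragments-per-element ratio. The per-element
#' full length is supplied by the caller (about 7,500 bp for the HERV-K
#' internal segment, 968 bp for the LTR).
#'
#' @param fragments fragment data.frame.
#' @param full_length_bp full-length element size in bp.
#' @return a `catalog_stats` list; see [stats_from_totals()].
#' @export
catalog_stats <- function(fragments, full_length_bp) {
  if (nrow(fragments) < 1L) stop("catalog_stats needs at least one fragment")
  stats_from_totals(nrow(fragments), sum(interval_length(fragments)),
                    full_length_bp)
}

#' Catalog statistics from totals
#'
#' Same arithmetic as [catalog_stats()] but starting from the fragment
#' count and total bp directly (useful when only published totals are
#' available). Reports both the real-valued mean/percentage and their
#' nearest-integer renderings.
#'
#' @param n_fragments fragment count (>= 1).
#' @param total_bp summed fragment length.
#' @param full_length_bp full-length element size in bp (> 0).
#' @return list with `n_fragments`, `total_bp`, `mean_len`, `mean_len_int`,
#'   `pct_of_full`, `pct_of_full_int`, `frags_per_element`.
#' @examples
#' s <- stats_from_totals(255, 487441, 7500)
#' s$mean_len_int     # 1911
#' s$pct_of_full_int  # 25
#' @export
stats_from_totals <- function(n_fragments, total_bp, full_length_bp) {
  stopifnot(n_fragments >= 1, full_length_bp > 0)
  mean_len <- total_bp / n_fragments
  pct <- 100 * mean_len / full_length_bp
  # integer rendering truncates (487,441/255 = 1911.5 prints as 1,911)
  structure(list(n_fragments = as.integer(n_fragments),
                 total_bp = total_bp,
                 mean_len = mean_len,
                 mean_len_int = as.integer(trunc(mean_len)),
                 pct_of_full = pct,
                 pct_of_full_int = as.integer(round(pct)),
                 frags_per_element = full_length_bp / mean_len),
            class = "catalog_stats")
}

#' @export
print.catalog_stats <- function(x, ...) {
  cat(sprintf("%d fragments, %s bp total\n", x$n_fragments,
              formatC(x$total_bp, format = "d", big.mark = ",")))
  cat(sprintf("mean length %.1f bp (~%d), %.1f%% (~%d%%) of full length, ~%.1f fragments/element\n",
              x$mean_len, x$mean_len_int, x$pct_of_full, x$pct_of_full_int,
              x$frags_per_element))
  invisible(x)
}

#' Cluster fragments into elements and classify them
#'
#' RepeatMasker reports one row per contiguous masked segment, so a single
#' provirus disrupted by insertions or a type-I deletion appears as several
#' fragments. This groups same-chromosome, same-strand fragments into
#' elements — by RepeatMasker joining ID when available, positionally
#' (gap <= `gap_tol_bp`) otherwise — and calls each element:
#' \itemize{
#'   \item `provirus`: >= 1 internal fragment plus >= 1 LTR fragment;
#'   \item `solo_ltr`: LTR-only element covering >= 50% of `ltr_full_bp`;
#'   \item `ltr_fragment`: LTR-only element below that;
#'   \item `internal_only`: internal fragments with no LTR.
#' }
#' Overlapping same-strand fragments are merged with a warning.
#'
#' @param ltr_fragments,internal_fragments fragment data.frames from
#'   [filter_hervk()].
#' @param gap_tol_bp positional clustering gap tolerance (default 2000 bp:
#'   above typical masker split gaps, below simulator inter-element spacing).
#' @param ltr_full_bp full LTR length (968 bp for human-specific HERV-K).
#' @return data.frame, one row per element: `chrom`, `start`, `end`,
#'   `strand`, `kind`, `n_fragments`, `n_ltr`, `n_internal`, `ltr_bp`,
#'   `internal_bp`, `members` (comma-joined input row labels).
#' @export
classify_elements <- function(ltr_fragments, internal_fragments,
                              gap_tol_bp = 2000L, ltr_full_bp = 968L) {
  ltr <- ltr_fragments; int <- internal_fragments
  if (nrow(ltr)) ltr$.cls <- "ltr"
  if (nrow(int)) int$.cls <- "internal"
  frags <- rbind(if (nrow(ltr)) ltr else NULL,
                 if (nrow(int)) int else NULL)
  if (is.null(frags) || nrow(frags) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      kind = character(), n_fragments = integer(),
                      n_ltr = integer(), n_internal = integer(),
                      ltr_bp = integer(), internal_bp = integer(),
                      members = character(), stringsAsFactors = FALSE))
  frags$.row <- seq_len(nrow(frags))
  out <- list()
  for (key in unique(paste(frags$chrom, frags$strand))) {
    sub <- frags[paste(frags$chrom, frags$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (any(sub$start[-1] < sub$end[-nrow(sub)]) && nrow(sub) > 1L)
      warning("overlapping same-strand fragments on ", key, "; merging")
    grp <- if (all(!is.na(sub$element_id)) && length(unique(sub$element_id)) > 0L)
      sub$element_id
    else
      cumsum(c(0L, as.integer(sub$start[-1] - cummax(sub$end)[-nrow(sub)] > gap_tol_bp)))
    for (g in unique(grp)) {
      m <- sub[grp == g, , drop = FALSE]
      n_ltr <- sum(m$.cls == "ltr"); n_int <- sum(m$.cls == "internal")
      ltr_bp <- sum(interval_length(m)[m$.cls == "ltr"])
      int_bp <- sum(interval_length(m)[m$.cls == "internal"])
      kind <- if (n_int >= 1L && n_ltr >= 1L) "provirus"
        else if (n_int >= 1L) "internal_only"
        else if (ltr_bp >= 0.5 * ltr_full_bp) "solo_ltr"
        else "ltr_fragment"
      out[[length(out) + 1L]] <- data.frame(
        chrom = m$chrom[1], start = min(m$start), end = max(m$end),
        strand = m$strand[1], kind = kind, n_fragments = nrow(m),
        n_ltr = n_ltr, n_internal = n_int,
        ltr_bp = ltr_bp, internal_bp = int_bp,
        members = paste(m$.row, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write fragments as BED6
#'
#' @param fragments fragment data.frame; `rep_name` becomes the BED name.
#' @param path output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(fragments$chrom, fragments$start, fragments$end,
                    fragments$rep_name, 0L,
                    ifelse(fragments$strand == ".", ".", fragments$strand))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
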