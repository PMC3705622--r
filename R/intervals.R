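#' Genome intervals
#'
#' Internal coordinates are 0-based half-open everywhere in this package;
#' 1-based inclusive coordinates appear only in UCSC-style display strings
#' and RepeatMasker `.out` input. `genome_interval()` builds a validated
#' one-row interval; vectors are recycled the usual way.
#'
#' @param chrom chromosome (or contig) names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   and class `c("genome_interval", "data.frame")`.
#' @examples
#' genome_interval("chr1", 0L, 968L, "+")
#' @export
genome_interval <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genome_interval", "data.frame")
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval coordinates must be non-missing integers")
  if (any(df$start < 0L))
    stop("interval start must be >= 0 (0-based half-open convention)")
  if (any(df$start >= df$end))
    stop("interval must satisfy start < end (0-based half-open convention)")
  bad <- setdiff(unique(df$strand), c("+", "-", "."))
  if (length(bad))
    stop("strand must be one of '+', '-', '.'; got: ", paste(bad, collapse = ", "))
  invisible(df)
}

#' Interval lengths
#'
#' @param x a `genome_interval` or any data.frame with `start`/`end`.
#' @return integer vector of `end - start`.
#' @export
interval_length <- function(x) as.integer(x$end - x$start)

#' Parse a UCSC-style coordinate span
#'
#' Converts a display span such as `"1q22:155,596,457-155,605,636"` (1-based
#' inclusive, thousands separators optional, en-dash or ASCII hyphen) into an
#' internal 0-based half-open interval. A bare `"<int>-<int>"` span is
#' accepted; its chromosome is recorded as `"."`.
#'
#' @param text character vector of spans.
#' @param strand strand to record (display spans carry none).
#' @return a `genome_interval` with one row per input span.
#' @examples
#' sp <- parse_ucsc_span("155,596,457–155,605,636")
#' interval_length(sp)  # 9180
#' @export
parse_ucsc_span <- function(text, strand = ".") {
  one <- function(t0) {
    t <- gsub("–", "-", t0, fixed = TRUE)  # en-dash -> hyphen
    chrom <- "."
    if (grepl(":", t, fixed = TRUE)) {
      parts <- strsplit(t, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("malformed span (multiple ':'): ", t0)
      chrom <- parts[1]
      t <- parts[2]
    }
    m <- regexec("^\\s*([0-9][0-9,]*)-([0-9][0-9,]*)\\s*$", t)
    g <- regmatches(t, m)[[1]]
    if (length(g) != 3L)
      stop("malformed coordinate span: '", t0, "' (offending token: '", t, "')")
    a <- as.numeric(gsub(",", "", g[2], fixed = TRUE))
    b <- as.numeric(gsub(",", "", g[3], fixed = TRUE))
    if (a > b)
      stop("span start exceeds end in: ", t0)
    c(chrom = chrom, start = a - 1, end = b)
  }
  parsed <- lapply(text, one)
  genome_interval(chrom = vapply(parsed, `[[`, "", "chrom"),
                  start = as.numeric(vapply(parsed, `[[`, "", "start")),
                  end = as.numeric(vapply(parsed, `[[`, "", "end")),
                  strand = strand)
}

#' Format an interval as a UCSC-style display span
#'
#' Inverse of [parse_ucsc_span()]: 0-based half-open back to 1-based
#' inclusive with thousands separators.
#'
#' @param x a `genome_interval`.
#' @param sep separator, en-dash by default to match UCSC rendering.
#' @return character vector of spans.
#' @export
format_ucsc_span <- function(x, sep = "–") {
  fmt <- function(n) formatC(n, format = "d", big.mark = ",")
  pre <- ifelse(x$chrom == ".", "", paste0(x$chrom, ":"))
  paste0(pre, fmt(x$start + 1L), sep, fmt(x$end))
}

# GRanges bridge: internal 0-based half-open -> 1-based inclusive GRanges.
as_granges <- function(df, id = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand == ".", "*", df$strand))
  if (!is.null(id)) S4Vectors::mcols(gr)$id <- id
  gr
}
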