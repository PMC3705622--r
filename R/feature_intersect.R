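#' Read locus intervals from BED6
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return data.frame `locus_id`, `chrom`, `start`, `end`, `strand`
#'   (internal 0-based half-open, which BED already uses).
#' @export
read_loci_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("expected BED6 (6 columns), got ", ncol(df))
  out <- data.frame(locus_id = as.character(df[[4]]),
                    chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    strand = as.character(df[[6]]),
                    stringsAsFactors = FALSE)
  validate_intervals(out)
  out
}

#' Read gene features from GTF
#'
#' Imports gene/exon/CDS/UTR records via \pkg{rtracklayer} and derives
#' introns as gene-minus-exons when no intron records are present. Feature
#' kinds are normalized to `gene`, `exon`, `intron`, `utr5`, `utr3`, `cds`.
#'
#' @param path GTF file.
#' @param coding_ids optional character vector of gene_ids to flag coding;
#'   by default a gene is coding iff it has any CDS record.
#' @return data.frame `gene_id`, `kind`, `chrom`, `start`, `end`, `strand`,
#'   `coding` (0-based half-open internally).
#' @export
read_gene_gtf <- function(path, coding_ids = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  kind_map <- c(gene = "gene", transcript = NA, exon = "exon", CDS = "cds",
                five_prime_utr = "utr5", three_prime_utr = "utr3",
                "5UTR" = "utr5", "3UTR" = "utr3", UTR = NA, intron = "intron")
  typ <- as.character(gr$type)
  kind <- unname(kind_map[typ])
  keep <- !is.na(kind)
  df <- data.frame(gene_id = as.character(gr$gene_id[keep]),
                   kind = kind[keep],
                   chrom = as.character(GenomicRanges::seqnames(gr)[keep]),
                   start = GenomicRanges::start(gr)[keep] - 1L,
                   end = GenomicRanges::end(gr)[keep],
                   strand = as.character(GenomicRanges::strand(gr)[keep]),
                   stringsAsFactors = FALSE)
  if (is.null(coding_ids))
    coding_ids <- unique(df$gene_id[df$kind == "cds"])
  df$coding <- df$gene_id %in% coding_ids
  if (!any(df$kind == "intron")) df <- rbind(df, derive_introns(df))
  rownames(df) <- NULL
  df
}

# introns = gene span minus exons, per gene
derive_introns <- function(features) {
  out <- list()
  for (g in unique(features$gene_id)) {
    gene <- features[features$gene_id == g & features$kind == "gene", , drop = FALSE]
    ex <- features[features$gene_id == g & features$kind == "exon", , drop = FALSE]
    if (nrow(gene) != 1L || nrow(ex) < 2L) next
    ex <- ex[order(ex$start), , drop = FALSE]
    istart <- ex$end[-nrow(ex)]; iend <- ex$start[-1]
    ok <- istart < iend
    if (!any(ok)) next
    out[[g]] <- data.frame(gene_id = g, kind = "intron", chrom = gene$chrom,
                           start = istart[ok], end = iend[ok],
                           strand = gene$strand, coding = gene$coding,
                           stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    features[0, , drop = FALSE]
}

#' Intersect loci with gene features
#'
#' One record per (locus, feature) pair overlapping by at least
#' `min_overlap` nt (the published rule is 1 nt). Orientation is `same`
#' iff strands are equal; strandless loci (`.`) are counted as `same` by
#' convention and flagged in the `strandless` column.
#'
#' @param loci data.frame from [read_loci_bed()] (columns `locus_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param features data.frame from [read_gene_gtf()].
#' @param min_overlap minimum overlap in nt (>= 1).
#' @return data.frame `locus_id`, `gene_id`, `feature_kind`, `coding`,
#'   `orientation`, `overlap_bp`, `strandless`.
#' @export
intersect_loci <- function(loci, features, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  empty <- data.frame(locus_id = character(), gene_id = character(),
                      feature_kind = character(), coding = logical(),
                      orientation = character(), overlap_bp = integer(),
                      strandless = logical(), stringsAsFactors = FALSE)
  if (nrow(loci) == 0L || nrow(features) == 0L) return(empty)
  lg <- as_granges(loci); fg <- as_granges(features)
  hits <- GenomicRanges::findOverlaps(lg, fg, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(lg)[qi],
                                           IRanges::ranges(fg)[si]))
  strandless <- loci$strand[qi] == "."
  same <- strandless | (loci$strand[qi] == features$strand[si])
  out <- data.frame(locus_id = loci$locus_id[qi],
                    gene_id = features$gene_id[si],
                    feature_kind = features$kind[si],
                    coding = features$coding[si],
                    orientation = ifelse(same, "same", "opposite"),
                    overlap_bp = as.integer(ov),
                    strandless = strandless,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify a locus as intergenic or intragenic
#'
#' A locus is intragenic iff it overlaps >= 1 gene span (transcribed
#' portion); a locus under two genes transcribed in opposite directions
#' contributes one orientation count per gene (the published
#' double-counting rule).
#'
#' @param records overlap records from [intersect_loci()].
#' @param loci the locus table (for loci with no records at all).
#' @return data.frame `locus_id`, `context` (`intergenic`/`intragenic`),
#'   `n_same`, `n_opposite` (distinct overlapping genes per orientation).
#' @export
classify_context <- function(records, loci) {
  gene_rec <- records[records$feature_kind == "gene", , drop = FALSE]
  per <- lapply(loci$locus_id, function(id) {
    r <- gene_rec[gene_rec$locus_id == id, , drop = FALSE]
    genes_same <- unique(r$gene_id[r$orientation == "same"])
    genes_opp <- unique(r$gene_id[r$orientation == "opposite"])
    data.frame(locus_id = id,
               context = if (nrow(r)) "intragenic" else "intergenic",
               n_same = length(genes_same), n_opposite = length(genes_opp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per)
}

#' Summarize overlap records into a gene-context table
#'
#' Produces the per-feature-kind, coding-status, orientation cell counts
#' plus intergenic/intragenic locus totals and the intragenic percentage.
#'
#' @param records overlap records from [intersect_loci()].
#' @param loci locus table.
#' @return list with `n_loci`, `intergenic`, `intragenic`, `pct_intragenic`,
#'   `context` (per-locus classification) and `cells` (data.frame
#'   `feature_kind`, `coding`, `n`, `same`, `opposite`).
#' @export
summarize_context <- function(records, loci) {
  ctx <- classify_context(records, loci)
  n_loci <- nrow(loci)
  intra <- sum(ctx$context == "intragenic")
  cells <- NULL
  if (nrow(records)) {
    key <- interaction(records$feature_kind, records$coding, drop = TRUE)
    cells <- do.call(rbind, lapply(split(records, key), function(r) {
      data.frame(feature_kind = r$feature_kind[1], coding = r$coding[1],
                 n = nrow(r),
                 same = sum(r$orientation == "same"),
                 opposite = sum(r$orientation == "opposite"),
                 stringsAsFactors = FALSE)
    }))
    rownames(cells) <- NULL
  } else {
    cells <- data.frame(feature_kind = character(), coding = logical(),
                        n = integer(), same = integer(), opposite = integer(),
                        stringsAsFactors = FALSE)
  }
  list(n_loci = n_loci, intergenic = n_loci - intra, intragenic = intra,
       pct_intragenic = if (n_loci) 100 * intra / n_loci else NA_real_,
       context = ctx, cells = cells)
}
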