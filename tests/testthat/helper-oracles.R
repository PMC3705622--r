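# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: the overlap oracle is a quadratic scan, the
# alignment oracle a full Gotoh DP, and both are only run at tiny sizes.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# quadratic all-pairs overlap scan on 0-based half-open intervals
brute_overlaps <- function(loci, features, min_overlap = 1L) {
  rows <- list()
  for (i in seq_len(nrow(loci))) for (j in seq_len(nrow(features))) {
    if (loci$chrom[i] != features$chrom[j]) next
    ov <- min(loci$end[i], features$end[j]) -
      max(loci$start[i], features$start[j])
    if (ov >= min_overlap) {
      strandless <- loci$strand[i] == "."
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loci$locus_id[i], gene_id = features$gene_id[j],
        feature_kind = features$kind[j], coding = features$coding[j],
        orientation = if (strandless || loci$strand[i] == features$strand[j])
          "same" else "opposite",
        overlap_bp = as.integer(ov), strandless = strandless,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(locus_id = character(), gene_id = character(),
                      feature_kind = character(), coding = logical(),
                      orientation = character(), overlap_bp = integer(),
                      strandless = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# full Gotoh local alignment DP: unit match/mismatch, gap of length L
# costs 2 + L (open 2, extend 1); returns the optimum score only
gotoh_local_score <- function(x, y) {
  xa <- strsplit(x, "")[[1]]; ya <- strsplit(y, "")[[1]]
  n <- length(xa); m <- length(ya)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)
  Iy <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (xa[i] == ya[j] && xa[i] %in% c("A", "C", "G", "T")) 1 else -1
    M[i + 1L, j + 1L] <- s + max(M[i, j], Ix[i, j], Iy[i, j], 0)
    Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - 3, Ix[i, j + 1L] - 1)
    Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - 3, Iy[i + 1L, j] - 1)
    best <- max(best, M[i + 1L, j + 1L], Ix[i + 1L, j + 1L],
                Iy[i + 1L, j + 1L])
  }
  best
}

# random locus / feature tables for the overlap oracle
rand_loci <- function(n, span = 1000L, chroms = c("c1", "c2")) {
  start <- sample(span, n, TRUE)
  data.frame(locus_id = sprintf("L%03d", seq_len(n)),
             chrom = sample(chroms, n, TRUE),
             start = start, end = start + sample(50L, n, TRUE),
             strand = sample(c("+", "-", "."), n, TRUE, c(.45, .45, .1)),
             stringsAsFactors = FALSE)
}

rand_features <- function(n, span = 1000L, chroms = c("c1", "c2")) {
  start <- sample(span, n, TRUE)
  data.frame(gene_id = sprintf("G%03d", seq_len(n)),
             kind = sample(c("gene", "exon", "intron", "cds"), n, TRUE),
             chrom = sample(chroms, n, TRUE),
             start = start, end = start + sample(80L, n, TRUE),
             strand = sample(c("+", "-"), n, TRUE),
             coding = sample(c(TRUE, FALSE), n, TRUE),
             stringsAsFactors = FALSE)
}

# canonical overlap-record ordering so record sets compare as sets
sort_records <- function(df) {
  df <- df[do.call(order, df[c("locus_id", "gene_id", "feature_kind",
                               "coding", "orientation", "overlap_bp")]), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# a small provirus-like model with controlled junction context, for
# splice tests that must not depend on the full generator
tiny_model <- function(seed = 1L, len = 3000L, ss5 = 600L, ss3 = 2200L) {
  set.seed(seed)
  s <- rand_seq(len)
  s <- paste0(substr(s, 1, ss5), "GTAAGT", substr(s, ss5 + 7L, len))
  s <- paste0(substr(s, 1, ss3 - 2L), "AG", substr(s, ss3 + 1L, len))
  provirus_model(s, ltr5 = c(0L, 100L), ltr3 = c(len - 100L, len),
                 canonical_5ss = ss5, canonical_3ss = ss3,
                 r_region = c(10L, 60L))
}

# independent substitution-noise model for test inputs
mutate_noise <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# excise [d, a) from a sequence (0-based half-open)
excise <- function(seq, d, a) paste0(substr(seq, 1, d),
                                     substr(seq, a + 1L, nchar(seq)))
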