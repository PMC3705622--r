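#' Read a Ct measurement table
#'
#' TSV with header columns `sample`, `amplicon`, `ct` (one row per
#' replicate). Ct values must lie in (0, 60).
#'
#' @param path TSV path.
#' @return data.frame `sample`, `amplicon`, `ct`.
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "amplicon", "ct")
  if (!all(need %in% names(df)))
    stop("Ct TSV needs columns: ", paste(need, collapse = ", "))
  df$ct <- as.numeric(df$ct)
  if (any(is.na(df$ct)) || any(df$ct <= 0 | df$ct >= 60))
    stop("Ct values must be numeric and in (0, 60)")
  df[need]
}

#' Delta-Ct between two amplicons of one sample
#'
#' `mean(reference replicates) - mean(target replicates)`: a more abundant
#' target crosses threshold earlier (lower Ct), giving a positive delta.
#' In the solo-LTR analysis the reference is the env amplicon and the
#' target the LTR amplicon.
#'
#' @param reference_cts,target_cts numeric replicate Ct vectors.
#' @return delta-Ct in cycles.
#' @examples
#' delta_ct(30.0, 22.8)  # 7.2
#' @export
delta_ct <- function(reference_cts, target_cts) {
  if (!length(reference_cts) || !length(target_cts))
    stop("delta_ct: empty replicate set")
  mean(reference_cts) - mean(target_cts)
}

#' Fold change implied by a delta-Ct
#'
#' `efficiency ^ delta_ct`, with the usual perfect-doubling default
#' `efficiency = 2`. Strictly increasing in delta-Ct and multiplicative:
#' `fold(a + b) = fold(a) * fold(b)`.
#'
#' @param delta_ct cycles.
#' @param efficiency amplification base, in (1, 2].
#' @return fold difference (> 0).
#' @examples
#' fold_change(7.2)  # ~147, i.e. >= 100-fold
#' @export
fold_change <- function(delta_ct, efficiency = 2) {
  stopifnot(efficiency > 1, efficiency <= 2)
  efficiency ^ delta_ct
}

#' Solo-LTR transcript excess
#'
#' Proviral transcripts carry two copies of the LTR R region per env copy
#' (transcription runs R-to-R), so an LTR/env fold of exactly `r_copies`
#' (default 2) is what proviral transcription alone explains. The excess
#' ratio `fold / r_copies` measures LTR signal beyond that; values > 1
#' indicate transcription of solo LTRs, values < 1 a deficit (flagged).
#'
#' @param fold LTR/env fold difference.
#' @param r_copies R-region copies per proviral transcript (default 2).
#' @return list `excess` (ratio) and `deficit` (TRUE when excess < 1).
#' @export
solo_ltr_excess <- function(fold, r_copies = 2L) {
  stopifnot(r_copies >= 1L)
  ex <- fold / r_copies
  list(excess = ex, deficit = ex < 1)
}

#' Normalize target Cts to housekeeping controls
#'
#' Standard delta-Ct normalization, one value per control gene (controls
#' are reported separately, never averaged).
#'
#' @param target_cts numeric replicate Cts of the target amplicon.
#' @param housekeeping a named list of replicate Ct vectors, one entry per
#'   control gene measured in the same sample.
#' @return named numeric vector: `mean(target) - mean(control)` per control.
#' @export
normalize_to_housekeeping <- function(target_cts, housekeeping) {
  if (!length(housekeeping) || is.null(names(housekeeping)))
    stop("housekeeping controls missing or unnamed")
  vapply(housekeeping, function(h) {
    if (!length(h)) stop("empty housekeeping replicate set")
    mean(target_cts) - mean(h)
  }, numeric(1))
}

#' Per-sample LTR-vs-env quantification table
#'
#' Applies [delta_ct()], [fold_change()] and [solo_ltr_excess()] to every
#' sample of a Ct table, and appends the across-sample mean delta-Ct as a
#' final row (reported separately from the per-sample values).
#'
#' @param ct_df Ct table from [read_ct_tsv()].
#' @param reference_amplicon,target_amplicon amplicon names (defaults
#'   `"q-env"` / `"q-LTR"`).
#' @param efficiency amplification base.
#' @param r_copies R copies per proviral transcript.
#' @return data.frame `sample`, `delta_ct`, `fold`, `solo_ltr_excess`.
#' @export
quantify_ltr_excess <- function(ct_df, reference_amplicon = "q-env",
                                target_amplicon = "q-LTR",
                                efficiency = 2, r_copies = 2L) {
  samples <- unique(ct_df$sample)
  rows <- lapply(samples, function(s) {
    ref <- ct_df$ct[ct_df$sample == s & ct_df$amplicon == reference_amplicon]
    tgt <- ct_df$ct[ct_df$sample == s & ct_df$amplicon == target_amplicon]
    if (!length(ref) || !length(tgt))
      stop("sample ", s, " lacks amplicon ", reference_amplicon, " or ",
           target_amplicon)
    dct <- delta_ct(ref, tgt)
    f <- fold_change(dct, efficiency)
    data.frame(sample = s, delta_ct = dct, fold = f,
               solo_ltr_excess = solo_ltr_excess(f, r_copies)$excess,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mdct <- mean(out$delta_ct)
  mf <- fold_change(mdct, efficiency)
  rbind(out, data.frame(sample = "mean", delta_ct = mdct, fold = mf,
                        solo_ltr_excess = solo_ltr_excess(mf, r_copies)$excess,
                        stringsAsFactors = FALSE))
}
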