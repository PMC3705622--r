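log_line <- function(log, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE, sep = "")
  invisible(msg)
}

ensure_dir <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Catalog stage: repeat table to histograms and statistics
#'
#' Parses a repeat table, filters the HERV-K names, and writes fragment
#' BED, size histograms (20-bp windows for LTR fragments, `window_bp` for
#' internal ones), catalog statistics, and element calls.
#'
#' @param rmsk_path repeat table path.
#' @param out_dir output directory.
#' @param dialect table dialect (see [parse_repeat_table()]).
#' @param window_bp internal-segment histogram window (default 200).
#' @param ltr_window_bp LTR histogram window (default 20).
#' @param full_internal_bp,full_ltr_bp full-length element sizes.
#' @param gap_tol_bp element clustering tolerance.
#' @return list of result objects, invisibly; files under `out_dir`.
#' @export
run_catalog <- function(rmsk_path, out_dir, dialect = "ucsc_rmsk_tsv",
                        window_bp = 200L, ltr_window_bp = 20L,
                        full_internal_bp = 7500L, full_ltr_bp = 968L,
                        gap_tol_bp = 2000L) {
  if (!file.exists(rmsk_path)) stop("input file not found: ", rmsk_path)
  ensure_dir(out_dir)
  log <- file.path(out_dir, "run.log")
  log_line(log, "catalog: dialect=%s window=%d ltr_window=%d gap_tol=%d",
           dialect, window_bp, ltr_window_bp, gap_tol_bp)
  frags <- parse_repeat_table(rmsk_path, dialect)
  parts <- filter_hervk(frags)
  write_fragments_bed(rbind(parts$ltr, parts$internal),
                      file.path(out_dir, "fragments.bed"))
  h_ltr <- size_histogram(parts$ltr, ltr_window_bp)
  h_int <- size_histogram(parts$internal, window_bp)
  write_tsv(h_ltr, file.path(out_dir, "hist_ltr.tsv"))
  write_tsv(h_int, file.path(out_dir, "hist_internal.tsv"))
  stats <- list(
    ltr = if (nrow(parts$ltr)) catalog_stats(parts$ltr, full_ltr_bp),
    internal = if (nrow(parts$internal))
      catalog_stats(parts$internal, full_internal_bp))
  sdf <- do.call(rbind, lapply(names(stats), function(k) {
    s <- stats[[k]]
    if (is.null(s)) return(NULL)
    data.frame(class = k, n_fragments = s$n_fragments, total_bp = s$total_bp,
               mean_len = s$mean_len, mean_len_int = s$mean_len_int,
               pct_of_full = s$pct_of_full, pct_of_full_int = s$pct_of_full_int,
               frags_per_element = s$frags_per_element)
  }))
  write_tsv(sdf, file.path(out_dir, "stats.tsv"))
  elements <- classify_elements(parts$ltr, parts$internal, gap_tol_bp,
                                full_ltr_bp)
  write_tsv(elements, file.path(out_dir, "elements.tsv"))
  log_line(log, "catalog: %d LTR + %d internal fragments, %d elements",
           nrow(parts$ltr), nrow(parts$internal), nrow(elements))
  invisible(list(fragments = frags, ltr_hist = h_ltr, internal_hist = h_int,
                 stats = stats, elements = elements))
}

#' Intersect stage: loci vs gene models
#'
#' @param loci_bed BED6 of loci.
#' @param gtf gene-model GTF.
#' @param out_dir output directory.
#' @param min_overlap minimum overlap (nt).
#' @return list(`records`, `summary`), invisibly; TSVs under `out_dir`.
#' @export
run_intersect <- function(loci_bed, gtf, out_dir, min_overlap = 1L) {
  for (p in c(loci_bed, gtf))
    if (!file.exists(p)) stop("input file not found: ", p)
  ensure_dir(out_dir)
  log <- file.path(out_dir, "run.log")
  log_line(log, "intersect: min_overlap=%d", min_overlap)
  loci <- read_loci_bed(loci_bed)
  features <- read_gene_gtf(gtf)
  records <- intersect_loci(loci, features, min_overlap)
  summ <- summarize_context(records, loci)
  write_tsv(records, file.path(out_dir, "overlaps.tsv"))
  write_tsv(summ$context, file.path(out_dir, "context.tsv"))
  write_tsv(summ$cells, file.path(out_dir, "summary_cells.tsv"))
  write_tsv(data.frame(n_loci = summ$n_loci, intergenic = summ$intergenic,
                       intragenic = summ$intragenic,
                       pct_intragenic = summ$pct_intragenic),
            file.path(out_dir, "summary.tsv"))
  invisible(list(records = records, summary = summ))
}

#' Assign stage: clones vs candidate loci
#'
#' @param clones_fa clone FASTA.
#' @param candidates_fa candidate-locus FASTA.
#' @param out_dir output directory.
#' @param min_identity identity threshold (percent, default 99).
#' @return assignment report data.frame, invisibly; TSVs under `out_dir`.
#' @export
run_assign <- function(clones_fa, candidates_fa, out_dir,
                       min_identity = 99) {
  for (p in c(clones_fa, candidates_fa))
    if (!file.exists(p)) stop("input file not found: ", p)
  ensure_dir(out_dir)
  log <- file.path(out_dir, "run.log")
  log_line(log, "assign: min_identity=%.2f", min_identity)
  report <- assign_clones(read_fasta(clones_fa), read_fasta(candidates_fa),
                          min_identity)
  write_tsv(report, file.path(out_dir, "assignments.tsv"))
  write_tsv(report[report$status == "below_threshold", , drop = FALSE],
            file.path(out_dir, "below_threshold.tsv"))
  invisible(report)
}

#' Splice stage: junction inference for a cDNA set
#'
#' @param cdna_fa cDNA FASTA.
#' @param model_fa single-record provirus FASTA.
#' @param landmarks_json landmark sidecar (see [write_model_json()]).
#' @param out_dir output directory.
#' @param search_window donor/acceptor window half-width.
#' @return junction report data.frame, invisibly.
#' @export
run_splice <- function(cdna_fa, model_fa, landmarks_json, out_dir,
                       search_window = 1000L) {
  for (p in c(cdna_fa, model_fa, landmarks_json))
    if (!file.exists(p)) stop("input file not found: ", p)
  ensure_dir(out_dir)
  model <- read_model_json(landmarks_json, unname(read_fasta(model_fa)[1]))
  cdnas <- read_fasta(cdna_fa)
  rows <- lapply(names(cdnas), function(id) {
    jx <- find_junction(cdnas[[id]], model, search_window)
    if (is.null(jx))
      return(data.frame(query = id, spliced = FALSE, donor_pos = NA,
                        acceptor_pos = NA, donor_offset = NA,
                        acceptor_offset = NA, donor_dinuc = NA,
                        acceptor_dinuc = NA, ss_class = NA, matches = NA))
    data.frame(query = id, spliced = TRUE, donor_pos = jx$donor_pos,
               acceptor_pos = jx$acceptor_pos,
               donor_offset = jx$donor_offset,
               acceptor_offset = jx$acceptor_offset,
               donor_dinuc = jx$donor_dinuc,
               acceptor_dinuc = jx$acceptor_dinuc,
               ss_class = jx$ss_class, matches = jx$matches)
  })
  report <- do.call(rbind, rows)
  write_tsv(report, file.path(out_dir, "junctions.tsv"))
  invisible(report)
}

#' qPCR stage: Ct table to fold/excess report
#'
#' @param ct_tsv Ct TSV (see [read_ct_tsv()]).
#' @param out_dir output directory.
#' @param efficiency amplification base.
#' @return quantification data.frame, invisibly.
#' @export
run_qpcr <- function(ct_tsv, out_dir, efficiency = 2) {
  if (!file.exists(ct_tsv)) stop("input file not found: ", ct_tsv)
  ensure_dir(out_dir)
  q <- quantify_ltr_excess(read_ct_tsv(ct_tsv), efficiency = efficiency)
  write_tsv(q, file.path(out_dir, "qpcr.tsv"))
  invisible(q)
}

#' Simulate stage: write a full synthetic world
#'
#' @param config a [sim_config()] (or a JSON path holding its fields).
#' @param out_dir output directory.
#' @return the `sim_world`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  if (is.character(config)) {
    j <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(sim_config, j)
  }
  world <- plant_loci(config)
  paths <- write_sim_world(world, ensure_dir(out_dir))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE)
  log_line(file.path(out_dir, "run.log"),
           "simulate: seed=%d md5(config)=%s", config$seed,
           unname(tools::md5sum(cfg_path)))
  invisible(world)
}

#' End-to-end truth-recovery run
#'
#' Generates a synthetic world, then re-analyzes it with the pipeline:
#' repeat-table element classification, clone assignment of sampled
#' unspliced amplicons, splice-junction recovery of programmed spliced
#' transcripts, and delta-Ct quantification; every result is compared to
#' the generator's ground truth.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param n_clones clones to sample from the unspliced amplicon pool.
#' @return list of recovery summaries (see the `recovery` element for the
#'   pass/fail counts), invisibly; TSV report under `out_dir`.
#' @export
run_end_to_end <- function(config, out_dir,
                           n_clones = config$clones_per_amplicon) {
  ensure_dir(out_dir)
  log <- file.path(out_dir, "run.log")
  world <- run_simulate(config, file.path(out_dir, "sim"))
  truth <- world$truth

  # element recovery from the emitted repeat table
  parts <- filter_hervk(world$fragments)
  elements <- classify_elements(parts$ltr, parts$internal)
  kind_truth <- truth$loci$kind
  el_match <- nrow(elements) == nrow(truth$loci) &&
    all(sort(elements$kind) == sort(kind_truth))

  # clone assignment on q-env amplicons (clone-length >= 400 via unspliced
  # pool): sample amplicons of the unspliced primer pair across sense
  # proviral transcripts, assign against the locus set
  primers <- design_primers(truth$ancestor)
  cdnas <- transcribe(world)
  tr <- truth$transcripts
  sense_unspliced <- tr$transcript_id[tr$strand == "+" & !tr$spliced &
    truth$loci$kind[match(tr$locus_id, truth$loci$locus_id)] == "provirus"]
  pool <- in_silico_pcr(cdnas[sense_unspliced],
                        primers[primers$name == "unspliced", ])
  candidates <- vapply(truth$locus_seqs[
    truth$loci$locus_id[truth$loci$kind == "provirus"]], identity, "")
  drawn <- sample_clones(pool$template,
                         tr$abundance[match(pool$template, tr$transcript_id)],
                         n_clones, config$seed)
  clone_seqs <- stats::setNames(pool$seq[match(drawn, pool$template)],
                                sprintf("clone%03d", seq_along(drawn)))
  assignments <- assign_clones(clone_seqs, candidates)
  clone_truth <- tr$locus_id[match(drawn, tr$transcript_id)]
  n_correct <- sum(assignments$status == "assigned" &
                     assignments$best_locus == clone_truth)
  n_wrong <- sum(assignments$status == "assigned" &
                   assignments$best_locus != clone_truth)
  n_ambig <- sum(assignments$status != "assigned")

  # splice recovery for every programmed spliced transcript
  spl <- tr[which(tr$spliced), , drop = FALSE]
  splice_rows <- lapply(seq_len(nrow(spl)), function(i) {
    model <- truth$models[[spl$locus_id[i]]]
    jx <- find_junction(cdnas[[spl$transcript_id[i]]], model)
    data.frame(transcript_id = spl$transcript_id[i],
               locus_id = spl$locus_id[i],
               true_donor_offset = spl$donor_offset[i],
               true_acceptor_offset = spl$acceptor_offset[i],
               donor_offset = if (is.null(jx)) NA else jx$donor_offset,
               acceptor_offset = if (is.null(jx)) NA else jx$acceptor_offset,
               ss_class = if (is.null(jx)) NA else jx$ss_class)
  })
  splice_report <- do.call(rbind, splice_rows)
  splice_exact <- !is.na(splice_report$donor_offset) &
    splice_report$donor_offset == splice_report$true_donor_offset &
    splice_report$acceptor_offset == splice_report$true_acceptor_offset

  # delta-Ct recovery
  ab <- qpcr_abundances(world)
  ct <- simulate_ct(ab, sample = "sim", noise_sd = config$ct_noise_sd,
                    seed = config$seed, baseline = config$ct_baseline)
  q <- quantify_ltr_excess(ct)
  programmed_dct <- log2(ab[["q-LTR"]] / ab[["q-env"]])

  recovery <- data.frame(
    check = c("elements_recovered", "clones_correct", "clones_wrong",
              "clones_ambiguous", "splice_junctions_exact", "delta_ct",
              "programmed_delta_ct"),
    value = c(el_match, n_correct, n_wrong, n_ambig, sum(splice_exact),
              q$delta_ct[q$sample == "sim"], programmed_dct))
  write_tsv(recovery, file.path(out_dir, "recovery.tsv"))
  write_tsv(assignments, file.path(out_dir, "assignments.tsv"))
  write_tsv(splice_report, file.path(out_dir, "splice_report.tsv"))
  log_line(log, "end-to-end: %d/%d clones correct, %d wrong, %d ambiguous",
           n_correct, length(drawn), n_wrong, n_ambig)
  invisible(list(world = world, elements = elements, el_match = el_match,
                 assignments = assignments, clone_truth = clone_truth,
                 n_correct = n_correct, n_wrong = n_wrong, n_ambig = n_ambig,
                 splice_report = splice_report, splice_exact = splice_exact,
                 quant = q, programmed_dct = programmed_dct,
                 recovery = recovery))
}

#' Command-line entry point
#'
#' Dispatches `catalog`, `intersect`, `assign`, `splice`, `qpcr`,
#' `simulate`, `end-to-end`. Flags are `--key value` pairs matching the
#' corresponding `run_*()` arguments; see `inst/cli/hervkit`.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return exit status (0 on success), invisibly.
#' @export
hervkit_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hervkit <subcommand> [--key value ...]",
    "subcommands:",
    "  catalog   --rmsk FILE --out DIR [--dialect D] [--window N]",
    "  intersect --loci BED --gtf GTF --out DIR [--min-overlap N]",
    "  assign    --clones FA --candidates FA --out DIR [--min-identity X]",
    "  splice    --cdna FA --model FA --landmarks JSON --out DIR",
    "  qpcr      --ct TSV --out DIR",
    "  simulate  --config JSON --out DIR | --seed N --out DIR",
    "  end-to-end --seed N --out DIR", sep = "\n")
  if (length(argv) < 1L) { message(usage); return(invisible(1L)) }
  sub <- argv[1]; args <- argv[-1]
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    switch(sub,
      catalog = run_catalog(opt$rmsk, opt$out,
                            dialect = opt$dialect %||% "ucsc_rmsk_tsv",
                            window_bp = as.integer(opt$window %||% 200L)),
      intersect = run_intersect(opt$loci, opt$gtf, opt$out,
                                min_overlap = as.integer(opt[["min-overlap"]] %||% 1L)),
      assign = run_assign(opt$clones, opt$candidates, opt$out,
                          min_identity = as.numeric(opt[["min-identity"]] %||% 99)),
      splice = run_splice(opt$cdna, opt$model, opt$landmarks, opt$out),
      qpcr = run_qpcr(opt$ct, opt$out),
      simulate = if (!is.null(opt$config)) run_simulate(opt$config, opt$out)
                 else run_simulate(sim_config(seed = as.integer(opt$seed %||% 1L)),
                                   opt$out),
      `end-to-end` = run_end_to_end(sim_config(seed = as.integer(opt$seed %||% 1L)),
                                    opt$out),
      { message(usage); stop("unknown subcommand: ", sub) })
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
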