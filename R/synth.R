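# Ancestor geometry (0-based, on the type II ancestor):
#   LTR 968 bp = U3 [0,700) + R [700,810) + U5 [810,968)
#   internal [968, 8482) (7,514 bp), 3'LTR [8482, 9450): total 9,450 bp
#   canonical env 5'SS (first intron base) at 1028, GTAAGT planted
#   canonical env 3'SS (first exon base after intron) at 6458, ..AG planted
#   292-bp pol-env (type II) segment [6468, 6760)
#   alternative U12-type donor site planted at 5'SS + 435 (ATATCC)
.anc <- list(ltr_bp = 968L, u3 = 700L, r = c(700L, 810L), u5 = c(810L, 968L),
             internal_bp = 7514L, total_bp = 9450L,
             ss5 = 1028L, ss3 = 6458L, type2 = c(6468L, 6760L),
             alt_donor_offset = 435L)

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483647)
}

plant_motif <- function(seq, pos, motif) {  # pos 0-based
  paste0(substr0(seq, 0L, pos), motif,
         substr(seq, pos + nchar(motif) + 1L, nchar(seq)))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-genome generator; the seed fully
#' determines all outputs. Defaults state the emulated world: paralogs
#' ~99% identical in pairwise comparisons (`pairwise_divergence = 0.01`,
#' applied as rate/2 per locus from a shared ancestor), 968-bp LTRs,
#' ~9,450-bp type II proviruses, a 292-bp pol–env segment deleted in type
#' I loci, 6-bp target-site duplications, and solo LTRs outnumbering
#' proviruses.
#'
#' @param seed integer seed.
#' @param genome_len background genome length in bp.
#' @param n_proviruses,n_solo_ltrs locus counts.
#' @param pairwise_divergence expected substitution divergence between two
#'   paralogs (each locus mutates at half this rate from the ancestor).
#' @param type1_fraction fraction of proviruses lacking the 292-bp segment.
#' @param tsd_len target-site duplication length (6 bp, HERV-K-typical).
#' @param p_insert per-untranscribed-provirus probability of a
#'   fragmenting foreign insertion into the internal segment.
#' @param insert_range insertion length range in bp.
#' @param gene_contexts per-locus gene context plan, recycled over loci in
#'   id order; values from `intergenic`, `intronic_same`,
#'   `intronic_opposite`, `exonic_opposite`.
#' @param unspliced_abundance,spliced_abundance,solo_abundance,
#'   antisense_abundance relative transcript abundances (arbitrary units).
#' @param clones_per_amplicon clones sampled per amplicon pool.
#' @param ct_noise_sd Ct measurement noise (cycles).
#' @param ct_baseline Ct of an abundance-1 template.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_len = 260000L,
                       n_proviruses = 5L, n_solo_ltrs = 10L,
                       pairwise_divergence = 0.01, type1_fraction = 0.4,
                       tsd_len = 6L, p_insert = 0.25,
                       insert_range = c(100L, 500L),
                       gene_contexts = c("intergenic", "intronic_same",
                                         "intronic_opposite", "intergenic",
                                         "exonic_opposite"),
                       unspliced_abundance = 10, spliced_abundance = 5,
                       solo_abundance = 20, antisense_abundance = 3,
                       clones_per_amplicon = 30L, ct_noise_sd = 0.3,
                       ct_baseline = 35) {
  stopifnot(pairwise_divergence >= 0, pairwise_divergence <= 1,
            type1_fraction >= 0, type1_fraction <= 1, p_insert >= 0,
            p_insert <= 1, n_proviruses >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

#' Build the shared ancestral provirus
#'
#' Deterministic (seeded) type II ancestor: byte-identical 968-bp LTRs
#' around a 7,514-bp internal segment (9,450 bp total), canonical env
#' splice sites with GT/AG planted, the 292-bp pol–env segment, and a
#' U12-type alternative donor motif planted 435 nt downstream of the
#' canonical donor.
#'
#' @param config a [sim_config()].
#' @return a [provirus_model()] (type II).
#' @export
build_ancestor <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  ltr <- random_dna(.anc$ltr_bp)
  internal <- random_dna(.anc$internal_bp)
  seq <- paste0(ltr, internal, ltr)
  seq <- plant_motif(seq, .anc$ss5, "GTAAGT")
  seq <- plant_motif(seq, .anc$ss3 - 2L, "AG")
  seq <- plant_motif(seq, .anc$ss5 + .anc$alt_donor_offset, "ATATCC")
  # AT..AC intron context for the alternative junction: last two intron
  # bases before the +6 acceptor, so the U12-type placement wins the
  # dinucleotide tie-break over sequence-identical shifted placements
  seq <- plant_motif(seq, .anc$ss3 + 4L, "AC")
  provirus_model(seq,
                 ltr5 = c(0L, .anc$ltr_bp),
                 ltr3 = c(.anc$total_bp - .anc$ltr_bp, .anc$total_bp),
                 canonical_5ss = .anc$ss5, canonical_3ss = .anc$ss3,
                 type2_segment = .anc$type2, r_region = .anc$r)
}

# landmark model for a derived locus (coordinates shifted for type I;
# insertions are only applied to untranscribed loci, so not handled here)
locus_model <- function(seq, type) {
  if (type == "II")
    provirus_model(seq, c(0L, .anc$ltr_bp),
                   c(.anc$total_bp - .anc$ltr_bp, .anc$total_bp),
                   .anc$ss5, .anc$ss3, .anc$type2, .anc$r)
  else
    provirus_model(seq, c(0L, .anc$ltr_bp),
                   c(.anc$total_bp - .anc$ltr_bp - 292L, .anc$total_bp - 292L),
                   .anc$ss5, .anc$ss3, NULL, .anc$r)
}

#' Plant paralogous loci into a synthetic genome
#'
#' Generates a background genome and inserts proviruses (type I loci have
#' the 292-bp segment excised) and solo LTRs, each with a `tsd_len`-bp
#' target-site duplication, each independently mutated from the ancestor
#' at `pairwise_divergence / 2`. Untranscribed proviruses may receive a
#' fragmenting foreign insertion into the internal segment. Emits the
#' repeat table exactly as a masker would (one row per contiguous HERV-K
#' segment: type I internal regions appear as two joined fragments, an
#' insertion splits a fragment in two), gene models per the per-locus
#' context plan, and the full ground truth.
#'
#' @param config a [sim_config()].
#' @return list (`sim_world`): `genome` (named character), `fragments`
#'   (repeat table data.frame), `features` (gene features), `truth` (list:
#'   `loci`, `transcripts` — filled by [transcribe()] —, `ancestor`,
#'   `locus_seqs`, `models`), `config`.
#' @export
plant_loci <- function(config) {
  anc <- build_ancestor(config)
  set.seed(derive_seed(config$seed, 2L))
  np <- config$n_proviruses; ns <- config$n_solo_ltrs
  k <- np + ns
  margin <- 10000L
  slot <- (config$genome_len - 2L * margin) %/% k
  if (slot < .anc$total_bp + 3000L)
    stop("genome_len too small for non-overlapping placement of ", k, " loci")
  ids <- c(sprintf("P%02d", seq_len(np)),
           if (ns) sprintf("S%02d", seq_len(ns)))
  kinds <- c(rep("provirus", np), rep("solo_ltr", ns))
  n1 <- round(config$type1_fraction * np)
  types <- c(rep("I", n1), rep("II", np - n1), rep(NA_character_, ns))
  strands <- rep(c("+", "-"), length.out = k)
  contexts <- rep(config$gene_contexts, length.out = k)
  slot_of <- sample(k)   # which slot hosts which locus
  program <- default_program(config, ids, kinds, types)
  transcribed <- unique(program$locus_id)

  bg <- random_dna(config$genome_len)
  ins_points <- sort(margin + (seq_len(k) - 1L) * slot +
                       sample(slot - .anc$total_bp - 2000L, k, replace = TRUE))
  ins_points <- ins_points[slot_of]  # locus j inserted into slot slot_of[j]
  # assemble in genomic order
  ord <- order(ins_points)
  pieces <- character(0); cursor <- 0L; offset <- 0L
  loci <- list(); frag_rows <- list(); locus_seqs <- list(); models <- list()
  for (j in ord) {
    p <- ins_points[j]
    # local (sense) locus sequence + its masker segments
    if (kinds[j] == "provirus") {
      seq <- mutate_seq(anc$seq, config$pairwise_divergence / 2)
      segs <- data.frame(start = c(0L, .anc$ltr_bp,
                                   .anc$total_bp - .anc$ltr_bp),
                         end = c(.anc$ltr_bp, .anc$total_bp - .anc$ltr_bp,
                                 .anc$total_bp),
                         name = c("LTR5_Hs", "HERVK-int", "LTR5_Hs"),
                         stringsAsFactors = FALSE)
      brk <- integer()
      if (types[j] == "I") {
        seq <- paste0(substr0(seq, 0L, .anc$type2[1]),
                      substr(seq, .anc$type2[2] + 1L, nchar(seq)))
        # masker reports the internal region as two joined fragments
        segs <- data.frame(
          start = c(0L, .anc$ltr_bp, .anc$type2[1],
                    .anc$total_bp - .anc$ltr_bp - 292L),
          end = c(.anc$ltr_bp, .anc$type2[1],
                  .anc$total_bp - .anc$ltr_bp - 292L, .anc$total_bp - 292L),
          name = c("LTR5_Hs", "HERVK-int", "HERVK-int", "LTR5_Hs"),
          stringsAsFactors = FALSE)
        brk <- .anc$type2[1]
      }
      if (!(ids[j] %in% transcribed) &&
          stats::runif(1) < config$p_insert) {
        ilen <- sample(seq(config$insert_range[1], config$insert_range[2]), 1L)
        int_lo <- .anc$ltr_bp + 500L
        int_hi <- nchar(seq) - .anc$ltr_bp - 500L
        q <- sample(seq(int_lo, int_hi), 1L)
        seq <- paste0(substr0(seq, 0L, q), random_dna(ilen),
                      substr(seq, q + 1L, nchar(seq)))
        segs <- split_segments(segs, q, ilen)
        brk <- c(brk, q)
      }
    } else {
      seq <- mutate_seq(substr0(anc$seq, 0L, .anc$ltr_bp),
                        config$pairwise_divergence / 2)
      segs <- data.frame(start = 0L, end = .anc$ltr_bp, name = "LTR5_Hs",
                         stringsAsFactors = FALSE)
      brk <- integer()
    }
    len <- nchar(seq)
    inserted <- if (strands[j] == "+") seq else unname(revcomp(seq))
    tsd <- substr0(bg, p - config$tsd_len, p)
    pieces <- c(pieces, substr(bg, cursor + 1L, p), inserted, tsd)
    gstart <- p + offset
    offset <- offset + len + config$tsd_len
    cursor <- p
    # genomic fragment rows
    gs <- if (strands[j] == "+") gstart + segs$start else gstart + len - segs$end
    ge <- if (strands[j] == "+") gstart + segs$end else gstart + len - segs$start
    frag_rows[[ids[j]]] <- data.frame(
      chrom = "synth1", start = gs, end = ge, strand = strands[j],
      rep_name = segs$name, rep_class = "LTR/ERVK",
      element_id = j, stringsAsFactors = FALSE)
    loci[[ids[j]]] <- data.frame(
      locus_id = ids[j], chrom = "synth1", start = gstart,
      end = gstart + len, strand = strands[j], kind = kinds[j],
      provirus_type = types[j], n_fragments = nrow(segs),
      breakpoints = paste(brk, collapse = ","),
      gene_context = contexts[j], stringsAsFactors = FALSE)
    locus_seqs[[ids[j]]] <- seq
    if (kinds[j] == "provirus" && ids[j] %in% transcribed)
      models[[ids[j]]] <- locus_model(seq, types[j])
  }
  pieces <- c(pieces, substr(bg, cursor + 1L, nchar(bg)))
  genome <- paste(pieces, collapse = "")
  loci_df <- do.call(rbind, loci[ids]); rownames(loci_df) <- NULL
  frags <- do.call(rbind, frag_rows[ids])
  frags <- frags[order(frags$start), , drop = FALSE]; rownames(frags) <- NULL
  features <- place_genes(loci_df, nchar(genome))
  list(genome = c(synth1 = genome), fragments = frags, features = features,
       truth = list(loci = loci_df, transcripts = program, ancestor = anc,
                    locus_seqs = locus_seqs, models = models),
       config = config)
}

# split masker segments by a foreign insertion of length ilen at local q
split_segments <- function(segs, q, ilen) {
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (q <= s$start) { s$start <- s$start + ilen; s$end <- s$end + ilen }
    else if (q >= s$end) { }  # untouched
    else {
      out[[length(out) + 1L]] <- data.frame(start = s$start, end = q,
                                            name = s$name)
      s$start <- q + ilen; s$end <- s$end + ilen
    }
    out[[length(out) + 1L]] <- s
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

# default transcript program: every provirus transcribes sense unspliced;
# the first type II adds a canonically spliced env mRNA; the first type I
# adds the +435/+6 alternatively spliced mRNA (the K60-like program); the
# second provirus adds an antisense transcript; every solo LTR transcribes.
default_program <- function(config, ids, kinds, types) {
  rows <- list()
  add <- function(locus, strand, spliced, d_off, a_off, abundance)
    rows[[length(rows) + 1L]] <<- data.frame(
      locus_id = locus, strand = strand, spliced = spliced,
      donor_offset = d_off, acceptor_offset = a_off,
      abundance = abundance, stringsAsFactors = FALSE)
  pv <- which(kinds == "provirus")
  for (i in pv) add(ids[i], "+", FALSE, NA, NA, config$unspliced_abundance)
  i2 <- pv[which(types[pv] == "II")[1]]
  if (!is.na(i2)) add(ids[i2], "+", TRUE, 0L, 0L, config$spliced_abundance)
  i1 <- pv[which(types[pv] == "I")[1]]
  if (length(i1) && !is.na(i1))
    add(ids[i1], "+", TRUE, .anc$alt_donor_offset, 6L,
        config$spliced_abundance)
  if (length(pv) >= 2L)
    add(ids[pv[2]], "-", FALSE, NA, NA, config$antisense_abundance)
  for (i in which(kinds == "solo_ltr"))
    add(ids[i], "+", FALSE, NA, NA, config$solo_abundance)
  out <- do.call(rbind, rows)
  out$transcript_id <- sprintf("T%02d", seq_len(nrow(out)))
  out[, c("transcript_id", setdiff(names(out), "transcript_id"))]
}

# gene models realizing each locus's planned context
place_genes <- function(loci, genome_len) {
  rows <- list(); gnum <- 0L
  for (i in seq_len(nrow(loci))) {
    ctx <- loci$gene_context[i]
    if (ctx == "intergenic") next
    gnum <- gnum + 1L
    gid <- sprintf("GENE%02d", gnum)
    ls <- loci$start[i]; le <- loci$end[i]
    gstrand <- if (ctx == "intronic_same") loci$strand[i]
               else if (loci$strand[i] == "+") "-" else "+"
    gs <- max(0L, ls - 1500L); ge <- min(genome_len, le + 1500L)
    if (ctx == "exonic_opposite") {
      ex <- data.frame(start = c(gs, ls + 100L, ge - 200L),
                       end = c(gs + 200L, ls + 400L, ge))
    } else {
      ex <- data.frame(start = c(gs, ge - 200L), end = c(gs + 200L, ge))
    }
    rows[[gid]] <- data.frame(
      gene_id = gid,
      kind = c("gene", rep("exon", nrow(ex)), "cds"),
      chrom = loci$chrom[i],
      start = c(gs, ex$start, gs + 20L),
      end = c(ge, ex$end, gs + 170L),
      strand = gstrand, coding = TRUE, stringsAsFactors = FALSE)
  }
  feats <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), kind = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               coding = logical(), stringsAsFactors = FALSE)
  rownames(feats) <- NULL
  if (nrow(feats)) feats <- rbind(feats, derive_introns(feats))
  rownames(feats) <- NULL
  feats
}

#' Realize the transcript program as cDNA sequences
#'
#' Proviral transcripts run from the R-region start in the 5' LTR to the
#' R-region end in the 3' LTR (hence exactly two R copies per env copy);
#' spliced transcripts excise the programmed intron
#' `[5'SS + donor_offset, 3'SS + acceptor_offset)`; antisense transcripts
#' are reverse complements; solo-LTR transcripts run from the R start to
#' the LTR end.
#'
#' @param world a `sim_world` from [plant_loci()].
#' @return named character vector of cDNA sequences, names =
#'   `transcript_id` from the truth table.
#' @export
transcribe <- function(world) {
  tr <- world$truth$transcripts
  loci <- world$truth$loci
  out <- character(0)
  for (i in seq_len(nrow(tr))) {
    lid <- tr$locus_id[i]
    seq <- world$truth$locus_seqs[[lid]]
    kind <- loci$kind[loci$locus_id == lid]
    if (kind == "solo_ltr") {
      t <- substr0(seq, .anc$r[1], nchar(seq))
    } else {
      t <- substr0(seq, .anc$r[1], nchar(seq) - (.anc$ltr_bp - .anc$r[2]))
      if (isTRUE(tr$spliced[i])) {
        d <- .anc$ss5 + tr$donor_offset[i]; a <- .anc$ss3 + tr$acceptor_offset[i]
        # transcript coords = locus coords - r_start
        t <- paste0(substr0(t, 0L, d - .anc$r[1]),
                    substr(t, a - .anc$r[1] + 1L, nchar(t)))
      }
    }
    if (tr$strand[i] == "-") t <- unname(revcomp(t))
    out[[tr$transcript_id[i]]] <- t
  }
  out
}

#' Design primer pairs on the ancestor model
#'
#' In-silico analogues of the published primer panel, taken verbatim from
#' the ancestor sequence: `unspliced` flanks the pol–env (292-bp) segment
#' (~2-kb product; type II minus type I product = 292 bp); `env1x` spans
#' the env intron (no product from unspliced templates under the 5-kb
#' cap, a short product from spliced ones); `q-LTR` sits inside the LTR R
#' region; `q-env` sits downstream of the 292-bp segment, common to
#' unspliced and spliced transcripts of both types.
#'
#' @param model the ancestor [provirus_model()] from [build_ancestor()].
#' @return data.frame `name`, `fwd`, `rev`.
#' @export
design_primers <- function(model) {
  s <- model$seq
  take <- function(a, b) substr0(s, a, b)
  data.frame(
    name = c("unspliced", "env1x", "q-LTR", "q-env"),
    fwd = c(take(5600L, 5620L), take(990L, 1010L), take(700L, 720L),
            take(6810L, 6830L)),
    rev = unname(revcomp(c(take(7580L, 7600L), take(6810L, 6830L),
                           take(790L, 810L), take(6890L, 6910L)))),
    stringsAsFactors = FALSE)
}

#' In-silico PCR over a set of templates
#'
#' @param templates named character vector of template sequences.
#' @param primer_pair list/row with `fwd`, `rev`.
#' @param max_mismatch per-primer mismatch allowance.
#' @param max_len product length cap (default 5000 bp).
#' @return data.frame `template`, `start`, `end`, `length`, `seq`.
#' @export
in_silico_pcr <- function(templates, primer_pair, max_mismatch = 1L,
                          max_len = 5000L) {
  rows <- lapply(names(templates), function(id) {
    am <- predict_amplicon_sizes(templates[[id]], primer_pair,
                                 max_mismatch, max_len)
    if (!nrow(am)) return(NULL)
    am$template <- id
    am$seq <- substr0(rep(templates[[id]], nrow(am)), am$start, am$end)
    am
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(), length = integer(),
                      template = character(), seq = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, c("template", "start", "end", "length", "seq")]
}

#' Sample clones from an amplicon pool
#'
#' Multinomial draw proportional to abundance; seeded and reproducible.
#'
#' @param ids template/amplicon identifiers.
#' @param abundances relative abundances (> 0), same length as `ids`.
#' @param n number of clones.
#' @param seed integer seed.
#' @return character vector of `n` drawn ids.
#' @export
sample_clones <- function(ids, abundances, n, seed) {
  stopifnot(length(ids) == length(abundances), n >= 1L,
            all(abundances > 0))
  set.seed(derive_seed(seed, 3L))
  counts <- stats::rmultinom(1L, n, prob = abundances / sum(abundances))[, 1]
  rep(ids, counts)
}

# qPCR-visible abundances implied by the truth table: sense proviral
# transcripts carry 2 R copies and 1 env copy; solo-LTR transcripts 1 R
# copy and no env; antisense transcripts are not oligo-dT primed and are
# excluded.
qpcr_abundances <- function(world) {
  tr <- world$truth$transcripts
  loci <- world$truth$loci
  kind <- loci$kind[match(tr$locus_id, loci$locus_id)]
  prov <- sum(tr$abundance[kind == "provirus" & tr$strand == "+"])
  solo <- sum(tr$abundance[kind == "solo_ltr" & tr$strand == "+"])
  c("q-LTR" = 2 * prov + solo, "q-env" = prov)
}

#' Simulate Ct measurements from template abundances
#'
#' `Ct = baseline - log_E(abundance) + Normal(0, noise_sd)` per replicate.
#'
#' @param abundances named numeric vector (one entry per amplicon).
#' @param sample sample name.
#' @param efficiency amplification base.
#' @param noise_sd Ct noise standard deviation (cycles).
#' @param seed integer seed.
#' @param baseline Ct of an abundance-1 template.
#' @param n_replicates replicates per amplicon (default 3).
#' @return data.frame `sample`, `amplicon`, `ct`.
#' @export
simulate_ct <- function(abundances, sample = "S1", efficiency = 2,
                        noise_sd = 0, seed = 1L, baseline = 35,
                        n_replicates = 3L) {
  stopifnot(all(abundances > 0))
  set.seed(derive_seed(seed, 4L))
  rows <- lapply(names(abundances), function(a) {
    ct <- baseline - log(abundances[[a]], base = efficiency) +
      stats::rnorm(n_replicates, 0, noise_sd)
    data.frame(sample = sample, amplicon = a, ct = ct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Write all simulator outputs to a directory
#'
#' Emits genome FASTA, rmsk-dialect repeat TSV, gene GTF, transcript
#' FASTA, Ct TSV, and a truth-table JSON.
#'
#' @param world a `sim_world` from [plant_loci()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_sim_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             rmsk = file.path(dir, "rmsk.tsv"),
             gtf = file.path(dir, "genes.gtf"),
             transcripts = file.path(dir, "transcripts.fa"),
             ct = file.path(dir, "ct.tsv"),
             truth = file.path(dir, "truth.json"))
  write_fasta(world$genome, paths["genome"])
  fr <- world$fragments
  utils::write.table(
    data.frame(genoName = fr$chrom, genoStart = fr$start, genoEnd = fr$end,
               strand = fr$strand, repName = fr$rep_name,
               repClass = fr$rep_class, id = fr$element_id),
    paths["rmsk"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_features_gtf(world$features, paths["gtf"])
  write_fasta(transcribe(world), paths["transcripts"])
  ct <- simulate_ct(qpcr_abundances(world), sample = "sim",
                    noise_sd = world$config$ct_noise_sd,
                    seed = world$config$seed,
                    baseline = world$config$ct_baseline)
  utils::write.table(ct, paths["ct"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(loci = world$truth$loci,
                            transcripts = world$truth$transcripts),
                       paths["truth"], dataframe = "rows", auto_unbox = TRUE)
  invisible(paths)
}

#' Write gene features as GTF
#'
#' @param features feature data.frame (shape of [read_gene_gtf()] output).
#' @param path output path.
#' @export
write_features_gtf <- function(features, path) {
  f <- features[features$kind != "intron", , drop = FALSE]  # derived on read
  type_map <- c(gene = "gene", exon = "exon", cds = "CDS",
                utr5 = "five_prime_utr", utr3 = "three_prime_utr")
  gr <- GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(f$start + 1L, f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- unname(type_map[f$kind])
  S4Vectors::mcols(gr)$gene_id <- f$gene_id
  S4Vectors::mcols(gr)$source <- "hervkit_sim"
  S4Vectors::mcols(gr)$phase <- ifelse(f$kind == "cds", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
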