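test_that("build_ancestor states the provirus geometry", {
  cfg <- sim_config(seed = 61)
  anc <- build_ancestor(cfg)
  expect_gte(nchar(anc$seq), 9400L)
  expect_lte(nchar(anc$seq), 9500L)
  expect_equal(diff(anc$type2_segment), 292L)
  expect_equal(anc$provirus_type, "II")
  # new insertions carry byte-identical LTR copies
  expect_identical(substring(anc$seq, anc$ltr5[1] + 1L, anc$ltr5[2]),
                   substring(anc$seq, anc$ltr3[1] + 1L, anc$ltr3[2]))
  # canonical dinucleotides planted
  expect_equal(substring(anc$seq, anc$canonical_5ss + 1L,
                         anc$canonical_5ss + 2L), "GT")
  expect_equal(substring(anc$seq, anc$canonical_3ss - 1L,
                         anc$canonical_3ss), "AG")
  # determinism
  expect_identical(anc$seq, build_ancestor(sim_config(seed = 61))$seq)
  expect_false(identical(anc$seq, build_ancestor(sim_config(seed = 62))$seq))
})

test_that("plant_loci emits loci, TSDs, repeat rows, and truth in agreement", {
  cfg <- sim_config(seed = 71, n_proviruses = 5L, n_solo_ltrs = 10L)
  w <- plant_loci(cfg)
  loci <- w$truth$loci
  expect_equal(sum(loci$kind == "provirus"), 5L)
  expect_equal(sum(loci$kind == "solo_ltr"), 10L)
  expect_equal(sum(loci$provirus_type == "I", na.rm = TRUE),
               round(cfg$type1_fraction * 5))
  ltr_rows <- w$fragments[w$fragments$rep_name %in% hervk_ltr_names, ]
  int_rows <- w$fragments[w$fragments$rep_name %in% hervk_internal_names, ]
  expect_gte(nrow(ltr_rows), 15L)
  expect_gte(nrow(int_rows), 5L)

  g <- unname(w$genome)
  for (i in seq_len(nrow(loci))) {
    # the genome carries the locus sequence at the recorded interval
    ins <- substring(g, loci$start[i] + 1L, loci$end[i])
    want <- w$truth$locus_seqs[[loci$locus_id[i]]]
    if (loci$strand[i] == "-") want <- unname(revcomp(want))
    expect_identical(ins, want, info = loci$locus_id[i])
    # target-site duplication flanks the insertion
    tsd_left <- substring(g, loci$start[i] - cfg$tsd_len + 1L, loci$start[i])
    tsd_right <- substring(g, loci$end[i] + 1L, loci$end[i] + cfg$tsd_len)
    expect_identical(tsd_left, tsd_right, info = loci$locus_id[i])
  }

  # determinism of the full world
  w2 <- plant_loci(cfg)
  expect_identical(w$genome, w2$genome)
  expect_identical(w$fragments, w2$fragments)
})

test_that("divergence 0 makes paralogs identical; default ~1% pairwise", {
  w0 <- plant_loci(sim_config(seed = 81, pairwise_divergence = 0,
                              n_proviruses = 3L, n_solo_ltrs = 2L,
                              type1_fraction = 0))
  seqs <- w0$truth$locus_seqs
  prov <- w0$truth$loci$locus_id[w0$truth$loci$kind == "provirus"]
  expect_length(unique(unlist(seqs[prov])), 1L)

  w1 <- plant_loci(sim_config(seed = 82, n_proviruses = 3L, n_solo_ltrs = 2L,
                              type1_fraction = 0))
  p <- w1$truth$loci$locus_id[w1$truth$loci$kind == "provirus"]
  a <- strsplit(w1$truth$locus_seqs[[p[1]]], "")[[1]]
  b <- strsplit(w1$truth$locus_seqs[[p[2]]], "")[[1]]
  div <- mean(a != b)
  expect_gt(div, 0.005)
  expect_lt(div, 0.015)  # ~99% identical paralogs
})

test_that("placement collisions are detected", {
  expect_error(plant_loci(sim_config(seed = 1, genome_len = 50000L)),
               "too small")
})

test_that("transcripts realize the program: R copies, splices, antisense", {
  cfg <- sim_config(seed = 91, pairwise_divergence = 0, type1_fraction = 0.4)
  w <- plant_loci(cfg)
  cd <- transcribe(w)
  tr <- w$truth$transcripts
  loci <- w$truth$loci
  anc <- w$truth$ancestor
  r_seq <- substring(anc$seq, anc$r_region[1] + 1L, anc$r_region[2])

  unsp <- tr[tr$strand == "+" & !tr$spliced &
               loci$kind[match(tr$locus_id, loci$locus_id)] == "provirus", ]
  # unspliced proviral mRNA contains the R region exactly twice
  n_r <- lengths(gregexpr(r_seq, cd[unsp$transcript_id], fixed = TRUE))
  expect_true(all(n_r == 2L))

  solo <- tr[loci$kind[match(tr$locus_id, loci$locus_id)] == "solo_ltr", ]
  n_r_solo <- lengths(gregexpr(r_seq, cd[solo$transcript_id], fixed = TRUE))
  expect_true(all(n_r_solo == 1L))

  # programmed +435/+6 round-trips through junction inference
  alt <- tr[which(tr$spliced & tr$donor_offset == 435), ]
  expect_equal(nrow(alt), 1L)
  jx <- find_junction(cd[[alt$transcript_id]],
                      w$truth$models[[alt$locus_id]])
  expect_equal(jx$donor_offset, 435L)
  expect_equal(jx$acceptor_offset, 6L)

  # antisense transcripts still assign to their true locus
  anti <- tr[tr$strand == "-", ]
  expect_gte(nrow(anti), 1L)
  cands <- vapply(w$truth$locus_seqs[loci$locus_id[loci$kind == "provirus"]],
                  identity, "")
  a <- assign_locus(substr(cd[[anti$transcript_id[1]]], 1, 1500), cands)
  # divergence 0: paralogs are identical, so the call is an honest tie
  expect_true(anti$locus_id[1] %in%
                c(a$best_locus, a$tied_loci))
})

test_that("in_silico_pcr: band logic, mismatch cap, and length cap", {
  cfg <- sim_config(seed = 3)
  anc <- build_ancestor(cfg)
  primers <- design_primers(anc)
  unsp <- primers[primers$name == "unspliced", ]
  type1 <- excise(anc$seq, anc$type2_segment[1], anc$type2_segment[2])
  amp <- in_silico_pcr(c(t2 = anc$seq, t1 = type1), unsp)
  expect_equal(nrow(amp), 2L)
  expect_equal(amp$length[amp$template == "t2"] -
                 amp$length[amp$template == "t1"], 292L)
  expect_identical(amp$seq[1],
                   substring(anc$seq, amp$start[1] + 1L, amp$end[1]))

  # 3 mismatches in the forward primer kill the product at max_mismatch 1
  f <- strsplit(unsp$fwd, "")[[1]]
  for (j in c(3L, 9L, 15L)) f[j] <- setdiff(c("A", "C", "G", "T"), f[j])[1]
  broken <- list(fwd = paste(f, collapse = ""), rev = unsp$rev)
  expect_equal(nrow(in_silico_pcr(c(t2 = anc$seq), broken)), 0L)

  # env1x crosses the intron: capped out on unspliced, present on spliced
  env1x <- primers[primers$name == "env1x", ]
  spliced <- excise(anc$seq, anc$canonical_5ss, anc$canonical_3ss)
  expect_equal(nrow(in_silico_pcr(c(u = anc$seq), env1x)), 0L)
  expect_equal(nrow(in_silico_pcr(c(s = spliced), env1x)), 1L)
})

test_that("sample_clones is a seeded multinomial draw", {
  d1 <- sample_clones(c("a", "b"), c(90, 10), 1000L, seed = 5L)
  d2 <- sample_clones(c("a", "b"), c(90, 10), 1000L, seed = 5L)
  expect_identical(d1, d2)
  p_a <- mean(d1 == "a")
  expect_lt(abs(p_a - 0.9), 0.03)  # 3 sigma of Binomial(1000, .9)

  expect_identical(sample_clones("only", 1, 7L, seed = 2L), rep("only", 7L))
})

test_that("simulate_ct realizes the programmed abundance ratios", {
  # solo abundance chosen so LTR/env = 2^7.2 exactly
  prov <- 60
  solo <- prov * (2 ^ 7.2 - 2)
  ab <- c("q-LTR" = 2 * prov + solo, "q-env" = prov)
  ct <- simulate_ct(ab, noise_sd = 0, seed = 8L)
  expect_equal(delta_ct(ct$ct[ct$amplicon == "q-env"],
                        ct$ct[ct$amplicon == "q-LTR"]), 7.2)

  # no solo transcription: only the R-copy effect remains
  ab0 <- c("q-LTR" = 2 * prov, "q-env" = prov)
  ct0 <- simulate_ct(ab0, noise_sd = 0, seed = 8L)
  expect_equal(delta_ct(ct0$ct[ct0$amplicon == "q-env"],
                        ct0$ct[ct0$amplicon == "q-LTR"]), 1)

  expect_identical(simulate_ct(ab, noise_sd = 0.4, seed = 9L),
                   simulate_ct(ab, noise_sd = 0.4, seed = 9L))
})

test_that("write_sim_world emits parseable standard formats", {
  w <- plant_loci(sim_config(seed = 31, n_proviruses = 2L, n_solo_ltrs = 3L))
  dir <- withr::local_tempdir()
  paths <- write_sim_world(w, dir)
  expect_true(all(file.exists(paths)))
  frags <- parse_repeat_table(paths[["rmsk"]], "ucsc_rmsk_tsv")
  expect_equal(nrow(frags), nrow(w$fragments))
  expect_equal(frags$start, w$fragments$start)
  genome <- read_fasta(paths[["genome"]])
  expect_identical(genome, w$genome)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(nrow(truth$loci), nrow(w$truth$loci))
})
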