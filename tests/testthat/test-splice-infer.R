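test_that("provirus_model validates its landmarks", {
  expect_error(provirus_model("ACGT", c(0, 2), c(2, 4), 3, 1), "canonical_5ss")
  expect_error(tiny_model() |> (\(m) provirus_model(m$seq, m$ltr5, m$ltr3,
                                                    m$canonical_5ss,
                                                    m$canonical_3ss,
                                                    c(0, 100)))(),
               "292")
})

test_that("model landmark JSON sidecar round-trips", {
  m <- build_ancestor(sim_config(seed = 5))
  p <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, p)
  m2 <- read_model_json(p, m$seq)
  expect_equal(m2[names(m2) != "seq"], m[names(m) != "seq"])
})

test_that("contiguous cDNAs yield no junction", {
  m <- tiny_model(seed = 31)
  cdna <- substr(m$seq, 201, 1400)
  expect_null(find_junction(cdna, m))
  expect_error(find_junction(substr(m$seq, 1, 40), m), "60 nt")
})

test_that("excising the canonical intron is recovered at offsets (0,0)", {
  m <- tiny_model(seed = 32)
  cdna <- excise(substr(m$seq, 101, 2800), m$canonical_5ss - 100L,
                 m$canonical_3ss - 100L)
  jx <- find_junction(cdna, m)
  expect_equal(jx$donor_offset, 0L)
  expect_equal(jx$acceptor_offset, 0L)
  expect_equal(jx$ss_class, "canonical")
  expect_equal(jx$donor_dinuc, "GT")
  expect_equal(jx$acceptor_dinuc, "AG")
})

test_that("the K60-like +435/+6 junction is recovered on the ancestor model", {
  anc <- build_ancestor(sim_config(seed = 2))
  d <- anc$canonical_5ss + 435L; a <- anc$canonical_3ss + 6L
  cdna <- excise(substr(anc$seq, 711, 8482), d - 710L, a - 710L)
  jx <- find_junction(cdna, anc)
  expect_equal(jx$donor_offset, 435L)
  expect_equal(jx$acceptor_offset, 6L)
  expect_equal(jx$ss_class, "alt_minor")   # planted U12-type donor
})

test_that("planted-intron recovery: exact when clean, >=95% under 1% noise", {
  # plant GT..AG introns at random offsets into one fixed model; clean
  # recovery must be exact, and exact in >= 95% of 200 noisy trials
  # a reduced-size run; the full 200-trial version lives in test-acceptance
  anc <- build_ancestor(sim_config(seed = 13))
  n_trials <- 40L
  set.seed(424243)
  exact <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    d_off <- sample(-300:300, 1); a_off <- sample(-300:300, 1)
    d <- anc$canonical_5ss + d_off; a <- anc$canonical_3ss + a_off
    s <- anc$seq
    substr(s, d + 1L, d + 2L) <- "GT"   # donor motif at the planted site
    substr(s, a - 1L, a) <- "AG"        # acceptor motif
    model <- provirus_model(s, anc$ltr5, anc$ltr3, anc$canonical_5ss,
                            anc$canonical_3ss, anc$type2_segment, anc$r_region)
    lo <- d - sample(25:600, 1); hi <- a + sample(25:600, 1)
    cdna <- excise(substr(s, lo + 1L, hi), d - lo, a - lo)
    if (t <= 20L) {  # clean subset: recovery must be exact
      jx <- find_junction(cdna, model)
      expect_false(is.null(jx), info = paste("trial", t))
      expect_equal(c(jx$donor_offset, jx$acceptor_offset), c(d_off, a_off),
                   info = paste("clean trial", t))
    }
    noisy <- mutate_noise(cdna, 0.01)
    jxn <- find_junction(noisy, model)
    exact[t] <- !is.null(jxn) && jxn$donor_offset == d_off &&
      jxn$acceptor_offset == a_off
  }
  expect_gte(mean(exact), 0.95)
})

test_that("find_junction mirrors under reverse complement", {
  anc <- build_ancestor(sim_config(seed = 17))
  L <- nchar(anc$seq)
  d <- anc$canonical_5ss; a <- anc$canonical_3ss
  cdna <- excise(substr(anc$seq, 711, 8482), d - 710L, a - 710L)
  mirror <- provirus_model(revcomp(anc$seq),
                           ltr5 = c(L - anc$ltr3[2], L - anc$ltr3[1]),
                           ltr3 = c(L - anc$ltr5[2], L - anc$ltr5[1]),
                           canonical_5ss = L - a, canonical_3ss = L - d,
                           r_region = anc$r_region)
  jx <- find_junction(cdna, anc)
  jm <- find_junction(unname(revcomp(cdna)), mirror)
  expect_equal(jm$donor_pos, L - jx$acceptor_pos)
  expect_equal(jm$acceptor_pos, L - jx$donor_pos)
})

test_that("classify_sites follows the canonical/major/minor precedence", {
  m <- tiny_model(seed = 41)
  mk <- function(d, a) list(donor_pos = d, acceptor_pos = a)
  expect_equal(classify_sites(m, mk(m$canonical_5ss, m$canonical_3ss)),
               "canonical")
  # GT intron start somewhere non-canonical -> alt_major
  s <- m$seq
  d2 <- m$canonical_5ss + 101L
  substr(s, d2 + 1L, d2 + 6L) <- "GTGAGT"
  m2 <- provirus_model(s, m$ltr5, m$ltr3, m$canonical_5ss, m$canonical_3ss,
                       r_region = m$r_region)
  expect_equal(classify_sites(m2, mk(d2, m$canonical_3ss + 5L)), "alt_major")
  # U12-type donor consensus
  substr(s, d2 + 1L, d2 + 6L) <- "ATATCC"
  m3 <- provirus_model(s, m$ltr5, m$ltr3, m$canonical_5ss, m$canonical_3ss,
                       r_region = m$r_region)
  expect_equal(classify_sites(m3, mk(d2, m$canonical_3ss + 5L)), "alt_minor")
  # neither consensus
  substr(s, d2 + 1L, d2 + 6L) <- "CCAACC"
  m4 <- provirus_model(s, m$ltr5, m$ltr3, m$canonical_5ss, m$canonical_3ss,
                       r_region = m$r_region)
  expect_equal(classify_sites(m4, mk(d2, m$canonical_3ss + 5L)),
               "non_canonical")
  expect_error(classify_sites(m, mk(-5L, 100L)), "outside")
})

test_that("detect_type finds the 292-bp deletion and only that", {
  anc <- build_ancestor(sim_config(seed = 23))
  self <- detect_type(anc$seq, anc)
  expect_equal(self$provirus_type, "II")
  expect_equal(self$deletion_len, 0L)

  type1 <- excise(anc$seq, anc$type2_segment[1], anc$type2_segment[2])
  t1 <- detect_type(type1, anc)
  expect_equal(t1$provirus_type, "I")
  expect_equal(t1$deletion_len, 292L)
  # reported deletion overlaps the segment
  expect_gt(min(t1$deletion_locus[2], anc$type2_segment[2]) -
              max(t1$deletion_locus[1], anc$type2_segment[1]), 0L)

  # a 292-bp deletion far from the pol-env boundary is NOT type I
  far <- excise(anc$seq, 2000L, 2292L)
  expect_equal(detect_type(far, anc)$provirus_type, "II")
  # nor is a small deletion inside the segment
  small <- excise(anc$seq, anc$type2_segment[1] + 10L,
                  anc$type2_segment[1] + 60L)
  expect_equal(detect_type(small, anc)$provirus_type, "II")
})

test_that("find_deletions recovers a planted 164-bp env deletion", {
  anc <- build_ancestor(sim_config(seed = 29))
  env_del_start <- anc$type2_segment[2] + 400L
  mut <- excise(anc$seq, env_del_start, env_del_start + 164L)
  dels <- find_deletions(mut, anc$seq, min_len = 100L)
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$width, 164L)
  expect_lt(abs(dels$start - env_del_start), 5L)  # alignment-shift slack
})

test_that("predict_amplicon_sizes: the type II - type I difference is 292", {
  cfg <- sim_config(seed = 3)
  anc <- build_ancestor(cfg)
  primers <- design_primers(anc)
  unsp <- primers[primers$name == "unspliced", ]
  type1 <- excise(anc$seq, anc$type2_segment[1], anc$type2_segment[2])
  a2 <- predict_amplicon_sizes(anc$seq, unsp)
  a1 <- predict_amplicon_sizes(type1, unsp)
  expect_equal(nrow(a2), 1L)
  expect_equal(nrow(a1), 1L)
  expect_equal(a2$length - a1$length, 292L)

  # primer absent from the template -> no product
  none <- predict_amplicon_sizes(anc$seq,
                                 list(fwd = "ACGTACGTACGTACGTACGT",
                                      rev = unsp$rev))
  expect_equal(nrow(none), 0L)

  # a pair spanning the canonical intron: product shorter by intron length
  env1x <- primers[primers$name == "env1x", ]
  intron <- anc$canonical_3ss - anc$canonical_5ss
  spliced <- excise(anc$seq, anc$canonical_5ss, anc$canonical_3ss)
  on_unspliced <- predict_amplicon_sizes(anc$seq, env1x, max_len = 10000L)
  on_spliced <- predict_amplicon_sizes(spliced, env1x, max_len = 10000L)
  expect_equal(on_unspliced$length - on_spliced$length, intron)
  # and the 5-kb cap suppresses the unspliced product
  expect_equal(nrow(predict_amplicon_sizes(anc$seq, env1x)), 0L)
})
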