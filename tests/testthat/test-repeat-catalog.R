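ucsc_table <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\tid",
               rows), path)
  path
}

test_that("parse_repeat_table handles both dialects' conventions", {
  p <- ucsc_table("chr1\t100\t200\t+\tLTR5_Hs\tLTR/ERVK\t7")
  fr <- parse_repeat_table(p, "ucsc_rmsk_tsv")
  expect_equal(interval_length(fr), 100L)       # already half-open
  expect_equal(fr$element_id, 7L)

  # .out rows: 1-based inclusive, strand C = minus
  out <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat class/family begin end (left) ID",
    "",
    " 1500    1.0  0.0  0.0  chr1      101   200  (900)  +  LTR5_Hs LTR/ERVK 1 100 (868) 3",
    " 1200    2.0  0.0  0.0  chr1      501   700  (400)  C  HERVK-int LTR/ERVK 1 200 (7314) 3"),
    out)
  fr2 <- parse_repeat_table(out, "rm_out")
  expect_equal(interval_length(fr2), c(100L, 200L))  # same lengths as display
  expect_equal(fr2$start, c(100L, 500L))             # converted to 0-based
  expect_equal(fr2$strand, c("+", "-"))
  expect_equal(fr2$element_id, c(3L, 3L))
})

test_that("parse_repeat_table: empty input and bad coordinates", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("genoName\tgenoStart\tgenoEnd\tstrand\trepName", empty)
  expect_equal(nrow(parse_repeat_table(empty, "ucsc_rmsk_tsv")), 0L)

  bad <- ucsc_table("chr1\tXX\t200\t+\tLTR5_Hs\tLTR/ERVK\t1")
  expect_error(parse_repeat_table(bad, "ucsc_rmsk_tsv"), "line 1")
})

test_that("filter_hervk partitions by repName and drops the rest", {
  p <- ucsc_table(c("chr1\t0\t968\t+\tLTR5_Hs\tLTR/ERVK\t1",
                    "chr1\t2000\t9000\t+\tHERVK-int\tLTR/ERVK\t2",
                    "chr1\t20000\t20300\t+\tAluY\tSINE/Alu\t3",
                    "chr2\t0\t900\t-\tLTR5A\tLTR/ERVK\t4",
                    "chr2\t5000\t5900\t-\tLTR5B\tLTR/ERVK\t5"))
  parts <- filter_hervk(parse_repeat_table(p, "ucsc_rmsk_tsv"))
  expect_equal(nrow(parts$ltr), 3L)       # all three LTR subfamilies
  expect_equal(nrow(parts$internal), 1L)
  expect_false("AluY" %in% c(parts$ltr$rep_name, parts$internal$rep_name))
})

test_that("size_histogram bins by floor(length/window) and conserves counts", {
  h <- size_histogram(968L, 20L)
  expect_equal(h, data.frame(bin_start = 960L, bin_end = 980L, count = 1L))

  h2 <- size_histogram(c(150L, 1911L, 7500L), 200L)
  expect_equal(h2$bin_start, c(0L, 1800L, 7400L))
  expect_equal(h2$count, c(1L, 1L, 1L))

  set.seed(5)
  for (i in 1:10) {
    lens <- sample.int(10000L, sample(1:400, 1), replace = TRUE)
    w <- sample(c(20L, 200L, 37L), 1)
    h3 <- size_histogram(lens, w)
    expect_equal(sum(h3$count), length(lens))
    expect_true(all(h3$bin_end - h3$bin_start == w))
  }
})

test_that("catalog statistics reproduce the published fragment accounting", {
  s <- stats_from_totals(255, 487441, 7500)
  expect_equal(s$mean_len_int, 1911L)     # mean internal fragment length
  expect_equal(s$pct_of_full_int, 25L)    # ~25% of a full internal segment
  expect_equal(s$frags_per_element, 7500 / (487441 / 255))  # ~3.9, "roughly 4"
  expect_lt(abs(s$frags_per_element - 4), 0.5)

  single <- catalog_stats(genome_interval("c", 0, 864, "+"), 968)
  expect_equal(single$mean_len, 864)
  expect_equal(single$total_bp, 864)

  set.seed(9)
  for (i in 1:10) {
    lens <- sample.int(9000L, sample(2:200, 1), replace = TRUE)
    fr <- genome_interval("c", seq_along(lens) * 20000, seq_along(lens) * 20000 + lens, "+")
    cs <- catalog_stats(fr, 7500)
    expect_equal(cs$mean_len, sum(lens) / length(lens))  # brute-force mean
  }
})

test_that("classify_elements clusters fragments and calls element kinds", {
  ltr <- data.frame(chrom = "c1", start = c(0L, 8440L), end = c(968L, 9408L),
                    strand = "+", rep_name = "LTR5_Hs", rep_class = "LTR/ERVK",
                    element_id = NA_integer_, stringsAsFactors = FALSE)
  int <- data.frame(chrom = "c1", start = 968L, end = 8440L, strand = "+",
                    rep_name = "HERVK-int", rep_class = "LTR/ERVK",
                    element_id = NA_integer_, stringsAsFactors = FALSE)
  el <- classify_elements(ltr, int)
  expect_equal(nrow(el), 1L)
  expect_equal(el$kind, "provirus")
  expect_equal(el$n_fragments, 3L)

  # lone full-length LTR far from anything -> solo; short scrap -> fragment
  solo <- data.frame(chrom = "c2", start = c(0L, 50000L),
                     end = c(968L, 50300L), strand = "+",
                     rep_name = "LTR5_Hs", rep_class = "LTR/ERVK",
                     element_id = NA_integer_, stringsAsFactors = FALSE)
  el2 <- classify_elements(solo, int[0, ])
  expect_equal(el2$kind, c("solo_ltr", "ltr_fragment"))

  # internal split by a 300-bp foreign insertion, both LTRs present
  int4 <- data.frame(chrom = "c1", start = c(968L, 4300L),
                     end = c(4000L, 8440L), strand = "+",
                     rep_name = "HERVK-int", rep_class = "LTR/ERVK",
                     element_id = NA_integer_, stringsAsFactors = FALSE)
  el3 <- classify_elements(ltr, int4)
  expect_equal(el3$kind, "provirus")
  expect_equal(el3$n_fragments, 4L)

  # internal-only cluster
  el4 <- classify_elements(ltr[0, ], int)
  expect_equal(el4$kind, "internal_only")

  # overlapping same-strand fragments merge with a warning
  ovl <- rbind(ltr, transform(ltr[1, ], start = 500L, end = 1500L))
  expect_warning(classify_elements(ovl, int), "overlap")
})

test_that("classify_elements reconstructs the generator's truth table", {
  world <- plant_loci(sim_config(seed = 101, n_proviruses = 4L,
                                 n_solo_ltrs = 6L))
  parts <- filter_hervk(world$fragments)
  expect_gte(nrow(parts$ltr), 4L + 6L)    # >= one LTR row per element
  expect_gte(nrow(parts$internal), 4L)
  el <- classify_elements(parts$ltr, parts$internal)
  expect_equal(nrow(el), nrow(world$truth$loci))
  expect_equal(sort(el$kind), sort(world$truth$loci$kind))
  # spans match the truth intervals exactly
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  expect_setequal(key(el), key(world$truth$loci))
})
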