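rec <- lmigratoria_satellitome()

test_that("the annotation table parses and matches its printed totals", {
  expect_equal(nrow(rec), 62)
  expect_equal(sum(rec$v), 107)
  expect_equal(sum(rec$ab_sl, na.rm = TRUE), 2.39241, tolerance = 1e-9)
  expect_equal(sum(rec$ab_nl, na.rm = TRUE), 2.7417, tolerance = 1e-9)
  # location cells only hold known tokens (parse would have failed otherwise)
  expect_error(
    read_annotation_table({
      f <- tempfile()
      writeLines(c("family\tlength\tat\tv\tab_sl\tab_nl\tdiv_sl\tdiv_nl\tcontigs\tmnrpc\tL1\tpattern",
                   "X\t10\t50\t1\t0.1\t0.1\t1\t1\t5\t2\tz\tc"), f)
      f
    }), "unknown location token")
})

test_that("location summary reproduces the cluster counts", {
  loc <- summarize_locations(rec)
  expect_equal(loc$p, 52)
  expect_equal(loc$i, 26)
  expect_equal(loc$d, 11)
  expect_equal(loc$total_loci, 89)
  expect_equal(loc$n_clustered_families, 47)
  expect_equal(round(loc$clusters_per_satdna, 2), 1.89)
  expect_equal(round(loc$clusters_per_chromosome, 2), 7.42)
  # empty table gives zeros
  empty <- summarize_locations(rec[0, ])
  expect_equal(empty$total_loci, 0)
  # toy table: one p on one chromosome, i and d on another
  toy <- rec[0, c("family", "pattern", "L1", "L2")]
  toy <- tibble::add_row(toy, family = "A", pattern = "c", L1 = "p", L2 = "")
  toy <- tibble::add_row(toy, family = "B", pattern = "c", L1 = "", L2 = "i,d")
  tl <- summarize_locations(toy)
  expect_equal(c(tl$p, tl$i, tl$d, tl$total_loci), c(1, 1, 1, 3))
})

test_that("the length gap divides short from long families", {
  ws <- satellitome_working_set(rec)
  expect_equal(nrow(ws), 58)
  ld <- length_distribution(ws)
  expect_equal(ld$gap, 37)
  expect_equal(c(ld$gap_lower, ld$gap_upper), c(90, 127))
  expect_equal(ld$n_short, 26)
  expect_equal(ld$n_long, 32)
  # a lone extreme length is not a group of its own
  toy <- tibble::tibble(length = c(10, 12, 15, 50, 52, 55, 300))
  ld2 <- length_distribution(toy)
  expect_equal(ld2$gap, 35)
  expect_equal(c(ld2$gap_lower, ld2$gap_upper), c(15, 50))
  # single family: no gap
  expect_true(is.na(length_distribution(tibble::tibble(length = 50))$gap))
})

test_that("rank statistics agree with brute-force oracles", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(mann_whitney_u(c(10, 20), c(1, 2)), 0)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4)), 1)
  expect_equal(mann_whitney_u(c(1, 1), c(1, 2)), oracle_mwu(c(1, 1), c(1, 2)))
  set.seed(801)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- sample(1:8, n, replace = TRUE)   # ties on purpose
    y <- sample(1:8, n, replace = TRUE)
    if (length(unique(x)) > 1 && length(unique(y)) > 1) {
      expect_equal(spearman_rho(x, y), oracle_spearman(x, y),
                   tolerance = 1e-12)
    }
    a <- sample(1:6, sample(2:6, 1), replace = TRUE)
    b <- sample(1:6, sample(2:6, 1), replace = TRUE)
    expect_equal(mann_whitney_u(a, b), oracle_mwu(a, b), tolerance = 1e-12)
  }
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("abundance-contig correlation and group comparison match the table", {
  sm <- satellitome_summary(rec)
  expect_equal(round(sm$spearman_abundance_contigs, 2), 0.46)
  expect_equal(sm$mwu_contigs_clustered_vs_not, 198)
  expect_equal(sm$total_variants, 107)
  expect_equal(round(sm$total_abundance_sl, 2), 2.39)
  expect_equal(sm$n_chromosome_specific, 33)
})

test_that("chromosome-specific families are those on a single chromosome", {
  cs <- chromosome_specific(rec)
  expect_length(cs, 33)
  # two clusters on one chromosome still count as specific
  expect_true("LmiSat21-38" %in% cs)
  # a family spread over many chromosomes does not
  expect_false("LmiSat01-193" %in% cs)
  expect_length(chromosome_specific(rec[0, ]), 0)
})
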