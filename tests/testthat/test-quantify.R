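test_that("K2P closed form matches hand-evaluated values", {
  expect_equal(k2p_divergence(0, 0), 0)
  expect_equal(round(k2p_divergence(0.1, 0.05), 2), 17.02)
  expect_equal(round(k2p_divergence(0.2, 0.1), 2), 40.24)
  # saturated inputs flagged as NA
  expect_true(is.na(k2p_divergence(0.5, 0.1)))
  expect_true(is.na(k2p_divergence(0.1, 0.5)))
  # monotone nondecreasing in P for fixed Q within the domain
  P <- seq(0, 0.3, by = 0.01)
  k <- k2p_divergence(P, 0.1)
  expect_true(all(diff(k[!is.na(k)]) >= 0))
})

test_that("K2P agrees with an established distance implementation", {
  skip_if_not_installed("ape")
  set.seed(401)
  a <- strsplit(random_dna(2000), "")[[1]]
  b <- a
  idx <- sample.int(2000, 200)
  for (p in idx) b[p] <- sample(setdiff(c("a", "c", "g", "t"),
                                        tolower(b[p])), 1)
  m <- rbind(tolower(a), tolower(b))
  d_ape <- ape::dist.dna(ape::as.DNAbin(m), model = "K80") * 100
  ts <- sum((toupper(m[1, ]) == "A" & toupper(m[2, ]) == "G") |
              (toupper(m[1, ]) == "G" & toupper(m[2, ]) == "A") |
              (toupper(m[1, ]) == "C" & toupper(m[2, ]) == "T") |
              (toupper(m[1, ]) == "T" & toupper(m[2, ]) == "C"))
  tv <- sum(toupper(m[1, ]) != toupper(m[2, ])) - ts
  expect_equal(k2p_divergence(ts / 2000, tv / 2000), as.numeric(d_ape),
               tolerance = 1e-8)
})

test_that("dimer references surpass 200 bp with the fewest copies", {
  expect_equal(nchar(build_reference_dimers("A")), 201)
  refs <- build_reference_dimers(c(strrep("A", 193), strrep("C", 30),
                                   strrep("G", 100)))
  expect_equal(nchar(refs), c(386, 210, 300))   # 2, 7 and 3 copies
  expect_equal(refs[1], strrep(strrep("A", 193), 2))
})

test_that("read-library alignment assigns reads to the best variant", {
  set.seed(402)
  monoA <- random_dna(100)
  monoB <- monoA
  for (p in sample.int(100, 15)) {
    substr(monoB, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(monoB, p, p)), 1)
  }
  lib <- tibble::tibble(family = c("famA", "famB"),
                        variant = c("famA#1", "famB#1"),
                        monomer_length = 100,
                        ref = build_reference_dimers(c(monoA, monoB)))
  # a read equal to a slice of A's reference
  read_exact <- substr(lib$ref[1], 20, 119)
  hits <- align_reads_to_library(c(q1 = read_exact), lib)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$family, "famA")
  expect_equal(hits$aligned_nt, 100)
  expect_equal(hits$k2p, 0)
  # a read a few substitutions from A stays with A, not B
  read_near <- read_exact
  for (p in c(10, 50, 90)) {
    substr(read_near, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(read_near, p, p)), 1)
  }
  hits2 <- align_reads_to_library(c(q2 = read_near), lib)
  expect_equal(hits2$family[which.max(hits2$aligned_nt)], "famA")
  # random reads produce nothing
  expect_equal(nrow(align_reads_to_library(random_dna(rep(100, 5)), lib)), 0)
})

test_that("abundance and weighted divergence aggregate hits correctly", {
  hits <- tibble::tibble(query_id = c("r1", "r2"),
                         family = "f", variant = "f#1",
                         q_start = 1L, q_end = 100L, strand = "+",
                         aligned_nt = c(300L, 100L), identity = 99,
                         P = 0, Q = 0, k2p = c(2, 6))
  fa <- family_abundance(hits, 100000)
  expect_equal(fa$abundance, 100 * 400 / 100000)
  expect_equal(fa$mean_divergence, 3)   # (300*2 + 100*6) / 400
  # landscape bins conserve family abundance
  ls <- repeat_landscape(hits, 100000)
  expect_equal(sum(ls$abundance), fa$abundance, tolerance = 1e-9)
  expect_setequal(ls$bin, c(2, 6))
})

test_that("abundance recovery from simulated reads is within 20% relative error", {
  set.seed(403)
  mono <- random_dna(150)
  g <- simulate_genome(family_spec(mono, 1, "clustered", name = "f",
                                   divergence = 0.02), 3e5, seed = 41)
  truth <- g$truth$families$proportion
  rp <- simulate_reads(g, 15000, seed = 42, error_rate = 0.01)
  lib <- tibble::tibble(family = "f", variant = "f#1", monomer_length = 150,
                        ref = build_reference_dimers(mono))
  reads <- c(rp$seq1, rp$seq2)
  hits <- align_reads_to_library(reads, lib)
  est <- family_abundance(hits, sum(nchar(reads)))$abundance
  expect_lt(abs(est - truth) / truth, 0.2)
})

test_that("assembly scan counts contigs by the 200-bp rule and reports MNRPC", {
  set.seed(404)
  mono <- random_dna(193)
  lib <- tibble::tibble(family = "f", variant = "f#1", monomer_length = 193,
                        ref = build_reference_dimers(mono))
  bg <- random_dna(2000)
  contigs <- c(
    c15 = paste0(random_dna(500), strrep(mono, 15), random_dna(500)),
    c150 = paste0(random_dna(300), substr(mono, 1, 150), random_dna(300)),
    c250 = paste0(random_dna(300), substr(strrep(mono, 2), 1, 250),
                  random_dna(300)),
    none = bg)
  scan <- scan_assembly(contigs, lib)
  sm <- scan$summary
  expect_equal(sm$n_contigs, 2)   # the 15-copy and the 250-bp contig
  expect_equal(sm$mnrpc, 15)
  cs <- scan$contig_stats
  expect_false("c150" %in% cs$contig_id[cs$aligned_nt >= 200])
  expect_true("c250" %in% cs$contig_id[cs$aligned_nt >= 200])
})

test_that("landscape mode sits at the planted divergence", {
  set.seed(405)
  mono <- random_dna(150)
  g <- simulate_genome(family_spec(mono, 2, "clustered", name = "f",
                                   divergence = 0.05), 2e5, seed = 51)
  rp <- simulate_reads(g, 8000, seed = 52, error_rate = 0)
  lib <- tibble::tibble(family = "f", variant = "f#1", monomer_length = 150,
                        ref = build_reference_dimers(mono))
  reads <- c(rp$seq1, rp$seq2)
  hits <- align_reads_to_library(reads, lib)
  ls <- repeat_landscape(hits, sum(nchar(reads)))
  mode_bin <- ls$bin[which.max(ls$abundance)]
  expect_true(mode_bin >= 4 && mode_bin <= 6)
})
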