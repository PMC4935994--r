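test_that("pairwise identity is symmetric and rotation/strand blind", {
  set.seed(301)
  a <- random_dna(100)
  expect_equal(pairwise_identity(a, a), 100)
  # one substitution in a 100-bp monomer
  b <- a
  substr(b, 37, 37) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 37, 37))[1]
  expect_equal(pairwise_identity(a, b), 99)
  for (i in 1:5) {
    x <- random_dna(60)
    y <- random_dna(60)
    expect_equal(pairwise_identity(x, y), pairwise_identity(y, x))
    expect_equal(pairwise_identity(x, rotate_seq(x, sample.int(59, 1))), 100)
    expect_equal(pairwise_identity(x, revcomp(x)), 100)
  }
})

test_that("catalog tiers follow the 95/80 thresholds", {
  set.seed(302)
  base <- random_dna(100)
  mutate_pct <- function(x, k) {
    pos <- sample.int(nchar(x), k)
    for (p in pos) {
      substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(x, p, p)), 1)
    }
    x
  }
  # 97% pair -> one family, one variant
  cat1 <- group_catalog(tibble::tibble(seq = c(base, mutate_pct(base, 3)),
                                       abundance = c(2, 1)))
  expect_equal(nrow(cat1$families), 1)
  expect_equal(nrow(cat1$variants), 1)
  # 85% pair -> one family, two variants
  cat2 <- group_catalog(tibble::tibble(seq = c(base, mutate_pct(base, 15)),
                                       abundance = c(2, 1)))
  expect_equal(nrow(cat2$families), 1)
  expect_equal(nrow(cat2$variants), 2)
  # ~70% pair with a long alignable core -> two families, one superfamily
  cat3 <- group_catalog(tibble::tibble(seq = c(base, mutate_pct(base, 30)),
                                       abundance = c(2, 1)))
  expect_equal(nrow(cat3$families), 2)
  expect_equal(length(unique(stats::na.omit(cat3$families$superfamily_id))), 1)
  # unrelated monomer stays outside any superfamily
  cat4 <- group_catalog(tibble::tibble(seq = c(base, random_dna(100)),
                                       abundance = c(2, 1)))
  expect_true(all(is.na(cat4$families$superfamily_id)))
})

test_that("single linkage collapses chained variants and ignores input order", {
  set.seed(303)
  a <- random_dna(100)
  b <- a; for (p in sample.int(100, 3)) {
    substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(b, p, p)), 1)
  }
  c_ <- b; for (p in sample.int(100, 3)) {
    substr(c_, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                       substr(c_, p, p)), 1)
  }
  # a~b and b~c above the variant threshold chain into one variant group
  for (ord in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    cat <- group_catalog(tibble::tibble(seq = c(a, b, c_)[ord],
                                        abundance = c(3, 2, 1)[ord]))
    expect_equal(nrow(cat$families), 1)
  }
})

test_that("naming encodes rank and monomer length recoverably", {
  set.seed(304)
  cat <- group_catalog(tibble::tibble(
    seq = c(random_dna(193), random_dna(176), random_dna(60)),
    abundance = c(3, 2, 1)))
  named <- name_families(cat, "Lmi")
  expect_equal(named$families$name[1], sprintf("LmiSat01-%d",
                                               named$families$monomer_length[1]))
  parsed <- parse_family_name(named$families$name)
  expect_equal(parsed$catalog_number, seq_len(3))
  expect_equal(parsed$monomer_length, named$families$monomer_length)
  expect_true(all(parsed$species_abbrev == "Lmi"))
  # functional suffix round-trips
  renamed <- rename_family(named, named$families$name[3], "tel")
  expect_match(renamed$families$name[3], "-tel$")
  expect_equal(parse_family_name(renamed$families$name[3])$suffix, "tel")
  # tidy/glance surface the catalog as tables
  td <- tidy(named)
  expect_true(all(c("family_id", "variant_index", "seq", "name") %in% names(td)))
  expect_equal(glance(named)$n_families, 3)
})

test_that("MST edges carry substitution and indel-event distances", {
  a <- "ACGTACGTAAGGCCTTACGTACGTACGT"
  b <- "ACGTACCTAAGGCCTTACGAACGTACGT"            # two substitutions
  b2 <- paste0(substr(b, 1, 10), substr(b, 14, 28))  # plus one 3-bp indel
  m <- build_mst(c(x = a, y = b2))
  expect_equal(m$s, 2)
  expect_equal(m$id, 1)
  expect_equal(m$id_nt, 3)
  expect_equal(m$weight, 3)
  # identical variants: zero-weight edge
  m0 <- build_mst(c(p = a, q = a))
  expect_equal(m0$weight, 0)
  expect_error(build_mst(c(a)), "at least 2")
})

test_that("MST total weight matches brute-force enumeration", {
  set.seed(305)
  for (rep_i in 1:3) {
    n <- 5
    base <- random_dna(60)
    seqs <- vapply(1:n, function(i) {
      x <- base
      for (p in sample.int(60, sample.int(8, 1))) {
        substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(x, p, p)), 1)
      }
      x
    }, character(1))
    names(seqs) <- paste0("v", 1:n)
    m <- build_mst(seqs)
    # brute-force weight matrix from the same pairwise distances
    w <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- satkit:::.rotational_identity_cpp(seqs[i], seqs[j])
      w[i, j] <- w[j, i] <- r$substitutions + r$indel_events
    }
    expect_equal(sum(m$weight), oracle_mst_weight(w))
  }
})
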