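test_that("edges require identity and overlap on either strand", {
  set.seed(101)
  a <- random_dna(100)
  # identical pair, a reverse complement, and two unrelated reads
  reads <- c(r1 = a, r2 = a, r3 = revcomp(a),
             r4 = random_dna(100), r5 = random_dna(100))
  g <- build_read_graph(reads, min_identity = 90)
  pairs <- paste(pmin(g$edges$from, g$edges$to),
                 pmax(g$edges$from, g$edges$to))
  expect_setequal(pairs, c("r1 r2", "r1 r3", "r2 r3"))
  expect_true(all(g$edges$identity == 100))
  expect_error(build_read_graph(character()), "no reads")
})

test_that("reads tiling a tandem array form one dense component", {
  set.seed(102)
  mono <- random_dna(50)
  arr <- strrep(mono, 12)
  reads <- tiling_reads(arr, 100, 50)
  g <- build_read_graph(reads)
  comps <- read_components(g)
  expect_equal(nrow(comps), 1)
  expect_equal(comps$n_reads[1], length(reads))
  expect_equal(comps$genome_proportion[1], 100)
  expect_gt(cluster_density(comps$reads[[1]], g), 1)
})

test_that("components match the transitive-closure oracle and ignore input order", {
  set.seed(103)
  for (rep_i in 1:5) {
    n <- sample(10:50, 1)
    seqs <- random_dna(rep(60, n))
    # plant identical groups to force edges
    grp <- sample.int(5, n, replace = TRUE)
    for (gidx in 1:5) {
      ix <- which(grp == gidx)
      if (length(ix) > 1) seqs[ix] <- seqs[ix[1]]
    }
    names(seqs) <- paste0("r", seq_len(n))
    g <- build_read_graph(seqs)
    comps <- read_components(g)
    memb <- integer(n)
    for (ci in seq_len(nrow(comps))) {
      memb[match(comps$reads[[ci]], names(seqs))] <- ci
    }
    from <- match(g$edges$from, names(seqs))
    to <- match(g$edges$to, names(seqs))
    oracle <- oracle_components(n, from, to)
    # same partition up to labels
    expect_equal(length(unique(memb)), length(unique(oracle)))
    expect_true(all(tapply(oracle, memb, function(z) length(unique(z))) == 1))
    # order invariance
    perm <- sample.int(n)
    g2 <- build_read_graph(seqs[perm])
    comps2 <- read_components(g2)
    expect_equal(sort(comps2$n_reads), sort(comps$n_reads))
    # conservation of genome proportion
    expect_equal(sum(comps$genome_proportion), 100)
  }
})

test_that("density equals mean links per read", {
  k4 <- tibble::tibble(id = paste0("n", 1:4), seq = rep(strrep("A", 10), 4))
  g <- structure(list(
    nodes = k4,
    edges = tibble::tibble(from = c("n1", "n1", "n1", "n2", "n2", "n3"),
                           to = c("n2", "n3", "n4", "n3", "n4", "n4"),
                           identity = 100, overlap_frac = 1),
    total_nt = 40), class = "sat_read_graph")
  expect_equal(cluster_density(paste0("n", 1:4), g), 3)   # K4: 2*6/4
  expect_equal(cluster_density("n1", structure(list(
    nodes = k4[1, ], edges = g$edges[0, ], total_nt = 10),
    class = "sat_read_graph")), 0)
  g2 <- structure(list(nodes = k4[1:2, ], edges = g$edges[1, ],
                       total_nt = 20), class = "sat_read_graph")
  expect_equal(cluster_density(c("n1", "n2"), g2), 1)
  expect_error(cluster_density(character(), g), "empty")
})

test_that("shape classification separates paths, cycles and balls", {
  path_graph <- function(n) {
    ids <- paste0("p", seq_len(n))
    structure(list(
      nodes = tibble::tibble(id = ids, seq = rep(strrep("A", 5), n)),
      edges = tibble::tibble(from = ids[-n], to = ids[-1],
                             identity = 100, overlap_frac = 1),
      total_nt = 5 * n), class = "sat_read_graph")
  }
  cycle_graph <- function(n) {
    g <- path_graph(n)
    g$edges <- dplyr::bind_rows(g$edges, tibble::tibble(
      from = paste0("p", n), to = "p1", identity = 100, overlap_frac = 1))
    g
  }
  g <- path_graph(20)
  expect_equal(classify_shape(g$nodes$id, g), "linear")
  for (n in c(10, 25, 50, 100)) {
    cg <- cycle_graph(n)
    expect_equal(classify_shape(cg$nodes$id, cg), "ring")
  }
  # short-monomer tandem reads give a dense near-complete graph
  set.seed(104)
  mono <- random_dna(20)
  reads <- tiling_reads(strrep(mono, 30), 100, 40)
  rg <- build_read_graph(reads)
  comps <- read_components(rg)
  expect_equal(classify_shape(comps$reads[[1]], rg), "globular")
  # degenerate tiny cluster
  expect_equal(classify_shape(c("a", "b"), rg), "linear")
})

test_that("candidate selection needs satellite shape and density above cutoff", {
  cl <- tibble::tibble(
    cluster_id = 1:4,
    reads = list("a", "b", "c", "d"),
    n_reads = c(10L, 10L, 10L, 10L), nt = 1, genome_proportion = 25,
    density = c(0.05, 5, 1.9, 0.11),
    shape = c("globular", "linear", "ring", "globular"))
  sel <- select_candidate_clusters(cl, 0.1)
  expect_equal(sel$cluster_id, c(3L, 4L))
})
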