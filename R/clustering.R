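#' Build a read-similarity graph
#'
#' Every unordered read pair whose best local alignment (either strand)
#' reaches `min_identity` percent identity over at least `min_overlap_frac`
#' of the shorter read becomes an edge.  An exact canonical k-mer prefilter
#' (reads must share at least one canonical k-mer before alignment) keeps the
#' all-vs-all cost tractable without changing the edge set at these
#' thresholds.
#'
#' @param reads Character vector of DNA reads (roughly uniform length), or a
#'   tibble with columns `id` and `seq`.
#' @param min_identity Minimum percent identity of the aligned region.
#' @param min_overlap_frac Minimum aligned fraction of the shorter read.
#' @param k Prefilter k-mer size.
#' @return An object of class `sat_read_graph`: a list with tibbles `nodes`
#'   (`id`, `seq`) and `edges` (`from`, `to`, `identity`, `overlap_frac`),
#'   plus `total_nt`, the summed read length.
#' @export
build_read_graph <- function(reads, min_identity = 90, min_overlap_frac = 0.55,
                             k = 13) {
  if (is.data.frame(reads)) {
    ids <- reads$id
    seqs <- toupper(reads$seq)
  } else {
    seqs <- toupper(unname(reads))
    ids <- names(reads) %||% paste0("read", seq_along(seqs))
  }
  if (length(seqs) == 0) abort("no reads supplied")
  check_dna(seqs, arg = "reads")
  cand <- kmer_candidate_pairs(seqs, k = k)
  edges <- tibble(from = character(), to = character(),
                  identity = numeric(), overlap_frac = numeric())
  if (length(cand$from)) {
    aln <- align_best_strand(seqs[cand$from], seqs[cand$to], mode = 0L)
    identity <- ifelse(aln$columns > 0, 100 * aln$matches / aln$columns, 0)
    shorter <- pmin(nchar(seqs[cand$from]), nchar(seqs[cand$to]))
    overlap <- aln$columns / shorter
    keep <- identity >= min_identity & overlap >= min_overlap_frac
    edges <- tibble(from = ids[cand$from[keep]], to = ids[cand$to[keep]],
                    identity = identity[keep], overlap_frac = overlap[keep])
  }
  structure(list(nodes = tibble(id = ids, seq = seqs),
                 edges = edges,
                 total_nt = sum(nchar(seqs))),
            class = "sat_read_graph")
}

graph_to_igraph <- function(graph, ids = NULL) {
  nodes <- graph$nodes
  edges <- graph$edges
  if (!is.null(ids)) {
    nodes <- nodes[nodes$id %in% ids, , drop = FALSE]
    edges <- edges[edges$from %in% ids & edges$to %in% ids, , drop = FALSE]
  }
  igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE,
                                vertices = nodes$id)
}

#' Extract connected components as repeat clusters
#'
#' Components are ordered by decreasing member count (singletons included, so
#' genome proportions sum to 100).  `genome_proportion` is the cluster's
#' share of all sampled nucleotides.
#'
#' @param graph A `sat_read_graph`.
#' @return A tibble with `cluster_id`, `reads` (list-column of read ids),
#'   `n_reads`, `nt` and `genome_proportion`.
#' @export
read_components <- function(graph) {
  g <- graph_to_igraph(graph)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  nt_by_id <- stats::setNames(nchar(graph$nodes$seq), graph$nodes$id)
  res <- tibble(
    reads = unname(members),
    n_reads = unname(lengths(members)),
    nt = unname(vapply(members, function(m) sum(nt_by_id[m]), numeric(1)))
  )
  res <- res[order(-res$n_reads), , drop = FALSE]
  res$cluster_id <- seq_len(nrow(res))
  res$genome_proportion <- 100 * res$nt / graph$total_nt
  res[, c("cluster_id", "reads", "n_reads", "nt", "genome_proportion")]
}

#' Mean number of links per read in a cluster
#'
#' Density is the mean degree `2 * E / V` over the cluster's internal edges.
#'
#' @param members Character vector of member read ids.
#' @param graph The `sat_read_graph` the cluster came from.
#' @return A single number `>= 0`.
#' @export
cluster_density <- function(members, graph) {
  if (length(members) == 0) abort("empty cluster")
  e <- graph$edges
  internal <- sum(e$from %in% members & e$to %in% members)
  2 * internal / length(members)
}

#' Classify the shape of a cluster's subgraph
#'
#' Ring clusters are recognised first: the 2-core must be a single cycle
#' (every 2-core vertex of degree exactly 2, connected) covering at least
#' `ring_cover` of the nodes.  Otherwise a normalised diameter
#' `D / V >= tau_lin` marks a linear cluster; everything else is globular,
#' the dense ball-like structure tandem repeats produce.  Clusters under 3
#' reads are degenerate and labelled linear.
#'
#' @param members Character vector of member read ids.
#' @param graph The `sat_read_graph`.
#' @param tau_lin Normalised-diameter threshold for linear clusters.
#' @param ring_cover Minimum fraction of nodes the cycle must cover.
#' @return One of `"linear"`, `"globular"`, `"ring"`.
#' @export
classify_shape <- function(members, graph, tau_lin = 0.5, ring_cover = 0.8) {
  if (length(members) < 3) return("linear")
  g <- graph_to_igraph(graph, ids = members)
  classify_shape_igraph(g, tau_lin = tau_lin, ring_cover = ring_cover)
}

classify_shape_igraph <- function(g, tau_lin = 0.5, ring_cover = 0.8) {
  nv <- igraph::vcount(g)
  if (nv < 3) return("linear")
  core <- igraph::coreness(g)
  two_core <- names(core)[core >= 2]
  if (length(two_core) >= 3 && length(two_core) >= ring_cover * nv) {
    sub <- igraph::induced_subgraph(g, two_core)
    if (all(igraph::degree(sub) == 2) && igraph::is_connected(sub)) {
      return("ring")
    }
  }
  d <- graph_diameter(g)
  if (d / nv >= tau_lin) return("linear")
  "globular"
}

# exact unweighted diameter for small graphs; double-BFS eccentricity
# estimate (tight on the path-like graphs that matter for the linear class)
# for large ones
graph_diameter <- function(g, exact_max = 2000) {
  if (igraph::vcount(g) <= exact_max) {
    return(igraph::diameter(g, weights = NA))
  }
  v0 <- igraph::V(g)[1]
  d1 <- igraph::distances(g, v = v0, weights = NA)
  far <- which.max(ifelse(is.finite(d1), d1, -1))
  d2 <- igraph::distances(g, v = igraph::V(g)[far], weights = NA)
  max(d2[is.finite(d2)])
}

#' Annotate clusters with density and shape
#'
#' @param clusters Cluster tibble from [read_components()].
#' @param graph The `sat_read_graph`.
#' @inheritParams classify_shape
#' @return `clusters` with `density` and `shape` columns added.
#' @export
annotate_clusters <- function(clusters, graph, tau_lin = 0.5, ring_cover = 0.8) {
  if (nrow(clusters) == 0) {
    clusters$density <- numeric()
    clusters$shape <- character()
    return(clusters)
  }
  lookup <- stats::setNames(rep(clusters$cluster_id, lengths(clusters$reads)),
                            unlist(clusters$reads))
  ef <- lookup[graph$edges$from]
  et <- lookup[graph$edges$to]
  same <- !is.na(ef) & !is.na(et) & ef == et
  ecount <- table(factor(ef[same], levels = clusters$cluster_id))
  clusters$density <- 2 * as.integer(ecount) / clusters$n_reads
  g <- graph_to_igraph(graph)
  clusters$shape <- vapply(clusters$reads, function(m) {
    if (length(m) < 3) return("linear")
    classify_shape_igraph(igraph::induced_subgraph(g, m),
                          tau_lin = tau_lin, ring_cover = ring_cover)
  }, character(1))
  clusters
}

#' Select satellite-candidate clusters
#'
#' Keeps clusters whose shape is globular (spherical) or ring and whose
#' density strictly exceeds the threshold.
#'
#' @param clusters Annotated cluster tibble (see [annotate_clusters()]).
#' @param density_threshold Minimum density (exclusive).
#' @return The selected subset of `clusters`.
#' @export
select_candidate_clusters <- function(clusters, density_threshold = 0.1) {
  clusters[clusters$shape %in% c("globular", "ring") &
             clusters$density > density_threshold, , drop = FALSE]
}

#' Cluster reads and report satellite candidates in one call
#'
#' Convenience wrapper chaining [build_read_graph()], [read_components()] and
#' [annotate_clusters()].
#'
#' @inheritParams build_read_graph
#' @inheritParams classify_shape
#' @param min_reads Drop components smaller than this before annotation.
#' @return A list with the `graph` and the annotated `clusters` tibble.
#' @export
cluster_reads <- function(reads, min_identity = 90, min_overlap_frac = 0.55,
                          k = 13, min_reads = 1, tau_lin = 0.5,
                          ring_cover = 0.8) {
  graph <- build_read_graph(reads, min_identity = min_identity,
                            min_overlap_frac = min_overlap_frac, k = k)
  clusters <- read_components(graph)
  clusters <- clusters[clusters$n_reads >= min_reads, , drop = FALSE]
  clusters <- annotate_clusters(clusters, graph, tau_lin = tau_lin,
                                ring_cover = ring_cover)
  list(graph = graph, clusters = clusters)
}
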