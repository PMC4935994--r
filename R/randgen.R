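#' Count dinucleotides in a sequence
#'
#' @param seq DNA string.
#' @return Named integer vector of the 16 ACGT dinucleotide counts.
#' @export
dinucleotide_counts <- function(seq) {
  Biostrings::dinucleotideFrequency(Biostrings::DNAString(seq))
}

# uniform random arborescence towards `t` on the 4-vertex dinucleotide
# multigraph, by loop-erased random walks (Wilson's algorithm); transition
# probabilities follow edge multiplicities
sample_arborescence <- function(counts, t, verts) {
  parent <- rep(NA_integer_, length(verts))
  in_tree <- rep(FALSE, length(verts))
  in_tree[t] <- TRUE
  for (v in verts) {
    if (in_tree[v]) next
    u <- v
    path_next <- rep(NA_integer_, length(verts))
    while (!in_tree[u]) {
      out <- counts[u, ]
      nxt <- sample.int(4L, 1L, prob = out)
      path_next[u] <- nxt
      u <- nxt
    }
    u <- v
    while (!in_tree[u]) {
      in_tree[u] <- TRUE
      parent[u] <- path_next[u]
      u <- path_next[u]
    }
  }
  parent
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Euler-path shuffle: the sequence is viewed as a walk on the 4-vertex
#' graph whose edges are its dinucleotides, and a uniform-ish random Eulerian
#' rearrangement is drawn (random arborescence of last-exit edges towards the
#' terminal base, remaining edges permuted).  The 16 dinucleotide counts,
#' length, first and last base are conserved exactly.  Runs of N split the
#' sequence; each N-free segment is shuffled independently.
#'
#' @param seq DNA string (A/C/G/T, N allowed as separator).
#' @param seed Integer seed.
#' @return The shuffled sequence (character scalar).
#' @export
dinucleotide_shuffle <- function(seq, seed = 1) {
  seq <- toupper(seq)
  check_dna(seq, allow_n = TRUE, arg = "seq")
  with_seed(seed, {
    parts <- regmatches(seq, gregexpr("[ACGT]+|N+", seq))[[1]]
    shuffled <- vapply(parts, function(p) {
      if (startsWith(p, "N") || nchar(p) < 3) p else euler_shuffle(p)
    }, character(1), USE.NAMES = FALSE)
    paste(shuffled, collapse = "")
  })
}

euler_shuffle <- function(p) {
  x <- match(strsplit(p, "", fixed = TRUE)[[1]], DNA_BASES)
  L <- length(x)
  s <- x[1]
  t <- x[L]
  counts <- matrix(0L, 4, 4)
  for (i in 1:(L - 1)) counts[x[i], x[i + 1]] <- counts[x[i], x[i + 1]] + 1L
  verts <- which(rowSums(counts) + colSums(counts) > 0)
  # out-adjacency: for each vertex, the multiset of outgoing edge targets
  parent <- sample_arborescence(counts, t, verts)
  ord <- vector("list", 4)
  for (u in 1:4) {
    targets <- rep(1:4, counts[u, ])
    if (u != t && !is.na(parent[u]) && length(targets)) {
      # remove one copy of the last-exit edge, append it after a shuffle
      drop <- match(parent[u], targets)
      rest <- targets[-drop]
      ord[[u]] <- c(if (length(rest)) rest[sample.int(length(rest))],
                    parent[u])
    } else if (length(targets)) {
      ord[[u]] <- targets[sample.int(length(targets))]
    } else {
      ord[[u]] <- integer()
    }
  }
  out <- integer(L)
  out[1] <- s
  ptr <- rep(1L, 4)
  cur <- s
  for (i in 2:L) {
    nxt <- ord[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(DNA_BASES[out], collapse = "")
}

#' Chance occurrence of satellite families in shuffled genomes
#'
#' Shuffles each contig of the genome (dinucleotide-preserving), scans the
#' shuffled assembly against the satellite library, and records per family
#' and replicate how many contigs carry at least `contig_min_nt` aligned bp
#' and how many nucleotides aligned in total — an empirical null for how
#' much of a short monomer's signal arises by composition alone.
#'
#' @param library Library tibble from [sat_library()].
#' @param genome Named character vector of contigs, or FASTA path.
#' @param n_replicates Number of shuffled replicates (>= 1).
#' @param seed Integer seed.
#' @param ... Passed to [scan_assembly()].
#' @param contig_min_nt Aligned-bp threshold for counting a contig.
#' @return Tibble `replicate`, `family`, `n_contigs`, `aligned_nt`.
#' @export
random_occurrence <- function(library, genome, n_replicates, seed = 1,
                              contig_min_nt = 200, ...) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    genome <- stats::setNames(as.character(x), sub(" .*", "", names(x)))
  }
  out <- list()
  for (rep_i in seq_len(n_replicates)) {
    shuf <- vapply(seq_along(genome), function(i) {
      dinucleotide_shuffle(genome[[i]], seed = seed + 1000L * rep_i + i)
    }, character(1))
    names(shuf) <- names(genome) %||% paste0("contig", seq_along(genome))
    scan <- scan_assembly(shuf, library, contig_min_nt = contig_min_nt, ...)
    tot <- scan$contig_stats |>
      group_by(.data$family) |>
      summarise(aligned_nt = sum(.data$aligned_nt), .groups = "drop")
    sm <- left_join(scan$summary[, c("family", "n_contigs")], tot,
                    by = "family")
    sm$aligned_nt[is.na(sm$aligned_nt)] <- 0L
    sm$replicate <- rep_i
    out[[rep_i]] <- sm[, c("replicate", "family", "n_contigs", "aligned_nt")]
  }
  bind_rows(out)
}
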