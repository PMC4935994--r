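# shared helpers: small deterministic fixtures built in code

qual_string <- function(q, len) strrep(intToUtf8(q + 33L), len)

make_pair <- function(id, seq1, q1, seq2 = seq1, q2 = q1) {
  tibble::tibble(id = id, seq1 = seq1, qual1 = q1, seq2 = seq2, qual2 = q2)
}

# reads tiling `genome` left to right at fixed step (plus strand)
tiling_reads <- function(genome, read_len, step) {
  starts <- seq(1, nchar(genome) - read_len + 1, by = step)
  substring(genome, starts, starts + read_len - 1)
}

# a tandem array of `copies` copies of `monomer`, each independently
# mutated at `rate` substitutions per base
tandem_array <- function(monomer, copies, rate = 0, seed = 1) {
  satkit:::with_seed(seed, {
    L <- nchar(monomer)
    base <- strsplit(monomer, "")[[1]]
    paste(vapply(seq_len(copies), function(i) {
      x <- base
      nm <- stats::rbinom(1, L, rate)
      if (nm > 0) {
        pos <- sample.int(L, nm)
        for (p in pos) {
          x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
        }
      }
      paste(x, collapse = "")
    }, character(1)), collapse = "")
  })
}

rotate_seq <- function(x, k) {
  L <- nchar(x)
  k <- k %% L
  if (k == 0) return(x)
  paste0(substring(x, k + 1, L), substring(x, 1, k))
}

# brute-force oracles ------------------------------------------------------

# connected components by boolean transitive closure
oracle_components <- function(n, from, to) {
  adj <- diag(TRUE, n)
  for (e in seq_along(from)) {
    adj[from[e], to[e]] <- TRUE
    adj[to[e], from[e]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[adj[i, ]] <- cid
    }
  }
  comp
}

# Spearman rho via explicit average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Mann-Whitney U via exhaustive pair counting with half credit for ties
oracle_mwu <- function(a, b) {
  u1 <- 0
  for (x in a) for (y in b) u1 <- u1 + (x > y) + 0.5 * (x == y)
  min(u1, length(a) * length(b) - u1)
}

# minimum spanning tree total weight by enumerating all spanning trees
# (Cayley: n^(n-2) trees, fine for n <= 6); edges as weight matrix
oracle_mst_weight <- function(w) {
  n <- nrow(w)
  verts <- seq_len(n)
  best <- Inf
  # enumerate spanning trees via all Pruefer sequences
  pruefer <- function(seq_left, acc) {
    if (length(acc) == n - 2) {
      # decode Pruefer sequence acc into a tree
      degree <- rep(1L, n)
      for (v in acc) degree[v] <- degree[v] + 1L
      total <- 0
      acc2 <- acc
      for (v in acc2) {
        leaf <- min(verts[degree == 1L])
        total <- total + w[leaf, v]
        degree[leaf] <- degree[leaf] - 1L
        degree[v] <- degree[v] - 1L
      }
      rest <- verts[degree == 1L]
      total <- total + w[rest[1], rest[2]]
      best <<- min(best, total)
      return(invisible())
    }
    for (v in verts) pruefer(seq_left, c(acc, v))
  }
  if (n == 2) return(w[1, 2])
  pruefer(verts, integer())
  best
}
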