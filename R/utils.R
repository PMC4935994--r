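#' @importFrom Rcpp evalCpp
#' @importFrom rlang %||% .data abort
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows left_join row_number desc n
#' @importFrom tibble tibble as_tibble
#' @useDynLib satkit, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' A+T content of DNA strings
#'
#' Percentage of A or T bases; N bases are excluded from the denominator.
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of percentages in \code{[0, 100]}.
#' @export
at_content <- function(x) {
  f <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(x),
                                     baseOnly = TRUE)
  at <- f[, "A"] + f[, "T"]
  acgt <- rowSums(f[, DNA_BASES, drop = FALSE])
  ifelse(acgt == 0, NA_real_, 100 * at / acgt)
}

#' Random DNA sequences
#'
#' @param n Sequence length(s).
#' @param gc GC fraction (bases drawn i.i.d.).
#' @return Character vector of sequences, one per element of `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(n, function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

check_dna <- function(x, allow_n = TRUE, arg = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside %s (first offender: %s)",
                  arg, if (allow_n) "ACGTN" else "ACGT",
                  substr(x[which(bad)[1]], 1, 40)))
  }
  invisible(x)
}

# 2-bit k-mer codes, canonical over strands.  Returns a list with integer
# vector `read` (index into `seqs`) and double vector `code`; windows touching
# a non-ACGT base are dropped.  Assumes k <= 26 so codes stay exact doubles.
kmer_codes <- function(seqs, k) {
  lens <- nchar(seqs)
  reads <- list()
  codes <- list()
  gi <- 0L
  for (L in sort(unique(lens))) {
    if (L < k) next
    idx <- which(lens == L)
    chars <- strsplit(seqs[idx], "", fixed = TRUE)
    m <- matrix(match(unlist(chars, use.names = FALSE), DNA_BASES) - 1L,
                nrow = length(idx), byrow = TRUE)
    nw <- L - k + 1L
    fw <- matrix(0, length(idx), nw)
    rc <- matrix(0, length(idx), nw)
    for (t in 0:(k - 1)) {
      col <- m[, (1 + t):(nw + t), drop = FALSE]
      fw <- fw + col * 4^(k - 1 - t)
      rc <- rc + (3 - col) * 4^t
    }
    can <- pmin(fw, rc)
    keep <- !is.na(as.vector(can))
    gi <- gi + 1L
    reads[[gi]] <- rep(idx, each = 1L, times = nw)[keep]
    codes[[gi]] <- as.vector(can)[keep]
  }
  list(read = as.integer(unlist(reads) %||% integer()),
       code = as.numeric(unlist(codes) %||% numeric()))
}

# All unordered read pairs sharing at least one canonical k-mer.
kmer_candidate_pairs <- function(seqs, k = 13) {
  kc <- kmer_codes(seqs, k)
  if (length(kc$read) == 0) {
    return(list(from = integer(), to = integer()))
  }
  o <- order(kc$code, kc$read)
  code <- kc$code[o]
  read <- kc$read[o]
  nn <- length(code)
  keep <- c(TRUE, !(code[-1] == code[-nn] & read[-1] == read[-nn]))
  code <- code[keep]
  read <- read[keep]
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sz <- r$lengths
  from <- list()
  to <- list()
  # size-2 groups are the bulk; handle them vectorised
  g2 <- which(sz == 2L)
  if (length(g2)) {
    from[[1]] <- read[starts[g2]]
    to[[1]] <- read[ends[g2]]
  }
  gbig <- which(sz > 2L)
  if (length(gbig)) {
    pl <- lapply(gbig, function(g) {
      ix <- read[starts[g]:ends[g]]
      cmb <- utils::combn(ix, 2L)
      list(cmb[1, ], cmb[2, ])
    })
    from[[2]] <- unlist(lapply(pl, `[[`, 1L))
    to[[2]] <- unlist(lapply(pl, `[[`, 2L))
  }
  from <- unlist(from) %||% integer()
  to <- unlist(to) %||% integer()
  if (length(from) == 0) {
    return(list(from = integer(), to = integer()))
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- a * 2^26 + b
  keep <- !duplicated(key)
  list(from = a[keep], to = b[keep])
}

# Indices of `seqs` containing at least one canonical k-mer of `refs`.
reads_matching_kmers <- function(seqs, refs, k = 11) {
  rk <- kmer_codes(refs, k)
  if (length(rk$code) == 0) return(integer())
  refset <- unique(rk$code)
  sk <- kmer_codes(seqs, k)
  hit <- sk$code %in% refset
  sort(unique(sk$read[hit]))
}

# All (read index, ref index) pairs sharing at least one canonical k-mer, so
# downstream alignment cost scales with genuine matches rather than with the
# reference count.
kmer_read_ref_pairs <- function(seqs, refs, k = 11) {
  rk <- kmer_codes(refs, k)
  empty <- list(read = integer(), ref = integer())
  if (length(rk$code) == 0) return(empty)
  keep <- !duplicated(rk$code * 2^20 + rk$read)
  o <- order(rk$code[keep], rk$read[keep])
  ru_code <- rk$code[keep][o]
  ru_ref <- rk$read[keep][o]
  r <- rle(ru_code)
  gstart <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  glen <- r$lengths
  sk <- kmer_codes(seqs, k)
  if (length(sk$code) == 0) return(empty)
  skeep <- !duplicated(sk$code * 2^24 + sk$read)
  scode <- sk$code[skeep]
  sread <- sk$read[skeep]
  grp <- match(scode, r$values)
  hit <- !is.na(grp)
  if (!any(hit)) return(empty)
  g <- grp[hit]
  read <- rep(sread[hit], glen[g])
  ref <- ru_ref[sequence(glen[g], from = gstart[g])]
  key <- read * 2^20 + ref
  keep2 <- !duplicated(key)
  list(read = read[keep2], ref = ref[keep2])
}

# Best local alignment per (a[i], b[i]) pair over both strands of b.
align_best_strand <- function(a, b, mode = 0L) {
  f <- .align_pairs_cpp(a, b, mode = mode)
  r <- .align_pairs_cpp(a, revcomp(b), mode = mode)
  use_r <- r$score > f$score
  out <- f
  out[use_r, ] <- r[use_r, ]
  out$strand <- ifelse(use_r, "-", "+")
  out
}

# Union length of a set of 1-based inclusive intervals.
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  tot <- 0L
  cs <- start[1]
  ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce + 1L) {
      ce <- max(ce, end[i])
    } else {
      tot <- tot + (ce - cs + 1L)
      cs <- start[i]
      ce <- end[i]
    }
  }
  tot + (ce - cs + 1L)
}
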