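#' Read paired-end FASTQ files into a read-pair table
#'
#' Parses two mate FASTQ files (plain or gzip-compressed, 4-line records,
#' Phred+33 qualities) into a tibble with one row per read pair.  Files with
#' Phred+64-looking qualities are rejected with an error rather than silently
#' mis-scored.
#'
#' @param file1,file2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A tibble with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#'   Qualities are kept as ASCII strings; see [phred_scores()].
#' @export
read_fastq_pairs <- function(file1, file2) {
  r1 <- read_fastq_one(file1)
  r2 <- read_fastq_one(file2)
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf("mate files differ in record count (%d vs %d)",
                  nrow(r1), nrow(r2)))
  }
  tibble(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
         seq2 = r2$seq, qual2 = r2$qual)
}

read_fastq_one <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- unname(as.character(S4Vectors::mcols(x)$qualities))
  seq <- unname(as.character(x))
  ids <- unname(sub("[/ ].*$", "", names(x)))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ record '%s' in %s: sequence and quality lengths differ",
                  ids[bad[1]], path))
  }
  codes <- utf8ToInt(paste(qual, collapse = ""))
  if (length(codes) && min(codes) >= 59 && max(codes) > 74) {
    abort(sprintf("%s looks Phred+64 encoded; only offset-33 FASTQ is supported", path))
  }
  tibble(id = ids, seq = toupper(seq), qual = qual)
}

#' Write a read-pair table to paired FASTQ files
#'
#' @param pairs Read-pair tibble as returned by [read_fastq_pairs()].
#' @param file1,file2 Output paths (mate 1 and mate 2).
#' @return `pairs`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, file1, file2) {
  write_one <- function(seq, qual, id, path) {
    x <- Biostrings::DNAStringSet(seq)
    names(x) <- id
    q <- Biostrings::PhredQuality(Biostrings::BStringSet(qual))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  write_one(pairs$seq1, pairs$qual1, paste0(pairs$id, "/1"), file1)
  write_one(pairs$seq2, pairs$qual2, paste0(pairs$id, "/2"), file2)
  invisible(pairs)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual Character vector of ASCII quality strings.
#' @return List of integer vectors, one per input string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Quality-control parameters for read-pair filtering
#'
#' Mirrors the Trimmomatic options `LEADING`/`TRAILING`/`SLIDINGWINDOW`/
#' `MINLEN`: a pair is retained only if trimming with these settings would
#' leave both mates untouched at full length, i.e. every base carries usable
#' quality.
#'
#' @param window Sliding-window width in bases.
#' @param min_mean_q Minimum mean Phred quality per window.
#' @param min_len Minimum read length; `NULL` means the read's own length
#'   (full-length retention).
#' @param leading_q,trailing_q Minimum quality of the first/last base.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(window = 4L, min_mean_q = 20, min_len = NULL,
                      leading_q = 3, trailing_q = 3) {
  stopifnot(window >= 1)
  if (!is.null(min_len) && min_len < window) {
    abort("min_len must be at least the window width")
  }
  structure(list(window = as.integer(window), min_mean_q = min_mean_q,
                 min_len = min_len, leading_q = leading_q,
                 trailing_q = trailing_q),
            class = "qc_params")
}

# TRUE for each quality string iff sliding-window/leading/trailing trimming
# would leave the read unmodified at full length.
qc_keep_read <- function(qual, params) {
  scores <- phred_scores(qual)
  w <- params$window
  vapply(scores, function(q) {
    L <- length(q)
    if (!is.null(params$min_len) && L < params$min_len) return(FALSE)
    if (L == 0) return(FALSE)
    if (q[1] < params$leading_q || q[L] < params$trailing_q) return(FALSE)
    if (L >= w) {
      cs <- cumsum(c(0, q))
      means <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
      if (any(means < params$min_mean_q)) return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' Quality-filter read pairs, keeping only untrimmed full-length pairs
#'
#' A pair passes only when both mates would survive leading/trailing/
#' sliding-window quality trimming with no base removed, so every retained
#' read keeps all of its original nucleotides.  Filtering is idempotent.
#'
#' @param pairs Read-pair tibble (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param params A [qc_params()] object.
#' @return The retained subset of `pairs`.
#' @export
trim_and_filter_pairs <- function(pairs, params = qc_params()) {
  if (nrow(pairs) == 0) return(pairs)
  check_dna(pairs$seq1, arg = "seq1")
  check_dna(pairs$seq2, arg = "seq2")
  keep <- qc_keep_read(pairs$qual1, params) & qc_keep_read(pairs$qual2, params)
  pairs[keep, , drop = FALSE]
}

#' Sample read pairs without replacement
#'
#' Uniform sampling without replacement, deterministic for a given seed; the
#' caller's RNG state is left untouched.
#'
#' @param pairs Read-pair tibble.
#' @param n Number of pairs to draw; must not exceed `nrow(pairs)`.
#' @param seed Integer seed.
#' @return A tibble of `n` sampled pairs.
#' @export
sample_pairs <- function(pairs, n, seed) {
  if (n > nrow(pairs)) {
    abort(sprintf("cannot sample %d pairs from a population of %d",
                  n, nrow(pairs)))
  }
  idx <- with_seed(seed, sample.int(nrow(pairs), n))
  pairs[idx, , drop = FALSE]
}
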