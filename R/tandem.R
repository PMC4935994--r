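#' Canonical rotation of a monomer
#'
#' The lexicographically smallest string among all rotations of the monomer
#' and all rotations of its reverse complement, so that rotated or
#' opposite-strand discoveries of the same satellite compare equal.
#'
#' @param monomer Character vector of DNA strings.
#' @return Character vector of canonical forms.
#' @export
canonical_rotation <- function(monomer) {
  vapply(monomer, function(x) {
    if (nchar(x) == 0) abort("empty monomer")
    L <- nchar(x)
    cands <- character(2 * L)
    for (src in c(x, revcomp(x))) {
      d <- paste0(src, src)
      off <- if (identical(src, x)) 0L else L
      cands[off + seq_len(L)] <- substring(d, seq_len(L), seq_len(L) + L - 1L)
    }
    min(cands)
  }, character(1), USE.NAMES = FALSE)
}

#' Detect the tandem period of a contig
#'
#' Numeric stand-in for a dotplot: the smallest shift `p` at which the contig
#' matches itself at `min_shift_identity` or better over the overlapping
#' region, provided the contig spans at least two periods.
#'
#' @param contig DNA string of length >= 30.
#' @param min_shift_identity Minimum ungapped identity at the shift (fraction).
#' @return The period in bp, or `NULL` when no periodicity is found.
#' @export
detect_tandem_period <- function(contig, min_shift_identity = 0.7) {
  L <- nchar(contig)
  if (L < 30) abort("contig shorter than 30 bp")
  x <- strsplit(toupper(contig), "", fixed = TRUE)[[1]]
  for (p in 2:floor(L / 2)) {
    idt <- mean(x[1:(L - p)] == x[(p + 1):L])
    if (idt >= min_shift_identity) return(p)
  }
  NULL
}

#' Split a contig into monomers of a given period
#'
#' Consecutive non-overlapping windows of length `period` from position 1;
#' a terminal remainder shorter than one period is reported separately.
#'
#' @param contig DNA string.
#' @param period Monomer length from [detect_tandem_period()].
#' @return A list with `monomers` (character vector of full monomers) and
#'   `remainder` (possibly empty string).
#' @export
split_into_monomers <- function(contig, period) {
  L <- nchar(contig)
  n_full <- L %/% period
  if (n_full < 2) abort("contig spans fewer than 2 full monomers")
  starts <- seq(1L, by = period, length.out = n_full)
  list(monomers = substring(contig, starts, starts + period - 1L),
       remainder = substring(contig, n_full * period + 1L, L))
}

#' Consensus monomer from aligned monomer copies
#'
#' Takes the per-column majority base; columns that are gaps in more than
#' half the rows are dropped, and ties break by fixed base order A < C < G <
#' T.  Equal-length monomers (the usual case after [split_into_monomers()])
#' are stacked directly; unequal-length copies are projected onto the modal-
#' length copy by global alignment first.  The result is reported in
#' canonical rotation.
#'
#' @param monomers Character vector of at least 2 monomer copies.
#' @return One-row tibble with `seq`, `length`, `at_content`.
#' @export
consensus_monomer <- function(monomers) {
  if (length(monomers) == 0) abort("no monomers supplied")
  monomers <- toupper(monomers)
  lens <- nchar(monomers)
  if (length(unique(lens)) == 1L) {
    m <- matrix(unlist(strsplit(monomers, "", fixed = TRUE)),
                nrow = length(monomers), byrow = TRUE)
  } else {
    # project every copy onto the modal-length reference's coordinates;
    # insertions relative to the reference are discarded (they are gap in
    # most rows whenever copies mostly agree)
    ref_len <- as.integer(names(which.max(table(lens))))
    ref <- monomers[lens == ref_len][1]
    m <- matrix("-", nrow = length(monomers), ncol = ref_len)
    for (i in seq_along(monomers)) {
      m[i, ] <- project_onto_ref(monomers[i], ref)
    }
  }
  cons <- apply(m, 2, function(col) {
    gaps <- sum(col == "-")
    if (gaps > length(col) / 2) return(NA_character_)
    col <- col[col %in% DNA_BASES]
    if (length(col) == 0) return(NA_character_)
    counts <- table(factor(col, levels = DNA_BASES))
    DNA_BASES[which.max(counts)]  # which.max takes the first => A < C < G < T
  })
  seq <- paste(cons[!is.na(cons)], collapse = "")
  seq <- canonical_rotation(seq)
  tibble(seq = seq, length = nchar(seq), at_content = at_content(seq))
}

# Per-reference-column characters of `x` after global alignment to `ref`
# (gap = "-"); used when monomer copies differ in length.
project_onto_ref <- function(x, ref) {
  p <- Biostrings::pairwiseAlignment(Biostrings::DNAString(x),
                                     Biostrings::DNAString(ref),
                                     type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(p)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(p)), "")[[1]]
  pat[sub != "-"]
}

#' Greedy overlap assembly of a cluster's reads into contigs
#'
#' Seeds a contig with an unused read and extends it rightwards through
#' dovetail overlaps (which, for tandem repeats, continue for as long as the
#' array's periodic homology allows, so the contig reaches several monomer
#' copies).  Reads contained in the finished contig are absorbed.  Contigs
#' are ordered by the number of reads they absorbed (coverage).
#'
#' @param reads Character vector of the cluster's read sequences.
#' @param min_overlap Minimum dovetail overlap in bp.
#' @param min_identity Minimum percent identity of an overlap.
#' @param max_len Stop extending once the contig reaches this length.
#' @param max_contigs Maximum number of contigs to assemble.
#' @return A tibble with columns `contig` and `n_reads`, ordered by
#'   decreasing `n_reads`.
#' @export
assemble_cluster_contig <- function(reads, min_overlap = 30, min_identity = 85,
                                    max_len = 1500, max_contigs = 3) {
  reads <- toupper(unname(reads))
  if (length(reads) == 0) abort("no reads supplied")
  if (length(reads) == 1) {
    return(tibble(contig = reads, n_reads = 1L))
  }
  remaining <- seq_along(reads)
  out <- list()
  while (length(remaining) >= 1 && length(out) < max_contigs) {
    seed_i <- remaining[which.max(nchar(reads[remaining]))]
    contig <- reads[seed_i]
    used <- seed_i
    pool <- setdiff(remaining, seed_i)
    # pre-extension contigs, so a junction that kills further extension
    # (typically an array-edge read contributing flanking sequence) can be
    # rolled back and the next candidate tried
    stack <- character()
    steps <- 0L
    reverts <- 0L
    # longest contig reached: a stall at the true end of an array triggers
    # backtracking, which must not unwind a genuinely complete contig
    best_contig <- contig
    repeat {
      steps <- steps + 1L
      if (nchar(contig) > nchar(best_contig)) best_contig <- contig
      if (nchar(contig) >= max_len || length(pool) == 0 || steps > 300L) break
      tail_seq <- substring(contig, max(1L, nchar(contig) - 150L), nchar(contig))
      cand <- pool[reads_matching_kmers(reads[pool], tail_seq, k = 11)]
      if (length(cand) == 0) {
        if (length(stack) && reverts < 8L) {
          reverts <- reverts + 1L
          contig <- stack[length(stack)]
          stack <- stack[-length(stack)]
          next
        }
        break
      }
      if (length(cand) > 200) cand <- cand[seq_len(200)]
      # tail-overlap mode: best alignment forced to end at the tail's end,
      # so tandem reads take the dovetail placement rather than wrapping
      # fully into the tail
      aln <- align_best_strand(rep(tail_seq, length(cand)), reads[cand],
                               mode = 2L)
      # orient candidates onto the contig strand; b-coordinates from
      # align_best_strand already refer to the oriented sequence
      cand_seq <- ifelse(aln$strand == "-", revcomp(reads[cand]), reads[cand])
      identity <- ifelse(aln$columns > 0, 100 * aln$matches / aln$columns, 0)
      ext <- nchar(cand_seq) - aln$b_end
      ok <- identity >= min_identity &
        (aln$matches + aln$mismatches) >= min_overlap & ext > 0
      if (!any(ok)) {
        # bounded backtracking: a handful of reverts recovers from a
        # poisoned junction; unbounded search at a true array end would
        # only re-derive the best contig already snapshotted
        if (length(stack) && reverts < 8L) {
          reverts <- reverts + 1L
          contig <- stack[length(stack)]
          stack <- stack[-length(stack)]
          next
        }
        break
      }
      # among acceptable junctions take the longest extension so the contig
      # reaches several monomer copies in few steps
      pick <- which(ok)[which.max(ext[ok])]
      stack <- c(stack, contig)
      contig <- paste0(contig, substring(cand_seq[pick], aln$b_end[pick] + 1L))
      used <- c(used, cand[pick])
      pool <- setdiff(pool, cand[pick])
    }
    if (nchar(best_contig) > nchar(contig)) contig <- best_contig
    # absorb reads contained in the contig (k-mer prefilter keeps this
    # cheap when a large non-repetitive cluster is being examined)
    if (length(pool)) {
      cand <- pool[reads_matching_kmers(reads[pool], contig, k = 11)]
      if (length(cand)) {
        cont <- align_best_strand(reads[cand], rep(contig, length(cand)),
                                  mode = 0L)
        idt <- ifelse(cont$columns > 0, 100 * cont$matches / cont$columns, 0)
        absorbed <- cand[idt >= min_identity &
                           cont$columns >= 0.8 * nchar(reads[cand])]
        used <- c(used, absorbed)
      }
    }
    out[[length(out) + 1]] <- tibble(contig = contig, n_reads = length(used))
    remaining <- setdiff(remaining, used)
    if (length(remaining) < 3) break
  }
  res <- dplyr::bind_rows(out)
  res[order(-res$n_reads), , drop = FALSE]
}
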