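#' Build concatenated-monomer (dimer) references
#'
#' Reads spanning a monomer junction only align if the reference carries at
#' least two copies, so each monomer is concatenated into a dimer; monomers
#' whose dimer is still `min_len` or shorter are concatenated further until
#' the reference strictly surpasses `min_len`.
#'
#' @param monomers Character vector of consensus monomers, or a tibble with a
#'   `seq` column.
#' @param min_len Length the reference must strictly exceed (bp).
#' @return Character vector of reference sequences, one per monomer.
#' @export
build_reference_dimers <- function(monomers, min_len = 200) {
  if (is.data.frame(monomers)) monomers <- monomers$seq
  if (length(monomers) == 0) abort("no monomers supplied")
  vapply(monomers, function(m) {
    L <- nchar(m)
    k <- max(2, floor(min_len / L) + 1)
    strrep(m, k)
  }, character(1), USE.NAMES = FALSE)
}

#' Subtract read pairs matching known repeats
#'
#' Drops a pair when either mate aligns locally to any reference (either
#' strand) at `min_identity` percent identity over at least `min_coverage`
#' of the mate's length; all other pairs pass through unchanged.  A k-mer
#' prefilter skips mates sharing no k-mer with any reference.
#'
#' @param pairs Read-pair tibble.
#' @param references Character vector of repeat references (e.g. from
#'   [build_reference_dimers()]).
#' @param min_identity Minimum percent identity of the matching alignment.
#' @param min_coverage Minimum aligned fraction of the mate.
#' @param k Prefilter k-mer size.
#' @return The retained subset of `pairs`.
#' @export
filter_matching_reads <- function(pairs, references, min_identity = 90,
                                  min_coverage = 0.9, k = 11) {
  if (length(references) == 0) abort("no references supplied")
  if (nrow(pairs) == 0) return(pairs)
  references <- toupper(references)
  drop <- rep(FALSE, nrow(pairs))
  for (mate in c("seq1", "seq2")) {
    seqs <- toupper(pairs[[mate]])
    combos <- kmer_read_ref_pairs(seqs, references, k = k)
    live <- !drop[combos$read]
    combos$read <- combos$read[live]
    combos$ref <- combos$ref[live]
    if (length(combos$read) == 0) next
    aln <- align_best_strand(seqs[combos$read], references[combos$ref],
                             mode = 0L)
    idt <- ifelse(aln$columns > 0, 100 * aln$matches / aln$columns, 0)
    cov <- (aln$matches + aln$mismatches) / nchar(seqs[combos$read])
    hit <- idt >= min_identity & cov >= min_coverage
    drop[unique(combos$read[hit])] <- TRUE
  }
  pairs[!drop, , drop = FALSE]
}

# Locate tandem structure in a contig: whole-contig periodicity first, and
# otherwise a scan of 150-bp windows so an array segment flanked by
# single-copy sequence (common when a rare family's cluster absorbs its
# genomic neighbourhood) is still found and cropped out.  Returns
# list(seq, period) or NULL.
find_tandem_segment <- function(contig, min_shift_identity = 0.7) {
  if (nchar(contig) >= 30) {
    p <- detect_tandem_period(contig, min_shift_identity)
    if (!is.null(p) && nchar(contig) %/% p >= 2) {
      return(list(seq = contig, period = p))
    }
  }
  L <- nchar(contig)
  # progressively smaller windows so short mixed contigs (a mostly-array
  # read with a flank) still reveal short-monomer periodicity
  for (win in c(150L, 90L, 60L)) {
    if (L < win + 30L) next
    step <- max(20L, win %/% 3L)
    starts <- seq(1L, L - win + 1L, by = step)
    pw <- vapply(starts, function(s) {
      p <- detect_tandem_period(substring(contig, s, s + win - 1L),
                                min_shift_identity)
      if (is.null(p)) NA_integer_ else as.integer(p)
    }, integer(1))
    if (all(is.na(pw))) next
    # longest run of windows agreeing on a period
    r <- rle(ifelse(is.na(pw), -1L, pw))
    rends <- cumsum(r$lengths)
    rstarts <- rends - r$lengths + 1L
    ok <- which(r$values > 0L)
    bi <- ok[which.max(r$lengths[ok])]
    seg <- substring(contig, starts[rstarts[bi]],
                     min(L, starts[rends[bi]] + win - 1L))
    p <- detect_tandem_period(seg, min_shift_identity)
    if (!is.null(p) && nchar(seg) %/% p >= 2) {
      return(list(seq = seg, period = p))
    }
  }
  NULL
}

#' Iterative satellite mining from read pairs
#'
#' Runs the cluster-filter-recluster cycle: per iteration a fresh batch of
#' pairs is sampled from the unused pool, reads matching all previously
#' found repeats are subtracted, the remainder is clustered, candidate
#' clusters (globular/ring, density above threshold) are assembled and
#' tandem-structured contigs yield consensus monomers.  A candidate monomer
#' counts as a new satellite only if its rotation/strand-normalised identity
#' to every known satellite is at most `new_identity_max`; 95-100 percent
#' matches merge into the known family as a variant.  Non-tandem contigs go
#' into a custom repeat database that is also subtracted in later rounds.
#' The loop stops when an iteration adds no new satellite.
#'
#' @param pairs Read-pair tibble (already quality-filtered).
#' @param schedule Integer vector of pairs to sample per iteration.
#' @param seed Integer seed driving all sampling.
#' @param min_cluster_reads Minimum reads in a cluster before a consensus is
#'   attempted.
#' @param density_threshold Cluster-density cutoff (exclusive).
#' @param min_identity,min_overlap_frac Read-graph edge criteria.
#' @param new_identity_max Maximum identity to a known satellite for a
#'   candidate to count as new (percent).
#' @param filter_identity,filter_coverage Read-subtraction criteria.
#' @return An object of class `sat_mining`: list with `satellites` (tibble
#'   `family_id`, `seq`, `length`, `at_content`, `iteration`,
#'   `genome_proportion`, `n_variants`), `variants` (tibble `family_id`,
#'   `seq`), `other_repeats` (character), `iterations` (per-iteration log
#'   tibble), `converged` (logical) and `seed`.
#' @export
satminer_loop <- function(pairs, schedule, seed = 1,
                          min_cluster_reads = 10, density_threshold = 0.1,
                          min_identity = 90, min_overlap_frac = 0.55,
                          new_identity_max = 95,
                          filter_identity = 90, filter_coverage = 0.9) {
  if (length(schedule) == 0) abort("schedule must be non-empty")
  pool <- pairs
  sats <- tibble(family_id = integer(), seq = character(), length = integer(),
                 at_content = numeric(), iteration = integer(),
                 genome_proportion = numeric(), n_variants = integer())
  variants <- tibble(family_id = integer(), seq = character())
  other <- character()
  log <- list()
  converged <- FALSE
  verbose <- isTRUE(getOption("satkit.verbose"))
  say <- function(...) if (verbose) message(sprintf(...))
  for (it in seq_along(schedule)) {
    n <- min(schedule[it], nrow(pool))
    if (n == 0) break
    samp <- sample_pairs(pool, n, seed = seed + it)
    pool <- pool[!(pool$id %in% samp$id), , drop = FALSE]
    refs <- c(if (nrow(sats)) build_reference_dimers(sats$seq), other)
    if (length(refs)) {
      t0 <- Sys.time()
      samp <- filter_matching_reads(samp, refs, min_identity = filter_identity,
                                    min_coverage = filter_coverage)
      say("iter %d: filtered to %d pairs against %d refs (%.1fs)", it,
          nrow(samp), length(refs), as.numeric(Sys.time() - t0, units = "secs"))
    }
    reads <- tibble(
      id = c(paste0(samp$id, "/1"), paste0(samp$id, "/2")),
      seq = c(samp$seq1, samp$seq2)
    )
    total_nt <- sum(nchar(reads$seq))
    new_found <- 0L
    clusters_examined <- 0L
    if (nrow(reads) > 0) {
      t0 <- Sys.time()
      cl <- cluster_reads(reads, min_identity = min_identity,
                          min_overlap_frac = min_overlap_frac,
                          min_reads = min_cluster_reads)
      cands <- select_candidate_clusters(cl$clusters, density_threshold)
      clusters_examined <- nrow(cands)
      say("iter %d: clustered %d reads, %d clusters >= %d reads, %d candidates (%.1fs)",
          it, nrow(reads), nrow(cl$clusters), min_cluster_reads, nrow(cands),
          as.numeric(Sys.time() - t0, units = "secs"))
      seq_by_id <- stats::setNames(cl$graph$nodes$seq, cl$graph$nodes$id)
      if (nrow(cands)) {
        for (ci in seq_len(nrow(cands))) {
          t0 <- Sys.time()
          member_seqs <- unname(seq_by_id[cands$reads[[ci]]])
          contigs <- assemble_cluster_contig(member_seqs)
          say("iter %d: cluster %d (%d reads) assembled (%.1fs)", it, ci,
              length(member_seqs), as.numeric(Sys.time() - t0, units = "secs"))
          got <- FALSE
          # contigs first; if none shows tandem structure, fall back to the
          # member reads themselves (a read from a short-monomer array can
          # carry several copies on its own)
          sources <- contigs$contig
          fallback <- setdiff(member_seqs, sources)
          sources <- c(sources, fallback[seq_len(min(20L, length(fallback)))])
          for (cg in sources) {
            if (is.na(cg) || nchar(cg) < 30) next
            seg <- find_tandem_segment(cg)
            if (is.null(seg)) next
            cons <- consensus_monomer(
              split_into_monomers(seg$seq, seg$period)$monomers)
            if (nchar(cons$seq) < 2) next
            if (nrow(sats)) {
              idt <- vapply(sats$seq, function(s) {
                .rotational_identity_cpp(cons$seq, s)$identity
              }, numeric(1))
            } else {
              idt <- numeric()
            }
            if (all(idt <= new_identity_max)) {
              fid <- nrow(sats) + 1L
              sats <- bind_rows(sats, tibble(
                family_id = fid, seq = cons$seq, length = cons$length,
                at_content = cons$at_content, iteration = it,
                genome_proportion = cands$genome_proportion[ci],
                n_variants = 1L))
              variants <- bind_rows(variants,
                                    tibble(family_id = fid, seq = cons$seq))
              new_found <- new_found + 1L
            } else {
              fid <- sats$family_id[which.max(idt)]
              if (max(idt) < 100 &&
                  !cons$seq %in% variants$seq[variants$family_id == fid]) {
                variants <- bind_rows(variants,
                                      tibble(family_id = fid, seq = cons$seq))
                sats$n_variants[sats$family_id == fid] <-
                  sum(variants$family_id == fid)
              }
            }
            got <- TRUE
            break
          }
          if (!got && nrow(contigs)) {
            other <- c(other, contigs$contig[1])
          }
        }
      }
    }
    log[[it]] <- tibble(iteration = it, reads_sampled = n,
                        pairs_after_filter = nrow(samp),
                        clusters_examined = clusters_examined,
                        new_satellites = new_found)
    if (new_found == 0L) {
      converged <- TRUE
      break
    }
  }
  structure(list(satellites = sats, variants = variants, other_repeats = other,
                 iterations = bind_rows(log), converged = converged,
                 seed = seed),
            class = "sat_mining")
}

#' @export
print.sat_mining <- function(x, ...) {
  cat(sprintf("satellite mining: %d famil%s in %d iteration%s (%s)\n",
              nrow(x$satellites), if (nrow(x$satellites) == 1) "y" else "ies",
              nrow(x$iterations), if (nrow(x$iterations) == 1) "" else "s",
              if (x$converged) "converged" else "schedule exhausted"))
  if (nrow(x$satellites)) {
    print(x$satellites[, c("family_id", "length", "at_content", "iteration",
                           "genome_proportion")])
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname satminer_loop
#' @param x A `sat_mining` object.
#' @param ... Unused.
#' @export
tidy.sat_mining <- function(x, ...) {
  x$satellites
}

#' @rdname satminer_loop
#' @export
glance.sat_mining <- function(x, ...) {
  tibble(n_families = nrow(x$satellites),
         n_variants = nrow(x$variants),
         n_other_repeats = length(x$other_repeats),
         iterations = nrow(x$iterations),
         converged = x$converged)
}
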