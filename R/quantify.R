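#' Kimura 2-parameter divergence from transition/transversion proportions
#'
#' `K = -0.5 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, returned as a percentage.
#' Inputs outside the model's domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`)
#' are saturated and returned as `NA` so they drop out of weighted means.
#'
#' @param P Transition proportion(s).
#' @param Q Transversion proportion(s).
#' @return Percent divergence, `NA` where saturated.
#' @export
k2p_divergence <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- w1 > 0 & w2 > 0
  out <- rep(NA_real_, length(w1))
  out[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok])) * 100
  out
}

#' Build an alignment library from a catalog
#'
#' One concatenated-monomer reference per variant (see
#' [build_reference_dimers()]), carrying the family name and monomer length
#' needed by the quantification functions.
#'
#' @param catalog A (preferably named) `sat_catalog`.
#' @param min_len Reference length to surpass (bp).
#' @return Tibble with `family`, `variant`, `monomer_length`, `ref`.
#' @export
sat_library <- function(catalog, min_len = 200) {
  td <- tidy(catalog)
  fam <- td$name %||% paste0("family", td$family_id)
  tibble(family = fam,
         variant = paste0(fam, "#", td$variant_index),
         monomer_length = nchar(td$seq),
         ref = build_reference_dimers(td$seq, min_len = min_len))
}

#' Align reads against a satellite library
#'
#' Local alignment of every read against every reference on both strands;
#' overlapping hits within a read are resolved greedily by score, discarding
#' hits that overlap an accepted hit by more than half their length.  Each
#' hit carries its transition (`P`) and transversion (`Q`) proportions and
#' Kimura 2-parameter divergence.  Reads sharing no k-mer with the library
#' are skipped before alignment.
#'
#' @param reads Character vector of read sequences (names used as query ids),
#'   or a tibble with `id` and `seq` columns.
#' @param library Library tibble from [sat_library()].
#' @param min_aligned Minimum aligned (non-gap) columns per hit.
#' @param min_identity Minimum percent identity per hit.
#' @param k Prefilter k-mer size.
#' @return Hit tibble: `query_id`, `family`, `variant`, `q_start`, `q_end`
#'   (1-based inclusive), `strand`, `aligned_nt`, `identity`, `P`, `Q`,
#'   `k2p`.
#' @export
align_reads_to_library <- function(reads, library, min_aligned = 30,
                                   min_identity = 65, k = 11) {
  if (nrow(library) == 0) abort("empty library")
  if (is.data.frame(reads)) {
    ids <- reads$id
    seqs <- toupper(reads$seq)
  } else {
    seqs <- toupper(unname(reads))
    ids <- names(reads) %||% paste0("read", seq_along(seqs))
  }
  empty <- tibble(query_id = character(), family = character(),
                  variant = character(), q_start = integer(),
                  q_end = integer(), strand = character(),
                  aligned_nt = integer(), identity = numeric(),
                  P = numeric(), Q = numeric(), k2p = numeric())
  if (length(seqs) == 0) return(empty)
  combos <- kmer_read_ref_pairs(seqs, library$ref, k = k)
  if (length(combos$read) == 0) return(empty)
  aln <- align_best_strand(seqs[combos$read], library$ref[combos$ref],
                           mode = 0L)
  aligned <- aln$matches + aln$mismatches
  idt <- ifelse(aln$columns > 0, 100 * aln$matches / aln$columns, 0)
  keep <- aligned >= min_aligned & idt >= min_identity
  if (!any(keep)) return(empty)
  P <- aln$transitions[keep] / aligned[keep]
  Q <- aln$transversions[keep] / aligned[keep]
  hits <- tibble(
    query_id = ids[combos$read[keep]],
    family = library$family[combos$ref[keep]],
    variant = library$variant[combos$ref[keep]],
    q_start = aln$a_start[keep], q_end = aln$a_end[keep],
    strand = aln$strand[keep], score = aln$score[keep],
    aligned_nt = aligned[keep], identity = idt[keep],
    P = P, Q = Q, k2p = k2p_divergence(P, Q))
  resolved <- hits |>
    group_by(.data$query_id) |>
    dplyr::group_modify(~ resolve_read_hits(.x)) |>
    ungroup()
  resolved[order(resolved$query_id, resolved$q_start),
           setdiff(names(resolved), "score")]
}

# greedy best-score-first selection of non-overlapping hits within one read;
# a hit is discarded if it overlaps an accepted hit by > 50% of its length
resolve_read_hits <- function(h) {
  h <- h[order(-h$score, h$variant), , drop = FALSE]
  acc <- integer()
  for (i in seq_len(nrow(h))) {
    len_i <- h$q_end[i] - h$q_start[i] + 1L
    ov <- 0L
    for (j in acc) {
      ov <- max(ov, min(h$q_end[i], h$q_end[j]) -
                  max(h$q_start[i], h$q_start[j]) + 1L)
    }
    if (ov <= 0.5 * len_i) acc <- c(acc, i)
  }
  h[acc, , drop = FALSE]
}

#' Family abundance and weighted mean divergence from library hits
#'
#' Abundance is the summed aligned nucleotides of all a family's variants,
#' normalised by the sampled nucleotides and expressed as percent of the
#' library (genome proportion); divergence is the abundance-weighted mean
#' Kimura distance over the family's hits.
#'
#' @param hits Hit tibble from [align_reads_to_library()].
#' @param total_sampled_nt Total nucleotides in the sampled reads.
#' @return Tibble `family`, `abundance`, `mean_divergence` (NA when the
#'   family has no usable hits).
#' @export
family_abundance <- function(hits, total_sampled_nt) {
  stopifnot(total_sampled_nt > 0)
  hits |>
    group_by(.data$family) |>
    summarise(
      abundance = 100 * sum(.data$aligned_nt) / total_sampled_nt,
      mean_divergence = if (all(is.na(.data$k2p))) NA_real_ else
        stats::weighted.mean(.data$k2p, .data$aligned_nt, na.rm = TRUE),
      .groups = "drop")
}

#' Repeat landscape: abundance binned by divergence
#'
#' Per family, hit abundance is accumulated into 1-percent Kimura-divergence
#' bins `[0,1), [1,2), ...`; bin sums reproduce [family_abundance()] exactly
#' (saturated hits excluded from both is impossible here since accepted hits
#' satisfy the model's domain).
#'
#' @inheritParams family_abundance
#' @return Tibble of class `sat_landscape`: `family`, `bin` (lower edge),
#'   `abundance`.
#' @export
repeat_landscape <- function(hits, total_sampled_nt) {
  stopifnot(total_sampled_nt > 0)
  out <- hits |>
    filter(!is.na(.data$k2p)) |>
    mutate(bin = floor(.data$k2p)) |>
    group_by(.data$family, .data$bin) |>
    summarise(abundance = 100 * sum(.data$aligned_nt) / total_sampled_nt,
              .groups = "drop")
  class(out) <- c("sat_landscape", class(out))
  out
}

#' Scan an assembly for satellite content
#'
#' Windows each contig, finds all non-overlapping local hits per reference
#' by iterative best-hit masking, and reports per contig and family the
#' union of aligned positions.  The per-family summary scores the number of
#' contigs holding at least `contig_min_nt` aligned bp and the maximum
#' number of repeats per contig (aligned nt over monomer length, rounded
#' down).
#'
#' @param contigs Named character vector of contig sequences, or a FASTA
#'   path.
#' @param library Library tibble from [sat_library()].
#' @param contig_min_nt Aligned-bp threshold for counting a contig.
#' @param min_aligned,min_identity Per-hit acceptance criteria.
#' @param window,step Window size and step for long contigs (bp).
#' @param k Prefilter k-mer size.
#' @return List with `contig_stats` (`contig_id`, `family`, `aligned_nt`,
#'   `n_repeats`) and `summary` (`family`, `n_contigs`, `mnrpc`).
#' @export
scan_assembly <- function(contigs, library, contig_min_nt = 200,
                          min_aligned = 30, min_identity = 65,
                          window = 3000, step = 2200, k = 11) {
  if (is.character(contigs) && length(contigs) == 1 && file.exists(contigs)) {
    x <- Biostrings::readDNAStringSet(contigs)
    contigs <- stats::setNames(as.character(x), sub(" .*", "", names(x)))
  }
  if (length(contigs) == 0) abort("empty assembly")
  if (is.null(names(contigs))) {
    names(contigs) <- paste0("contig", seq_along(contigs))
  }
  contigs <- toupper(contigs)
  recs <- list()
  for (ci in seq_along(contigs)) {
    cseq <- contigs[[ci]]
    L <- nchar(cseq)
    starts <- if (L <= window) 1L else
      unique(c(seq(1L, L - window + 1L, by = step), L - window + 1L))
    for (ws in starts) {
      wseq <- substring(cseq, ws, min(L, ws + window - 1L))
      if (length(reads_matching_kmers(wseq, library$ref, k = k)) == 0) next
      for (ri in seq_len(nrow(library))) {
        masked <- wseq
        for (iter in 1:30) {
          aln <- align_best_strand(masked, library$ref[ri], mode = 0L)
          aligned <- aln$matches + aln$mismatches
          idt <- if (aln$columns > 0) 100 * aln$matches / aln$columns else 0
          if (aligned < min_aligned || idt < min_identity) break
          recs[[length(recs) + 1]] <- tibble(
            contig_id = names(contigs)[ci], family = library$family[ri],
            start = ws + aln$a_start - 1L, end = ws + aln$a_end - 1L)
          # mask the hit so further, weaker hits in the window surface
          substr(masked, aln$a_start, aln$a_end) <-
            strrep("N", aln$a_end - aln$a_start + 1L)
        }
      }
    }
  }
  mono_len <- library |>
    group_by(.data$family) |>
    summarise(monomer_length = min(.data$monomer_length), .groups = "drop")
  if (length(recs) == 0) {
    contig_stats <- tibble(contig_id = character(), family = character(),
                           aligned_nt = integer(), n_repeats = numeric())
  } else {
    contig_stats <- bind_rows(recs) |>
      group_by(.data$contig_id, .data$family) |>
      summarise(aligned_nt = interval_union_length(.data$start, .data$end),
                .groups = "drop") |>
      left_join(mono_len, by = "family") |>
      mutate(n_repeats = floor(.data$aligned_nt / .data$monomer_length)) |>
      select(-"monomer_length")
  }
  summary <- contig_stats |>
    group_by(.data$family) |>
    summarise(n_contigs = sum(.data$aligned_nt >= contig_min_nt),
              mnrpc = if (n() == 0) 0 else max(.data$n_repeats),
              .groups = "drop")
  missing <- setdiff(unique(library$family), summary$family)
  if (length(missing)) {
    summary <- bind_rows(summary,
                         tibble(family = missing, n_contigs = 0L, mnrpc = 0))
  }
  list(contig_stats = contig_stats, summary = summary[order(summary$family), ])
}
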