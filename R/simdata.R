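#' Specify a satellite family to plant in a simulated genome
#'
#' @param monomer Monomer sequence (A/C/G/T).
#' @param proportion Target genome proportion, percent of the final genome.
#' @param layout `"clustered"` (few large arrays), `"scattered"` (many
#'   arrays, each under `max_scattered_array` bp — below the cytological
#'   detection threshold) or `"mixed"` (half and half).
#' @param n_loci Number of loci; defaults to 1 for clustered, enough loci of
#'   near-maximal sub-threshold arrays for scattered.
#' @param divergence Per-copy substitution rate (fraction, 0-0.3).
#' @param name Family label in the truth table.
#' @param max_scattered_array Largest scattered-array size (bp); 1.5 kb
#'   mirrors the FISH visibility threshold.
#' @return One-row tibble.
#' @export
family_spec <- function(monomer, proportion, layout = c("clustered",
                                                        "scattered", "mixed"),
                        n_loci = NA_integer_, divergence = 0.02,
                        name = NULL, max_scattered_array = 1500) {
  layout <- match.arg(layout)
  check_dna(monomer, allow_n = FALSE, arg = "monomer")
  stopifnot(proportion > 0, proportion <= 50,
            divergence >= 0, divergence <= 0.3)
  tibble(name = name %||% NA_character_, monomer = toupper(monomer),
         proportion = proportion, layout = layout,
         n_loci = as.integer(n_loci), divergence = divergence,
         max_scattered_array = max_scattered_array)
}

# one mutated copy set: `copies` rows of the monomer with independent
# substitutions at rate `rate`; returns list(seqs, n_sub)
mutate_copies <- function(monomer, copies, rate) {
  L <- nchar(monomer)
  base <- strsplit(monomer, "", fixed = TRUE)[[1]]
  m <- matrix(rep(base, copies), nrow = copies, byrow = TRUE)
  nmut <- stats::rbinom(1, copies * L, rate)
  n_sub <- integer(copies)
  if (nmut > 0) {
    idx <- sample.int(copies * L, nmut)
    row <- (idx - 1L) %% copies + 1L
    col <- (idx - 1L) %/% copies + 1L
    oldc <- match(m[cbind(row, col)], DNA_BASES)
    shift <- sample.int(3L, nmut, replace = TRUE)
    m[cbind(row, col)] <- DNA_BASES[(oldc - 1L + shift) %% 4L + 1L]
    tab <- table(factor(row, levels = seq_len(copies)))
    n_sub <- as.integer(tab)
  }
  list(seqs = apply(m, 1, paste, collapse = ""), n_sub = n_sub)
}

#' Simulate a satellite-bearing genome with known truth
#'
#' Plants tandem arrays of each specified family into a random background at
#' the requested genome proportions: clustered families get few large
#' arrays, scattered families many short (sub-threshold) arrays, and every
#' monomer copy is independently mutated at the family's per-copy divergence.
#' The truth table records each locus and the realised (exact) proportions.
#'
#' @param specs Tibble of [family_spec()] rows (zero rows allowed).
#' @param genome_size Target genome size in bp.
#' @param seed Integer seed.
#' @param gc Background GC fraction.
#' @param n_contigs Number of background contigs to split the genome into.
#' @return List with `genome` (named character vector of contigs) and
#'   `truth` (list of tibbles `loci` and `families`).
#' @export
simulate_genome <- function(specs, genome_size, seed = 1, gc = 0.5,
                            n_contigs = 1) {
  if (nrow(specs) > 0 && sum(specs$proportion) >= 50) {
    abort("total planted proportion must stay below 50%")
  }
  with_seed(seed, {
    if (nrow(specs) > 0 && any(is.na(specs$name))) {
      specs$name[is.na(specs$name)] <- paste0("fam", which(is.na(specs$name)))
    }
    inserts <- list()   # per locus: family, seq, copies, n_sub
    for (fi in seq_len(nrow(specs))) {
      sp <- specs[fi, ]
      L <- nchar(sp$monomer)
      target_nt <- sp$proportion / 100 * genome_size
      plan <- switch(sp$layout,
        clustered = {
          k <- if (is.na(sp$n_loci)) 1L else sp$n_loci
          rep(ceiling(target_nt / k), k)
        },
        scattered = {
          arr <- min(sp$max_scattered_array,
                     max(2 * L, sp$max_scattered_array %/% 2))
          k <- if (is.na(sp$n_loci)) max(2L, round(target_nt / arr)) else sp$n_loci
          rep(ceiling(target_nt / k), k)
        },
        mixed = {
          arr <- min(sp$max_scattered_array, max(2 * L, 600))
          ks <- max(1L, round(target_nt / 2 / arr))
          c(ceiling(target_nt / 2), rep(ceiling(target_nt / 2 / ks), ks))
        })
      for (arr_nt in plan) {
        copies <- max(2L, round(arr_nt / L))
        mc <- mutate_copies(sp$monomer, copies, sp$divergence)
        inserts[[length(inserts) + 1]] <- list(
          family = sp$name, seq = paste(mc$seqs, collapse = ""),
          copies = copies, n_sub = mc$n_sub, monomer_len = L)
      }
    }
    ins_nt <- sum(vapply(inserts, function(z) nchar(z$seq), numeric(1)))
    bg_nt <- genome_size - ins_nt
    if (bg_nt < max(1, length(inserts))) {
      abort("planted arrays do not fit in the requested genome size")
    }
    contig_bg <- rep(bg_nt %/% n_contigs, n_contigs)
    contig_bg[1] <- contig_bg[1] + bg_nt %% n_contigs
    # assign each locus to a contig with probability proportional to size
    locus_contig <- if (length(inserts)) {
      sort(sample.int(n_contigs, length(inserts), replace = TRUE,
                      prob = contig_bg))
    } else {
      integer()
    }
    genome <- character(n_contigs)
    loci <- list()
    for (ci in seq_len(n_contigs)) {
      bg <- random_dna(contig_bg[ci], gc = gc)
      here <- which(locus_contig == ci)
      if (!length(here)) {
        genome[ci] <- bg
        next
      }
      cuts <- sort(sample.int(contig_bg[ci] - 1L, length(here)))
      pieces <- character(2 * length(here) + 1)
      pos <- 1L
      cur_len <- 0L
      prev <- 0L
      for (t in seq_along(here)) {
        pieces[2 * t - 1] <- substring(bg, prev + 1L, cuts[t])
        cur_len <- cur_len + (cuts[t] - prev)
        z <- inserts[[here[t]]]
        loci[[length(loci) + 1]] <- tibble(
          family = z$family, contig = paste0("contig", ci),
          start = cur_len + 1L, end = cur_len + nchar(z$seq),
          copies = z$copies)
        pieces[2 * t] <- z$seq
        cur_len <- cur_len + nchar(z$seq)
        prev <- cuts[t]
      }
      pieces[2 * length(here) + 1] <- substring(bg, prev + 1L, contig_bg[ci])
      genome[ci] <- paste(pieces, collapse = "")
    }
    names(genome) <- paste0("contig", seq_len(n_contigs))
    total <- sum(nchar(genome))
    fam_truth <- if (length(inserts)) {
      tibble(
        family = vapply(inserts, `[[`, character(1), "family"),
        nt = vapply(inserts, function(z) nchar(z$seq), numeric(1)),
        sub_rate = vapply(inserts, function(z) {
          sum(z$n_sub) / (z$copies * z$monomer_len)
        }, numeric(1))
      ) |>
        group_by(.data$family) |>
        summarise(monomer = specs$monomer[match(.data$family[1], specs$name)],
                  planted_nt = sum(.data$nt),
                  proportion = 100 * sum(.data$nt) / total,
                  mean_divergence = stats::weighted.mean(.data$sub_rate,
                                                         .data$nt),
                  n_loci = n(), .groups = "drop")
    } else {
      tibble(family = character(), monomer = character(),
             planted_nt = numeric(), proportion = numeric(),
             mean_divergence = numeric(), n_loci = integer())
    }
    list(genome = genome,
         truth = list(loci = bind_rows(loci), families = fam_truth))
  })
}

#' Simulate paired-end reads from a genome
#'
#' Uniform fragment sampling over contigs (probability proportional to
#' length), both strands, truncated-normal insert sizes floored at the read
#' length, independent substitution errors, and flat Phred qualities
#' consistent with the error rate.  Deterministic for a given seed.
#'
#' @param genome Named character vector of contigs (or the list returned by
#'   [simulate_genome()]).
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Insert-size distribution (bp).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return Read-pair tibble (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @export
simulate_reads <- function(genome, n_pairs, read_len = 100,
                           insert_mean = 226, insert_sd = 81,
                           error_rate = 0.01, seed = 1) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  lens <- nchar(genome)
  if (all(lens < insert_mean)) {
    # still fine: inserts are capped per contig, but the genome must at
    # least hold one read
    if (all(lens < read_len)) abort("genome shorter than the read length")
  }
  with_seed(seed, {
    ci <- sample.int(length(genome), n_pairs, replace = TRUE, prob = lens)
    insert <- pmax(read_len, round(stats::rnorm(n_pairs, insert_mean,
                                                insert_sd)))
    insert <- pmin(insert, lens[ci])
    start <- floor(stats::runif(n_pairs) * (lens[ci] - insert + 1)) + 1L
    frag_fwd <- substring(genome[ci], start, start + insert - 1L)
    minus <- stats::runif(n_pairs) < 0.5
    frag <- ifelse(minus, revcomp(frag_fwd), frag_fwd)
    r1 <- substring(frag, 1L, read_len)
    r2 <- revcomp(substring(frag, insert - read_len + 1L, insert))
    if (error_rate > 0) {
      r1 <- mutate_seqs(r1, error_rate)
      r2 <- mutate_seqs(r2, error_rate)
    }
    q <- if (error_rate > 0) {
      min(40L, as.integer(round(-10 * log10(error_rate))))
    } else {
      40L
    }
    qs <- strrep(intToUtf8(q + 33L), read_len)
    tibble(id = sprintf("read%07d", seq_len(n_pairs)),
           seq1 = r1, qual1 = qs, seq2 = r2, qual2 = qs)
  })
}

# independent substitution errors at `rate` across a vector of equal-length
# sequences
mutate_seqs <- function(x, rate) {
  L <- nchar(x[1])
  n <- length(x)
  nmut <- stats::rbinom(1, n * L, rate)
  if (nmut == 0) return(x)
  idx <- sample.int(n * L, nmut)
  row <- (idx - 1L) %% n + 1L
  col <- (idx - 1L) %/% n + 1L
  oldc <- match(substring(x[row], col, col), DNA_BASES)
  shift <- sample.int(3L, nmut, replace = TRUE)
  newb <- DNA_BASES[(oldc - 1L + shift) %% 4L + 1L]
  for (t in seq_along(idx)) {
    if (!is.na(newb[t])) substr(x[row[t]], col[t], col[t]) <- newb[t]
  }
  x
}
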