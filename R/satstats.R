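CHROMOSOMES <- c("L1", "L2", "X", "M3", "M4", "M5", "M6", "M7", "M8",
                 "S9", "S10", "S11")
LOCATION_TOKENS <- c("p", "i", "d", "t")

#' Read a satellitome annotation table
#'
#' Tab-separated table with one row per satellite family: `family`, `length`,
#' `at`, `v` (variants), abundance/divergence columns for each sequenced
#' individual (`ab_sl`, `ab_nl`, `div_sl`, `div_nl`), draft-genome columns
#' (`contigs`, `mnrpc`), one column per chromosome holding comma-separated
#' location tokens (p = proximal, i = interstitial, d = distal, t =
#' telomeric) and a `pattern` column (c = clustered, nc = non-clustered, m =
#' mixed, empty = unassessed).
#'
#' @param path Path to the TSV.
#' @return Tibble of annotation records.
#' @export
read_annotation_table <- function(path) {
  rec <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(),
    length = readr::col_integer(), at = readr::col_double(),
    v = readr::col_integer(), ab_sl = readr::col_double(),
    ab_nl = readr::col_double(), div_sl = readr::col_double(),
    div_nl = readr::col_double(), contigs = readr::col_integer(),
    mnrpc = readr::col_integer()))
  chr_cols <- intersect(CHROMOSOMES, names(rec))
  for (cc in chr_cols) {
    rec[[cc]][is.na(rec[[cc]])] <- ""
    toks <- unlist(strsplit(rec[[cc]][rec[[cc]] != ""], ","))
    bad <- setdiff(unique(toks), LOCATION_TOKENS)
    if (length(bad)) {
      row <- which(grepl(paste(bad, collapse = "|"), rec[[cc]]))[1]
      abort(sprintf("unknown location token '%s' in row '%s', column %s",
                    bad[1], rec$family[row], cc))
    }
  }
  rec$pattern[is.na(rec$pattern)] <- ""
  rec
}

#' The *Locusta migratoria* satellitome annotation table
#'
#' The shipped 62-family annotation table for the migratory locust (Southern
#' and Northern lineage individuals), as used by the satellitome summary
#' statistics.
#'
#' @return Tibble of 62 annotation records.
#' @export
lmigratoria_satellitome <- function() {
  read_annotation_table(system.file("extdata", "lmigratoria_satellitome.tsv",
                                    package = "satkit", mustWork = TRUE))
}

#' Default working set of families for satellitome statistics
#'
#' Excludes the telomeric repeat (known function) and families whose
#' presence could not be PCR-confirmed in the reference population — for the
#' shipped locust table, LmiSat07-5-tel, LmiSat46-353, LmiSat52-143 and
#' LmiSat57-230, leaving 58 families.
#'
#' @param records Annotation tibble.
#' @param exclude Family names to drop; defaults to the telomeric family
#'   (name ending `-tel`) plus families with no cytological pattern.
#' @return The retained subset of `records`.
#' @export
satellitome_working_set <- function(records, exclude = NULL) {
  if (is.null(exclude)) {
    exclude <- records$family[grepl("-tel$", records$family) |
                                records$pattern == ""]
  }
  records[!(records$family %in% exclude), , drop = FALSE]
}

# long view of the chromosome-location cells of clustered/mixed families
location_tokens <- function(records) {
  chr_cols <- intersect(CHROMOSOMES, names(records))
  out <- list()
  for (cc in chr_cols) {
    has <- which(records[[cc]] != "")
    if (!length(has)) next
    toks <- strsplit(records[[cc]][has], ",")
    out[[cc]] <- tibble(family = rep(records$family[has], lengths(toks)),
                        chromosome = cc,
                        location = unlist(toks))
  }
  bind_rows(out)
}

#' Summarise chromosomal cluster locations
#'
#' Counts proximal/interstitial/distal clusters over the clustered and
#' mixed-pattern families (the telomeric family excluded by default), and
#' derives clusters per satellite family and per chromosome.
#'
#' @param records Annotation tibble.
#' @param exclude Family names to exclude (default: the telomeric family).
#' @return One-row tibble: `p`, `i`, `d`, `total_loci`,
#'   `n_clustered_families`, `clusters_per_satdna`,
#'   `clusters_per_chromosome`.
#' @export
summarize_locations <- function(records,
                                exclude = records$family[grepl("-tel$",
                                                               records$family)]) {
  rec <- records[!(records$family %in% exclude) &
                   records$pattern %in% c("c", "m"), , drop = FALSE]
  toks <- location_tokens(rec)
  cnt <- function(tok) if (nrow(toks)) sum(toks$location == tok) else 0L
  p <- cnt("p"); i <- cnt("i"); d <- cnt("d")
  total <- p + i + d
  nfam <- nrow(rec)
  nchr <- length(intersect(CHROMOSOMES, names(records)))
  tibble(p = p, i = i, d = d, total_loci = total,
         n_clustered_families = nfam,
         clusters_per_satdna = if (nfam) total / nfam else NA_real_,
         clusters_per_chromosome = if (nchr) total / nchr else NA_real_)
}

#' Monomer-length distribution and the gap dividing short from long families
#'
#' Sorts the distinct monomer lengths and finds the dividing gap of the
#' bimodal distribution: the largest difference between consecutive lengths
#' such that both resulting groups hold at least `max(2, ceiling(min_group_frac
#' * n))` families — so a lone extreme-length family cannot masquerade as a
#' mode of its own.
#'
#' @param records Annotation tibble (typically the working set).
#' @param min_group_frac Minimum fraction of families per side of the gap.
#' @return One-row tibble: `n_short`, `n_long`, `gap`, `gap_lower`,
#'   `gap_upper` (NA when fewer than 2 distinct lengths).
#' @export
length_distribution <- function(records, min_group_frac = 0.05) {
  lens <- records$length
  u <- sort(unique(lens))
  if (length(u) < 2) {
    return(tibble(n_short = length(lens), n_long = 0L, gap = NA_integer_,
                  gap_lower = NA_integer_, gap_upper = NA_integer_))
  }
  min_group <- max(2L, ceiling(min_group_frac * length(lens)))
  gaps <- diff(u)
  best <- NA_integer_
  for (gi in order(-gaps)) {
    below <- sum(lens <= u[gi])
    above <- sum(lens >= u[gi + 1])
    if (below >= min_group && above >= min_group) {
      best <- gi
      break
    }
  }
  if (is.na(best)) {
    return(tibble(n_short = length(lens), n_long = 0L, gap = NA_integer_,
                  gap_lower = NA_integer_, gap_upper = NA_integer_))
  }
  tibble(n_short = sum(lens <= u[best]), n_long = sum(lens >= u[best + 1]),
         gap = gaps[best], gap_lower = u[best], gap_upper = u[best + 1])
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-rank-transformed vectors (ties allowed).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return `rho`, or `NA` when either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Mann-Whitney U statistic
#'
#' `U = min(U1, U2)` with `U1` the number of pairs where `a > b` plus half
#' the ties — the two-sided test statistic as classically reported.
#'
#' @param a,b Non-empty numeric vectors.
#' @return The U statistic.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  u1 <- unname(suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE)$statistic))
  min(u1, length(a) * length(b) - u1)
}

#' Families clustered on exactly one chromosome
#'
#' Chromosome-specific families: clustered or mixed-pattern families whose
#' clusters all sit on a single chromosome (the telomeric family excluded by
#' default).
#'
#' @param records Annotation tibble.
#' @param exclude Family names to exclude.
#' @return Character vector of family names.
#' @export
chromosome_specific <- function(records,
                                exclude = records$family[grepl("-tel$",
                                                               records$family)]) {
  rec <- records[!(records$family %in% exclude) &
                   records$pattern %in% c("c", "m"), , drop = FALSE]
  toks <- location_tokens(rec)
  if (!nrow(toks)) return(character())
  nchr <- tapply(toks$chromosome, toks$family, function(x) length(unique(x)))
  names(nchr)[nchr == 1]
}

#' Satellitome summary across the annotation table
#'
#' Bundles the headline satellitome statistics: location totals, monomer
#' length classes and dividing gap, variant totals, abundance totals, the
#' abundance-contig correlation and the clustered-vs-non-clustered contig
#' comparison.
#'
#' @param records Annotation tibble (all families).
#' @param working_set Records used for the length/correlation statistics;
#'   defaults to [satellitome_working_set()].
#' @param abundance_col Abundance column paired with the draft-genome contig
#'   counts; the draft genome is from the Northern-lineage individual, so
#'   `"ab_nl"` by default.  Missing abundances are treated as 0.
#' @return One-row tibble of summary statistics.
#' @export
satellitome_summary <- function(records,
                                working_set = satellitome_working_set(records),
                                abundance_col = "ab_nl") {
  loc <- summarize_locations(records)
  len <- length_distribution(working_set)
  ab <- working_set[[abundance_col]]
  ab[is.na(ab)] <- 0
  rho <- spearman_rho(ab, working_set$contigs)
  cl <- working_set$pattern %in% c("c", "m")
  u <- mann_whitney_u(working_set$contigs[cl], working_set$contigs[!cl])
  dplyr::bind_cols(
    loc, len,
    tibble(n_families = nrow(records),
           n_working = nrow(working_set),
           total_variants = sum(records$v, na.rm = TRUE),
           total_abundance_sl = sum(records$ab_sl, na.rm = TRUE),
           total_abundance_nl = sum(records$ab_nl, na.rm = TRUE),
           spearman_abundance_contigs = rho,
           mwu_contigs_clustered_vs_not = u,
           n_chromosome_specific = length(chromosome_specific(records))))
}
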