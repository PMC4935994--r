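#' Rotation- and strand-normalised percent identity between monomers
#'
#' Global alignment identity maximised over all rotations of `a` and both
#' strands: identity is matches over alignment columns, so the measure is
#' symmetric and equals 100 for any rotation or reverse complement of the
#' same monomer.
#'
#' @param a,b DNA strings.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  .rotational_identity_cpp(toupper(a), toupper(b))$identity
}

#' Identity thresholds for variant/family/superfamily tiers
#'
#' Monomers above `same_variant` percent identity are the same variant;
#' above `same_family` they are variants of one family; below `same_family`
#' but with a significant local alignment (at least `sf_min_len` aligned bp
#' at `sf_min_identity` percent) the families share a superfamily.  All
#' thresholds are strict (exclusive).
#'
#' @param same_variant Variant-merge threshold (percent).
#' @param same_family Family-merge threshold (percent).
#' @param sf_min_len Minimum aligned length for a superfamily link (bp).
#' @param sf_min_identity Minimum identity of that alignment (percent).
#' @return A list of class `identity_thresholds`.
#' @export
identity_thresholds <- function(same_variant = 95, same_family = 80,
                                sf_min_len = 50, sf_min_identity = 60) {
  stopifnot(same_variant > same_family)
  structure(list(same_variant = same_variant, same_family = same_family,
                 sf_min_len = sf_min_len, sf_min_identity = sf_min_identity),
            class = "identity_thresholds")
}

# single-linkage components from a logical adjacency matrix
single_linkage <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  unname(igraph::components(g)$membership)
}

#' Group consensus monomers into variants, families and superfamilies
#'
#' Single-linkage grouping on rotation/strand-normalised identity: monomers
#' above the variant threshold merge (the most abundant representative is
#' kept), families form above the family threshold, and families joined by a
#' significant-but-weaker local alignment share a superfamily.  Single
#' linkage makes the grouping independent of input order.
#'
#' @param monomers A tibble with columns `seq` and `abundance` (percent
#'   genome proportion used for ranking), or a character vector (abundance
#'   then defaults to equal).
#' @param thresholds An [identity_thresholds()] object.
#' @return An object of class `sat_catalog`: list with tibbles `families`
#'   (`family_id`, `seq`, `monomer_length`, `at_content`, `abundance`,
#'   `n_variants`, `superfamily_id`) and `variants` (`family_id`,
#'   `variant_index`, `seq`, `abundance`).
#' @export
group_catalog <- function(monomers, thresholds = identity_thresholds()) {
  if (is.character(monomers)) {
    monomers <- tibble(seq = monomers, abundance = 1)
  }
  if (nrow(monomers) == 0) abort("no monomers supplied")
  if (is.null(monomers$abundance)) monomers$abundance <- 1
  seqs <- canonical_rotation(toupper(monomers$seq))
  ab <- monomers$abundance
  n <- length(seqs)
  idm <- matrix(100, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        idm[i, j] <- idm[j, i] <- .rotational_identity_cpp(seqs[i], seqs[j])$identity
      }
    }
  }
  # 1. merge identical variants (> same_variant), keep most abundant rep
  vgrp <- single_linkage(idm > thresholds$same_variant)
  reps <- vapply(split(seq_len(n), vgrp), function(ix) {
    ix[order(-ab[ix], seqs[ix])][1]
  }, integer(1))
  vseq <- seqs[reps]
  vab <- ab[reps]
  m <- length(reps)
  vidm <- idm[reps, reps, drop = FALSE]
  # 2. families: single linkage above the family threshold
  fgrp <- single_linkage(vidm > thresholds$same_family)
  fam_ids <- sort(unique(fgrp))
  variants <- tibble(family_id = fgrp, seq = vseq, abundance = vab)
  variants <- variants[order(variants$family_id, -variants$abundance,
                             variants$seq), , drop = FALSE]
  variants <- variants |>
    group_by(.data$family_id) |>
    mutate(variant_index = row_number()) |>
    ungroup()
  families <- variants |>
    group_by(.data$family_id) |>
    summarise(seq = .data$seq[1], abundance = sum(.data$abundance),
              n_variants = n(), .groups = "drop")
  families$monomer_length <- nchar(families$seq)
  families$at_content <- at_content(families$seq)
  # 3. superfamilies: significant weaker similarity between family reps
  nf <- nrow(families)
  sf_adj <- matrix(FALSE, nf, nf)
  if (nf > 1) {
    for (i in 1:(nf - 1)) {
      for (j in (i + 1):nf) {
        # identity between the closest variants of the two families
        vi <- variants$seq[variants$family_id == families$family_id[i]]
        vj <- variants$seq[variants$family_id == families$family_id[j]]
        best <- 0
        linked <- FALSE
        for (a in vi) {
          for (b in vj) {
            if (significant_similarity(a, b, thresholds)) linked <- TRUE
          }
        }
        sf_adj[i, j] <- sf_adj[j, i] <- linked
      }
    }
  }
  sfgrp <- single_linkage(sf_adj)
  sf_sizes <- table(sfgrp)
  families$superfamily_id <- ifelse(
    as.vector(sf_sizes[as.character(sfgrp)]) > 1, sfgrp, NA_integer_)
  structure(list(families = families,
                 variants = variants[, c("family_id", "variant_index",
                                         "seq", "abundance")]),
            class = "sat_catalog")
}

# significant-but-below-family similarity: best local alignment between the
# doubled monomers (rotation-safe), either strand, spanning >= sf_min_len
# aligned bp at >= sf_min_identity percent identity
significant_similarity <- function(a, b, thresholds) {
  da <- strrep(a, 2)
  db <- strrep(b, 2)
  aln <- align_best_strand(da, db, mode = 0L)
  aligned <- aln$matches + aln$mismatches
  idt <- ifelse(aln$columns > 0, 100 * aln$matches / aln$columns, 0)
  aligned >= thresholds$sf_min_len && idt >= thresholds$sf_min_identity
}

#' Name satellite families by decreasing abundance
#'
#' Families are sorted by decreasing abundance (ties break by longer monomer,
#' then lexicographic consensus) and named
#' `<Abbrev>Sat<NN>-<monomer_length>` with a zero-padded catalog number, the
#' most abundant family first.  An optional functional `suffix` (e.g.
#' `"tel"`) can be attached per family afterwards via [rename_family()].
#'
#' @param catalog A `sat_catalog` from [group_catalog()].
#' @param species_abbrev Species abbreviation, e.g. `"Lmi"`.
#' @return The catalog with a `name` column added to `families`, re-numbered
#'   so `family_id` follows catalog order.
#' @export
name_families <- function(catalog, species_abbrev) {
  fam <- catalog$families
  ord <- order(-fam$abundance, -fam$monomer_length, fam$seq)
  fam <- fam[ord, , drop = FALSE]
  old_id <- fam$family_id
  fam$catalog_number <- seq_len(nrow(fam))
  fam$name <- sprintf("%sSat%02d-%d", species_abbrev, fam$catalog_number,
                      fam$monomer_length)
  id_map <- stats::setNames(fam$catalog_number, old_id)
  fam$family_id <- fam$catalog_number
  # renumber superfamilies in catalog order of their first member
  if (any(!is.na(fam$superfamily_id))) {
    first_seen <- unique(fam$superfamily_id[!is.na(fam$superfamily_id)])
    fam$superfamily_id <- match(fam$superfamily_id, first_seen)
  }
  variants <- catalog$variants
  variants$family_id <- unname(id_map[as.character(variants$family_id)])
  variants <- variants[order(variants$family_id, variants$variant_index), ,
                       drop = FALSE]
  structure(list(families = fam, variants = variants), class = "sat_catalog")
}

#' Attach a functional suffix to one family's name
#'
#' @param catalog A named `sat_catalog`.
#' @param name Current family name.
#' @param suffix Suffix to append (e.g. `"tel"`).
#' @return The catalog with the family renamed `<name>-<suffix>`.
#' @export
rename_family <- function(catalog, name, suffix) {
  i <- match(name, catalog$families$name)
  if (is.na(i)) abort(sprintf("no family named '%s'", name))
  catalog$families$name[i] <- paste0(name, "-", suffix)
  catalog
}

#' Parse a satellite family name into its parts
#'
#' @param name Family names like `"LmiSat01-193"` or `"LmiSat07-5-tel"`.
#' @return Tibble with `species_abbrev`, `catalog_number`, `monomer_length`,
#'   `suffix`.
#' @export
parse_family_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+)Sat([0-9]+)-([0-9]+)(?:-(.+))?$",
                                name))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) abort(sprintf("unparseable family name '%s'", name[bad][1]))
  tibble(
    species_abbrev = vapply(m, `[`, character(1), 2),
    catalog_number = as.integer(vapply(m, `[`, character(1), 3)),
    monomer_length = as.integer(vapply(m, `[`, character(1), 4)),
    suffix = ifelse(vapply(m, `[`, character(1), 5) == "",
                    NA_character_, vapply(m, `[`, character(1), 5))
  )
}

#' Minimum spanning tree over satellite variants
#'
#' Edge distance between two variants is substitutions plus indel events
#' (each contiguous indel counts one change, whatever its length), measured
#' on the best rotation/strand-normalised global alignment; the total
#' nucleotides involved in indels are reported per edge.  Setting
#' `indel_unit = "nt"` instead counts every gap column as a change.
#'
#' @param variants Character vector of variant sequences (>= 2), or a tibble
#'   with a `seq` column; names (or a `name` column) label the nodes.
#' @param indel_unit `"event"` (default) or `"nt"`.
#' @return A tibble of MST edges: `from`, `to`, `s` (substitutions), `id`
#'   (indel events), `id_nt` (indel nucleotides), `weight`.
#' @export
build_mst <- function(variants, indel_unit = c("event", "nt")) {
  indel_unit <- match.arg(indel_unit)
  if (is.data.frame(variants)) {
    labels <- variants$name %||% paste0("v", seq_len(nrow(variants)))
    seqs <- variants$seq
  } else {
    seqs <- unname(variants)
    labels <- names(variants) %||% paste0("v", seq_along(seqs))
  }
  n <- length(seqs)
  if (n < 2) abort("need at least 2 variants")
  pairs <- utils::combn(n, 2)
  stats_list <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    r <- .rotational_identity_cpp(toupper(seqs[i]), toupper(seqs[j]))
    tibble(from = labels[i], to = labels[j], s = r$substitutions,
           id = r$indel_events, id_nt = r$indel_nt)
  })
  edges <- bind_rows(stats_list)
  edges$weight <- edges$s +
    if (indel_unit == "event") edges$id else edges$id_nt
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = labels)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  out <- igraph::as_data_frame(mst, what = "edges")
  as_tibble(out[, c("from", "to", "s", "id", "id_nt", "weight")])
}

#' @export
print.sat_catalog <- function(x, ...) {
  cat(sprintf("satellite catalog: %d families, %d variants, %d superfamilies\n",
              nrow(x$families), nrow(x$variants),
              length(unique(stats::na.omit(x$families$superfamily_id)))))
  print(x$families)
  invisible(x)
}

#' @rdname group_catalog
#' @param x A `sat_catalog`.
#' @param ... Unused.
#' @export
tidy.sat_catalog <- function(x, ...) {
  left_join(x$variants, x$families[, c("family_id",
                                       setdiff(names(x$families),
                                               names(x$variants)))],
            by = "family_id")
}

#' @rdname group_catalog
#' @export
glance.sat_catalog <- function(x, ...) {
  tibble(n_families = nrow(x$families),
         n_variants = nrow(x$variants),
         n_superfamilies = length(unique(stats::na.omit(x$families$superfamily_id))),
         total_abundance = sum(x$families$abundance))
}

#' Write a catalog to FASTA
#'
#' One record per variant with headers `Name#variant`.
#'
#' @param catalog A named `sat_catalog`.
#' @param path Output FASTA path.
#' @return `catalog`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  td <- tidy(catalog)
  x <- Biostrings::DNAStringSet(td$seq)
  names(x) <- paste0(td$name %||% paste0("family", td$family_id),
                     "#", td$variant_index)
  Biostrings::writeXStringSet(x, path)
  invisible(catalog)
}
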