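#' Pipeline configuration
#'
#' Collects every tunable parameter of the discovery pipeline with the
#' protocol's defaults.  Input reads come either from paired FASTQ files
#' (`in1`/`in2`) or directly as a read-pair tibble (`pairs`).
#'
#' @param in1,in2 Paired FASTQ paths (optional if `pairs` given).
#' @param pairs Read-pair tibble (optional).
#' @param out_dir Output directory for artifacts.
#' @param species_abbrev Species abbreviation for family names.
#' @param schedule Pairs sampled per mining iteration.
#' @param seed Master seed; every stage derives from it.
#' @param qc [qc_params()] settings.
#' @param min_identity,min_overlap_frac Read-graph edge criteria.
#' @param density_threshold Cluster-density cutoff.
#' @param min_cluster_reads Minimum cluster size for consensus calling.
#' @param thresholds [identity_thresholds()] for catalog grouping.
#' @param quant_pairs Pairs sampled for quantification (0 = reuse all
#'   filtered input pairs).
#' @return A list of class `run_config`.
#' @export
run_config <- function(in1 = NULL, in2 = NULL, pairs = NULL,
                       out_dir = tempfile("satkit_run_"),
                       species_abbrev = "Sim",
                       schedule = c(5000, 20000, 20000), seed = 1,
                       qc = qc_params(),
                       min_identity = 90, min_overlap_frac = 0.55,
                       density_threshold = 0.1, min_cluster_reads = 10,
                       thresholds = identity_thresholds(),
                       quant_pairs = 0) {
  structure(list(in1 = in1, in2 = in2, pairs = pairs, out_dir = out_dir,
                 species_abbrev = species_abbrev, schedule = schedule,
                 seed = seed, qc = qc, min_identity = min_identity,
                 min_overlap_frac = min_overlap_frac,
                 density_threshold = density_threshold,
                 min_cluster_reads = min_cluster_reads,
                 thresholds = thresholds, quant_pairs = quant_pairs),
            class = "run_config")
}

pipeline_fail <- function(stage, msg) {
  abort(sprintf("pipeline stage '%s' failed: %s", stage, msg),
        class = "satkit_pipeline_error")
}

#' Run the full discovery pipeline
#'
#' Quality filtering, iterative mining, catalog grouping and naming,
#' read-based quantification and the repeat landscape, with all artifacts
#' written to the configured output directory (catalog FASTA and TSV,
#' mining report, quantification and landscape TSVs, and a log stamped with
#' the seed and a configuration hash).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `mining`, `catalog`, `quant`, `landscape`,
#'   `hits`, `total_nt` and the artifact paths.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "satkit.log")
  cfg_hash <- sum(utf8ToInt(paste(deparse(config[setdiff(names(config),
                                                         c("pairs"))]),
                                  collapse = ""))) %% 100000L
  note <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = logf, append = TRUE)
  }
  note("run seed=%d config_hash=%05d", config$seed, cfg_hash)

  # --- qc ---------------------------------------------------------------
  pairs <- config$pairs
  if (is.null(pairs)) {
    if (is.null(config$in1) || is.null(config$in2)) {
      pipeline_fail("qc", "no input reads: supply in1/in2 or pairs")
    }
    pairs <- read_fastq_pairs(config$in1, config$in2)
  }
  if (nrow(pairs) == 0) pipeline_fail("qc", "no input read pairs")
  pairs <- trim_and_filter_pairs(pairs, config$qc)
  if (nrow(pairs) == 0) pipeline_fail("qc", "no pairs survived quality filtering")
  note("qc: %d pairs retained", nrow(pairs))

  # --- mine -------------------------------------------------------------
  mining <- satminer_loop(pairs, schedule = config$schedule,
                          seed = config$seed,
                          min_cluster_reads = config$min_cluster_reads,
                          density_threshold = config$density_threshold,
                          min_identity = config$min_identity,
                          min_overlap_frac = config$min_overlap_frac)
  for (i in seq_len(nrow(mining$iterations))) {
    note("mine iter %d: %d new satellites",
         mining$iterations$iteration[i], mining$iterations$new_satellites[i])
  }
  readr::write_tsv(mining$iterations, file.path(config$out_dir, "mining.tsv"))
  if (nrow(mining$satellites) == 0) {
    note("mine: no satellites found; stopping after mining")
    return(invisible(list(mining = mining, catalog = NULL, quant = NULL,
                          landscape = NULL, paths = list(
                            mining = file.path(config$out_dir, "mining.tsv"),
                            log = logf))))
  }

  # --- catalog ----------------------------------------------------------
  monomers <- tibble(seq = mining$variants$seq,
                     abundance = mining$satellites$genome_proportion[
                       match(mining$variants$family_id,
                             mining$satellites$family_id)])
  catalog <- group_catalog(monomers, config$thresholds)
  catalog <- name_families(catalog, config$species_abbrev)
  fa_path <- file.path(config$out_dir, "catalog.fasta")
  write_catalog_fasta(catalog, fa_path)
  readr::write_tsv(tidy(catalog), file.path(config$out_dir, "catalog.tsv"))
  note("catalog: %d families / %d variants", nrow(catalog$families),
       nrow(catalog$variants))

  # --- quantify ---------------------------------------------------------
  qp <- if (config$quant_pairs > 0) {
    sample_pairs(pairs, min(config$quant_pairs, nrow(pairs)),
                 seed = config$seed + 777L)
  } else {
    pairs
  }
  lib <- sat_library(catalog)
  reads <- tibble(id = c(paste0(qp$id, "/1"), paste0(qp$id, "/2")),
                  seq = c(qp$seq1, qp$seq2))
  total_nt <- sum(nchar(reads$seq))
  hits <- align_reads_to_library(reads, lib)
  quant <- family_abundance(hits, total_nt)
  landscape <- repeat_landscape(hits, total_nt)
  readr::write_tsv(quant, file.path(config$out_dir, "quantification.tsv"))
  readr::write_tsv(landscape, file.path(config$out_dir, "landscape.tsv"))
  note("quantify: %d families quantified over %d nt", nrow(quant), total_nt)

  invisible(list(mining = mining, catalog = catalog, quant = quant,
                 landscape = landscape, hits = hits, total_nt = total_nt,
                 paths = list(
                   catalog_fasta = fa_path,
                   catalog_tsv = file.path(config$out_dir, "catalog.tsv"),
                   mining = file.path(config$out_dir, "mining.tsv"),
                   quant = file.path(config$out_dir, "quantification.tsv"),
                   landscape = file.path(config$out_dir, "landscape.tsv"),
                   log = logf)))
}
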