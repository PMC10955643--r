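#' Pipeline configuration
#'
#' One object driving the full analysis: cohort source (a simulation
#' configuration, or paths to on-disk cohorts), QC thresholds, the
#' screening threshold `alpha`, the burden subset-size guard, the
#' classifier design and an output directory. Defaults follow the
#' extreme-phenotype design throughout: `alpha = 0.05`, `DP >= 20`,
#' `FS <= 60`, `SOR <= 40`.
#'
#' @param sim a [simulation_config()] (simulate mode), or `NULL` when
#'   reading cohorts from disk.
#' @param disc_prefix,val_prefix file prefixes for [read_cohort()]
#'   (ingest mode); ignored in simulate mode.
#' @param qc a [qc_thresholds()].
#' @param alpha screening threshold in (0, 1).
#' @param k_max burden subset-search guard (see [subset_burden()]).
#' @param ml_families classifier families to train (`NULL` disables the
#'   classifier stage).
#' @param ml_k_folds CV folds for the classifier stage.
#' @param collections optional path to a GMT file of gene-set collections
#'   for the enrichment stage (`NULL` skips it).
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; the simulation seed and classifier seed are
#'   derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(), disc_prefix = NULL,
                            val_prefix = NULL, qc = qc_thresholds(),
                            alpha = 0.05, k_max = 12,
                            ml_families = c("LR", "SVC", "RF", "GbRF"),
                            ml_k_folds = 5, collections = NULL,
                            out_dir = "xassoc_out", seed = 1) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)")
  mode <- if (is.null(sim)) "ingest" else "simulate"
  if (mode == "ingest") {
    for (p in c(disc_prefix, val_prefix))
      if (!file.exists(paste0(p, ".vcf")))
        stop("cohort file not found: ", paste0(p, ".vcf"))
  }
  structure(list(mode = mode, sim = sim, disc_prefix = disc_prefix,
                 val_prefix = val_prefix, qc = qc, alpha = alpha,
                 k_max = k_max, ml_families = ml_families,
                 ml_k_folds = ml_k_folds, collections = collections,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim` and `qc`
#' are nested maps passed to [simulation_config()] and [qc_thresholds()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$sim)) args$sim <- do.call(simulation_config, y$sim)
  if (!is.null(y$qc)) args$qc <- do.call(qc_thresholds, y$qc)
  do.call(pipeline_config, args)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full two-cohort association pipeline
#'
#' Stages, executed on both cohorts over one shared variant panel:
#' simulate (or ingest) the cohorts; site-level QC and functional
#' prioritization; PCA structure check; per-variant exact allelic
#' association; exhaustive-subset gene burden; cross-cohort validation of
#' variants and genes; optional gene-set enrichment of validated genes
#' (universe: all genes with at least one tested variant); classifier
#' training on the validated-variant allelic-dose matrix. Every stage
#' writes a TSV/JSON artifact into `config$out_dir`, plus `manifest.json`
#' recording the seed, configuration, and per-stage record counts.
#' Re-running with the same configuration reproduces all artifacts
#' byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  if (config$mode == "simulate") {
    sim <- config$sim
    sim$seed <- config$seed
    pair <- simulate_cohort_pair(sim)
    disc <- pair$discovery; val <- pair$validation
    .write_tsv(pair$truth, out("truth.tsv"))
  } else {
    disc <- read_cohort(config$disc_prefix)
    val <- read_cohort(config$val_prefix)
    if (!identical(colnames(disc$genotypes), colnames(val$genotypes)))
      stop("stage qc: discovery and validation cohorts must share one ",
           "variant panel")
  }
  n_in <- n_variants(disc)

  qc <- apply_site_filters(disc$variants, config$qc)
  retained <- prioritize_functional(qc$retained)
  .write_tsv(data.frame(rule = names(qc$removed),
                        removed = as.integer(qc$removed)), out("qc.tsv"))
  if (!nrow(retained)) stop("stage qc: no variant survived filtering")
  disc <- subset_cohort(disc, retained$variant_id)
  val <- subset_cohort(val, retained$variant_id)

  structure_disc <- suppressWarnings(pca_structure_check(disc))

  assoc_d <- run_association(disc, config$alpha)
  assoc_v <- run_association(val, config$alpha)
  .write_tsv(assoc_d$all, out("assoc_disc.tsv"))
  .write_tsv(assoc_v$all, out("assoc_val.tsv"))

  burden_d <- run_burden(assoc_d$all, config$alpha, config$k_max)
  burden_v <- run_burden(assoc_v$all, config$alpha, config$k_max)
  .write_tsv(burden_d, out("burden_disc.tsv"))
  .write_tsv(burden_v, out("burden_val.tsv"))

  vv <- validate_variants(assoc_d$all, assoc_v$all, config$alpha)
  .write_tsv(vv$validated, out("validated_variants.tsv"))
  .write_tsv(vv$discordant, out("discordant_variants.tsv"))
  vg <- validate_genes(assoc_d$all, assoc_v$all, burden_d, burden_v,
                       config$alpha)
  .write_tsv(vg, out("validated_genes.tsv"))

  enrichment <- NULL
  if (!is.null(config$collections) && nrow(vg)) {
    collections <- read_gmt(config$collections)
    universe <- unique(disc$variants$gene)
    enrichment <- hypergeom_enrichment(intersect(vg$gene, universe),
                                       universe, collections)
    .write_tsv(enrichment, out("enrichment.tsv"))
  }

  ml <- NULL
  if (!is.null(config$ml_families) && nrow(vv$validated)) {
    ml <- run_ml(disc, val, vv$validated$variant_id,
                 families = config$ml_families, mode = "variant",
                 k_folds = config$ml_k_folds, seed = config$seed)
    report <- lapply(ml$models, function(f)
      list(best_params = as.list(f$best_params),
           cv_accuracy = f$cv_accuracy, cv_auc = f$cv_auc,
           accuracy = f$accuracy, precision = f$precision,
           recall = f$recall, f1 = f$f1, auc = f$auc,
           roc = list(fpr = f$roc$fpr, tpr = f$roc$tpr)))
    jsonlite::write_json(report, out("ml_report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package = "xassoc",
    version = as.character(utils::packageVersion("xassoc")),
    seed = config$seed,
    alpha = config$alpha,
    mode = config$mode,
    counts = list(
      variants_in = n_in,
      variants_after_qc = nrow(retained),
      pc1_fraction = structure_disc$pc1_fraction,
      structured = structure_disc$structured,
      significant_disc = nrow(assoc_d$significant),
      significant_val = nrow(assoc_v$significant),
      eligible_genes_disc = nrow(burden_d),
      eligible_genes_val = nrow(burden_v),
      validated_variants = nrow(vv$validated),
      discordant_variants = nrow(vv$discordant),
      validated_genes = nrow(vg)),
    ml = if (!is.null(ml)) ml$summary else NULL)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
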