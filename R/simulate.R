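#' Simulation configuration for a paired extreme-phenotype cohort design
#'
#' Describes the synthetic world generated by [simulate_cohort_pair()]: two
#' independent cohorts (discovery and validation) genotyped over one shared
#' panel of biallelic variants grouped into genes. Most variants are null
#' (one minor-allele frequency shared by cases and controls); a small set of
#' planted variants differs between cases and controls with the same
#' per-allele odds ratio in both cohorts, either case-enriched ("risk") or
#' control-enriched ("protective"). Planted variants come in two flavours:
#' singletons, each in its own gene, and variant-rich genes carrying several
#' planted variants of one direction.
#'
#' Defaults mirror the extreme-phenotype study design the package targets:
#' 50 cases / 50 controls in discovery, 66 cases / 83 controls in
#' validation, 16 planted singleton variants, and 3 variant-rich genes of
#' 4 variants each.
#'
#' @param n_case_disc,n_ctrl_disc,n_case_val,n_ctrl_val cohort sizes.
#' @param n_variants total number of variants on the shared panel.
#' @param n_genes total number of genes; null variants are assigned
#'   round-robin to the genes not reserved for planted signal.
#' @param maf_low,maf_high bounds of the uniform distribution null
#'   minor-allele frequencies are drawn from.
#' @param n_planted_case,n_planted_ctrl number of planted singleton
#'   case-enriched / control-enriched variants.
#' @param planted_or per-allele odds ratio of every planted variant
#'   (must be > 1; the enriched group's allele frequency is solved from the
#'   baseline frequency and this odds ratio).
#' @param planted_maf baseline (non-enriched group) allele frequency of
#'   planted variants.
#' @param n_variant_rich_genes number of genes carrying several planted
#'   variants of one direction (directions alternate case, control, ...).
#' @param variants_per_rich_gene planted variants per variant-rich gene.
#' @param nocall_rate probability that any single genotype is missing.
#' @param seed integer RNG seed; the full cohort pair is a deterministic
#'   function of the configuration including this seed.
#'
#' @return a validated `simulation_config` list.
#' @seealso [simulate_cohort_pair()]
#' @export
simulation_config <- function(n_case_disc = 50, n_ctrl_disc = 50,
                              n_case_val = 66, n_ctrl_val = 83,
                              n_variants = 5000, n_genes = 500,
                              maf_low = 0.01, maf_high = 0.30,
                              n_planted_case = 8, n_planted_ctrl = 8,
                              planted_or = 4, planted_maf = 0.15,
                              n_variant_rich_genes = 3,
                              variants_per_rich_gene = 4,
                              nocall_rate = 0.02, seed = 1) {
  cfg <- list(n_case_disc = n_case_disc, n_ctrl_disc = n_ctrl_disc,
              n_case_val = n_case_val, n_ctrl_val = n_ctrl_val,
              n_variants = n_variants, n_genes = n_genes,
              maf_low = maf_low, maf_high = maf_high,
              n_planted_case = n_planted_case,
              n_planted_ctrl = n_planted_ctrl,
              planted_or = planted_or, planted_maf = planted_maf,
              n_variant_rich_genes = n_variant_rich_genes,
              variants_per_rich_gene = variants_per_rich_gene,
              nocall_rate = nocall_rate, seed = as.integer(seed))
  counts <- c("n_case_disc", "n_ctrl_disc", "n_case_val", "n_ctrl_val",
              "n_variants", "n_genes", "n_planted_case", "n_planted_ctrl",
              "n_variant_rich_genes", "variants_per_rich_gene")
  for (f in counts)
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop("configuration error: `", f, "` must be a non-negative count")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high < 0.5))
    stop("configuration error: need 0 < maf_low <= maf_high < 0.5")
  if (planted_or <= 1)
    stop("configuration error: `planted_or` must be > 1")
  if (!(planted_maf > 0 && planted_maf < 0.5))
    stop("configuration error: `planted_maf` must lie in (0, 0.5)")
  if (nocall_rate < 0 || nocall_rate >= 0.5)
    stop("configuration error: `nocall_rate` must lie in [0, 0.5)")
  n_planted <- n_planted_case + n_planted_ctrl +
    n_variant_rich_genes * variants_per_rich_gene
  if (n_planted > n_variants)
    stop("configuration error: planted variants (", n_planted,
         ") exceed `n_variants` (", n_variants, ")")
  n_signal_genes <- n_planted_case + n_planted_ctrl + n_variant_rich_genes
  if (n_genes <= n_signal_genes && n_planted < n_variants)
    stop("configuration error: `n_genes` (", n_genes, ") must exceed the ",
         n_signal_genes, " genes reserved for planted variants")
  class(cfg) <- "simulation_config"
  cfg
}

# enriched-group allele frequency implied by a baseline frequency and a
# per-allele odds ratio: af' = OR*af / (1 + af*(OR - 1))
.af_from_or <- function(af, or) (or * af) / (1 + af * (or - 1))

#' Simulate a paired discovery/validation cohort with planted signal
#'
#' Generates two independent case-control cohorts over one shared variant
#' panel. For every variant each group (cases, controls) has a generating
#' allele frequency; individual genotypes are drawn under Hardy-Weinberg
#' equilibrium (alt-allele count ~ Binomial(2, af)), then no-calls are
#' applied independently per cell at the configured rate. Null variants use
#' one frequency for both groups; planted variants have the enriched
#' group's frequency raised so the per-allele odds ratio equals
#' `planted_or` in both cohorts. Ages and pack-years are drawn uniformly
#' inside the extreme-phenotype eligibility windows (cases 35-56 years,
#' controls 74-87 years, both >= 15 pack-years) and are metadata only.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `discovery` and `validation` (each a
#'   [cohort()]) and `truth`, a data.frame with one row per variant:
#'   `variant_id`, `status` (`"null"`, `"planted_case"`, `"planted_ctrl"`),
#'   `gene`, `maf_ctrl`, `maf_case`.
#' @export
simulate_cohort_pair <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  set.seed(config$seed)
  nv <- config$n_variants
  n_rich <- config$n_variant_rich_genes
  vpr <- config$variants_per_rich_gene
  n_pc <- config$n_planted_case
  n_pt <- config$n_planted_ctrl
  n_rich_var <- n_rich * vpr
  n_null <- nv - n_rich_var - n_pc - n_pt

  # variant panel layout: rich-gene variants, planted singletons, nulls
  status <- c(rep(rep(c("planted_case", "planted_ctrl"),
                      length.out = max(n_rich, 0)), each = vpr),
              rep("planted_case", n_pc), rep("planted_ctrl", n_pt),
              rep("null", n_null))
  gene <- character(nv)
  if (n_rich_var > 0)
    gene[seq_len(n_rich_var)] <- rep(sprintf("GR%03d", seq_len(n_rich)),
                                     each = vpr)
  if (n_pc + n_pt > 0)
    gene[n_rich_var + seq_len(n_pc + n_pt)] <-
      sprintf("GP%04d", seq_len(n_pc + n_pt))
  if (n_null > 0) {
    null_genes <- sprintf("G%04d", seq_len(config$n_genes - n_rich - n_pc - n_pt))
    gene[n_rich_var + n_pc + n_pt + seq_len(n_null)] <-
      rep(null_genes, length.out = n_null)
  }

  pos <- 1000L * seq_len(nv)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  variant_id <- paste("1", pos, ref, alt, sep = ":")

  maf_ctrl <- stats::runif(nv, config$maf_low, config$maf_high)
  maf_case <- maf_ctrl
  pc <- status == "planted_case"
  pt <- status == "planted_ctrl"
  maf_ctrl[pc] <- config$planted_maf
  maf_case[pc] <- .af_from_or(config$planted_maf, config$planted_or)
  maf_case[pt] <- config$planted_maf
  maf_ctrl[pt] <- .af_from_or(config$planted_maf, config$planted_or)

  truth <- data.frame(variant_id = variant_id, status = status, gene = gene,
                      maf_ctrl = maf_ctrl, maf_case = maf_case,
                      stringsAsFactors = FALSE)

  anno <- data.frame(
    variant_id = variant_id, chrom = "1", pos = pos, ref = ref, alt = alt,
    gene = gene,
    func_class = ifelse(status == "null",
                        sample(.functional_keep, nv, replace = TRUE),
                        "nonsynonymous_snv"),
    var_type = "snv",
    DP = round(stats::runif(nv, 20, 100), 2),
    FS = round(stats::runif(nv, 0, 60), 2),
    SOR = round(stats::runif(nv, 0, 40), 2),
    stringsAsFactors = FALSE)

  draw_cohort <- function(n_case, n_ctrl, tag) {
    n <- n_case + n_ctrl
    ids <- c(sprintf("%s_CASE_%03d", tag, seq_len(n_case)),
             sprintf("%s_CTRL_%03d", tag, seq_len(n_ctrl)))
    labels <- c(rep("case", n_case), rep("control", n_ctrl))
    g <- matrix(NA_integer_, n, nv, dimnames = list(ids, variant_id))
    if (n_case > 0)
      g[seq_len(n_case), ] <- stats::rbinom(n_case * nv, 2L,
                                            rep(maf_case, each = n_case))
    if (n_ctrl > 0)
      g[n_case + seq_len(n_ctrl), ] <- stats::rbinom(n_ctrl * nv, 2L,
                                                     rep(maf_ctrl, each = n_ctrl))
    if (config$nocall_rate > 0)
      g[stats::runif(length(g)) < config$nocall_rate] <- NA_integer_
    age <- round(ifelse(labels == "case", stats::runif(n, 35, 56),
                        stats::runif(n, 74, 87)), 1)
    py <- round(ifelse(labels == "case", stats::runif(n, 15, 99),
                       stats::runif(n, 30, 151)), 1)
    cohort(g, labels, anno, age = age, pack_years = py)
  }

  discovery <- draw_cohort(config$n_case_disc, config$n_ctrl_disc, "D")
  validation <- draw_cohort(config$n_case_val, config$n_ctrl_val, "V")
  list(discovery = discovery, validation = validation, truth = truth)
}

#' Simulate one cohort with two subpopulations (stratification exercise)
#'
#' Produces a deliberately structured genotype matrix: half the samples
#' belong to a subpopulation whose allele frequency is shifted by `delta`
#' on half of the variants. Exists only to exercise
#' [pca_structure_check()]; the main generator draws unstructured cohorts.
#'
#' @param n_samples,n_variants matrix dimensions.
#' @param delta allele-frequency shift applied to the second subpopulation
#'   on the first half of the variants.
#' @param maf baseline allele frequency.
#' @param seed RNG seed.
#' @return a `cohort` whose labels split cases/controls across both
#'   subpopulations evenly.
#' @export
simulate_structured_cohort <- function(n_samples = 100, n_variants = 500,
                                       delta = 0.3, maf = 0.2, seed = 1) {
  set.seed(seed)
  pos <- 1000L * seq_len(n_variants)
  variant_id <- paste("1", pos, "A", "G", sep = ":")
  af <- matrix(maf, n_samples, n_variants)
  half_s <- seq_len(floor(n_samples / 2))
  half_v <- seq_len(floor(n_variants / 2))
  af[-half_s, half_v] <- pmin(maf + delta, 0.95)
  g <- matrix(stats::rbinom(length(af), 2L, af), n_samples, n_variants,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                              variant_id))
  anno <- data.frame(variant_id = variant_id, chrom = "1", pos = pos,
                     ref = "A", alt = "G",
                     gene = sprintf("G%04d", seq_len(n_variants)),
                     func_class = "nonsynonymous_snv", var_type = "snv",
                     DP = 50, FS = 0, SOR = 0, stringsAsFactors = FALSE)
  cohort(g, rep(c("case", "control"), length.out = n_samples), anno)
}
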