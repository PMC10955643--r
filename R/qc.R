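#' Site-level QC thresholds
#'
#' The three named site filters: depth-normalized variant quality
#' (`DP`, exclude < `dp_min`), phred-scaled Fisher strand bias
#' (`FS`, exclude > `fs_max`) and symmetric strand odds ratio
#' (`SOR`, exclude > `sor_max`). A site is retained only if it passes every
#' enabled rule; boundaries are retained (exclusion is strict). Set a
#' threshold to `NULL` to disable that rule.
#'
#' @param dp_min minimum DP retained (default 20).
#' @param fs_max maximum FS retained (default 60).
#' @param sor_max maximum SOR retained (default 40).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(dp_min = 20, fs_max = 60, sor_max = 40) {
  for (v in list(dp_min, fs_max, sor_max))
    if (!is.null(v) && v <= 0) stop("QC thresholds must be positive")
  structure(list(dp_min = dp_min, fs_max = fs_max, sor_max = sor_max),
            class = "qc_thresholds")
}

#' Apply site-level quality filters
#'
#' Retains exactly the variants with `DP >= dp_min`, `FS <= fs_max` and
#' `SOR <= sor_max` (order preserved). A variant with a missing enabled
#' metric is removed and counted under `missing_metric`. Filtering is
#' idempotent.
#'
#' @param variants variant annotation data.frame with `DP`, `FS`, `SOR`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `retained` (filtered data.frame) and `removed`
#'   (named integer vector: removals per rule, plus `missing_metric`;
#'   a variant failing several rules is counted under each).
#' @export
apply_site_filters <- function(variants, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(variants))
  if (!inherits(thresholds, "qc_thresholds"))
    thresholds <- do.call(qc_thresholds, thresholds)
  n <- nrow(variants)
  pass <- rep(TRUE, n)
  missing <- rep(FALSE, n)
  removed <- c(dp = 0L, fs = 0L, sor = 0L, missing_metric = 0L)
  rule <- function(metric, fail_fun, name) {
    vals <- variants[[metric]]
    if (is.null(vals)) vals <- rep(NA_real_, n)
    miss <- is.na(vals)
    fail <- !miss & fail_fun(vals)
    removed[[name]] <<- sum(fail)
    missing <<- missing | miss
    pass <<- pass & !fail & !miss
  }
  if (!is.null(thresholds$dp_min))
    rule("DP", function(v) v < thresholds$dp_min, "dp")
  if (!is.null(thresholds$fs_max))
    rule("FS", function(v) v > thresholds$fs_max, "fs")
  if (!is.null(thresholds$sor_max))
    rule("SOR", function(v) v > thresholds$sor_max, "sor")
  removed[["missing_metric"]] <- sum(missing)
  list(retained = variants[pass, , drop = FALSE], removed = removed)
}

#' Retain protein-altering and canonical splice-flank variants
#'
#' Keeps variants whose `func_class` is one of [functional_classes()]
#' (nonsynonymous SNVs, frameshift and in-frame indels, stop gains/losses,
#' canonical splice flanks); class `"other"` — synonymous, deep intronic,
#' UTR — is removed. Order is preserved and an empty result is allowed.
#'
#' @param variants variant annotation data.frame with `func_class`.
#' @return the retained rows.
#' @export
prioritize_functional <- function(variants) {
  stopifnot(is.data.frame(variants), !is.null(variants$func_class))
  variants[variants$func_class %in% .functional_keep, , drop = FALSE]
}

#' Population-structure check by principal component analysis
#'
#' Encodes genotypes as alternate-allele counts (0/1/2) with no-calls
#' mean-imputed per variant, centres columns, and reports the fraction of
#' total variance explained by each of the leading principal components.
#' The cohort is flagged as structured when PC1 explains more than
#' `pc1_threshold` of the variance; the flag is advisory (a warning is
#' emitted), never a hard stop — an unstructured extreme-phenotype cohort
#' shows a flat eigenvalue profile with PC1 around 1%.
#'
#' @param x a [cohort()].
#' @param n_components number of leading components to report.
#' @param pc1_threshold structured-flag threshold on the PC1 variance
#'   fraction (default 0.05).
#' @return a `structure_report` list: `variance_fractions`, `pc1_fraction`,
#'   `structured`.
#' @export
pca_structure_check <- function(x, n_components = 10, pc1_threshold = 0.05) {
  stopifnot(inherits(x, "cohort"))
  if (n_samples(x) < 2 || n_variants(x) < 2)
    stop("need at least 2 samples and 2 variants for a structure check")
  g <- x$genotypes
  storage.mode(g) <- "double"
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(g))
  if (length(idx)) g[idx] <- mu[(idx - 1L) %/% nrow(g) + 1L]
  vars <- apply(g, 2, stats::var)
  if (all(vars == 0))
    stop("degenerate input: genotype matrix is constant in every variant")
  pc <- stats::prcomp(g, center = TRUE, scale. = FALSE)
  fractions <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, length(fractions))
  report <- structure(
    list(variance_fractions = fractions[seq_len(k)],
         pc1_fraction = fractions[1],
         structured = fractions[1] > pc1_threshold),
    class = "structure_report")
  if (report$structured)
    warning(sprintf(paste0("possible population structure: PC1 explains ",
                           "%.1f%% of variance (threshold %.1f%%)"),
                    100 * report$pc1_fraction, 100 * pc1_threshold),
            call. = FALSE)
  report
}

#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report> PC1 fraction:",
      format(round(x$pc1_fraction, 4)),
      if (x$structured) "(STRUCTURED)" else "(unstructured)", "\n")
  cat("  leading variance fractions:",
      paste(format(round(x$variance_fractions, 4)), collapse = " "), "\n")
  invisible(x)
}
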