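#' Cohort container
#'
#' A `cohort` bundles a genotype matrix with per-sample phenotype metadata
#' and per-variant annotation for one case-control cohort. Genotypes are
#' stored as integer alternate-allele counts per sample and biallelic site:
#' `0` homozygous reference, `1` heterozygous, `2` homozygous alternate,
#' `NA` no-call. Rows are samples, columns variants; dimnames carry the
#' sample and variant identifiers.
#'
#' @param genotypes integer matrix (samples x variants) with values in
#'   `{0, 1, 2, NA}` and complete dimnames.
#' @param labels character vector, one of `"case"` / `"control"` per sample.
#' @param variants data.frame of variant annotation with at least columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `func_class`,
#'   `var_type`, `DP`, `FS`, `SOR`; one row per genotype column, same order.
#' @param age numeric vector of ages in years (metadata only).
#' @param pack_years numeric vector of smoking exposure in pack-years
#'   (metadata only).
#'
#' @return An object of class `cohort`.
#' @export
cohort <- function(genotypes, labels, variants, age = NULL, pack_years = NULL) {
  if (!is.matrix(genotypes))
    stop("`genotypes` must be a matrix (samples x variants)")
  storage.mode(genotypes) <- "integer"
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0 (homref), 1 (het), 2 (homalt) or NA (nocall)")
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop("`genotypes` needs sample IDs as rownames and variant IDs as colnames")
  labels <- as.character(labels)
  if (length(labels) != nrow(genotypes))
    stop("`labels` length (", length(labels), ") does not match the ",
         nrow(genotypes), " samples")
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  if (!is.data.frame(variants))
    stop("`variants` must be a data.frame of variant annotation")
  if (nrow(variants) != ncol(genotypes))
    stop("annotation covers ", nrow(variants), " variants but the genotype ",
         "matrix has ", ncol(genotypes))
  if (!identical(as.character(variants$variant_id), colnames(genotypes)))
    stop("annotation variant_id order must match genotype columns")
  if (is.null(age)) age <- rep(NA_real_, nrow(genotypes))
  if (is.null(pack_years)) pack_years <- rep(NA_real_, nrow(genotypes))
  stopifnot(length(age) == nrow(genotypes),
            length(pack_years) == nrow(genotypes))
  structure(
    list(sample_ids = rownames(genotypes),
         labels = labels,
         genotypes = genotypes,
         variants = variants,
         age = as.numeric(age),
         pack_years = as.numeric(pack_years)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$sample_ids), " samples (",
      sum(x$labels == "case"), " cases / ",
      sum(x$labels == "control"), " controls), ",
      ncol(x$genotypes), " variants, ",
      length(unique(x$variants$gene)), " genes\n", sep = "")
  nc <- mean(is.na(x$genotypes))
  cat("  no-call rate: ", format(round(nc, 4)), "\n", sep = "")
  invisible(x)
}

#' Number of samples / variants in a cohort
#' @param x a `cohort`
#' @return integer count
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname n_samples
#' @export
n_variants <- function(x) ncol(x$genotypes)

#' Restrict a cohort to a subset of variants
#'
#' @param x a `cohort`
#' @param variant_ids character vector of variant identifiers to keep;
#'   original panel order is preserved.
#' @return a `cohort` over the reduced panel
#' @export
subset_cohort <- function(x, variant_ids) {
  stopifnot(inherits(x, "cohort"))
  keep <- colnames(x$genotypes) %in% variant_ids
  if (!any(keep)) stop("no requested variant is present in the cohort panel")
  cohort(x$genotypes[, keep, drop = FALSE], x$labels,
         x$variants[keep, , drop = FALSE],
         age = x$age, pack_years = x$pack_years)
}

# Functional annotation classes retained by the prioritization step:
# protein-altering coding changes plus canonical splice-flank variants.
.functional_keep <- c("nonsynonymous_snv", "frameshift_ins", "frameshift_del",
                      "nonframeshift_ins", "nonframeshift_del",
                      "stopgain", "stoploss", "splice_canonical")

#' Functional classes retained by prioritization
#'
#' The set of annotation classes treated as protein-altering (coding
#' nonsynonymous changes, in-frame and frameshift indels, stop gains and
#' losses) or canonical splice-site flanking; everything else
#' (class `"other"`, e.g. synonymous or intronic) is dropped by
#' [prioritize_functional()].
#'
#' @return character vector of class names
#' @export
functional_classes <- function() .functional_keep
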