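#' Allele-count table for one variant
#'
#' Tabulates alternate/reference allele counts in cases and controls. Each
#' called genotype contributes two alleles (homref: 2 ref; het: 1 + 1;
#' homalt: 2 alt); no-calls contribute nothing — missing genotypes are
#' dropped from the allele totals, not imputed.
#'
#' @param x a [cohort()].
#' @param variant_id a variant identifier present in the cohort panel.
#' @return an `allele_table`: named list `case_alt`, `case_ref`,
#'   `ctrl_alt`, `ctrl_ref`.
#' @export
allele_counts <- function(x, variant_id) {
  stopifnot(inherits(x, "cohort"))
  j <- match(variant_id, colnames(x$genotypes))
  if (is.na(j)) stop("unknown variant: ", variant_id)
  g <- x$genotypes[, j]
  is_case <- x$labels == "case"
  cnt <- function(sel) {
    called <- sum(!is.na(g[sel]))
    alt <- sum(g[sel], na.rm = TRUE)
    c(alt = alt, ref = 2L * called - alt)
  }
  ca <- cnt(is_case); co <- cnt(!is_case)
  allele_table(ca[["alt"]], ca[["ref"]], co[["alt"]], co[["ref"]])
}

#' @rdname allele_counts
#' @param case_alt,case_ref,ctrl_alt,ctrl_ref non-negative allele counts.
#' @export
allele_table <- function(case_alt, case_ref, ctrl_alt, ctrl_ref) {
  tab <- list(case_alt = case_alt, case_ref = case_ref,
              ctrl_alt = ctrl_alt, ctrl_ref = ctrl_ref)
  if (any(unlist(tab) < 0)) stop("allele counts must be non-negative")
  structure(tab, class = "allele_table")
}

# scalar worker: two-sided exact allelic p-value for one 2x2 allele table.
# Conditional on both margins, the case alt-allele count is hypergeometric;
# the two-sided p sums the probabilities of all tables whose point
# probability does not exceed that of the observed table (point-probability
# rule, with the customary 1 + 1e-7 relative tolerance against ties lost to
# floating point). Any zero margin gives p = 1.
.allelic_p <- function(case_alt, case_ref, ctrl_alt, ctrl_ref) {
  m <- case_alt + case_ref
  n <- ctrl_alt + ctrl_ref
  k <- case_alt + ctrl_alt
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0, k - n)
  d <- stats::dhyper(lo:min(k, m), k, m + n - k, m)
  keep <- d <= d[[case_alt - lo + 1]] * (1 + 1e-7)
  if (all(keep)) return(1)
  min(1, sum(d[keep]))
}

#' Exact allelic association test on a 2x2 allele-count table
#'
#' The allelic test compares alternate-allele frequencies between cases and
#' controls on the allele scale (two alleles per called genotype).
#' Conditional on the table margins the case alternate-allele count is
#' hypergeometric; the reported p-value is the exact two-sided tail under
#' the point-probability rule (the probability mass of all tables as or
#' less probable than the observed one), the same convention as the
#' classical conditional exact test on 2x2 tables. The enrichment direction
#' is `"case"` when the case allele frequency exceeds the control
#' frequency, `"control"` for the reverse, `"none"` when they are equal or
#' one group has no called alleles. When any margin is zero, p = 1.
#'
#' @param table an [allele_table()] (or a list with the same four fields).
#' @return list with `p`, `direction`, `af_case`, `af_ctrl`.
#' @export
exact_allelic_test <- function(table) {
  ca <- table$case_alt; cr <- table$case_ref
  ta <- table$ctrl_alt; tr <- table$ctrl_ref
  m <- ca + cr; n <- ta + tr
  if (m == 0 && n == 0)
    stop("degenerate input: both groups have zero called alleles")
  af_case <- if (m > 0) ca / m else NA_real_
  af_ctrl <- if (n > 0) ta / n else NA_real_
  direction <-
    if (m == 0 || n == 0 || af_case == af_ctrl) "none"
    else if (af_case > af_ctrl) "case" else "control"
  list(p = .allelic_p(ca, cr, ta, tr), direction = direction,
       af_case = af_case, af_ctrl = af_ctrl)
}

#' Per-variant allelic association across a cohort
#'
#' Runs [exact_allelic_test()] on every variant of the cohort panel and
#' screens at the raw p-value threshold `alpha` (screening deliberately
#' uses unadjusted p-values; [bh_adjust()] is available for reporting).
#'
#' @param x a [cohort()] containing both cases and controls.
#' @param alpha screening threshold on the raw p-value (default 0.05).
#' @return list with `all` — a data.frame of one row per variant
#'   (`variant_id`, `gene`, the four allele counts, `af_case`, `af_ctrl`,
#'   `p`, `direction`), sorted by ascending p with ties broken by
#'   `variant_id` — and `significant`, the rows with `p < alpha`.
#' @export
run_association <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "cohort"))
  if (length(unique(x$labels)) < 2)
    stop("design error: cohort must contain both cases and controls")
  if (!(alpha > 0 && alpha <= 1)) stop("`alpha` must lie in (0, 1]")
  g <- x$genotypes
  is_case <- x$labels == "case"
  gc <- g[is_case, , drop = FALSE]
  gt <- g[!is_case, , drop = FALSE]
  case_alt <- colSums(gc, na.rm = TRUE)
  case_ref <- 2L * colSums(!is.na(gc)) - case_alt
  ctrl_alt <- colSums(gt, na.rm = TRUE)
  ctrl_ref <- 2L * colSums(!is.na(gt)) - ctrl_alt
  nv <- ncol(g)
  p <- numeric(nv)
  for (j in seq_len(nv))
    p[j] <- .allelic_p(case_alt[j], case_ref[j], ctrl_alt[j], ctrl_ref[j])
  m <- case_alt + case_ref
  n <- ctrl_alt + ctrl_ref
  af_case <- ifelse(m > 0, case_alt / m, NA_real_)
  af_ctrl <- ifelse(n > 0, ctrl_alt / n, NA_real_)
  direction <- ifelse(m == 0 | n == 0 | af_case == af_ctrl, "none",
                      ifelse(af_case > af_ctrl, "case", "control"))
  direction[is.na(direction)] <- "none"
  res <- data.frame(
    variant_id = colnames(g), gene = x$variants$gene,
    case_alt = as.integer(case_alt), case_ref = as.integer(case_ref),
    ctrl_alt = as.integer(ctrl_alt), ctrl_ref = as.integer(ctrl_ref),
    af_case = af_case, af_ctrl = af_ctrl, p = p, direction = direction,
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p, res$variant_id), , drop = FALSE]
  rownames(res) <- NULL
  list(all = res, significant = res[res$p < alpha, , drop = FALSE])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (monotone, capped at 1, returned
#' in the original order). Provided for reporting; the screening steps of
#' the pipeline use raw p-values.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
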