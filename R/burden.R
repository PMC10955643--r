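#' Genes eligible for burden analysis
#'
#' A gene enters the burden stage when it harbours two or more variants
#' whose marginal allelic p-value is below `alpha`.
#'
#' @param results association results data.frame (the `all` element of
#'   [run_association()]), carrying `gene`, `p`, `direction`.
#' @param alpha significance threshold (default 0.05).
#' @return named list mapping each eligible gene to the data.frame of its
#'   significant variants (with directions).
#' @export
eligible_genes <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), !is.null(results$gene))
  sig <- results[results$p < alpha, , drop = FALSE]
  out <- split(sig, sig$gene)
  out <- out[vapply(out, nrow, 0L) >= 2L]
  out[order(names(out))]
}

# Bonferroni-adjusted minimum subset p over the given variant indices:
# enumerate every non-empty subset, pool the four allele counts across the
# subset, apply the exact allelic test, take the minimum p multiplied by
# the number of subsets (capped at 1). Returns the winning subset
# (lexicographically smallest sorted variant_id list on ties).
.subset_scan <- function(counts, ids, idx) {
  k <- length(idx)
  if (k == 0L) return(list(p = 1, adj_p = 1, best = character(0)))
  n_sub <- 2L^k - 1L
  best_p <- Inf
  best <- NULL
  sub <- counts[idx, , drop = FALSE]
  for (mask in seq_len(n_sub)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    pooled <- colSums(sub[sel, , drop = FALSE])
    p <- .allelic_p(pooled[[1]], pooled[[2]], pooled[[3]], pooled[[4]])
    if (p < best_p - 1e-15) {
      best_p <- p; best <- sort(ids[idx[sel]])
    } else if (p <= best_p + 1e-15) {
      best_p <- min(best_p, p)
      cand <- sort(ids[idx[sel]])
      if (paste(cand, collapse = "\r") < paste(best, collapse = "\r"))
        best <- cand
    }
  }
  list(p = best_p, adj_p = min(1, best_p * n_sub), best = best)
}

#' Exhaustive-subset burden analysis for one gene
#'
#' Explores all possible subsets of a gene's significant variants. For
#' every non-empty subset the four allele counts are pooled (summed) across
#' the subset's variants and the exact allelic test applied, so the burden
#' statistic stays on the allele scale used throughout. Three adjusted
#' minima are reported, each Bonferroni-multiplied by its own number of
#' subsets and capped at 1:
#' \describe{
#'   \item{meta_p}{over all `2^k - 1` subsets of the `k` variants;}
#'   \item{subset_case_meta_p}{restricted to subsets of the case-enriched
#'     variants only (the high-risk signal);}
#'   \item{subset_control_meta_p}{restricted to control-enriched variants
#'     (the low-risk signal).}
#' }
#' The two directional meta-p-values are combined by
#' [combine_subset_meta()] into `subset_meta_p`. A direction with no
#' eligible variants yields meta-p 1 and an empty best subset. Variant
#' directions are taken from the marginal association results.
#'
#' @param gene_variants data.frame of one gene's significant variants as
#'   produced by [run_association()] (columns `variant_id`, `gene`,
#'   `case_alt`, `case_ref`, `ctrl_alt`, `ctrl_ref`, `direction`).
#' @param k_max refuse genes with more than this many variants (the search
#'   cost is `2^k`; default 12). Raise explicitly if needed.
#' @return a `gene_burden` list: `gene`, `variant_ids`, `meta_p`,
#'   `subset_case_meta_p`, `subset_control_meta_p`, `subset_meta_p`,
#'   `best_case_subset`, `best_control_subset`, `best_subset`.
#' @export
subset_burden <- function(gene_variants, k_max = 12) {
  stopifnot(is.data.frame(gene_variants))
  k <- nrow(gene_variants)
  if (k < 2) stop("design error: burden analysis needs >= 2 variants")
  if (length(unique(gene_variants$gene)) != 1L)
    stop("all variants must come from one gene")
  if (k > k_max)
    stop("gene has ", k, " significant variants; the exhaustive subset ",
         "search costs 2^k tests. Raise `k_max` (currently ", k_max,
         ") to process it anyway.")
  counts <- as.matrix(gene_variants[, c("case_alt", "case_ref",
                                        "ctrl_alt", "ctrl_ref")])
  ids <- as.character(gene_variants$variant_id)
  all_scan <- .subset_scan(counts, ids, seq_len(k))
  case_scan <- .subset_scan(counts, ids, which(gene_variants$direction == "case"))
  ctrl_scan <- .subset_scan(counts, ids, which(gene_variants$direction == "control"))
  structure(
    list(gene = gene_variants$gene[[1]],
         variant_ids = ids,
         meta_p = all_scan$adj_p,
         subset_case_meta_p = case_scan$adj_p,
         subset_control_meta_p = ctrl_scan$adj_p,
         subset_meta_p = combine_subset_meta(case_scan$adj_p, ctrl_scan$adj_p),
         best_subset = all_scan$best,
         best_case_subset = case_scan$best,
         best_control_subset = ctrl_scan$best),
    class = "gene_burden")
}

#' Combine the two directional subset meta-p-values
#'
#' Fisher's method on the case and control subset signals:
#' `X = -2 (ln p_case + ln p_ctrl)` referred to a chi-square distribution
#' with 4 degrees of freedom. Symmetric in its arguments and decreasing in
#' each; `(1, 1)` maps to 1. A zero input is clamped to the smallest
#' positive double with a warning.
#'
#' @param p_case,p_ctrl directional meta-p-values in (0, 1].
#' @return the combined p-value.
#' @export
combine_subset_meta <- function(p_case, p_ctrl) {
  stopifnot(p_case >= 0, p_case <= 1, p_ctrl >= 0, p_ctrl <= 1)
  if (p_case == 0 || p_ctrl == 0) {
    warning("zero p-value clamped to the smallest positive double",
            call. = FALSE)
    p_case <- max(p_case, .Machine$double.xmin)
    p_ctrl <- max(p_ctrl, .Machine$double.xmin)
  }
  stats::pchisq(-2 * (log(p_case) + log(p_ctrl)), df = 4, lower.tail = FALSE)
}

#' Burden analysis over all eligible genes of a cohort
#'
#' Applies [subset_burden()] to every gene selected by [eligible_genes()].
#' Genes whose significant-variant count exceeds `k_max` are reported with
#' `processed = FALSE` and `NA` p-values rather than silently truncated.
#'
#' @param results association results (`all` element of
#'   [run_association()]).
#' @param alpha variant significance threshold (default 0.05).
#' @param k_max subset-search size guard passed to [subset_burden()].
#' @return data.frame with one row per eligible gene: `gene`, `n_variants`,
#'   `meta_p`, `subset_case_meta_p`, `subset_control_meta_p`,
#'   `subset_meta_p`, `best_case_subset`, `best_control_subset` (comma
#'   separated), `processed`; sorted by `subset_meta_p`.
#' @export
run_burden <- function(results, alpha = 0.05, k_max = 12) {
  genes <- eligible_genes(results, alpha)
  rows <- lapply(names(genes), function(gn) {
    gv <- genes[[gn]]
    if (nrow(gv) > k_max)
      return(data.frame(gene = gn, n_variants = nrow(gv), meta_p = NA_real_,
                        subset_case_meta_p = NA_real_,
                        subset_control_meta_p = NA_real_,
                        subset_meta_p = NA_real_,
                        best_case_subset = "", best_control_subset = "",
                        processed = FALSE, stringsAsFactors = FALSE))
    b <- subset_burden(gv, k_max = k_max)
    data.frame(gene = gn, n_variants = nrow(gv), meta_p = b$meta_p,
               subset_case_meta_p = b$subset_case_meta_p,
               subset_control_meta_p = b$subset_control_meta_p,
               subset_meta_p = b$subset_meta_p,
               best_case_subset = paste(b$best_case_subset, collapse = ","),
               best_control_subset = paste(b$best_control_subset, collapse = ","),
               processed = TRUE, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    rows <- list(data.frame(gene = character(0), n_variants = integer(0),
                            meta_p = numeric(0),
                            subset_case_meta_p = numeric(0),
                            subset_control_meta_p = numeric(0),
                            subset_meta_p = numeric(0),
                            best_case_subset = character(0),
                            best_control_subset = character(0),
                            processed = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$subset_meta_p, out$gene), , drop = FALSE]
}
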