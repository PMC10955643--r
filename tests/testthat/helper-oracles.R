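# Independent oracles used across the suite. These are written against the
# definitions, not against the package internals: the exact test oracle
# enumerates 2x2 tables with log-binomial coefficients, the burden oracle
# literally enumerates subsets with combn() and re-tests pooled tables, and
# the AUC oracle is the normalized Mann-Whitney pair count.

# brute-force two-sided exact allelic p for one table (point-probability
# rule, same 1 + 1e-7 tie tolerance as the implementation under test)
oracle_fisher_p <- function(case_alt, case_ref, ctrl_alt, ctrl_ref) {
  m <- case_alt + case_ref
  n <- ctrl_alt + ctrl_ref
  k <- case_alt + ctrl_alt
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  obs <- probs[xs == case_alt]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# vectorized oracle for one margin class (m case alleles, n control
# alleles, k alt alleles): exact p for every table in the support
oracle_fisher_class <- function(m, n, k) {
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  d <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  ord <- order(d)
  cs <- cumsum(d[ord])
  pmin(1, cs[findInterval(d * (1 + 1e-7), d[ord])])
}

# enumerate-and-retest burden oracle over a data.frame of association rows
oracle_burden <- function(df) {
  scan <- function(idx) {
    if (!length(idx)) return(1)
    # enumerate subset POSITIONS then map to indices (combn(x, m) with a
    # scalar x would enumerate seq_len(x) instead of the single index)
    subs <- unlist(lapply(seq_along(idx),
                          function(s) utils::combn(length(idx), s,
                                                   simplify = FALSE)),
                   recursive = FALSE)
    subs <- lapply(subs, function(pos) idx[pos])
    ps <- vapply(subs, function(s)
      oracle_fisher_p(sum(df$case_alt[s]), sum(df$case_ref[s]),
                      sum(df$ctrl_alt[s]), sum(df$ctrl_ref[s])), 0)
    min(1, min(ps) * length(subs))
  }
  pc <- scan(which(df$direction == "case"))
  pt <- scan(which(df$direction == "control"))
  list(meta_p = scan(seq_len(nrow(df))),
       subset_case_meta_p = pc,
       subset_control_meta_p = pt,
       subset_meta_p = stats::pchisq(-2 * (log(pc) + log(pt)), df = 4,
                                     lower.tail = FALSE))
}

# rank-based (Mann-Whitney) AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# one association-results row with the given counts; p and direction from
# the package's own test unless overridden
assoc_row <- function(variant_id, gene, case_alt, case_ref, ctrl_alt,
                      ctrl_ref, p = NULL, direction = NULL) {
  tst <- exact_allelic_test(allele_table(case_alt, case_ref, ctrl_alt,
                                         ctrl_ref))
  data.frame(variant_id = variant_id, gene = gene,
             case_alt = case_alt, case_ref = case_ref,
             ctrl_alt = ctrl_alt, ctrl_ref = ctrl_ref,
             af_case = tst$af_case, af_ctrl = tst$af_ctrl,
             p = if (is.null(p)) tst$p else p,
             direction = if (is.null(direction)) tst$direction else direction,
             stringsAsFactors = FALSE)
}

# tiny hand-built cohort: genotype codes given as a samples x variants
# matrix of 0/1/2/NA
toy_cohort <- function(geno, labels, genes = NULL) {
  nv <- ncol(geno)
  if (is.null(colnames(geno)))
    colnames(geno) <- paste("1", 1000 * seq_len(nv), "A", "G", sep = ":")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("S%02d", seq_len(nrow(geno)))
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nv))
  anno <- data.frame(variant_id = colnames(geno), chrom = "1",
                     pos = 1000 * seq_len(nv), ref = "A", alt = "G",
                     gene = genes, func_class = "nonsynonymous_snv",
                     var_type = "snv", DP = 50, FS = 0, SOR = 0,
                     stringsAsFactors = FALSE)
  anno$variant_id <- colnames(geno)
  cohort(geno, labels, anno)
}
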