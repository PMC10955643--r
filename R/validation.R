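#' Intersection-union combination of two cohort p-values
#'
#' The cross-cohort claim is "significant in both cohorts"; the
#' intersection-union test rejects only when every component rejects, and
#' its p-value is the maximum of the component p-values. Hence
#' `combined_p < alpha` exactly when both inputs are below `alpha`.
#'
#' @param p_disc,p_val per-cohort p-values in \[0, 1\] (vectorized).
#' @return element-wise `max(p_disc, p_val)`.
#' @export
iut_combine <- function(p_disc, p_val) {
  if (any(p_disc < 0 | p_disc > 1 | p_val < 0 | p_val > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pmax(p_disc, p_val)
}

#' Cross-cohort validation of individual variants
#'
#' A variant validates when it is significant (`p < alpha`) in BOTH
#' cohorts with the SAME enrichment direction. Variants significant in
#' both cohorts but with opposite directions are discarded from further
#' analyses and reported separately. Variant identity across cohorts is
#' the `chrom:pos:ref:alt` key carried in `variant_id`. The rule is
#' symmetric in the two cohorts (up to the naming of the p-value columns).
#'
#' @param disc,val association results (`all` element of
#'   [run_association()]) for the discovery and validation cohorts.
#' @param alpha per-cohort significance threshold (default 0.05).
#' @return list with `validated` — data.frame (`variant_id`, `gene`,
#'   `af_case_disc`, `af_ctrl_disc`, `af_case_val`, `af_ctrl_val`,
#'   `p_disc`, `p_val`, `direction`, `combined_p`), sorted by
#'   `combined_p` — and `discordant`, the same columns for
#'   direction-incoherent variants (with both directions shown).
#' @export
validate_variants <- function(disc, val, alpha = 0.05) {
  for (d in list(disc, val))
    if (anyDuplicated(d$variant_id))
      stop("duplicated variant identifier within one cohort's results; ",
           "conflicting alleles under one chrom:pos:ref:alt key")
  m <- merge(disc, val, by = "variant_id", suffixes = c("_disc", "_val"))
  sig_both <- m$p_disc < alpha & m$p_val < alpha
  coherent <- m$direction_disc == m$direction_val &
    m$direction_disc %in% c("case", "control")
  shape <- function(rows, coherent_dir) {
    out <- data.frame(
      variant_id = rows$variant_id,
      gene = rows$gene_disc,
      af_case_disc = rows$af_case_disc, af_ctrl_disc = rows$af_ctrl_disc,
      af_case_val = rows$af_case_val, af_ctrl_val = rows$af_ctrl_val,
      p_disc = rows$p_disc, p_val = rows$p_val,
      direction = if (coherent_dir) rows$direction_disc
                  else paste(rows$direction_disc, rows$direction_val,
                             sep = "/"),
      combined_p = iut_combine(rows$p_disc, rows$p_val),
      stringsAsFactors = FALSE)
    out <- out[order(out$combined_p, out$variant_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(validated = shape(m[sig_both & coherent, , drop = FALSE], TRUE),
       discordant = shape(m[sig_both & !coherent, , drop = FALSE], FALSE))
}

#' Cross-cohort validation of variant-rich genes
#'
#' A gene validates when it harbours significant and coherent variants —
#' the same or different physical variants — in both cohorts:
#' \itemize{
#'   \item each cohort contributes at least one significant variant in the
#'     gene;
#'   \item all significant variants of the gene, pooled over both cohorts,
#'     share one enrichment direction (genes mixing case- and
#'     control-enriched significant variants are dropped);
#'   \item per cohort, the evidence passes `alpha`: where the cohort has
#'     two or more significant variants in the gene, the matching
#'     directional subset meta-p from the burden stage; where it has
#'     exactly one, that variant's individual allelic p (already below
#'     `alpha` by construction).
#' }
#'
#' @param disc_assoc,val_assoc association results (`all` element) per
#'   cohort.
#' @param disc_burden,val_burden burden tables from [run_burden()] per
#'   cohort; required for every gene with >= 2 significant variants in
#'   that cohort.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per validated gene: `gene`,
#'   `direction`, `n_var_disc`, `n_var_val`, `p_disc`, `p_val`, sorted by
#'   `iut_combine(p_disc, p_val)` then gene.
#' @export
validate_genes <- function(disc_assoc, val_assoc, disc_burden, val_burden,
                           alpha = 0.05) {
  sig_d <- disc_assoc[disc_assoc$p < alpha, , drop = FALSE]
  sig_v <- val_assoc[val_assoc$p < alpha, , drop = FALSE]
  genes <- intersect(unique(sig_d$gene), unique(sig_v$gene))
  evidence <- function(sig, burden, gene, dir) {
    rows <- sig[sig$gene == gene, , drop = FALSE]
    if (nrow(rows) == 1L) return(rows$p)
    b <- burden[burden$gene == gene, , drop = FALSE]
    if (nrow(b) != 1L)
      stop("pipeline-order error: no burden record for multi-variant gene ",
           gene)
    if (!isTRUE(b$processed)) return(NA_real_)  # k_max guard: unprocessed
    if (dir == "case") b$subset_case_meta_p else b$subset_control_meta_p
  }
  rows <- lapply(genes, function(gn) {
    dirs <- unique(c(sig_d$direction[sig_d$gene == gn],
                     sig_v$direction[sig_v$gene == gn]))
    if (length(dirs) != 1L || !dirs %in% c("case", "control")) return(NULL)
    p_d <- evidence(sig_d, disc_burden, gn, dirs)
    p_v <- evidence(sig_v, val_burden, gn, dirs)
    if (is.na(p_d) || is.na(p_v) || p_d >= alpha || p_v >= alpha)
      return(NULL)
    data.frame(gene = gn, direction = dirs,
               n_var_disc = sum(sig_d$gene == gn),
               n_var_val = sum(sig_v$gene == gn),
               p_disc = p_d, p_val = p_v, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(gene = character(0), direction = character(0),
                      n_var_disc = integer(0), n_var_val = integer(0),
                      p_disc = numeric(0), p_val = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(iut_combine(out$p_disc, out$p_val), out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of validated genes in gene sets
#'
#' For each collection set, the one-sided hypergeometric tail probability
#' of drawing at least the observed overlap when `|validated|` genes are
#' sampled without replacement from the universe containing
#' `|set within universe|` set members. The universe should be the
#' assayable gene space (by default in the pipeline: all genes carrying at
#' least one tested variant). BH-adjusted q-values are attached.
#'
#' @param validated_genes character vector of validated gene symbols
#'   (must all belong to `universe`).
#' @param universe character vector of background gene symbols.
#' @param collections named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame sorted by p: `collection`, `set_size` (within the
#'   universe), `overlap`, `p`, `q`, `genes` (overlap members, comma
#'   separated).
#' @export
hypergeom_enrichment <- function(validated_genes, universe, collections) {
  validated_genes <- unique(validated_genes)
  universe <- unique(universe)
  if (!length(collections)) stop("`collections` must be non-empty")
  outside <- setdiff(validated_genes, universe)
  if (length(outside))
    stop("validated gene(s) outside the universe: ",
         paste(outside, collapse = ", "))
  N <- length(universe)
  n_draw <- length(validated_genes)
  rows <- lapply(names(collections), function(nm) {
    set_u <- intersect(collections[[nm]], universe)
    hit <- intersect(validated_genes, set_u)
    k <- length(hit)
    p <- stats::phyper(k - 1, length(set_u), N - length(set_u), n_draw,
                       lower.tail = FALSE)
    data.frame(collection = nm, set_size = length(set_u), overlap = k,
               p = p, genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$collection),
             c("collection", "set_size", "overlap", "p", "q", "genes")]
  rownames(out) <- NULL
  out
}
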