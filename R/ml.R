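#' Allelic-dose encoding of genotypes
#'
#' Encodes each genotype cell as an ordinal allelic dose: `0` no-call
#' (no information for that variant in that individual), `1` variant
#' absent (homozygous reference), `2` heterozygous, `3` homozygous
#' alternate. Extreme cases are the positive class (`y = 1`).
#'
#' @param x a [cohort()].
#' @param features character vector of variant identifiers to encode
#'   (must all be on the cohort panel); column order follows `features`.
#' @return a `dose_matrix`: list with `x` (integer matrix samples x
#'   features), `y` (0/1 labels, case = 1), `features`, `mode = "variant"`.
#' @export
encode_allelic_dose <- function(x, features) {
  stopifnot(inherits(x, "cohort"))
  miss <- setdiff(features, colnames(x$genotypes))
  if (length(miss))
    stop("unknown feature(s): ", paste(miss, collapse = ", "))
  g <- x$genotypes[, features, drop = FALSE]
  d <- g + 1L
  d[is.na(d)] <- 0L
  structure(list(x = d, y = as.integer(x$labels == "case"),
                 features = features, mode = "variant"),
            class = "dose_matrix")
}

#' Per-gene variant-count encoding
#'
#' For each sample and gene, the number of the gene's listed variants the
#' sample carries (heterozygous or homozygous alternate); no-calls
#' contribute 0.
#'
#' @param x a [cohort()].
#' @param genes character vector of gene symbols to encode.
#' @param variant_map named list mapping each gene to its variant
#'   identifiers (e.g. validated variants per gene); must cover `genes`
#'   with non-empty lists.
#' @return a `dose_matrix` with `mode = "gene"` and integer counts.
#' @export
encode_gene_counts <- function(x, genes, variant_map) {
  stopifnot(inherits(x, "cohort"))
  counts <- vapply(genes, function(gn) {
    vs <- variant_map[[gn]]
    if (is.null(vs) || !length(vs))
      stop("configuration error: empty variant list for gene ", gn)
    miss <- setdiff(vs, colnames(x$genotypes))
    if (length(miss))
      stop("unknown feature(s): ", paste(miss, collapse = ", "))
    g <- x$genotypes[, vs, drop = FALSE]
    as.integer(rowSums(g >= 1L, na.rm = TRUE))
  }, integer(n_samples(x)))
  counts <- matrix(counts, nrow = n_samples(x),
                   dimnames = list(x$sample_ids, genes))
  structure(list(x = counts, y = as.integer(x$labels == "case"),
                 features = genes, mode = "gene"),
            class = "dose_matrix")
}

#' Classifier design: family, hyperparameter grid, CV folds
#'
#' The four supported families: `"LR"` — ridge-penalized logistic
#' regression (glmnet) with a grid over the regularization strength
#' `lambda`; `"SVC"` — squared-hinge kernel support vector classifier,
#' grid over kernel (linear / RBF) and `cost`; `"RF"` — bagged random
#' forest, grid over tree depth; `"GbRF"` — gradient-boosted trees, grid
#' over ensemble size and tree depth. The default grids are deliberately
#' modest stand-ins (the design keeps CV deterministic and desk-scale);
#' pass `grid` to override. Dose codes are standardized for LR/SVC using
#' training-fold statistics only; tree models see the raw codes.
#'
#' @param model_family one of `"LR"`, `"SVC"`, `"RF"`, `"GbRF"`.
#' @param grid data.frame of hyperparameter combinations (one row each);
#'   `NULL` for the family default. Row order is the deterministic
#'   tie-break order of the grid search.
#' @param k_folds number of stratified CV folds (default 5).
#' @param seed integer seed controlling fold assignment and any model
#'   randomness.
#' @return an `ml_design` list.
#' @export
ml_design <- function(model_family = c("LR", "SVC", "RF", "GbRF"),
                      grid = NULL, k_folds = 5, seed = 1) {
  model_family <- match.arg(model_family)
  if (k_folds < 2) stop("`k_folds` must be >= 2")
  if (is.null(grid)) grid <- .default_grid(model_family)
  if (!nrow(grid)) stop("hyperparameter grid must be non-empty")
  structure(list(model_family = model_family, grid = grid,
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 selection_metric = "accuracy"),
            class = "ml_design")
}

.default_grid <- function(family) {
  switch(family,
    LR = data.frame(lambda = c(0.001, 0.01, 0.1, 1)),
    SVC = expand.grid(kernel = c("linear", "rbf"), cost = c(0.1, 1, 10),
                      stringsAsFactors = FALSE),
    RF = expand.grid(n_trees = 200L, max_depth = c(4L, 8L)),
    GbRF = expand.grid(n_trees = c(50L, 100L), learning_rate = 0.1,
                       max_depth = c(2L, 3L)))
}

# standardization statistics from training data (sd 0 -> 1 to keep
# constant columns harmless)
.scale_stats <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(center = mu, scale = sd)
}
.scale_apply <- function(x, st)
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")

# fit one family at one grid point; x arrives already standardized for
# LR/SVC. Returns an `xassoc_model`.
.fit_family <- function(family, x, y, params, seed) {
  set.seed(seed)
  fit <- switch(family,
    LR = {
      xg <- if (ncol(x) == 1L) cbind(x, .pad = 0) else x
      glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                     lambda = params$lambda, standardize = FALSE)
    },
    SVC = .svc_fit(x, y, cost = params$cost,
                   kernel = as.character(params$kernel)),
    RF = .rf_fit(x, y, n_trees = params$n_trees,
                 max_depth = params$max_depth),
    GbRF = .gbm_fit(x, y, n_trees = params$n_trees,
                    learning_rate = params$learning_rate,
                    max_depth = params$max_depth))
  structure(list(family = family, params = params, fit = fit,
                 features = colnames(x)),
            class = "xassoc_model")
}

# classifier score: P(case) for the soft classifiers, the decision value
# for the SVC (usable like a probability for ROC purposes)
.predict_score <- function(model, x) {
  switch(model$family,
    LR = {
      xg <- if (ncol(x) == 1L) cbind(x, .pad = 0) else x
      drop(stats::predict(model$fit, newx = xg, type = "response"))
    },
    SVC = .svc_decision(model$fit, x),
    RF = .rf_predict(model$fit, x),
    GbRF = .gbm_predict(model$fit, x))
}

.predict_class <- function(model, x) {
  s <- .predict_score(model, x)
  cut <- if (model$family == "SVC") 0 else 0.5
  as.integer(s > cut)
}

# deterministic stratified fold assignment
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' K-fold cross-validated grid search on the discovery cohort
#'
#' For every hyperparameter combination, fits on K-1 stratified folds and
#' scores accuracy on the left-out fold; the combination with the highest
#' mean left-out accuracy wins (ties: first row of the grid). The winner
#' is then retrained on the entire discovery set. Standardization for
#' LR/SVC is fitted on the training folds only and applied to the held-out
#' fold, so no information leaks across the split. Deterministic given the
#' design seed.
#'
#' @param design an [ml_design()].
#' @param discovery a `dose_matrix` from [encode_allelic_dose()] or
#'   [encode_gene_counts()] for the discovery cohort.
#' @return list: `model` (retrained winner, carrying its scaling stats),
#'   `best_params` (winning grid row), `cv_accuracy` (its mean left-out
#'   accuracy), `cv_auc` (AUC of the winner's pooled out-of-fold scores),
#'   `cv_table` (per-grid-point mean accuracies).
#' @export
cv_grid_search <- function(design, discovery) {
  stopifnot(inherits(design, "ml_design"), inherits(discovery, "dose_matrix"))
  x <- discovery$x; y <- discovery$y
  storage.mode(x) <- "double"
  if (length(unique(y)) < 2) stop("discovery labels contain a single class")
  k <- design$k_folds
  fold <- .stratified_folds(y, k, design$seed)
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2))
    stop("stratification error: a fold is missing a class")
  scale_model <- design$model_family %in% c("LR", "SVC")
  grid <- design$grid
  acc <- matrix(NA_real_, nrow(grid), k)
  oof <- matrix(NA_real_, length(y), nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- grid[gi, , drop = FALSE]
    for (fi in seq_len(k)) {
      tr <- fold != fi
      xtr <- x[tr, , drop = FALSE]; xte <- x[!tr, , drop = FALSE]
      if (scale_model) {
        st <- .scale_stats(xtr)
        xtr <- .scale_apply(xtr, st); xte <- .scale_apply(xte, st)
      }
      m <- .fit_family(design$model_family, xtr, y[tr], params,
                       seed = design$seed * 1000L + fi)
      acc[gi, fi] <- mean(.predict_class(m, xte) == y[!tr])
      oof[!tr, gi] <- .predict_score(m, xte)
    }
  }
  mean_acc <- rowMeans(acc)
  best <- which.max(mean_acc)   # first maximum = deterministic tie-break
  st <- if (scale_model) .scale_stats(x) else NULL
  xfull <- if (scale_model) .scale_apply(x, st) else x
  model <- .fit_family(design$model_family, xfull, y,
                       grid[best, , drop = FALSE],
                       seed = design$seed * 1000L)
  model$scaling <- st
  cv_table <- cbind(grid, cv_accuracy = mean_acc)
  list(model = model, best_params = grid[best, , drop = FALSE],
       cv_accuracy = mean_acc[best],
       cv_auc = .auc(oof[, best], y),
       cv_table = cv_table)
}

#' ROC curve points and area under the curve
#'
#' Scores are swept from high to low; tied scores collapse to one
#' threshold so ties receive half credit, making the trapezoidal area
#' identical to the normalized Mann-Whitney statistic. A constant scorer
#' yields the chance diagonal (AUC 0.5).
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels 0/1 labels (1 = case).
#' @return data.frame with columns `fpr`, `tpr` (including the (0,0)
#'   anchor), with the AUC as attribute `"auc"`.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  n_pos <- sum(l == 1); n_neg <- sum(l == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to build a ROC curve")
  block_end <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(l == 1)[block_end] / n_pos)
  fpr <- c(0, cumsum(l == 0)[block_end] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

.auc <- function(scores, labels) attr(roc_points(scores, labels), "auc")

#' Evaluate a fitted classifier on the held-out validation cohort
#'
#' Computes accuracy, precision (positive predictive value on the case
#' class), recall (sensitivity), F1 and ROC-AUC; for the soft classifiers
#' the ROC uses class probabilities, for the SVC its decision function.
#' The validation features must match the training features exactly and
#' in order.
#'
#' @param model a fitted model from [cv_grid_search()].
#' @param validation a `dose_matrix` for the validation cohort.
#' @return list: `accuracy`, `precision`, `recall`, `f1`, `auc`, `roc`
#'   (data.frame of curve points), `scores` (per-sample classifier scores),
#'   `confusion` (2x2 table).
#' @export
evaluate_on_validation <- function(model, validation) {
  stopifnot(inherits(validation, "dose_matrix"))
  feats <- colnames(validation$x)
  if (!identical(feats, model$features)) {
    d1 <- setdiff(model$features, feats); d2 <- setdiff(feats, model$features)
    if (length(d1) || length(d2))
      stop("feature mismatch between training and validation matrices; ",
           "missing: [", paste(d1, collapse = ", "), "] extra: [",
           paste(d2, collapse = ", "), "]")
    stop("validation features must be ordered as in training")
  }
  x <- validation$x; storage.mode(x) <- "double"
  if (!is.null(model$scaling)) x <- .scale_apply(x, model$scaling)
  y <- validation$y
  score <- .predict_score(model, x)
  pred <- .predict_class(model, x)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  roc <- roc_points(score, y)
  list(accuracy = (tp + tn) / length(y), precision = precision,
       recall = recall, f1 = f1, auc = attr(roc, "auc"), roc = roc,
       scores = score,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(pred = c("case", "control"),
                                          truth = c("case", "control"))))
}

#' Train, tune and evaluate the classifier families end to end
#'
#' For each requested family: stratified K-fold CV grid search on the
#' discovery cohort, retrain on the full discovery set, evaluate on the
#' validation cohort. The primary feature set is the allelic-dose encoding
#' of the supplied variants (`mode = "variant"`); `mode = "gene"` encodes
#' per-gene variant counts instead.
#'
#' @param discovery,validation [cohort()] objects sharing the variant
#'   panel.
#' @param features variant identifiers (variant mode) or a named list of
#'   gene -> variant identifiers (gene mode).
#' @param families subset of `c("LR", "SVC", "RF", "GbRF")`.
#' @param mode `"variant"` (allelic dose) or `"gene"` (variant counts).
#' @param k_folds,seed CV design parameters (see [ml_design()]).
#' @return an `ml_report`: list with per-family results (`best_params`,
#'   `cv_accuracy`, `cv_auc`, validation metrics, ROC points) and a
#'   `summary` data.frame.
#' @export
run_ml <- function(discovery, validation, features,
                   families = c("LR", "SVC", "RF", "GbRF"),
                   mode = c("variant", "gene"), k_folds = 5, seed = 1) {
  mode <- match.arg(mode)
  enc <- function(coh) {
    if (mode == "variant") encode_allelic_dose(coh, features)
    else encode_gene_counts(coh, names(features), features)
  }
  dm_disc <- enc(discovery); dm_val <- enc(validation)
  fits <- lapply(families, function(fam) {
    design <- ml_design(fam, k_folds = k_folds, seed = seed)
    cv <- cv_grid_search(design, dm_disc)
    ev <- evaluate_on_validation(cv$model, dm_val)
    list(family = fam, best_params = cv$best_params,
         cv_accuracy = cv$cv_accuracy, cv_auc = cv$cv_auc,
         accuracy = ev$accuracy, precision = ev$precision,
         recall = ev$recall, f1 = ev$f1, auc = ev$auc, roc = ev$roc,
         confusion = ev$confusion)
  })
  names(fits) <- families
  summary <- do.call(rbind, lapply(fits, function(f)
    data.frame(family = f$family, cv_accuracy = f$cv_accuracy,
               cv_auc = f$cv_auc, accuracy = f$accuracy,
               precision = f$precision, recall = f$recall, f1 = f$f1,
               auc = f$auc, stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(models = fits, summary = summary, mode = mode,
                 n_features = length(features)),
            class = "ml_report")
}

#' @export
print.ml_report <- function(x, ...) {
  cat("<ml_report> ", x$n_features, " features (", x$mode, " mode)\n",
      sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
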