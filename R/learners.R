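# Internal small-data learners for the classifier stage.
#
# The model families the pipeline exposes (logistic regression, support
# vector classifier, random forest, gradient-boosted trees) are standard,
# but no tree or SVM package is available in the supported dependency set,
# so the tree ensembles and the SVC are implemented here directly. They
# are deliberately plain implementations tuned for the desk-scale inputs
# of this pipeline (tens of features, ~100-150 samples), with determinism
# given the RNG state as the overriding design goal.

# Least-squares regression tree (CART-style): binary splits on numeric
# features maximizing the sum-of-squares reduction. Used both for the
# forest (on 0/1 labels, leaves = class fractions) and for boosting (on
# gradient residuals).
.tree_fit <- function(x, y, max_depth = 6L, min_node = 2L, mtry = ncol(x)) {
  grow <- function(idx, depth) {
    yy <- y[idx]
    m <- mean(yy)
    if (depth >= max_depth || length(idx) < 2L * min_node ||
        max(yy) - min(yy) < 1e-12)
      return(list(leaf = TRUE, value = m))
    feats <- if (mtry < ncol(x)) sample.int(ncol(x), mtry)
             else seq_len(ncol(x))
    n_here <- length(idx)
    parent_score <- sum(yy)^2 / n_here
    best <- NULL
    best_score <- parent_score + 1e-12
    for (j in feats) {
      xv <- x[idx, j]
      o <- order(xv)
      xs <- xv[o]
      cl <- cumsum(yy[o])
      tot <- cl[n_here]
      nl <- seq_len(n_here - 1L)
      ok <- which(xs[-n_here] < xs[-1L])
      ok <- ok[ok >= min_node & (n_here - ok) >= min_node]
      if (!length(ok)) next
      score <- cl[ok]^2 / nl[ok] + (tot - cl[ok])^2 / (n_here - nl[ok])
      b <- which.max(score)
      if (score[b] > best_score) {
        best_score <- score[b]
        best <- list(feature = j, threshold = (xs[ok[b]] + xs[ok[b] + 1L]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, value = m))
    go_left <- x[idx, best$feature] <= best$threshold
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }
  grow(seq_len(nrow(x)), 0L)
}

.tree_predict <- function(tree, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$leaf) { out[idx] <<- node$value; return(invisible()) }
    gl <- x[idx, node$feature] <= node$threshold
    rec(node$left, idx[gl])
    rec(node$right, idx[!gl])
  }
  rec(tree, seq_len(nrow(x)))
  out
}

# Random forest: bootstrap-aggregated regression trees on the 0/1 labels
# with per-node feature subsampling; the ensemble score is the mean leaf
# class fraction, read as P(case).
.rf_fit <- function(x, y, n_trees = 200L, max_depth = 8L, min_node = 2L,
                    mtry = max(1L, floor(sqrt(ncol(x))))) {
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(nrow(x), replace = TRUE)
    trees[[t]] <- .tree_fit(x[idx, , drop = FALSE], y[idx],
                            max_depth = max_depth, min_node = min_node,
                            mtry = mtry)
  }
  list(trees = trees)
}

.rf_predict <- function(fit, x) {
  preds <- vapply(fit$trees, .tree_predict, numeric(nrow(x)), x = x)
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

# Gradient boosting for binary log-loss: shallow regression trees fitted
# to the residual y - p, with shrinkage and optional row subsampling.
.gbm_fit <- function(x, y, n_trees = 100L, learning_rate = 0.1,
                     max_depth = 2L, min_node = 2L, subsample = 0.8) {
  n <- nrow(x)
  pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(pbar / (1 - pbar))
  f <- rep(f0, n)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    r <- y - stats::plogis(f)
    idx <- if (subsample < 1) sample.int(n, max(2L, floor(subsample * n)))
           else seq_len(n)
    tr <- .tree_fit(x[idx, , drop = FALSE], r[idx], max_depth = max_depth,
                    min_node = min_node, mtry = ncol(x))
    f <- f + learning_rate * .tree_predict(tr, x)
    trees[[t]] <- tr
  }
  list(f0 = f0, learning_rate = learning_rate, trees = trees)
}

.gbm_predict <- function(fit, x) {
  f <- rep(fit$f0, nrow(x))
  for (tr in fit$trees) f <- f + fit$learning_rate * .tree_predict(tr, x)
  stats::plogis(f)
}

.svc_kernel <- function(x1, x2, kernel, gamma) {
  if (kernel == "linear") return(x1 %*% t(x2))
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
  exp(-gamma * pmax(d2, 0))
}

# Kernel support vector classifier, squared-hinge primal in the kernel
# expansion f(x) = K(x, X) alpha + b (representer form), solved with BFGS.
# Deterministic: no random initialization. The decision value f plays the
# role of a score for ROC purposes.
.svc_fit <- function(x, y, cost = 1, kernel = c("linear", "rbf"),
                     gamma = 1 / ncol(x)) {
  kernel <- match.arg(kernel)
  ys <- ifelse(y == 1, 1, -1)
  n <- nrow(x)
  K <- .svc_kernel(x, x, kernel, gamma)
  obj <- function(par) {
    a <- par[seq_len(n)]; b <- par[n + 1L]
    f <- drop(K %*% a) + b
    h <- pmax(0, 1 - ys * f)
    0.5 * sum(a * drop(K %*% a)) + cost * sum(h^2)
  }
  grad <- function(par) {
    a <- par[seq_len(n)]; b <- par[n + 1L]
    Ka <- drop(K %*% a)
    h <- pmax(0, 1 - ys * (Ka + b))
    c(Ka - 2 * cost * drop(K %*% (ys * h)), -2 * cost * sum(ys * h))
  }
  opt <- stats::optim(rep(0, n + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(x = x, alpha = opt$par[seq_len(n)], b = opt$par[n + 1L],
       kernel = kernel, gamma = gamma)
}

.svc_decision <- function(fit, x) {
  drop(.svc_kernel(x, fit$x, fit$kernel, fit$gamma) %*% fit$alpha) + fit$b
}
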