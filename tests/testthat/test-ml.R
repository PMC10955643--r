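test_that("allelic-dose encoding maps the four genotype states to 0-3", {
  g <- matrix(c(NA, 0L, 1L, 2L,
                0L, 0L, 0L, 0L), 4, 2)
  coh <- toy_cohort(g, c("case", "case", "control", "control"))
  dm <- encode_allelic_dose(coh, colnames(coh$genotypes))
  expect_identical(dm$x[, 1], c(S01 = 0L, S02 = 1L, S03 = 2L, S04 = 3L))
  expect_identical(dm$x[, 2], c(S01 = 1L, S02 = 1L, S03 = 1L, S04 = 1L))
  expect_identical(dm$y, c(1L, 1L, 0L, 0L))
  expect_error(encode_allelic_dose(coh, "missing"), "unknown feature")

  # cellwise audit against an independent recoding pass on a larger cohort
  cfg <- simulation_config(n_variants = 40, n_genes = 25, nocall_rate = 0.1,
                           seed = 23)
  val <- simulate_cohort_pair(cfg)$validation
  feats <- colnames(val$genotypes)[1:16]
  dm2 <- encode_allelic_dose(val, feats)
  expect_identical(dim(dm2$x), c(149L, 16L))
  recode <- vapply(seq_along(feats), function(j)
    vapply(val$genotypes[, feats[j]], function(gt)
      if (is.na(gt)) 0L else gt + 1L, 0L),
    integer(149))
  expect_identical(unname(dm2$x), unname(recode))
})

test_that("gene-count encoding counts carried variants, no-calls as zero", {
  # S1 het at 2 of the gene's 3 variants; S2 all no-call; S3 homalt at one
  g <- matrix(c(1L, 1L, 0L,
                NA, NA, NA,
                0L, 0L, 2L), 3, 3, byrow = TRUE)
  coh <- toy_cohort(g, c("case", "control", "control"),
                    genes = c("A", "A", "A"))
  vm <- list(A = colnames(coh$genotypes))
  dm <- encode_gene_counts(coh, "A", vm)
  expect_identical(unname(dm$x[, "A"]), c(2L, 0L, 1L))
  expect_error(encode_gene_counts(coh, "B", list(B = character(0))),
               "configuration error")
})

test_that("ROC and AUC behave at the extremes and match the rank oracle", {
  y <- c(1, 1, 1, 0, 0)
  perfect <- roc_points(c(0.9, 0.8, 0.7, 0.2, 0.1), y)
  expect_identical(attr(perfect, "auc"), 1)
  constant <- roc_points(rep(0.5, 5), y)
  expect_identical(attr(constant, "auc"), 0.5)
  set.seed(12)
  for (i in 1:20) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)  # heavy ties
    lab <- rbinom(30, 1, 0.5)
    if (length(unique(lab)) < 2) next
    expect_equal(xassoc:::.auc(s, lab), oracle_auc(s, lab), tolerance = 1e-10)
    # invariance under a strictly monotone transform of scores
    expect_equal(xassoc:::.auc(exp(3 * s) - 1, lab), xassoc:::.auc(s, lab),
                 tolerance = 1e-12)
  }
})

test_that("CV grid search selects by left-out accuracy and is deterministic", {
  # perfectly separable: one feature fully determines the label
  set.seed(5)
  n <- 60
  y <- rep(c(1L, 0L), each = n / 2)
  x <- cbind(feat = ifelse(y == 1, 3L, 1L),
             noise = sample(0:3, n, replace = TRUE))
  rownames(x) <- sprintf("S%02d", seq_len(n))
  dm <- structure(list(x = x, y = y, features = colnames(x),
                       mode = "variant"), class = "dose_matrix")
  cv <- cv_grid_search(ml_design("LR", k_folds = 5, seed = 3), dm)
  expect_identical(cv$cv_accuracy, 1)
  expect_identical(cv$cv_auc, 1)

  # singleton grid: that point is chosen, accuracy is the fold mean
  single <- ml_design("GbRF", grid = data.frame(n_trees = 20L,
                                                learning_rate = 0.1,
                                                max_depth = 2L),
                      k_folds = 4, seed = 9)
  cv1 <- cv_grid_search(single, dm)
  expect_identical(cv1$best_params$n_trees, 20L)
  cv2 <- cv_grid_search(single, dm)
  expect_identical(cv1$cv_accuracy, cv2$cv_accuracy)
  expect_identical(cv1$cv_auc, cv2$cv_auc)
})

test_that("validation metrics are internally consistent for every family", {
  cfg <- simulation_config(n_variants = 200, n_genes = 30, planted_or = 4,
                           seed = 41)
  pair <- simulate_cohort_pair(cfg)
  vv <- validate_variants(run_association(pair$discovery)$all,
                          run_association(pair$validation)$all)
  expect_gt(nrow(vv$validated), 4)
  rep <- run_ml(pair$discovery, pair$validation, vv$validated$variant_id,
                k_folds = 5, seed = 2)
  for (fam in names(rep$models)) {
    m <- rep$models[[fam]]
    metrics <- unlist(m[c("cv_accuracy", "cv_auc", "accuracy", "precision",
                          "recall", "f1", "auc")])
    expect_true(all(metrics >= 0 & metrics <= 1))
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-12)
    # planted signal of this strength is learnable by every family
    expect_gt(m$auc, 0.8)
  }
  # determinism end to end
  rep2 <- run_ml(pair$discovery, pair$validation, vv$validated$variant_id,
                 k_folds = 5, seed = 2)
  expect_identical(rep$summary, rep2$summary)

  # feature mismatch is a contract error naming the differences
  dm_val <- encode_allelic_dose(pair$validation,
                                vv$validated$variant_id[-1])
  model <- cv_grid_search(ml_design("LR", seed = 2),
                          encode_allelic_dose(pair$discovery,
                                              vv$validated$variant_id))$model
  expect_error(evaluate_on_validation(model, dm_val), "feature mismatch")
})

test_that("perfect and uninformative classifiers hit the metric boundaries", {
  # a model whose score reproduces the labels exactly
  n <- 40
  y <- rep(c(1L, 0L), n / 2)
  x <- cbind(f = as.numeric(y))
  rownames(x) <- sprintf("S%02d", seq_len(n))
  dm <- structure(list(x = x, y = y, features = "f", mode = "variant"),
                  class = "dose_matrix")
  cv <- cv_grid_search(ml_design("RF", grid = data.frame(n_trees = 30L,
                                                         max_depth = 3L),
                                 k_folds = 4, seed = 1), dm)
  ev <- evaluate_on_validation(cv$model, dm)
  expect_identical(ev$accuracy, 1)
  expect_identical(ev$precision, 1)
  expect_identical(ev$recall, 1)
  expect_identical(ev$f1, 1)
  expect_identical(ev$auc, 1)
})

test_that("label-permuted data gives chance-level CV accuracy", {
  cfg <- simulation_config(n_case_disc = 50, n_ctrl_disc = 50,
                           n_case_val = 10, n_ctrl_val = 10,
                           n_variants = 30, n_genes = 10,
                           n_planted_case = 0, n_planted_ctrl = 0,
                           n_variant_rich_genes = 0, seed = 77)
  disc <- simulate_cohort_pair(cfg)$discovery
  dm <- encode_allelic_dose(disc, colnames(disc$genotypes))
  set.seed(101)
  dm$y <- sample(dm$y)
  cv <- cv_grid_search(ml_design("LR", k_folds = 5, seed = 6), dm)
  se <- sqrt(0.25 / 100)
  expect_lt(abs(cv$cv_accuracy - 0.5), 3.5 * se)
})
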