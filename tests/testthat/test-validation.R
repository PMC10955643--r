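test_that("intersection-union combination is the component maximum", {
  expect_identical(iut_combine(0.01, 0.04), 0.04)
  expect_identical(iut_combine(0.3, 0.3), 0.3)
  # rejects iff both components reject, over a random grid
  set.seed(8)
  p1 <- runif(10000); p2 <- runif(10000)
  for (alpha in c(0.01, 0.05, 0.1))
    expect_identical(iut_combine(p1, p2) < alpha, p1 < alpha & p2 < alpha)
  expect_error(iut_combine(-0.1, 0.5), "0, 1")
})

test_that("variant validation keeps coherent significant variants only", {
  disc <- rbind(assoc_row("v1", "A", 30, 70, 10, 90),    # case-enriched, sig
                assoc_row("v2", "B", 10, 90, 30, 70),    # ctrl-enriched, sig
                assoc_row("v3", "C", 30, 70, 10, 90),    # sig, will flip in val
                assoc_row("v4", "D", 16, 84, 15, 85))    # not sig
  val <- rbind(assoc_row("v1", "A", 28, 72, 9, 91),
               assoc_row("v2", "B", 12, 88, 33, 67),
               assoc_row("v3", "C", 10, 90, 30, 70),     # discordant direction
               assoc_row("v4", "D", 30, 70, 10, 90))     # sig here only
  out <- validate_variants(disc, val, alpha = 0.05)
  expect_setequal(out$validated$variant_id, c("v1", "v2"))
  expect_identical(out$discordant$variant_id, "v3")
  v1 <- out$validated[out$validated$variant_id == "v1", ]
  expect_equal(v1$combined_p, max(v1$p_disc, v1$p_val), tolerance = 1e-15)
  expect_identical(v1$direction, "case")
  # sorted by combined p
  expect_true(!is.unsorted(out$validated$combined_p))

  # symmetric in which cohort is called discovery
  swapped <- validate_variants(val, disc, alpha = 0.05)
  expect_setequal(swapped$validated$variant_id, out$validated$variant_id)
  expect_equal(sort(swapped$validated$combined_p),
               sort(out$validated$combined_p), tolerance = 1e-15)

  # raising alpha never shrinks the validated set
  sets <- lapply(c(0.01, 0.05, 0.1), function(a)
    validate_variants(disc, val, a)$validated$variant_id)
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))

  dup <- rbind(disc, disc[1, ])
  expect_error(validate_variants(dup, val), "duplicated")
})

test_that("gene validation implements the coherence and evidence rules", {
  # 4 case-enriched significant variants per cohort with strong directional
  # burden evidence: validates in the case direction
  mk <- function(ids, gene, ca, ta) do.call(rbind, lapply(seq_along(ids),
    function(i) assoc_row(ids[i], gene, ca[i], 100 - ca[i], ta[i], 100 - ta[i])))
  disc <- mk(sprintf("h%d", 1:4), "HLAA", c(30, 28, 26, 31), c(10, 9, 11, 8))
  val <- mk(sprintf("h%d", 5:8), "HLAA", c(29, 27, 30, 28), c(10, 12, 9, 11))
  bd <- run_burden(disc); bv <- run_burden(val)
  out <- validate_genes(disc, val, bd, bv, alpha = 0.05)
  expect_identical(out$gene, "HLAA")
  expect_identical(out$direction, "case")
  expect_identical(out$n_var_disc, 4L)
  expect_identical(out$n_var_val, 4L)
  expect_identical(out$p_disc, bd$subset_case_meta_p[bd$gene == "HLAA"])
  expect_identical(out$p_val, bv$subset_case_meta_p[bv$gene == "HLAA"])

  # opposite directions across cohorts: excluded
  val_flip <- mk(sprintf("h%d", 5:8), "HLAA", c(10, 12, 9, 11),
                 c(29, 27, 30, 28))
  expect_identical(
    nrow(validate_genes(disc, val_flip, bd, run_burden(val_flip))), 0L)

  # single significant variant on each side: individual p is the evidence,
  # no burden record needed
  d1 <- assoc_row("s1", "SOLO", 30, 70, 10, 90)
  v1 <- assoc_row("s2", "SOLO", 28, 72, 11, 89)
  empty_burden <- run_burden(d1)
  out1 <- validate_genes(d1, v1, empty_burden, empty_burden)
  expect_identical(out1$gene, "SOLO")
  expect_identical(out1$n_var_disc, 1L)
  expect_identical(out1$p_disc, d1$p)

  # multi-variant gene with no burden record is a pipeline-order error
  expect_error(validate_genes(disc, v1 <- assoc_row("h9", "HLAA", 30, 70, 10, 90),
                              empty_burden, empty_burden),
               "pipeline-order")
})

test_that("validated variants and genes recover the planted truth", {
  cfg <- simulation_config(n_variants = 1000, n_genes = 100, planted_or = 4,
                           seed = 17)
  pair <- simulate_cohort_pair(cfg)
  ad <- run_association(pair$discovery)
  av <- run_association(pair$validation)
  vv <- validate_variants(ad$all, av$all)
  truth <- pair$truth
  planted <- truth$variant_id[truth$status != "null"]
  nulls <- truth$variant_id[truth$status == "null"]
  recovered <- intersect(vv$validated$variant_id, planted)
  expect_gt(length(recovered) / length(planted), 0.7)
  false_val <- intersect(vv$validated$variant_id, nulls)
  expect_lte(length(false_val) / length(nulls), 0.01)
  # every validated planted variant carries its planted direction
  status <- truth$status[match(recovered, truth$variant_id)]
  dir <- vv$validated$direction[match(recovered, vv$validated$variant_id)]
  expect_identical(dir == "case", status == "planted_case")

  vg <- validate_genes(ad$all, av$all, run_burden(ad$all), run_burden(av$all))
  rich <- unique(truth$gene[startsWith(truth$gene, "GR")])
  expect_true(all(rich %in% vg$gene))
  # per-record invariant: gene direction equals its variants' common direction
  for (i in seq_len(nrow(vg))) {
    g <- vg$gene[i]
    dirs <- unique(c(ad$significant$direction[ad$significant$gene == g],
                     av$significant$direction[av$significant$gene == g]))
    expect_identical(dirs, vg$direction[i])
  }
})

test_that("hypergeometric enrichment matches the exact tail sum", {
  universe <- sprintf("g%04d", 1:1000)
  validated <- universe[1:33]
  sets <- list(hit = c(universe[1:10], universe[500:539]),  # overlap 10, size 50
               none = universe[900:949],                    # overlap 0
               all = universe)
  enr <- hypergeom_enrichment(validated, universe, sets)
  # oracle: direct tail sum over the hypergeometric pmf
  tail_sum <- sum(dhyper(10:33, 50, 950, 33))
  row <- enr[enr$collection == "hit", ]
  expect_equal(row$p, tail_sum, tolerance = 1e-12)
  expect_identical(row$overlap, 10L)
  expect_identical(row$set_size, 50L)
  # zero overlap and the full-universe set are both forced to p = 1
  expect_identical(enr$p[enr$collection == "none"], 1)
  expect_identical(enr$p[enr$collection == "all"], 1)
  # degenerate urn: validated = set = universe
  deg <- hypergeom_enrichment(universe[1:5], universe[1:5],
                              list(s = universe[1:5]))
  expect_identical(deg$p, 1)
  expect_equal(enr$q, bh_adjust(enr$p), tolerance = 1e-15)
  expect_error(hypergeom_enrichment(c("g0001", "zzz"), universe, sets), "zzz")
})

test_that("GMT collections parse into named gene sets", {
  path <- file.path(withr::local_tempdir(), "sets.gmt")
  writeLines(c("pathA\tdesc\tTP53\tKRAS\tEGFR",
               "pathB\thttp://x\tHLA-A\tHLA-B"), path)
  sets <- read_gmt(path)
  expect_identical(names(sets), c("pathA", "pathB"))
  expect_identical(sets$pathA, c("TP53", "KRAS", "EGFR"))
  writeLines("bad\tonly-description", path)
  expect_error(read_gmt(path), "malformed")
})
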