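test_that("family generation is reproducible and honours the model", {
  fm <- family_model(n_core = 20, length = 80, n_blocks = 4,
                     gap_prob = 0.5, jitter = 1, rng_seed = 3)
  a <- make_family(fm)
  b <- make_family(fm)
  expect_identical(a, b)
  expect_equal(a$n, 20L)
  expect_equal(a$width, 80L)

  # deterministic blocks, always present: identical masks, zero matrix
  fm1 <- family_model(10, 60, gap_blocks = list(c(5, 12), c(30, 40)),
                      gap_prob = 1, jitter = 0, rng_seed = 1)
  m <- gap_mask(make_family(fm1))
  expect_true(all(gap_dist_matrix(m, "linear") == 0))
  expect_equal(unname(colSums(m)[5:12]), rep(10, 8))

  # no gaps at all
  fm0 <- family_model(8, 40, gap_blocks = list(c(3, 6)), gap_prob = 0,
                      jitter = 0, rng_seed = 1)
  m0 <- gap_mask(make_family(fm0))
  expect_true(all(m0 == 0))
  expect_error(family_model(1, 40), "degenerate")
  expect_error(family_model(5, 40, gap_blocks = list(c(0, 10))),
               "within")
})

test_that("outlier injection labels, shuffles and length-checks", {
  fam <- make_family(family_model(95, 120, n_blocks = 5, gap_prob = 0.8,
                                  jitter = 1, rng_seed = 2,
                                  columns = 1:60))
  om <- family_model(5, 120, n_blocks = 5, gap_prob = 0.8, jitter = 1,
                     rng_seed = 12, columns = 61:120)
  ds <- inject_outliers(fam, 5, om, rng_seed = 4)
  expect_equal(ds$alignment$n, 100L)
  expect_equal(sum(ds$labels), 5L)
  expect_true(all(startsWith(ds$alignment$ids[ds$labels], "outl")))
  expect_setequal(ds$alignment$ids[!ds$labels], fam$ids)

  ds0 <- inject_outliers(fam, 0, om)
  expect_equal(sum(ds0$labels), 0L)
  expect_identical(ds0$alignment, fam)

  # an all-gap outlier model violates the 10% ungapped-length rule
  gappy <- family_model(5, 120, gap_blocks = list(c(1, 100)),
                        gap_prob = 1, jitter = 0, rng_seed = 9)
  expect_error(inject_outliers(fam, 5, gappy), "ungapped length")
  wrong_len <- family_model(5, 90, n_blocks = 3, rng_seed = 9)
  expect_error(inject_outliers(fam, 5, wrong_len), "width")
})

test_that("ROC sweep: perfect separation, permutation null, monotonicity", {
  perfect <- roc_auc(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$auc, 1)
  # permutation null: scores carry no label information
  set.seed(41)
  aucs <- replicate(200, {
    sc <- rnorm(60)
    roc_auc(sc, sample(rep(c(TRUE, FALSE), c(6, 54))))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  # TPR and FPR non-increasing in the threshold
  sc <- rnorm(100); lb <- sc + rnorm(100) > 1
  cv <- roc_auc(sc, lb)$curve
  ord <- order(cv$threshold)
  expect_true(all(diff(cv$TPR[ord]) <= 0))
  expect_true(all(diff(cv$FPR[ord]) <= 0))
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("trapezoidal AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(42)
  sc <- rnorm(150)
  lb <- sc + rnorm(150, sd = 1.5) > 0.8
  skip_if(!any(lb) || all(lb))
  ours <- roc_auc(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("divergent-architecture outliers are near-perfectly detected", {
  mods <- diffclan_models(n_core = 195, L = 200, rng_seed = 5)
  bm <- benchmark_run(mods$family, mods$outlier, k = 5, n_datasets = 3,
                      rng_seed = 11)
  expect_gte(bm$auc, 0.95)
  expect_true(all(diff(bm$rates$TPR) <= 0))
  expect_true(all(diff(bm$rates$FPR) <= 0))
})

test_that("partially overlapping architectures degrade but beat chance", {
  mods <- diffclan_models(n_core = 195, L = 200, rng_seed = 6)
  shifted <- lapply(mods$family$gap_blocks, function(b) b + 2L)
  om <- family_model(5, 200, gap_blocks = shifted, gap_prob = 0.8,
                     jitter = 2, rng_seed = 106)
  bm <- benchmark_run(mods$family, om, k = 5, n_datasets = 3,
                      rng_seed = 11)
  expect_gt(bm$auc, 0.5)
  diff_bm <- benchmark_run(mods$family, mods$outlier, k = 5,
                           n_datasets = 3, rng_seed = 11)
  expect_lt(bm$auc, diff_bm$auc)
})

test_that("seed-mode and full-mode flags agree on seeded datasets", {
  mods <- diffclan_models(n_core = 295, L = 200, rng_seed = 7)
  ds <- inject_outliers(make_family(mods$family), 5, mods$outlier,
                        rng_seed = 8)
  f_full <- detect_outliers(ds$alignment, mode = "full", rng_seed = 8)
  f_mbed <- detect_outliers(ds$alignment, mode = "mbed", rng_seed = 8)
  expect_gte(mean(f_full$flags == f_mbed$flags), 0.9)
})
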