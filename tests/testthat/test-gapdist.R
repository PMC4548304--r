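test_that("gap masks recode gaps as 1 and residues as 0", {
  aln <- msa(c("a", "b", "c"), c("A-C.", "ACDE", "----"))
  m <- gap_mask(aln)
  expect_equal(unname(m[1, ]), c(0L, 1L, 0L, 1L))
  expect_equal(unname(m[2, ]), rep(0L, 4))
  expect_equal(unname(m[3, ]), rep(1L, 4))
  expect_equal(rownames(m), aln$ids)
})

test_that("worked pair-metric examples match hand evaluation", {
  expect_equal(pair_linear(c(0, 0, 1), c(0, 1, 0)), 2)
  expect_equal(pair_linear(c(1, 1, 1, 1), c(0, 0, 0, 0)), 4)
  expect_equal(pair_linear(c(0, 1, 0), c(0, 1, 0)), 0)

  expect_equal(pair_affine(c(0, 0, 1, 1, 0), c(0, 0, 0, 0, 0)), 4)
  expect_equal(pair_affine(c(1, 0, 1, 0), c(0, 0, 0, 0)), 6)
  expect_equal(pair_affine(c(1, 1, 0), c(1, 1, 0)), 0)
  # a disagreement at the first column opens (scores 3)
  expect_equal(pair_affine(1, 0), 3)

  expect_equal(pair_cumulative(c(0, 1, 1, 1, 0), c(0, 0, 0, 0, 0)), 6)
  expect_equal(pair_cumulative(c(1, 0, 1), c(0, 0, 0)), 2)
  expect_equal(pair_cumulative(c(1, 1), c(1, 1)), 0)

  expect_error(pair_linear(c(0, 1), c(0, 1, 0)), "length")
})

test_that("pair metrics agree with the independent reference walk", {
  set.seed(11)
  for (i in 1:200) {
    p <- random_mask_pair()
    expect_identical(pair_linear(p$a, p$b), ref_linear(p$a, p$b))
    expect_identical(pair_affine(p$a, p$b), ref_affine(p$a, p$b))
    expect_identical(pair_cumulative(p$a, p$b), ref_cumulative(p$a, p$b))
  }
})

test_that("metric algebra and symmetry hold on random pairs", {
  set.seed(12)
  for (i in 1:200) {
    p <- random_mask_pair()
    lin <- pair_linear(p$a, p$b)
    aff <- pair_affine(p$a, p$b)
    cum <- pair_cumulative(p$a, p$b)
    expect_gte(aff, lin)
    expect_lte(aff, 3 * lin)
    expect_gte(cum, lin)
    d <- as.integer(p$a != p$b)
    if (length(d) < 2 || !any(d[-1] & d[-length(d)]))
      expect_equal(cum, lin)  # no adjacent double-mismatch: runs are 1-long
    expect_equal(pair_linear(p$b, p$a), lin)
    expect_equal(pair_affine(p$b, p$a), aff)
    expect_equal(pair_cumulative(p$b, p$a), cum)
  }
})

test_that("linear metric satisfies the triangle inequality", {
  set.seed(13)
  for (i in 1:100) {
    L <- sample.int(60, 1)
    a <- rbinom(L, 1, 0.4); b <- rbinom(L, 1, 0.4); c <- rbinom(L, 1, 0.4)
    expect_lte(pair_linear(a, c), pair_linear(a, b) + pair_linear(b, c))
  }
})

test_that("full matrices are symmetric, zero-diagonal, pair-consistent", {
  aln <- msa(c("a", "b", "c"), c("AA--", "A-A-", "AAAA"))
  m <- gap_mask(aln)
  for (metric in c("linear", "affine", "cumulative")) {
    S <- gap_dist_matrix(m, metric)
    expect_identical(unname(S), unname(t(S)))
    expect_equal(unname(diag(S)), c(0, 0, 0))
    fun <- switch(metric, linear = pair_linear, affine = pair_affine,
                  cumulative = pair_cumulative)
    for (i in 1:2) for (j in (i + 1):3)
      expect_equal(S[i, j], fun(m[i, ], m[j, ]))
    expect_equal(attr(S, "n_pair_evals"), 3)
  }
  m2 <- matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE)
  expect_equal(unname(gap_dist_matrix(m2, "linear")[1, 2]), 2)
  z <- gap_dist_matrix(matrix(0L, 3, 5), "linear")
  expect_true(all(z == 0))
  expect_error(gap_dist_matrix(m, "nope"))
})

test_that("mean scores are row means excluding the diagonal", {
  expect_equal(unname(mean_scores(matrix(c(0, 3, 3, 0), 2))), c(3, 3))
  expect_equal(unname(mean_scores(matrix(0, 4, 4))), rep(0, 4))
  S <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  expect_equal(unname(mean_scores(S)), c(1.5, 2, 2.5))
  expect_error(mean_scores(matrix(0, 1, 1)), "at least 2")
})

test_that("seed-mode means reduce to full-mode means when M = N", {
  set.seed(21)
  mask <- matrix(rbinom(40 * 30, 1, 0.3), 40, 30)
  rownames(mask) <- paste0("s", 1:40)
  for (metric in c("linear", "cumulative")) {
    full <- mean_scores(gap_dist_matrix(mask, metric))
    mb <- mbed_means(mask, metric, n_seeds = 40, rng_seed = 5)
    expect_equal(as.numeric(mb), as.numeric(full))
  }
})

test_that("seed mode is reproducible and respects evaluation bounds", {
  set.seed(22)
  mask <- matrix(rbinom(60 * 40, 1, 0.3), 60, 40)
  a <- mbed_means(mask, "linear", n_seeds = 8, rng_seed = 9)
  b <- mbed_means(mask, "linear", n_seeds = 8, rng_seed = 9)
  expect_identical(a, b)
  c <- mbed_means(mask, "linear", n_seeds = 8, rng_seed = 10)
  expect_false(identical(attr(a, "seeds"), attr(c, "seeds")))
  expect_equal(attr(a, "n_pair_evals"), 8 * 60 - 8)
  expect_lte(attr(a, "n_pair_evals"), 8 * 60)
  expect_equal(length(attr(a, "seeds")), 8L)
  expect_error(mbed_means(mask, "linear", n_seeds = 0), "between")
  expect_error(mbed_means(mask, "linear", n_seeds = 61), "between")
  expect_error(mbed_means(mask, "linear", n_seeds = 1), "seed itself")
})

test_that("default seed count grows logarithmically with a floor of 5", {
  expect_equal(mbed_seed_count(10), 5L)
  expect_equal(mbed_seed_count(3), 3L)
  expect_equal(mbed_seed_count(500), 9L)
  expect_equal(mbed_seed_count(2^16), 16L)
})
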