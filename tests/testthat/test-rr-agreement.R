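test_that("exact signed-rank p equals brute-force sign enumeration", {
  cases <- list(
    c(1, 2, 3, 4, 5),                    # all positive, tie-free
    c(0.12, -0.05, 0.3, 0.07, -0.2, 0.01),
    c(1, 1, -1, 2, 2),                   # heavy ties
    c(0.5, -0.5, 0.25, 0.25, -0.125, 0.75, -0.3, 0.9),
    c(-1, -2, -3)                        # all negative
  )
  for (d in cases) {
    pairs <- rr_paired(1 + pmax(d, 0) + 0.001, 1 - pmin(d, 0) + 0.001)
    got <- wilcoxon_signed_rank(pairs)
    expect_equal(got$p_value, brute_force_signed_rank_p(d), tolerance = 1e-12,
                 label = paste("diffs", paste(d, collapse = ",")))
    expect_equal(got$method, "exact")
  }
})

test_that("five positive unit differences give the textbook p of 2/32", {
  pairs <- rr_paired(c(1.1, 1.2, 1.3, 1.4, 1.5), rep(1, 5))
  w <- wilcoxon_signed_rank(pairs)
  expect_equal(w$statistic, 15)          # maximal positive-rank sum
  expect_equal(w$p_value, 0.0625)
})

test_that("the exact path agrees with the reference implementation", {
  # tie-free case so the reference can use its exact distribution too
  set.seed(33)
  a <- round(runif(12, 0.7, 1.3), 3)
  b <- round(a + rnorm(12, 0.02, 0.05), 4)
  ok <- a != b & !duplicated(abs(a - b))
  a <- a[ok]; b <- b[ok]
  ours <- wilcoxon_signed_rank(rr_paired(a, b))
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  expect_equal(ours$statistic, unname(ref$statistic))
})

test_that("zero differences are dropped and all-zero gives p = 1", {
  same <- rr_paired(c(1, 1.1, 0.9), c(1, 1.1, 0.9))
  w <- wilcoxon_signed_rank(same)
  expect_equal(w$p_value, 1)
  expect_equal(w$n_zero_diffs, 3)

  mixed <- rr_paired(c(1, 1.2, 1.3, 0.8), c(1, 1.0, 1.1, 1.0))
  w2 <- wilcoxon_signed_rank(mixed)
  expect_equal(w2$n_zero_diffs, 1)
  expect_equal(w2$n_pairs, 4)

  expect_error(rr_paired(c(1, 2), c(1, 2, 3)), "equal lengths")
  expect_error(rr_paired(c(1, -2), c(1, 1)), "positive")
})

test_that("normal approximation agrees with the exact path near the cutoff", {
  set.seed(44)
  a <- runif(25, 0.6, 1.2)
  b <- a + rnorm(25, 0.01, 0.06)
  pairs <- rr_paired(a, pmax(b, 0.1))
  p_exact <- wilcoxon_signed_rank(pairs, exact_limit = 25)$p_value
  p_approx <- wilcoxon_signed_rank(pairs, exact_limit = 5)$p_value
  expect_equal(p_exact, p_approx, tolerance = 0.01)
  expect_equal(wilcoxon_signed_rank(pairs, exact_limit = 5)$method,
               "normal approximation")
})

test_that("p is invariant under pair order and symmetric under series swap", {
  set.seed(55)
  a <- runif(10, 0.7, 1.3)
  b <- a + rnorm(10, 0, 0.05)
  pairs <- rr_paired(a, b)
  perm <- sample(10)
  w1 <- wilcoxon_signed_rank(pairs)
  w2 <- wilcoxon_signed_rank(rr_paired(a[perm], b[perm]))
  expect_equal(w1$p_value, w2$p_value)

  w3 <- wilcoxon_signed_rank(rr_paired(b, a))
  expect_equal(w1$p_value, w3$p_value)
  # statistics of the two orientations mirror about n(n+1)/4 * 2
  expect_equal(w1$statistic + w3$statistic, 10 * 11 / 2)
})

test_that("MA coordinates and band fraction follow their definitions", {
  pairs <- rr_paired(c(1.0, 0.8, 1.2), c(0.9, 0.8, 1.4))
  ma <- ma_points(pairs)
  expect_equal(ma$mean, c(0.95, 0.8, 1.3))
  expect_equal(ma$difference, c(0.1, 0, -0.2))

  swapped <- ma_points(rr_paired(c(0.9, 0.8, 1.4), c(1.0, 0.8, 1.2)))
  expect_equal(swapped$difference, -ma$difference)

  expect_equal(band_fraction(pairs, 0.1), 2 / 3)
  expect_equal(band_fraction(pairs, 1e6), 1)
  d2 <- rr_paired(c(1.05, 1.15), c(1, 1))
  expect_equal(band_fraction(d2, 0.1), 0.5)   # diffs 0.05 and 0.15
  expect_error(band_fraction(pairs, 0), "positive")
})

test_that("the agreement report assembles all three statistics", {
  set.seed(66)
  a <- runif(40, 0.7, 1.1)
  b <- a + rnorm(40, 0, 0.03)
  rep <- rr_agreement(rr_paired(a, b), band = 0.1)
  expect_equal(rep$n_pairs, 40)
  expect_equal(nrow(rep$ma_points), 40)
  expect_gte(rep$band_fraction, 0)
  expect_lte(rep$band_fraction, 1)
  expect_identical(rep$significant, rep$p_value < 0.05)
  expect_output(print(rep), "Wilcoxon signed-rank")
})
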