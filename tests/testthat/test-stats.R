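test_that("dice matches identities and a brute-force count", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(a, b), 2 * 1 / (2 + 2))
  big_a <- with_seed(1, matrix(runif(400) > 0.5, 20, 20))
  big_b <- with_seed(2, matrix(runif(400) > 0.5, 20, 20))
  expect_equal(dice(big_a, big_b),
               2 * sum(big_a & big_b) / (sum(big_a) + sum(big_b)))
  expect_error(dice(a, matrix(TRUE, 3, 3)), "shapes differ")
  expect_error(dice(a * 1, b), "logical")
  expect_error(dice(a & FALSE, b & FALSE), "both masks empty")
})

test_that("the signed-rank null distribution matches enumeration and dsignrank", {
  for (n in c(4, 8, 12)) {
    dens <- signed_rank_null(n)
    expect_equal(dens, stats::dsignrank(0:(n * (n + 1) / 2), n),
                 tolerance = 1e-12)
    # brute force over all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(0:1), n)))
    w <- signs %*% seq_len(n)
    brute <- tabulate(w + 1, nbins = n * (n + 1) / 2 + 1) / 2^n
    expect_equal(dens, brute, tolerance = 1e-12)
  }
})

test_that("wilcoxon exact p-values match closed forms and stats::wilcox.test", {
  # all six differences positive: W+ = 21, p = 2 * P(W >= 21) = 2 / 64
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$statistic, 21)
  expect_equal(r$p, 2 / 64)

  for (seed in 1:5) {
    d <- with_seed(seed, round(rnorm(10), 6))  # tie/zero-free a.s.
    ours <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_true(ours$exact)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the normal approximation matches stats::wilcox.test under ties", {
  d <- c(1, 1, -2, 3, 3, 3, -4, 5, 6, 6, -7, 8, 2, -2)
  ours <- wilcoxon_signed_rank(d)
  ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
  expect_false(ours$exact)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # exact_limit forces the approximation even on clean data
  approx <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, -7, 8), exact_limit = 5)
  expect_false(approx$exact)

  # zeros are ranked (Pratt), not dropped before ranking
  dz <- c(0, 0, 1, 2, 3, 4, 5)
  rz <- wilcoxon_signed_rank(dz)
  expect_equal(rz$statistic, sum(rank(abs(dz))[dz > 0]))
  expect_false(rz$degenerate)

  z <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
  expect_error(wilcoxon_signed_rank(numeric(0)), "non-empty")
  expect_error(wilcoxon_signed_rank(c(1, NA)), "finite")
})

test_that("paired differences and Bland-Altman match hand-computed values", {
  s <- paired_series(c(10, 12, 12, 10), c(10, 10, 10, 10))
  pd <- paired_difference(s)
  expect_equal(pd$mean_diff, 1)
  expect_equal(pd$sd_diff, sqrt(4 / 3))
  ba <- bland_altman(s)
  expect_equal(ba$bias, 1)
  expect_equal(ba$loa_low, 1 - 1.96 * sqrt(4 / 3))
  expect_equal(ba$loa_high, 1 + 1.96 * sqrt(4 / 3))
  expect_equal(ba$pairs$mean, c(10, 11, 11, 10))
  expect_equal(ba$pairs$diff, c(0, 2, 2, 0))

  # translation equivariance: shifting both series leaves differences alone
  s2 <- paired_series(s$values_a + 100, s$values_b + 100)
  expect_equal(bland_altman(s2)$bias, ba$bias)
  expect_equal(bland_altman(s2)$loa_high, ba$loa_high)
  # scale equivariance
  s3 <- paired_series(s$values_a * 3, s$values_b * 3)
  expect_equal(bland_altman(s3)$bias, 3 * ba$bias)
  expect_equal(bland_altman(s3)$sd_diff, 3 * ba$sd_diff)

  expect_error(paired_series(1:4, 1:3), "equal length")
  expect_error(paired_series(1:2, 1:2), "at least 3")
  expect_error(paired_series(c(1, 2, Inf), 1:3), "finite")
})

test_that("pearson matches known correlations and is affine invariant", {
  expect_equal(pearson(paired_series(1:10, 2 * (1:10) + 5)), 1)
  expect_equal(pearson(paired_series(1:10, -3 * (1:10))), -1)
  expect_equal(pearson(paired_series(c(1, 2, 3), c(1, 3, 2))), 0.5)
  a <- with_seed(4, rnorm(50))
  b <- with_seed(5, rnorm(50))
  r0 <- pearson(paired_series(a, b))
  expect_equal(pearson(paired_series(2 * a + 7, -1 * b + 3)), -r0)
  expect_error(pearson(paired_series(rep(1, 5), 1:5)), "constant")
})

test_that("shapiro-wilk flags uniform data and keeps its nominal level", {
  u <- with_seed(6, runif(5000))
  expect_lt(shapiro_wilk(u)$p, 0.001)
  norm_p <- vapply(1:100, function(s) {
    shapiro_wilk(with_seed(1000 + s, rnorm(40)))$p
  }, 0)
  # at level 0.05 the rejection count across 100 normal draws is Binomial
  # (100, 0.05); more than 12 rejections has probability ~1e-3
  expect_gte(sum(norm_p > 0.05), 88)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
})

test_that("size agreement ratio, ordering and confusion table are exact", {
  mk <- function(labels) {
    lapply(labels, function(l) {
      structure(list(device_family = "dev", size_label = l, input_value = 1),
                class = "device_selection")
    })
  }
  # 105 agreements out of 118 cases
  la <- c(rep("23", 60), rep("26", 45), rep("23", 8), rep("29", 3),
          rep("OUT_OF_RANGE_LOW", 2))
  lb <- c(rep("23", 60), rep("26", 45), rep("26", 8), rep("26", 3),
          rep("23", 2))
  ag <- size_agreement(mk(la), mk(lb))
  expect_equal(ag$n, 118)
  expect_equal(ag$ratio, 105 / 118)
  expect_equal(ag$n_under, 8 + 2)  # a below b, sentinel LOW counts as lowest
  expect_equal(ag$n_over, 3)
  expect_equal(unname(ag$confusion["23", "26"]), 8)
  expect_equal(sum(ag$confusion), 118)

  perfect <- size_agreement(mk(la), mk(la))
  expect_equal(perfect$ratio, 1)
  expect_equal(perfect$n_under + perfect$n_over, 0)

  expect_error(size_agreement(mk(la), mk(lb[1:5])), "equal length")
  other <- mk(lb)
  other[[1]]$device_family <- "other"
  expect_error(size_agreement(mk(la), other), "family mismatch")
})
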