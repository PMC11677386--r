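# Agreement statistics: frozen closed forms, brute-force oracles, and
# Monte-Carlo properties.

test_that("Pearson correlation handles exact and hand-computed cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("CCC matches its closed forms", {
  x <- rnorm(50)
  res <- lin_ccc(x, x)
  expect_equal(res$rho_c, 1)
  expect_equal(res$category, "near perfect")

  # constant shift c = 1: rho_c = 2 s^2 / (2 s^2 + c^2), population var 2/3
  res2 <- lin_ccc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res2$rho_c, 4 / 7, tolerance = 1e-12)
  expect_equal(res2$category, "poor")

  # definitional oracle on arbitrary data
  set.seed(5)
  a <- rnorm(200, 3, 2); b <- 0.8 * a + rnorm(200, 1, 1)
  expect_equal(lin_ccc(a, b)$rho_c, ccc_oracle(a, b), tolerance = 1e-12)
})

test_that("CCC equals the analytic value for a bivariate normal sample", {
  set.seed(101)
  n <- 1e5
  rho <- 0.9; delta <- 0.5
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n) + delta
  # analytic: 2*rho / (1 + 1 + delta^2) = 1.8 / 2.25 = 0.8
  res <- lin_ccc(x, y)
  expect_equal(res$rho_c, 0.8, tolerance = 0.01)
  expect_lt(res$ci_low, res$rho_c)
  expect_gt(res$ci_high, res$rho_c)
})

test_that("CCC never exceeds |r| and equals r at matched moments", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(30, runif(1, -2, 2), runif(1, 0.5, 3))
    y <- 0.5 * x + rnorm(30, runif(1, -2, 2), runif(1, 0.5, 3))
    expect_lte(abs(lin_ccc(x, y)$rho_c), abs(pearson_r(x, y)) + 1e-12)
  }
  x <- rnorm(100)
  y <- sample(x)  # same marginal: equal means and variances
  expect_equal(lin_ccc(x, y)$rho_c, pearson_r(x, y), tolerance = 1e-12)
})

test_that("CCC categories split at the conventional bands", {
  expect_equal(ccc_category(c(0.995, 0.97, 0.92, 0.5)),
               c("near perfect", "substantial", "moderate", "poor"))
})

test_that("kappa matches hand arithmetic and the identity case", {
  v <- rep(c("a", "b"), 50)
  expect_equal(cohen_kappa(v, v)$kappa, 1)

  tab <- labels_from_2x2(40, 10, 10, 40)
  res <- cohen_kappa(tab$a, tab$b)
  expect_equal(res$kappa, 0.6, tolerance = 1e-12)
  expect_equal(res$p_observed, 0.8)
  expect_equal(res$p_expected, 0.5)

  expect_error(cohen_kappa(rep("a", 5), rep("a", 5)), "undefined")
})

test_that("kappa equals the brute-force oracle on all small 2x2 tables", {
  for (a in 0:6) for (b in 0:(6 - a)) for (c in 0:(6 - a - b)) {
    for (d in 0:(6 - a - b - c)) {
      n <- a + b + c + d
      if (n < 1) next
      want <- kappa_oracle_2x2(a, b, c, d)
      labs <- labels_from_2x2(a, b, c, d)
      if (is.na(want)) {
        expect_error(cohen_kappa(labs$a, labs$b))
      } else {
        expect_equal(cohen_kappa(labs$a, labs$b)$kappa, want,
                     tolerance = 1e-12,
                     info = sprintf("table %d %d %d %d", a, b, c, d))
      }
    }
  }
})

test_that("kappa is near zero for independent raters", {
  set.seed(8)
  a <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  b <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  res <- cohen_kappa(a, b)
  expect_lt(abs(res$kappa), 0.03)
  expect_gt(res$p_value, 1e-4)
})

test_that("Bland-Altman fields follow their definitions", {
  ref <- c(10, 12, 15, 18, 20)
  res <- bland_altman(ref, ref - 2)
  expect_equal(res$bias, 2)
  expect_equal(res$sd_diff, 0)
  expect_equal(res$loa_low, 2)
  expect_equal(res$loa_high, 2)
  expect_equal(res$n_outside, 0)

  # bias is exactly mean(ref) - mean(index) for any input
  set.seed(9)
  r2 <- rnorm(50, 20, 5); i2 <- r2 + rnorm(50, -1, 2)
  ba <- bland_altman(r2, i2)
  expect_equal(ba$bias, mean(r2) - mean(i2), tolerance = 1e-12)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("a bias of 1.5 with SD 3.6 gives limits (-5.6, 8.6) at 1 dp", {
  set.seed(10)
  base <- rnorm(156, 24, 5)
  raw <- rnorm(156)
  d <- 1.5 + 3.6 * as.numeric(scale(raw))  # sample mean/SD exactly 1.5/3.6
  res <- bland_altman(base, base - d)
  expect_equal(res$bias, 1.5, tolerance = 1e-10)
  expect_equal(res$sd_diff, 3.6, tolerance = 1e-10)
  expect_equal(round(res$loa_low, 1), -5.6)
  expect_equal(round(res$loa_high, 1), 8.6)
})

test_that("Bland-Altman recovers simulated bias and coverage", {
  set.seed(12)
  n <- 10000
  ref <- rnorm(n, 25, 5)
  idx <- ref - rnorm(n, 2, 1)
  res <- bland_altman(ref, idx)
  expect_lt(abs(res$bias - 2), 3 / sqrt(n))
  expect_equal(res$pct_outside, 5, tolerance = 0.3 * 5)
  expect_equal(res$sd_diff, 1, tolerance = 0.05)
})

test_that("dose-dependent bias regression detects a proportional error", {
  set.seed(13)
  ref <- rnorm(500, 25, 5)
  idx <- 0.8 * ref + rnorm(500, 0, 0.5)  # difference grows with level
  res <- bland_altman(ref, idx)
  expect_gt(res$slope, 0)
  expect_lt(res$slope_p, 1e-6)
})

test_that("the Shapiro-Wilk gate passes normal and fails skewed samples", {
  set.seed(14)
  expect_true(normality_gate(rnorm(200)))
  expect_false(normality_gate(rexp(500)))
  expect_error(normality_gate(rep(1, 10)), "constant")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("compare_location picks the gated test and detects shifts", {
  x <- rnorm(30)
  res <- compare_location(x, x, paired = TRUE)
  expect_equal(res$p_value, 1)

  set.seed(15)
  a <- rnorm(200); b <- rnorm(200, 1)
  res2 <- compare_location(a, b, paired = FALSE)
  expect_equal(res2$test, "two-sample t")
  expect_lt(res2$p_value, 0.001)

  ca <- rcauchy(200); cb <- rcauchy(200, 1)
  res3 <- compare_location(ca, cb, paired = FALSE)
  expect_equal(res3$test, "wilcoxon rank-sum")

  d1 <- rnorm(100); d2 <- d1 + rexp(100) - 0.3
  res4 <- compare_location(d1, d2, paired = TRUE)
  expect_true(res4$test %in% c("paired t", "wilcoxon signed-rank"))
  expect_error(compare_location(numeric(0), rnorm(5), paired = FALSE),
               "at least 3")
})
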