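# Method-comparison statistics: Pearson correlation, Lin's concordance
# correlation coefficient, Cohen's kappa, Bland-Altman analysis, and the
# normality-gated comparisons of central tendency.
#
# The agreement statistics themselves (CCC, kappa, Bland-Altman) are
# implemented here from their definitions; only classic test internals
# (Shapiro-Wilk, t, Wilcoxon, Levene) are delegated to stats/car.

.drop_incomplete_pairs <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(x, y)
  list(x = x[ok], y = y[ok])
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors (pairwise-complete, length >= 3
#'   after dropping missing pairs).
#' @return The correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  p <- .drop_incomplete_pairs(x, y)
  if (length(p$x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(p$x, p$y)
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line as
#' rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2), with
#' population (1/n) moments as in the original concordance definition.
#' The 95% confidence interval uses the Fisher z-transform with the
#' standard asymptotic variance. The qualitative category follows the
#' conventional bands: > 0.99 near perfect, 0.95-0.99 substantial,
#' 0.90-0.95 moderate, < 0.90 poor.
#'
#' @param x,y Paired numeric vectors.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `ccc_result`: list with `rho_c`, `ci_low`,
#'   `ci_high`, `category`, `n`.
#' @examples
#' lin_ccc(1:10, 1:10 + 0.5)
#' @export
lin_ccc <- function(x, y, conf_level = 0.95) {
  p <- .drop_incomplete_pairs(x, y)
  x <- p$x; y <- p$y
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    stop("concordance undefined: both vectors constant and equal",
         call. = FALSE)
  }
  rho_c <- 2 * sxy / denom

  # Fisher z CI with the asymptotic variance of z(rho_c) (Lin 1989)
  if (sx2 == 0 || sy2 == 0) {
    ci <- c(NA_real_, NA_real_)
  } else {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mx - my) / (sx2 * sy2)^0.25   # location-shift relative to scale
    z <- atanh(min(max(rho_c, -1 + 1e-15), 1 - 1e-15))
    if (abs(r) < 1e-15 || abs(rho_c) >= 1) {
      ci <- c(NA_real_, NA_real_)
    } else {
      var_z <- ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
                  4 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
                  2 * rho_c^4 * u^4 / (r^2 * (1 - rho_c^2)^2)) / (n - 2)
      q <- stats::qnorm(1 - (1 - conf_level) / 2)
      ci <- tanh(z + c(-1, 1) * q * sqrt(max(var_z, 0)))
    }
  }
  out <- list(rho_c = rho_c, ci_low = ci[1], ci_high = ci[2],
              category = ccc_category(rho_c), n = n)
  class(out) <- "ccc_result"
  out
}

#' Qualitative agreement band for a concordance coefficient
#'
#' @param rho_c Concordance correlation coefficient.
#' @return `"near perfect"` (> 0.99), `"substantial"` (0.95-0.99),
#'   `"moderate"` (0.90-0.95), or `"poor"` (< 0.90).
#' @export
ccc_category <- function(rho_c) {
  dplyr::case_when(
    rho_c > 0.99 ~ "near perfect",
    rho_c >= 0.95 ~ "substantial",
    rho_c >= 0.90 ~ "moderate",
    TRUE ~ "poor"
  )
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("Lin's CCC: rho_c = %.3f (95%% CI %.3f, %.3f), %s, n = %d\n",
              x$rho_c, x$ci_low, x$ci_high, x$category, x$n))
  invisible(x)
}

#' Cohen's kappa for categorical agreement
#'
#' Unweighted kappa from the k x k contingency table of two raters:
#' kappa = (p_o - p_e) / (1 - p_e), with the large-sample normal
#' approximation for the p-value of kappa = 0.
#'
#' @param a,b Paired categorical vectors (factor, character, or
#'   logical) over a shared label space.
#' @return An object of class `kappa_result`: list with `kappa`,
#'   `p_observed`, `p_expected`, `se`, `p_value`, `n`.
#' @examples
#' cohen_kappa(rep(c(TRUE, FALSE), 50), rep(c(TRUE, FALSE), 50))
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length", call. = FALSE)
  }
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no complete pairs", call. = FALSE)
  levs <- sort(unique(c(as.character(a), as.character(b))))
  a <- factor(as.character(a), levels = levs)
  b <- factor(as.character(b), levels = levs)
  tab <- table(a, b)
  p <- tab / n
  p_o <- sum(diag(p))
  pa <- rowSums(p)
  pb <- colSums(p)
  p_e <- sum(pa * pb)
  if (p_e >= 1) {
    stop("kappa undefined: expected agreement is 1 (both raters constant)",
         call. = FALSE)
  }
  kap <- (p_o - p_e) / (1 - p_e)
  # SE under H0 (Fleiss): for testing kappa = 0; the variance term can
  # round below zero on tiny degenerate tables
  var0 <- (p_e + p_e^2 - sum(pa * pb * (pa + pb))) / (n * (1 - p_e)^2)
  se0 <- sqrt(max(var0, 0))
  p_value <- if (se0 > 0) 2 * stats::pnorm(-abs(kap / se0)) else NA_real_
  out <- list(kappa = kap, p_observed = p_o, p_expected = p_e,
              se = se0, p_value = p_value, n = n)
  class(out) <- "kappa_result"
  out
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (p_o = %.3f, p_e = %.3f, p = %.3g, n = %d)\n",
              x$kappa, x$p_observed, x$p_expected, x$p_value, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `reference - index`, so a positive bias
#' means the index method underestimates the reference. Reports the
#' systematic bias (mean difference), the sample SD of differences, the
#' 95% limits of agreement bias +/- 1.96 SD, a least-squares regression
#' of the differences on the pairwise means (dose-dependent bias) with
#' its slope p-value, and the count of pairs outside the limits.
#'
#' @param reference Measurements by the reference method.
#' @param index Paired measurements by the index method.
#' @return An object of class `bland_altman_result`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `slope`, `slope_p`, `n_outside`,
#'   `pct_outside`, `n`, and the `differences` and `means` vectors.
#' @examples
#' set.seed(1)
#' ref <- rnorm(100, 24, 5)
#' bland_altman(ref, ref - rnorm(100, 1.5, 3.6))
#' @export
bland_altman <- function(reference, index) {
  p <- .drop_incomplete_pairs(reference, index)
  reference <- p$x; index <- p$y
  n <- length(reference)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- reference - index
  m <- (reference + index) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  if (sd_diff == 0) {
    # constant difference: no dose dependence by construction
    slope <- 0
    slope_p <- NA_real_
  } else if (stats::sd(m) > 0) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    slope_p <- summary(fit)$coefficients[2, 4]
  } else {
    slope <- NA_real_
    slope_p <- NA_real_
  }
  outside <- d < loa_low | d > loa_high
  out <- list(bias = bias, sd_diff = sd_diff, loa_low = loa_low,
              loa_high = loa_high, slope = slope, slope_p = slope_p,
              n_outside = sum(outside), pct_outside = 100 * mean(outside),
              n = n, differences = d, means = m)
  class(out) <- "bland_altman_result"
  out
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f (SD %.2f), LoA (%.2f, %.2f)\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  dose-dependent slope %.3f (p = %.3g); %d/%d (%.1f%%) outside LoA\n",
              x$slope, x$slope_p, x$n_outside, x$n, x$pct_outside))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' The test statistic is defined for 3 to 5000 observations; beyond
#' 5000 the gate is evaluated on 5000 evenly spaced order statistics of
#' the sample, a deterministic thinning that preserves the empirical
#' distribution shape.
#'
#' @param x Numeric vector, n >= 3, non-constant.
#' @param alpha Significance level of the gate.
#' @return `TRUE` if the Shapiro-Wilk p-value exceeds `alpha` (no
#'   evidence against normality), else `FALSE`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("normality test undefined for a constant vector",
                              call. = FALSE)
  if (length(x) > 5000) {
    x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
  }
  stats::shapiro.test(x)$p.value > alpha
}

#' Normality-gated comparison of central tendency
#'
#' Paired case: a paired t-test if the within-pair differences pass the
#' Shapiro-Wilk gate, otherwise the Wilcoxon signed-rank test (zero
#' differences dropped, Wilcoxon's original convention). Unpaired case:
#' a two-sample t-test if both groups pass the normality gate and
#' Levene's test finds no heteroscedasticity at the same alpha,
#' otherwise the Wilcoxon rank-sum (Mann-Whitney) test.
#'
#' @param x,y Numeric samples; equal length required when `paired`.
#' @param paired Logical.
#' @param alpha Level for the normality and homoscedasticity gates.
#' @return A list with `test` (name of the test that fired),
#'   `statistic`, `p_value`, `normal` (gate outcome), and sample sizes.
#' @examples
#' set.seed(2)
#' compare_location(rnorm(50), rnorm(50, 1), paired = FALSE)
#' @export
compare_location <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (paired) {
    p <- .drop_incomplete_pairs(x, y)
    x <- p$x; y <- p$y
    if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
    d <- x - y
    if (length(unique(d)) == 1 && d[1] == 0) {
      # identical samples: no location difference by construction
      return(list(test = "wilcoxon signed-rank", statistic = NA_real_,
                  p_value = 1, normal = NA, n = length(x)))
    }
    normal <- if (stats::sd(d) == 0) FALSE else normality_gate(d, alpha)
    if (normal) {
      ht <- stats::t.test(x, y, paired = TRUE)
      list(test = "paired t", statistic = unname(ht$statistic),
           p_value = ht$p.value, normal = TRUE, n = length(x))
    } else {
      d_nz <- d[d != 0]
      if (length(d_nz) == 0) {
        return(list(test = "wilcoxon signed-rank", statistic = NA_real_,
                    p_value = 1, normal = FALSE, n = length(x)))
      }
      ht <- suppressWarnings(stats::wilcox.test(d_nz))
      list(test = "wilcoxon signed-rank", statistic = unname(ht$statistic),
           p_value = ht$p.value, normal = FALSE, n = length(x))
    }
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) {
      stop("need at least 3 observations per group", call. = FALSE)
    }
    normal <- stats::sd(x) > 0 && stats::sd(y) > 0 &&
      normality_gate(x, alpha) && normality_gate(y, alpha)
    homosced <- FALSE
    if (normal) {
      g <- factor(rep(c("x", "y"), c(length(x), length(y))))
      lev <- car::leveneTest(c(x, y), g)
      homosced <- lev[["Pr(>F)"]][1] > alpha
    }
    if (normal && homosced) {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      list(test = "two-sample t", statistic = unname(ht$statistic),
           p_value = ht$p.value, normal = TRUE,
           n = c(length(x), length(y)))
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y))
      list(test = "wilcoxon rank-sum", statistic = unname(ht$statistic),
           p_value = ht$p.value, normal = normal,
           n = c(length(x), length(y)))
    }
  }
}
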