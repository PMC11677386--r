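# Refit of the ultrasound -> L3-SMA regression on an arbitrary cohort.

#' Refit the ultrasound regression for L3 muscle area
#'
#' Ordinary least-squares fit of measured L3-SMA (cm^2) on quadriceps
#' thickness Q (cm), weight W (kg), height H (cm), and sex S (female = 0,
#' male = 1) — the predictor set of the USVALID ultrasound equation — so
#' the model can be re-estimated on any cohort.
#'
#' @param cohort A cohort tibble with columns `l3_sma`, `quad_mt` (mm),
#'   `weight` (kg), `height` (m), and `sex`. Rows with any of these
#'   missing are dropped.
#' @return An object of class `sma_regression`: a list with `intercept`,
#'   `coefficients` (named `quad_mt_cm`, `weight`, `height_cm`, `sex`),
#'   `adjusted_r2`, `n`, and the underlying `lm` fit.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 200, seed = 7))
#' fit <- fit_sma_regression(cohort)
#' fit$adjusted_r2
#' @export
fit_sma_regression <- function(cohort) {
  need <- c("l3_sma", "quad_mt", "weight", "height", "sex")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- tibble::tibble(
    l3_sma = cohort$l3_sma,
    quad_mt_cm = cohort$quad_mt / 10,
    weight = cohort$weight,
    height_cm = cohort$height * 100,
    sex = cohort$sex
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  p <- 4L
  if (n < p + 2L) {
    stop("need at least ", p + 2L, " complete records to fit; got ", n,
         call. = FALSE)
  }
  fit <- stats::lm(l3_sma ~ quad_mt_cm + weight + height_cm + sex, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular fit: predictors are collinear or constant", call. = FALSE)
  }
  s <- summary(fit)
  out <- list(
    intercept = unname(stats::coef(fit)[1]),
    coefficients = stats::coef(fit)[-1],
    adjusted_r2 = s$adj.r.squared,
    n = n,
    fit = fit
  )
  class(out) <- "sma_regression"
  out
}

#' @export
print.sma_regression <- function(x, ...) {
  cat("Ultrasound -> L3-SMA regression (OLS)\n")
  cat(sprintf(
    "  L3-SMA = %.2f + %.2f x Q(cm) + %.2f x W(kg) + %.2f x H(cm) + %.2f x S\n",
    x$intercept, x$coefficients[["quad_mt_cm"]], x$coefficients[["weight"]],
    x$coefficients[["height_cm"]], x$coefficients[["sex"]]
  ))
  cat(sprintf("  adjusted R^2 = %.3f, n = %d\n", x$adjusted_r2, x$n))
  invisible(x)
}
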