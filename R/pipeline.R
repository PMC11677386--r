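# Cohort I/O, validation, stratified summary tables, correlation
# matrices, and the per-pair agreement report.

.cohort_schema <- c(
  "id", "sex", "age", "height", "weight", "l3_sma", "l3_smd", "rz", "xc",
  "z", "theta", "rf_mt", "quad_mt", "rf_csa", "hgs", "talluri_mm",
  "talluri_ffm", "weight_loss_pct", "weight_loss_window",
  "weight_loss_voluntary"
)

#' Validate a cohort table
#'
#' Checks the subject-record invariants: required columns present, sex
#' coded 0/1, positive heights/weights, non-negative age, positive
#' resistive quantities where present, radiodensity within the
#' segmentation window \[-29, 150\] HU, and unit plausibility (heights
#' are metres — a column of values > 3 is almost certainly centimetres).
#' Row numbers are reported with every violation.
#'
#' @param cohort A data frame of subject records.
#' @return The cohort as a tibble, invisibly unchanged, or an error
#'   listing every violation.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  required <- c("id", "sex", "age", "height", "weight")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(cohort), .cohort_schema)
  # extra columns (e.g. paired channels) are allowed, but warn on near-miss
  problems <- character()
  offend <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("%s (rows %s)", msg,
                                       paste(utils::head(rows, 5),
                                             collapse = ", ")))
    }
  }
  if (nrow(cohort) > 0) {
    offend(!is.na(cohort$sex) & !cohort$sex %in% c(0, 1),
           "sex must be coded female = 0, male = 1")
    offend(is.na(cohort$height) | cohort$height <= 0,
           "height must be positive")
    offend(!is.na(cohort$height) & cohort$height > 3,
           "height > 3: expected metres, looks like centimetres")
    offend(is.na(cohort$weight) | cohort$weight <= 0,
           "weight must be positive")
    offend(!is.na(cohort$age) & cohort$age < 0, "age must be >= 0")
    for (col in c("rz", "xc", "z")) {
      if (col %in% names(cohort)) {
        offend(!is.na(cohort[[col]]) & cohort[[col]] <= 0,
               paste(col, "must be positive when present"))
      }
    }
    if ("l3_smd" %in% names(cohort)) {
      offend(!is.na(cohort$l3_smd) &
               (cohort$l3_smd < -29 | cohort$l3_smd > 150),
             "l3_smd outside the segmentation window [-29, 150] HU")
    }
    for (col in c("l3_sma", "rf_mt", "quad_mt", "rf_csa", "hgs")) {
      if (col %in% names(cohort)) {
        offend(!is.na(cohort[[col]]) & cohort[[col]] <= 0,
               paste(col, "must be positive when present"))
      }
    }
  }
  if (length(problems) > 0) {
    stop("cohort validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cohort
}

#' Read a cohort CSV
#'
#' One row per subject; header names follow the subject-record schema
#' (`height` in metres, thicknesses in mm, areas in cm^2, masses in kg,
#' resistive quantities in ohm, phase angle in degrees, radiodensity in
#' HU). Empty cells are missing values.
#'
#' @param path CSV file path.
#' @return A validated cohort tibble. An empty file yields an empty
#'   cohort with a warning.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warning("cohort file '", path, "' has no rows", call. = FALSE)
    for (col in setdiff(.cohort_schema, names(raw))) {
      raw[[col]] <- if (col == "id") character() else numeric()
    }
  }
  unknown <- setdiff(names(raw), .cohort_schema)
  if (length(unknown) > 0) {
    stop("unknown cohort columns: ", paste(unknown, collapse = ", "),
         "; expected a subset of the subject-record schema", call. = FALSE)
  }
  validate_cohort(raw)
}

#' Write a cohort CSV
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Stratified biomarker summary
#'
#' Per-stratum mean, SD, median, IQR, and range for each requested
#' biomarker, with a normality-gated comparison of central tendency
#' between the two strata (two-sample t-test when both groups pass the
#' Shapiro-Wilk gate and Levene's test, Wilcoxon rank-sum otherwise).
#' Strata with fewer than 3 subjects have their statistics suppressed.
#'
#' @param derived Output of [derive_biomarkers()] (possibly joined with
#'   diagnosis columns).
#' @param stratifier One of `"sex"`, `"age"`, `"obesity"`, `"glim"`, or
#'   the name of any logical/factor column.
#' @param biomarkers Character vector of numeric columns to summarize.
#' @param age_threshold Age split (years) used when `stratifier =
#'   "age"`; subjects at or above it form the older stratum.
#' @param alpha Gate level for the location test.
#' @return A tibble, one row per (biomarker, stratum), with columns
#'   `biomarker`, `stratum`, `n`, `mean`, `sd`, `median`, `iqr`, `min`,
#'   `max`, `test`, `p_value` (test columns repeated on both rows of a
#'   pair; `NA` when suppressed).
#' @export
stratified_summary <- function(derived, stratifier,
                               biomarkers = c("l3_sma", "l3_smd", "smi_ct",
                                              "smg", "shen_mm",
                                              "mourtzakis_ffm"),
                               age_threshold = 70, alpha = 0.05) {
  stopifnot(is.data.frame(derived))
  group <- switch(
    stratifier,
    sex = factor(ifelse(derived$sex == 1, "male", "female"),
                 levels = c("female", "male")),
    age = factor(ifelse(derived$age >= age_threshold, "older", "younger"),
                 levels = c("younger", "older")),
    obesity = factor(ifelse(is_obese(derived$bmi), "obese", "non-obese"),
                     levels = c("non-obese", "obese")),
    glim = factor(ifelse(
      glim(derived$age, derived$bmi,
           if ("weight_loss_pct" %in% names(derived))
             derived$weight_loss_pct else NA_real_,
           if ("weight_loss_window" %in% names(derived))
             derived$weight_loss_window else NA_real_,
           if ("weight_loss_voluntary" %in% names(derived))
             derived$weight_loss_voluntary else FALSE) != "none",
      "malnourished", "well-nourished"),
      levels = c("well-nourished", "malnourished")),
    {
      if (!stratifier %in% names(derived)) {
        stop("unknown stratifier: ", stratifier, call. = FALSE)
      }
      as.factor(derived[[stratifier]])
    }
  )
  missing_bm <- setdiff(biomarkers, names(derived))
  if (length(missing_bm) > 0) {
    stop("unknown biomarker columns: ", paste(missing_bm, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (bm in biomarkers) {
    x <- derived[[bm]]
    test_name <- NA_character_
    p_value <- NA_real_
    levs <- levels(group)
    if (length(levs) == 2) {
      g1 <- x[group == levs[1] & !is.na(x)]
      g2 <- x[group == levs[2] & !is.na(x)]
      if (length(g1) >= 3 && length(g2) >= 3 &&
          stats::sd(g1) > 0 && stats::sd(g2) > 0) {
        cl <- compare_location(g1, g2, paired = FALSE, alpha = alpha)
        test_name <- cl$test
        p_value <- cl$p_value
      }
    }
    for (lev in levs) {
      xi <- x[group == lev & !is.na(x)]
      n_i <- length(xi)
      suppress <- n_i < 3
      rows[[length(rows) + 1]] <- tibble::tibble(
        biomarker = bm, stratum = lev, n = n_i,
        mean = if (suppress) NA_real_ else mean(xi),
        sd = if (suppress) NA_real_ else stats::sd(xi),
        median = if (suppress) NA_real_ else stats::median(xi),
        iqr = if (suppress) NA_real_ else stats::IQR(xi),
        min = if (suppress) NA_real_ else min(xi),
        max = if (suppress) NA_real_ else max(xi),
        test = test_name, p_value = p_value,
        suppressed = suppress
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Pairwise correlation matrix
#'
#' Symmetric correlation matrix over a set of derived columns with
#' pairwise-complete handling of missing values and a matching matrix
#' of pairwise p-values. Cells with fewer than 3 complete pairs are
#' `NA`.
#'
#' @param derived A data frame.
#' @param variables Character vector of numeric column names.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `r` (correlation matrix), `p` (p-value matrix),
#'   and `n` (complete-pair counts).
#' @export
correlation_matrix <- function(derived, variables,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  missing_v <- setdiff(variables, names(derived))
  if (length(missing_v) > 0) {
    stop("unknown columns: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  k <- length(variables)
  r <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p <- r
  nmat <- matrix(0L, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    nmat[i, i] <- sum(!is.na(derived[[variables[i]]]))
    if (i == k) next
    for (j in seq(i + 1, k)) {
      x <- derived[[variables[i]]]
      y <- derived[[variables[j]]]
      ok <- stats::complete.cases(x, y)
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  list(r = r, p = p, n = nmat)
}

#' Per-pair agreement report
#'
#' For each (reference, index) column pair: Pearson r, Lin's CCC with CI
#' and category, the Bland-Altman fields, and the paired normality-gated
#' location test. Logical pairs (diagnosis flags) are summarized with
#' Cohen's kappa instead.
#'
#' @param data A data frame holding all referenced columns.
#' @param pairs A data frame with columns `reference` and `index`
#'   (column names in `data`).
#' @return A tibble with one row per pair: `reference`, `index`, `n`,
#'   and either the quantitative fields (`pearson_r`, `ccc`, `ccc_low`,
#'   `ccc_high`, `ccc_category`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `slope`, `slope_p`, `n_outside`, `pct_outside`,
#'   `location_test`, `location_p`) or `kappa` and `kappa_p` for
#'   categorical pairs.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 100, seed = 5))
#' derived <- derive_biomarkers(cohort)
#' agreement_report(derived,
#'   pairs = data.frame(reference = "shen_mm", index = "janssen_mm"))
#' @export
agreement_report <- function(data, pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("reference", "index") %in% names(pairs)))
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    ref_name <- pairs$reference[k]
    idx_name <- pairs$index[k]
    for (nm in c(ref_name, idx_name)) {
      if (!nm %in% names(data)) {
        stop("unknown column: ", nm, call. = FALSE)
      }
    }
    ref <- data[[ref_name]]
    idx <- data[[idx_name]]
    categorical <- (is.logical(ref) || is.factor(ref)) &&
      (is.logical(idx) || is.factor(idx))
    if (categorical) {
      kp <- cohen_kappa(ref, idx)
      rows[[k]] <- tibble::tibble(
        reference = ref_name, index = idx_name, type = "categorical",
        n = kp$n, kappa = kp$kappa, kappa_p = kp$p_value
      )
    } else {
      ok <- stats::complete.cases(ref, idx)
      r <- pearson_r(ref[ok], idx[ok])
      cc <- lin_ccc(ref[ok], idx[ok])
      ba <- bland_altman(ref[ok], idx[ok])
      loc <- compare_location(ref[ok], idx[ok], paired = TRUE)
      rows[[k]] <- tibble::tibble(
        reference = ref_name, index = idx_name, type = "quantitative",
        n = sum(ok), pearson_r = r,
        ccc = cc$rho_c, ccc_low = cc$ci_low, ccc_high = cc$ci_high,
        ccc_category = cc$category,
        bias = ba$bias, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        slope = ba$slope, slope_p = ba$slope_p,
        n_outside = ba$n_outside, pct_outside = ba$pct_outside,
        location_test = loc$test, location_p = loc$p_value
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Kappa grid across diagnostic definitions
#'
#' Cohen's kappa for every pair of logical columns in a flags table —
#' the intra-/inter-technique categorical-agreement grid.
#'
#' @param flags A data frame of logical diagnosis columns.
#' @param columns Optional subset of column names.
#' @return A tibble with `definition_a`, `definition_b`, `kappa`,
#'   `p_value`, `n`. Pairs where kappa is undefined (both raters
#'   constant and equal) are reported as `NA`.
#' @export
kappa_grid <- function(flags, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(flags)[vapply(flags, is.logical, logical(1))]
  }
  if (length(columns) < 2) {
    stop("need at least two logical columns", call. = FALSE)
  }
  combs <- utils::combn(columns, 2)
  rows <- apply(combs, 2, function(pair) {
    res <- tryCatch(cohen_kappa(flags[[pair[1]]], flags[[pair[2]]]),
                    error = function(e) NULL)
    tibble::tibble(
      definition_a = pair[1], definition_b = pair[2],
      kappa = if (is.null(res)) NA_real_ else res$kappa,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      n = if (is.null(res)) NA_integer_ else res$n
    )
  })
  dplyr::bind_rows(rows)
}

#' Bland-Altman plot
#'
#' Differences (reference - index) against pairwise means, with the
#' bias and limits of agreement as horizontal lines.
#'
#' @param ba A [bland_altman()] result.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_bland_altman <- function(ba) {
  stopifnot(inherits(ba, "bland_altman_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- tibble::tibble(mean = ba$means, difference = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        colour = "red") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "blue", linewidth = 0.5) +
    ggplot2::labs(x = "Mean of methods", y = "Reference - index")
}
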