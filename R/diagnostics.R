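# Operationalized diagnoses: muscle atrophy, myosteatosis, dynapenia,
# sarcopenia, GLIM malnutrition, BMI categories, and cohort prevalence.
#
# All threshold rules follow the same convention: a value strictly below
# its stratum threshold is abnormal; the boundary value is normal.

#' Classify muscle atrophy against a cut-off set
#'
#' @param value Biomarker values on the scale of the cut-off set (e.g.
#'   SMI-CT in cm^2/m^2, SMI-Janssen in kg/m^2, RF-MT in mm).
#' @param sex,bmi,age Covariates; only those the cut-off set stratifies
#'   by are required. A covariate outside every declared stratum raises
#'   an error rather than silently defaulting.
#' @param cutoffs A [cutoff_set()].
#' @return Logical vector: `TRUE` = atrophy; `NA` where the biomarker or
#'   a needed covariate is missing.
#' @examples
#' dolan <- shipped_cutoff_sets()$dolan_smi
#' classify_atrophy(44, sex = 1, bmi = 24, cutoffs = dolan)
#' @export
classify_atrophy <- function(value, sex = NULL, bmi = NULL, age = NULL,
                             cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  thr <- .match_threshold(cutoffs, sex = sex, bmi = bmi, age = age,
                          n = length(value))
  value < thr
}

#' Classify myosteatosis from muscle radiodensity
#'
#' @param smd Mean skeletal muscle radiodensity at L3, HU.
#' @param bmi BMI in kg/m^2 (the shipped SMD thresholds are BMI-conditional).
#' @param cutoffs A [cutoff_set()] on an SMD biomarker.
#' @return Logical vector: `TRUE` = myosteatosis.
#' @export
classify_myosteatosis <- function(smd, bmi = NULL, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  thr <- .match_threshold(cutoffs, bmi = bmi, n = length(smd))
  smd < thr
}

#' Read a normative handgrip table
#'
#' The dynapenia rule compares maximal handgrip strength to the
#' age/sex-specific 10th percentile of a normative population. No such
#' centile table is bundled from the normative publication; the packaged
#' default (`grip_p10_synthetic.yaml`) is a synthetic placeholder with
#' plausible adult values, intended to be replaced by the user's own
#' table.
#'
#' @param path Path to a YAML table with entries `sex`, `age_min`,
#'   `age_max`, `p10` (kg); `NULL` loads the synthetic default.
#' @return A tibble with columns `sex`, `age_min`, `age_max`, `p10`.
#' @export
read_grip_norms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "grip_p10_synthetic.yaml",
                        package = "morphoagree")
  }
  doc <- yaml::read_yaml(path)
  tab <- dplyr::bind_rows(lapply(doc$rows, tibble::as_tibble))
  stopifnot(all(c("sex", "age_min", "age_max", "p10") %in% names(tab)))
  tab
}

#' Classify dynapenia from handgrip strength
#'
#' Dynapenia is maximal handgrip strength strictly below the age- and
#' sex-specific 10th percentile of a normative table. Age bands are
#' `[age_min, age_max)`.
#'
#' @param hgs Maximal handgrip strength, kg.
#' @param age Age in years.
#' @param sex Sex code, female = 0 / male = 1.
#' @param normative Normative table as returned by [read_grip_norms()].
#' @return Logical vector: `TRUE` = dynapenia; `NA` where an input is
#'   missing. An (age, sex) combination outside the table raises an
#'   error.
#' @export
dynapenia <- function(hgs, age, sex, normative = read_grip_norms()) {
  n <- length(hgs)
  stopifnot(length(age) == n, length(sex) == n)
  out <- rep(NA, n)
  for (i in seq_len(n)) {
    if (is.na(hgs[i]) || is.na(age[i]) || is.na(sex[i])) next
    hit <- normative$sex == sex[i] &
      age[i] >= normative$age_min & age[i] < normative$age_max
    if (sum(hit) == 0) {
      stop(sprintf("no normative handgrip row covers sex=%d, age=%.1f",
                   sex[i], age[i]), call. = FALSE)
    }
    out[i] <- hgs[i] < normative$p10[which(hit)[1]]
  }
  out
}

#' Sarcopenia as atrophy plus dynapenia
#'
#' The conjunction of a muscle-atrophy flag (under any definition) and
#' dynapenia. If either component is unresolved (`NA`) the result is
#' unresolved.
#'
#' @param atrophy,dynapenia Logical vectors.
#' @return Logical vector.
#' @export
sarcopenia <- function(atrophy, dynapenia) {
  ifelse(is.na(atrophy) | is.na(dynapenia), NA, atrophy & dynapenia)
}

#' GLIM malnutrition severity
#'
#' Applies the phenotypic GLIM criteria — involuntary weight loss and
#' low BMI — and returns the worst severity across them. The etiologic
#' criterion is assumed satisfied for every subject (appropriate for a
#' cohort defined by an inflammatory disease); only involuntary weight
#' loss counts. Thresholds: moderate weight loss is >5% within 6 months
#' or >10% beyond 6 months; severe is >10% within 6 months or >20%
#' beyond. Low-BMI moderate is BMI < 20 under age 70 or < 22 at 70 and
#' over; severe is BMI < 18.5 under 70 or < 20 at 70 and over (age
#' exactly 70 is assigned to the older band).
#'
#' @param age Age in years.
#' @param bmi BMI in kg/m^2.
#' @param weight_loss_pct Percent body-weight lost (positive = loss);
#'   `NA` means no reported loss.
#' @param weight_loss_window Months over which the loss occurred.
#' @param weight_loss_voluntary Logical; voluntary loss is ignored.
#' @return Ordered factor with levels `none < moderate < severe`.
#' @examples
#' glim(age = 65, bmi = 19.5)
#' glim(age = 60, bmi = 25, weight_loss_pct = 12, weight_loss_window = 5)
#' @export
glim <- function(age, bmi, weight_loss_pct = NA_real_,
                 weight_loss_window = NA_real_,
                 weight_loss_voluntary = FALSE) {
  n <- max(length(age), length(bmi))
  age <- rep_len(age, n)
  bmi <- rep_len(bmi, n)
  weight_loss_pct <- rep_len(weight_loss_pct, n)
  weight_loss_window <- rep_len(weight_loss_window, n)
  weight_loss_voluntary <- rep_len(weight_loss_voluntary, n)

  sev <- integer(n)  # 0 none, 1 moderate, 2 severe
  older <- !is.na(age) & age >= 70

  # phenotypic: low BMI, age-conditional thresholds
  bmi_mod <- ifelse(older, 22.0, 20.0)
  bmi_sev <- ifelse(older, 20.0, 18.5)
  sev <- pmax(sev, ifelse(!is.na(bmi) & bmi < bmi_mod, 1L, 0L))
  sev <- pmax(sev, ifelse(!is.na(bmi) & bmi < bmi_sev, 2L, 0L))

  # phenotypic: involuntary weight loss
  wl <- weight_loss_pct
  wl[is.na(wl)] <- 0
  vol <- !is.na(weight_loss_voluntary) & weight_loss_voluntary
  wl[vol] <- 0
  win <- weight_loss_window
  recent <- !is.na(win) & win <= 6
  wl_mod <- (recent & wl > 5) | (!recent & wl > 10)
  wl_sev <- (recent & wl > 10) | (!recent & wl > 20)
  sev <- pmax(sev, ifelse(wl_mod, 1L, 0L), ifelse(wl_sev, 2L, 0L))

  factor(c("none", "moderate", "severe")[sev + 1L],
         levels = c("none", "moderate", "severe"), ordered = TRUE)
}

#' WHO BMI category
#'
#' Bands: underweight < 18.5, normal < 25, overweight < 30, obesity
#' grade 1 < 35, grade 2 < 40, grade 3 >= 40. Obesity is BMI >= 30
#' (i.e. any obesity grade).
#'
#' @param bmi BMI in kg/m^2; must be positive.
#' @return Factor with the six WHO bands.
#' @seealso [is_obese()]
#' @export
bmi_category <- function(bmi) {
  .check_positive(bmi, "bmi")
  cut(bmi,
      breaks = c(0, 18.5, 25, 30, 35, 40, Inf),
      labels = c("underweight", "normal", "overweight",
                 "obesity grade 1", "obesity grade 2", "obesity grade 3"),
      right = FALSE)
}

#' Obesity flag
#'
#' @inheritParams bmi_category
#' @return Logical: BMI >= 30.
#' @export
is_obese <- function(bmi) {
  .check_positive(bmi, "bmi")
  bmi >= 30
}

#' Diagnose a derived cohort under every shipped definition
#'
#' Applies each cut-off set to its biomarker column, the dynapenia rule,
#' sarcopenia for every atrophy definition, GLIM, and the BMI bands.
#'
#' @param derived Output of [derive_biomarkers()].
#' @param cutoff_sets Named list of [cutoff_set()] objects; defaults to
#'   [shipped_cutoff_sets()].
#' @param grip_norms Normative table for dynapenia; see
#'   [read_grip_norms()].
#' @return A tibble with `id`, one `atrophy_*`/`myosteatosis_*` column
#'   per applicable cut-off set, `dynapenia`, one `sarcopenia_*` column
#'   per atrophy definition, `glim`, `bmi_category`, `obesity`.
#' @export
diagnose_cohort <- function(derived, cutoff_sets = shipped_cutoff_sets(),
                            grip_norms = read_grip_norms()) {
  stopifnot(is.data.frame(derived), "bmi" %in% names(derived))
  out <- tibble::tibble(id = derived$id)
  col_or_na <- function(nm) {
    if (nm %in% names(derived)) derived[[nm]] else
      rep(NA_real_, nrow(derived))
  }
  for (cs in cutoff_sets) {
    value <- col_or_na(cs$biomarker)
    is_smd <- grepl("smd", cs$biomarker)
    flag <- if (is_smd) {
      classify_myosteatosis(value, bmi = derived$bmi, cutoffs = cs)
    } else {
      classify_atrophy(value, sex = derived$sex, bmi = derived$bmi,
                       age = derived$age, cutoffs = cs)
    }
    prefix <- if (is_smd) "myosteatosis_" else "atrophy_"
    out[[paste0(prefix, cs$name)]] <- flag
  }
  out$dynapenia <- dynapenia(col_or_na("hgs"), derived$age, derived$sex,
                             normative = grip_norms)
  for (nm in grep("^atrophy_", names(out), value = TRUE)) {
    out[[sub("^atrophy_", "sarcopenia_", nm)]] <-
      sarcopenia(out[[nm]], out$dynapenia)
  }
  out$glim <- glim(
    derived$age, derived$bmi,
    weight_loss_pct = col_or_na("weight_loss_pct"),
    weight_loss_window = col_or_na("weight_loss_window"),
    weight_loss_voluntary = if ("weight_loss_voluntary" %in% names(derived))
      derived$weight_loss_voluntary else FALSE
  )
  out$bmi_category <- bmi_category(derived$bmi)
  out$obesity <- is_obese(derived$bmi)
  out
}

#' Prevalence of diagnostic flags over a cohort
#'
#' @param flags A data frame of logical/factor diagnosis columns (e.g.
#'   from [diagnose_cohort()]), or a single logical vector.
#' @return A tibble with `definition`, `n_positive`, `n`, and `pct`
#'   (positives as a percentage of non-missing classifications). For
#'   factor columns each non-reference level is counted as positive.
#' @examples
#' prevalence(c(TRUE, FALSE, FALSE, TRUE, NA))
#' @export
prevalence <- function(flags) {
  if (!is.data.frame(flags)) flags <- tibble::tibble(flag = flags)
  cols <- names(flags)[vapply(flags, function(x)
    is.logical(x) || is.factor(x), logical(1))]
  if (length(cols) == 0 || nrow(flags) == 0) {
    stop("no diagnostic columns (or empty cohort) to summarize",
         call. = FALSE)
  }
  rows <- lapply(cols, function(nm) {
    x <- flags[[nm]]
    pos <- if (is.factor(x)) !is.na(x) & x != levels(x)[1] else x
    n <- sum(!is.na(pos))
    k <- sum(pos, na.rm = TRUE)
    tibble::tibble(definition = nm, n_positive = k, n = n,
                   pct = if (n > 0) 100 * k / n else NA_real_)
  })
  dplyr::bind_rows(rows)
}
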