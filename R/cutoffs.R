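# Covariate-conditional cut-off sets.
#
# A cut-off set is a named table of strata (keyed by sex, BMI, and/or age
# ranges) with one threshold per stratum. All shipped sets use the
# "strictly below threshold = abnormal" convention; boundary values are
# normal. Range semantics are [min, max): a rule's `bmi_min`/`age_min`
# is inclusive and its `bmi_max`/`age_max` exclusive, so adjacent strata
# tile the covariate axis without gap or overlap.

#' Construct a cut-off set
#'
#' @param name Identifier for the set.
#' @param biomarker Name of the derived-biomarker column the thresholds
#'   apply to (e.g. `"smi_ct"`, `"l3_smd"`, `"rf_mt"`).
#' @param rules A data frame with a `threshold` column and any of the
#'   stratum keys `sex` (0/1; omit or `NA` for both sexes), `bmi_min`,
#'   `bmi_max`, `age_min`, `age_max` (omitted bounds are unbounded).
#' @param units Units of the biomarker and thresholds.
#' @param citation Free-text provenance for the thresholds.
#' @param note Optional free-text note (e.g. a synthetic-placeholder flag).
#' @return An object of class `cutoff_set`.
#' @examples
#' cs <- cutoff_set("demo", "smi_ct",
#'   rules = data.frame(sex = c(0, 1), threshold = c(39, 45)))
#' classify_atrophy(c(38, 46), sex = c(0, 1), cutoffs = cs)
#' @export
cutoff_set <- function(name, biomarker, rules, units = NULL,
                       citation = NULL, note = NULL) {
  rules <- tibble::as_tibble(rules)
  if (!"threshold" %in% names(rules) || nrow(rules) == 0) {
    stop("`rules` must be a non-empty data frame with a `threshold` column",
         call. = FALSE)
  }
  for (col in c("sex", "bmi_min", "bmi_max", "age_min", "age_max")) {
    if (!col %in% names(rules)) rules[[col]] <- NA_real_
  }
  rules$bmi_min[is.na(rules$bmi_min)] <- -Inf
  rules$bmi_max[is.na(rules$bmi_max)] <- Inf
  rules$age_min[is.na(rules$age_min)] <- -Inf
  rules$age_max[is.na(rules$age_max)] <- Inf
  if (any(!is.na(rules$sex) & !rules$sex %in% c(0, 1))) {
    stop("rule `sex` must be 0, 1, or NA (both)", call. = FALSE)
  }
  out <- structure(
    list(name = name, biomarker = biomarker, rules = rules,
         direction = "below", units = units, citation = citation,
         note = note),
    class = "cutoff_set"
  )
  .check_strata_disjoint(out)
  out
}

# Overlapping strata would make the matched threshold order-dependent;
# reject them at construction.
.check_strata_disjoint <- function(cs) {
  r <- cs$rules
  n <- nrow(r)
  if (n < 2) return(invisible(cs))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sex_overlap <- is.na(r$sex[i]) || is.na(r$sex[j]) ||
        r$sex[i] == r$sex[j]
      bmi_overlap <- r$bmi_min[i] < r$bmi_max[j] && r$bmi_min[j] < r$bmi_max[i]
      age_overlap <- r$age_min[i] < r$age_max[j] && r$age_min[j] < r$age_max[i]
      if (sex_overlap && bmi_overlap && age_overlap) {
        stop(sprintf("cut-off set '%s': rules %d and %d overlap", cs$name,
                     i, j), call. = FALSE)
      }
    }
  }
  invisible(cs)
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("Cut-off set '%s' on %s (abnormal = strictly below)\n",
              x$name, x$biomarker))
  if (!is.null(x$citation)) cat("  source:", x$citation, "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  print(x$rules, ...)
  invisible(x)
}

#' Read a cut-off set from a YAML file
#'
#' @param path Path to a YAML document with fields `name`, `biomarker`,
#'   `rules` (a list of stratum maps), and optionally `units`,
#'   `citation`, `note`.
#' @return A [cutoff_set()] object.
#' @export
read_cutoff_set <- function(path) {
  doc <- yaml::read_yaml(path)
  rules <- dplyr::bind_rows(lapply(doc$rules, tibble::as_tibble))
  cutoff_set(doc$name, doc$biomarker, rules, units = doc$units,
             citation = doc$citation, note = doc$note)
}

#' Cut-off sets shipped with the package
#'
#' Loads every YAML cut-off configuration under the package's
#' `extdata/cutoffs` directory: CT atrophy (Dolan SMI-CT), CT
#' myosteatosis (Dolan SMD), BIA atrophy (Masanes and European
#' SMI-Janssen), ultrasound atrophy (DRECO RF-MT and RF-CSA), plus a
#' synthetic placeholder standing in for externally sourced SMI
#' thresholds. Users can point individual analyses at their own files
#' via [read_cutoff_set()].
#'
#' @return A named list of [cutoff_set()] objects.
#' @export
shipped_cutoff_sets <- function() {
  dir <- system.file("extdata", "cutoffs", package = "morphoagree")
  paths <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  sets <- lapply(paths, read_cutoff_set)
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

# Matches each observation to exactly one rule; returns threshold vector.
.match_threshold <- function(cs, sex = NULL, bmi = NULL, age = NULL, n) {
  r <- cs$rules
  uses_sex <- any(!is.na(r$sex))
  uses_bmi <- any(is.finite(r$bmi_min) | is.finite(r$bmi_max))
  uses_age <- any(is.finite(r$age_min) | is.finite(r$age_max))
  if (uses_sex && is.null(sex)) {
    stop(sprintf("cut-off set '%s' stratifies by sex; supply `sex`",
                 cs$name), call. = FALSE)
  }
  if (uses_bmi && is.null(bmi)) {
    stop(sprintf("cut-off set '%s' stratifies by BMI; supply `bmi`",
                 cs$name), call. = FALSE)
  }
  if (uses_age && is.null(age)) {
    stop(sprintf("cut-off set '%s' stratifies by age; supply `age`",
                 cs$name), call. = FALSE)
  }
  if (is.null(sex)) sex <- rep(NA_real_, n)
  if (is.null(bmi)) bmi <- rep(NA_real_, n)
  if (is.null(age)) age <- rep(NA_real_, n)
  thr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    covar_missing <- (uses_sex && is.na(sex[i])) ||
      (uses_bmi && is.na(bmi[i])) || (uses_age && is.na(age[i]))
    if (covar_missing) next
    hit <- (is.na(r$sex) | (!is.na(sex[i]) & r$sex == sex[i])) &
      (is.na(bmi[i]) | (bmi[i] >= r$bmi_min & bmi[i] < r$bmi_max)) &
      (is.na(age[i]) | (age[i] >= r$age_min & age[i] < r$age_max))
    hit[is.na(hit)] <- FALSE
    if (sum(hit) == 0) {
      stop(sprintf(
        "cut-off set '%s': no stratum covers sex=%s, BMI=%s, age=%s",
        cs$name, format(sex[i]), format(bmi[i]), format(age[i])),
        call. = FALSE)
    }
    thr[i] <- r$threshold[which(hit)[1]]
  }
  thr
}
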