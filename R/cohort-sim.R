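# Synthetic cohort generator.
#
# A single latent "muscularity" factor M ~ N(0, 1) per subject drives
# every muscle channel: the CT muscle area, ultrasound thicknesses, and
# handgrip load positively on M, BIA resistance loads negatively, and
# muscle radiodensity declines with age and BMI. This is the minimal
# structure that reproduces the sign pattern seen in multi-technique
# morphofunctional studies (resistance inversely correlated with muscle
# area, phase angle positively with strength); it is a testing device,
# not a model of any real cohort.

#' Specification for a synthetic cohort
#'
#' Defaults emulate an older oncology outpatient cohort: n = 156, 48.1%
#' female, ages on \[50, 90) with median ~65, median BMI ~27.3 kg/m^2,
#' mean L3-SMA ~126 cm^2 with a marked sex difference, and BIA/US/HGS
#' channels tied to the shared latent factor.
#'
#' @param n Number of subjects.
#' @param female_fraction Probability a subject is female.
#' @param age_shape,age_scale,age_min,age_max Shifted-gamma age model:
#'   age = `age_min` + Gamma(shape, scale), truncated at `age_max`.
#' @param height_mean_f,height_mean_m,height_sd Sex-specific height
#'   distributions, metres.
#' @param bmi_meanlog,bmi_sdlog Log-normal BMI model, kg/m^2.
#' @param latent_mean Mean of the latent muscularity factor M; raising
#'   it shifts every muscle channel up (and atrophy prevalence down).
#' @param sma_base,sma_sex,sma_weight,sma_latent,sma_sd L3-SMA channel:
#'   base + sex effect + weight slope (about 75 kg) + latent loading +
#'   Gaussian noise, cm^2.
#' @param smd_base,smd_age,smd_bmi,smd_latent,smd_sd Radiodensity
#'   channel (HU), with age (about 65 y) and BMI (about 27.3) slopes.
#' @param rz_base,rz_sex,rz_latent,rz_weight,rz_sd Resistance channel
#'   (ohm), decreasing in muscularity and weight.
#' @param xc_base,xc_rz,xc_latent,xc_sd Reactance channel (ohm), tied to
#'   resistance and the latent factor; phase angle and impedance are
#'   derived as theta = atan(Xc/Rz) in degrees and Z = sqrt(Rz^2 + Xc^2)
#'   so the raw BIA quartet stays internally consistent.
#' @param hgs_base,hgs_sex,hgs_latent,hgs_age,hgs_sd Handgrip channel, kg.
#' @param rf_mt_base,rf_mt_sex,rf_mt_latent,rf_mt_weight,rf_mt_sd
#'   Rectus-femoris thickness channel, mm.
#' @param quad_mt_base,quad_mt_sex,quad_mt_latent,quad_mt_weight,quad_mt_sd
#'   Whole-quadriceps thickness channel, mm.
#' @param rf_csa_base,rf_csa_sex,rf_csa_latent,rf_csa_weight,rf_csa_sd
#'   Rectus-femoris area channel, cm^2.
#' @param missing_rate Per-channel probability that an optional
#'   measurement is missing (uniform at random).
#' @param seed Integer seed making generation deterministic.
#' @return A `cohort_spec` object (a validated named list).
#' @examples
#' spec <- cohort_spec(n = 50, seed = 42)
#' cohort <- generate_cohort(spec)
#' @export
cohort_spec <- function(n = 156,
                        female_fraction = 0.481,
                        age_shape = 3, age_scale = 5.5,
                        age_min = 50, age_max = 90,
                        height_mean_f = 1.58, height_mean_m = 1.70,
                        height_sd = 0.06,
                        bmi_meanlog = log(27.3), bmi_sdlog = 0.155,
                        latent_mean = 0,
                        sma_base = 105.8, sma_sex = 38, sma_weight = 0.45,
                        sma_latent = 12, sma_sd = 8,
                        smd_base = 40.7, smd_age = -0.25, smd_bmi = -0.4,
                        smd_latent = 2, smd_sd = 6,
                        rz_base = 560, rz_sex = -35, rz_latent = -28,
                        rz_weight = -1.2, rz_sd = 30,
                        xc_base = 1, xc_rz = 0.09, xc_latent = 2.5,
                        xc_sd = 2,
                        hgs_base = 29, hgs_sex = 11, hgs_latent = 5.5,
                        hgs_age = -0.25, hgs_sd = 5,
                        rf_mt_base = 12.9, rf_mt_sex = 2.4,
                        rf_mt_latent = 1.8, rf_mt_weight = 0.08,
                        rf_mt_sd = 1.5,
                        quad_mt_base = 25.5, quad_mt_sex = 5,
                        quad_mt_latent = 3.5, quad_mt_weight = 0.18,
                        quad_mt_sd = 3,
                        rf_csa_base = 3.9, rf_csa_sex = 0.9,
                        rf_csa_latent = 0.55, rf_csa_weight = 0.02,
                        rf_csa_sd = 0.5,
                        missing_rate = 0,
                        seed = 1L) {
  spec <- as.list(environment())
  if (spec$n < 0) stop("`n` must be >= 0", call. = FALSE)
  if (spec$female_fraction < 0 || spec$female_fraction > 1) {
    stop("`female_fraction` must be in [0, 1]", call. = FALSE)
  }
  sds <- c("sma_sd", "smd_sd", "rz_sd", "xc_sd", "hgs_sd", "rf_mt_sd",
           "quad_mt_sd", "rf_csa_sd", "height_sd")
  if (any(unlist(spec[sds]) < 0)) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (spec$missing_rate < 0 || spec$missing_rate > 1) {
    stop("`missing_rate` must be in [0, 1]", call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

#' Write / read a cohort specification
#'
#' @param spec A [cohort_spec()].
#' @param path YAML file path.
#' @return `read_cohort_spec()` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  # precision 17 so doubles round-trip exactly (bit-identical cohorts)
  yaml::write_yaml(unclass(spec), path, precision = 17)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  do.call(cohort_spec, yaml::read_yaml(path))
}

#' Generate a synthetic cohort
#'
#' Draws `spec$n` subject records as a deterministic function of
#' `(spec, spec$seed)`. All records satisfy the subject-record
#' invariants: positive heights, weights, resistive quantities and
#' thicknesses, radiodensity clamped to the segmentation window
#' \[-29, 150\] HU.
#'
#' @param spec A [cohort_spec()].
#' @return A cohort tibble, one row per subject, with the raw
#'   measurement columns (`id`, `sex`, `age`, `height`, `weight`,
#'   `l3_sma`, `l3_smd`, `rz`, `xc`, `z`, `theta`, `rf_mt`, `quad_mt`,
#'   `rf_csa`, `hgs`, and empty GLIM weight-history columns).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  if (n == 0) {
    return(validate_cohort(.empty_cohort()))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  sex <- stats::rbinom(n, 1, 1 - spec$female_fraction)  # 1 = male
  age <- spec$age_min + stats::rgamma(n, shape = spec$age_shape,
                                      scale = spec$age_scale)
  age <- pmin(age, spec$age_max)
  height <- stats::rnorm(n,
                         ifelse(sex == 1, spec$height_mean_m,
                                spec$height_mean_f),
                         spec$height_sd)
  height <- pmax(height, 1.30)
  bmi_val <- stats::rlnorm(n, spec$bmi_meanlog, spec$bmi_sdlog)
  weight <- bmi_val * height^2
  m <- stats::rnorm(n, spec$latent_mean, 1)

  l3_sma <- spec$sma_base + spec$sma_sex * sex +
    spec$sma_weight * (weight - 75) + spec$sma_latent * m +
    stats::rnorm(n, 0, spec$sma_sd)
  l3_sma <- pmax(l3_sma, 30)
  l3_smd <- spec$smd_base + spec$smd_age * (age - 65) +
    spec$smd_bmi * (bmi_val - 27.3) + spec$smd_latent * m +
    stats::rnorm(n, 0, spec$smd_sd)
  l3_smd <- pmin(pmax(l3_smd, -29), 150)
  rz <- spec$rz_base + spec$rz_sex * sex + spec$rz_latent * m +
    spec$rz_weight * (weight - 75) + stats::rnorm(n, 0, spec$rz_sd)
  rz <- pmax(rz, 200)
  xc <- spec$xc_base + spec$xc_rz * rz + spec$xc_latent * m +
    stats::rnorm(n, 0, spec$xc_sd)
  xc <- pmax(xc, 5)
  theta <- atan2(xc, rz) * 180 / pi
  z <- sqrt(rz^2 + xc^2)
  hgs <- spec$hgs_base + spec$hgs_sex * sex + spec$hgs_latent * m +
    spec$hgs_age * (age - 65) + stats::rnorm(n, 0, spec$hgs_sd)
  hgs <- pmax(hgs, 2)
  rf_mt <- spec$rf_mt_base + spec$rf_mt_sex * sex +
    spec$rf_mt_latent * m + spec$rf_mt_weight * (weight - 75) +
    stats::rnorm(n, 0, spec$rf_mt_sd)
  rf_mt <- pmax(rf_mt, 2)
  quad_mt <- spec$quad_mt_base + spec$quad_mt_sex * sex +
    spec$quad_mt_latent * m + spec$quad_mt_weight * (weight - 75) +
    stats::rnorm(n, 0, spec$quad_mt_sd)
  quad_mt <- pmax(quad_mt, 4)
  rf_csa <- spec$rf_csa_base + spec$rf_csa_sex * sex +
    spec$rf_csa_latent * m + spec$rf_csa_weight * (weight - 75) +
    stats::rnorm(n, 0, spec$rf_csa_sd)
  rf_csa <- pmax(rf_csa, 0.5)

  cohort <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    age = age,
    height = height,
    weight = weight,
    l3_sma = l3_sma,
    l3_smd = l3_smd,
    rz = rz,
    xc = xc,
    z = z,
    theta = theta,
    rf_mt = rf_mt,
    quad_mt = quad_mt,
    rf_csa = rf_csa,
    hgs = hgs,
    weight_loss_pct = NA_real_,
    weight_loss_window = NA_real_,
    weight_loss_voluntary = NA
  )
  if (spec$missing_rate > 0) {
    optional <- c("l3_sma", "l3_smd", "rz", "xc", "z", "theta", "rf_mt",
                  "quad_mt", "rf_csa", "hgs")
    for (col in optional) {
      drop <- stats::runif(n) < spec$missing_rate
      cohort[[col]][drop] <- NA_real_
    }
  }
  validate_cohort(cohort)
}

.empty_cohort <- function() {
  tibble::tibble(
    id = character(), sex = numeric(), age = numeric(), height = numeric(),
    weight = numeric(), l3_sma = numeric(), l3_smd = numeric(),
    rz = numeric(), xc = numeric(), z = numeric(), theta = numeric(),
    rf_mt = numeric(), quad_mt = numeric(), rf_csa = numeric(),
    hgs = numeric(), weight_loss_pct = numeric(),
    weight_loss_window = numeric(), weight_loss_voluntary = logical()
  )
}

#' Add a paired measurement channel with known bias and noise
#'
#' Creates a new column equal to an existing one plus a fixed additive
#' bias and Gaussian noise — the ground-truth construction used in
#' Bland-Altman parameter-recovery experiments.
#'
#' @param cohort A cohort tibble.
#' @param source_field Name of the column to copy.
#' @param new_field Name of the new column.
#' @param bias Additive offset.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed Integer seed.
#' @return The cohort with the new column appended.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 20, seed = 3))
#' cohort <- make_paired_channel(cohort, "hgs", "hgs2", bias = 1, noise_sd = 0.5, seed = 4)
#' @export
make_paired_channel <- function(cohort, source_field, new_field,
                                bias = 0, noise_sd = 0, seed = 1L) {
  if (!source_field %in% names(cohort)) {
    stop("source field '", source_field, "' not present", call. = FALSE)
  }
  if (anyNA(cohort[[source_field]])) {
    stop("source field '", source_field, "' has missing values",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  cohort[[new_field]] <- cohort[[source_field]] + bias +
    stats::rnorm(nrow(cohort), 0, noise_sd)
  cohort
}
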