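# Body-composition prediction equations.
#
# Unit conventions are canonical across the package: height is stored in
# metres, muscle thicknesses in millimetres, areas in cm^2, masses in kg,
# resistive quantities in ohm, radiodensity in Hounsfield units. Each
# equation adapter performs its own declared conversion (cm where the
# source publication used cm, cm from mm for the quadriceps thickness) so
# the conversions are testable in isolation. Sex is coded female = 0,
# male = 1 everywhere.

.check_positive <- function(x, name) {
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    stop(sprintf("`%s` must be > 0 (offending value: %g)", name, x[bad][1]),
         call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  bad <- !is.na(x) & x < 0
  if (any(bad)) {
    stop(sprintf("`%s` must be >= 0 (offending value: %g)", name, x[bad][1]),
         call. = FALSE)
  }
  invisible(x)
}

.check_sex <- function(sex) {
  bad <- !is.na(sex) & !(sex %in% c(0, 1))
  if (any(bad)) {
    stop("`sex` must be coded female = 0, male = 1", call. = FALSE)
  }
  invisible(sex)
}

#' Body mass index
#'
#' @param weight Body weight in kg; must be positive.
#' @param height Standing height in metres; must be positive.
#' @return BMI in kg/m^2.
#' @examples
#' bmi(80, 2.0)
#' @export
bmi <- function(weight, height) {
  .check_positive(weight, "weight")
  .check_positive(height, "height")
  weight / height^2
}

#' Height-indexed muscle quantity (skeletal muscle index)
#'
#' Divides a muscle area (cm^2) or mass (kg) by height squared, giving
#' SMI-CT (cm^2/m^2) from L3-SMA or a mass-based SMI (kg/m^2) from a
#' whole-body estimate.
#'
#' @param value Muscle area (cm^2) or mass (kg); non-negative.
#' @param height Height in metres; must be positive.
#' @return The value divided by height squared.
#' @export
smi <- function(value, height) {
  .check_positive(height, "height")
  value / height^2
}

#' Skeletal muscle gauge
#'
#' The product of the CT skeletal muscle index (cm^2/m^2) and the mean
#' muscle radiodensity (HU), a combined quantity-quality index in
#' arbitrary units. Note that the cohort mean SMG is not the product of
#' the mean SMI and the mean SMD.
#'
#' @param smi_ct CT skeletal muscle index, cm^2/m^2.
#' @param smd Mean skeletal muscle radiodensity, HU.
#' @return SMG in arbitrary units.
#' @export
smg <- function(smi_ct, smd) {
  smi_ct * smd
}

#' Whole-body muscle mass from L3 muscle area (Shen)
#'
#' MM (kg) = (0.166 x L3-SMA + 2.142) x 1.06. Linear in the muscle area,
#' so cohort means and medians map through the equation exactly.
#'
#' @param l3_sma Skeletal muscle cross-sectional area at L3, cm^2;
#'   non-negative.
#' @return Estimated whole-body muscle mass, kg.
#' @examples
#' shen_mm(125.8)
#' @export
shen_mm <- function(l3_sma) {
  .check_nonneg(l3_sma, "l3_sma")
  (0.166 * l3_sma + 2.142) * 1.06
}

#' Whole-body fat-free mass from L3 muscle area (Mourtzakis)
#'
#' FFM (kg) = 0.30 x L3-SMA + 6.06.
#'
#' @inheritParams shen_mm
#' @return Estimated fat-free mass, kg.
#' @export
mourtzakis_ffm <- function(l3_sma) {
  .check_nonneg(l3_sma, "l3_sma")
  0.30 * l3_sma + 6.06
}

#' Whole-body muscle mass from BIA resistance (Janssen)
#'
#' MM (kg) = 5.102 + 0.401 x (H^2/R) + 3.825 x S - 0.071 x A, with height
#' H in centimetres (the unit of the source publication; only cm yields
#' adult-range masses), resistance R in ohm at 50 kHz, sex S coded
#' female = 0 / male = 1, and age A in years.
#'
#' @param height_cm Height in centimetres; positive.
#' @param resistance BIA resistance R_z at 50 kHz, ohm; positive.
#' @param sex Sex code, female = 0 / male = 1.
#' @param age Age in years; non-negative.
#' @return Estimated whole-body muscle mass, kg.
#' @examples
#' janssen_mm(170, 500, 1, 60)
#' @export
janssen_mm <- function(height_cm, resistance, sex, age) {
  .check_positive(height_cm, "height_cm")
  .check_positive(resistance, "resistance")
  .check_sex(sex)
  .check_nonneg(age, "age")
  5.102 + 0.401 * (height_cm^2 / resistance) + 3.825 * sex - 0.071 * age
}

#' Fat-free mass from BIA resistance and reactance (Kanellakis)
#'
#' FFM (kg) = 12.299 + 0.164 x W + 7.287 x S - 0.116 x (R_z/H)
#' + 0.365 x (X_c/H^2) + 21.570 x H, with height H in metres throughout.
#'
#' @param weight Weight, kg; positive.
#' @param sex Sex code, female = 0 / male = 1.
#' @param rz Resistance at 50 kHz, ohm; positive.
#' @param xc Capacitive reactance at 50 kHz, ohm; non-negative.
#' @param height_m Height in metres; positive.
#' @return Estimated fat-free mass, kg.
#' @export
kanellakis_ffm <- function(weight, sex, rz, xc, height_m) {
  .check_positive(weight, "weight")
  .check_sex(sex)
  .check_positive(rz, "rz")
  .check_nonneg(xc, "xc")
  .check_positive(height_m, "height_m")
  12.299 + 0.164 * weight + 7.287 * sex - 0.116 * (rz / height_m) +
    0.365 * (xc / height_m^2) + 21.570 * height_m
}

#' Fat-free mass from BIA impedance (Kotler)
#'
#' FFM (kg) = 0.88 x ((H^2.24 / Z^0.63) x (1.0/37.63)) + 0.16 x W - 3.96,
#' with height H in centimetres and impedance Z in ohm. The source
#' publication gives sex-specific coefficients; this single form is the
#' one used for both sexes here.
#'
#' @param height_cm Height in centimetres; positive.
#' @param impedance Impedance Z at 50 kHz, ohm; positive.
#' @param weight Weight, kg; non-negative.
#' @return Estimated fat-free mass, kg.
#' @export
kotler_ffm <- function(height_cm, impedance, weight) {
  .check_positive(height_cm, "height_cm")
  .check_positive(impedance, "impedance")
  .check_nonneg(weight, "weight")
  0.88 * ((height_cm^2.24 / impedance^0.63) * (1.0 / 37.63)) +
    0.16 * weight - 3.96
}

#' Estimated L3 muscle area from ultrasound (USVALID / Fischer)
#'
#' L3-SMA (cm^2) = -54.0 + 21.0 x S + 0.4 x W + 0.6 x H + 15.0 x Q, with
#' height H in centimetres and quadriceps muscle thickness Q in
#' centimetres.
#'
#' @param sex Sex code, female = 0 / male = 1.
#' @param weight Weight, kg; non-negative.
#' @param height_cm Height in centimetres; non-negative.
#' @param quad_mt_cm Quadriceps (rectus femoris plus vastus intermedius)
#'   thickness in centimetres; non-negative.
#' @return Estimated L3 skeletal muscle area, cm^2.
#' @export
fischer_sma <- function(sex, weight, height_cm, quad_mt_cm) {
  .check_sex(sex)
  .check_nonneg(weight, "weight")
  .check_nonneg(height_cm, "height_cm")
  .check_nonneg(quad_mt_cm, "quad_mt_cm")
  -54.0 + 21.0 * sex + 0.4 * weight + 0.6 * height_cm + 15.0 * quad_mt_cm
}

#' Estimated L3 muscle area from ultrasound (cohort-refitted model)
#'
#' L3-SMA (cm^2) = -74.04 + 12.03 x Q + 0.56 x W + 0.70 x H + 18.86 x S,
#' the refitted form of the ultrasound regression with Q in centimetres
#' and H in centimetres.
#'
#' @inheritParams fischer_sma
#' @return Estimated L3 skeletal muscle area, cm^2.
#' @export
newmodel_sma <- function(sex, weight, height_cm, quad_mt_cm) {
  .check_sex(sex)
  .check_nonneg(weight, "weight")
  .check_nonneg(height_cm, "height_cm")
  .check_nonneg(quad_mt_cm, "quad_mt_cm")
  -74.04 + 12.03 * quad_mt_cm + 0.56 * weight + 0.70 * height_cm +
    18.86 * sex
}

#' Derive all biomarkers for a cohort
#'
#' Evaluates every prediction equation and derived index on a validated
#' cohort table. A derived column is `NA` exactly where one of its
#' required inputs is missing; missing inputs are never zero-filled.
#'
#' @param cohort A cohort tibble with the subject-record columns (see
#'   [read_cohort()]); must pass [validate_cohort()].
#' @return The cohort with derived columns appended: `bmi`, `smi_ct`,
#'   `smg`, `shen_mm`, `smi_shen`, `mourtzakis_ffm`, `janssen_mm`,
#'   `smi_janssen`, `kanellakis_ffm`, `kotler_ffm`, `fischer_sma`,
#'   `newmodel_sma`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 10, seed = 1))
#' derived <- derive_biomarkers(cohort)
#' @export
derive_biomarkers <- function(cohort) {
  cohort <- validate_cohort(cohort)
  h_m <- cohort$height
  h_cm <- h_m * 100
  opt <- function(nm) if (nm %in% names(cohort)) cohort[[nm]] else NA_real_
  l3_sma <- opt("l3_sma")
  l3_smd <- opt("l3_smd")
  rz <- opt("rz")
  xc <- opt("xc")
  z <- opt("z")
  quad_cm <- opt("quad_mt") / 10   # stored mm -> equation cm

  out <- dplyr::mutate(
    tibble::as_tibble(cohort),
    bmi = bmi(.data$weight, h_m),
    smi_ct = smi(l3_sma, h_m),
    smg = smg(.data$smi_ct, l3_smd),
    shen_mm = shen_mm(l3_sma),
    smi_shen = smi(.data$shen_mm, h_m),
    mourtzakis_ffm = mourtzakis_ffm(l3_sma),
    janssen_mm = janssen_mm(h_cm, rz, .data$sex, .data$age),
    smi_janssen = smi(.data$janssen_mm, h_m),
    kanellakis_ffm = kanellakis_ffm(.data$weight, .data$sex, rz, xc, h_m),
    kotler_ffm = kotler_ffm(h_cm, z, .data$weight),
    fischer_sma = fischer_sma(.data$sex, .data$weight, h_cm, quad_cm),
    newmodel_sma = newmodel_sma(.data$sex, .data$weight, h_cm, quad_cm)
  )
  out
}

#' Equation registry
#'
#' Reads the machine-readable registry of prediction equations shipped
#' with the package (name, coefficients, unit conventions), so new linear
#' equations can be inspected or added without code changes.
#'
#' @param path Optional path to a replacement YAML registry.
#' @return A named list, one entry per equation.
#' @export
equation_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "equations.yaml", package = "morphoagree")
  }
  yaml::read_yaml(path)
}
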