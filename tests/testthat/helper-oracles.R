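# Independent oracles used across test files. These deliberately avoid
# the package's own code paths.

# Direct kappa from a 2x2 table of counts [[a, b], [c, d]] (rows = rater
# 1, cols = rater 2).
kappa_oracle_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# Expand a 2x2 count table into paired label vectors.
labels_from_2x2 <- function(a, b, c, d) {
  r1 <- c(rep("pos", a + b), rep("neg", c + d))
  r2 <- c(rep("pos", a), rep("neg", b), rep("pos", c), rep("neg", d))
  list(a = r1, b = r2)
}

# CCC from its definitional formula, population moments, no shared code.
ccc_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# Brute-force classifier for a cutoff_set: scan every rule with plain
# loops and nested conditions, independent of the engine's matching.
classify_oracle <- function(cs, value, sex, bmi, age) {
  r <- cs$rules
  for (i in seq_len(nrow(r))) {
    sex_ok <- is.na(r$sex[i]) || (!is.na(sex) && r$sex[i] == sex)
    bmi_ok <- is.na(bmi) || (bmi >= r$bmi_min[i] && bmi < r$bmi_max[i])
    age_ok <- is.na(age) || (age >= r$age_min[i] && age < r$age_max[i])
    if (sex_ok && bmi_ok && age_ok) return(value < r$threshold[i])
  }
  NA
}

# A small fully observed cohort for pipeline tests.
tiny_cohort <- function(n = 40, seed = 99) {
  generate_cohort(cohort_spec(n = n, seed = seed))
}
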