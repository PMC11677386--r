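# Diagnostic rule engine: shipped thresholds, strictly-below decision
# rule, GLIM severity, BMI bands, prevalence arithmetic, and the
# brute-force truth-table equivalence property.

sets <- shipped_cutoff_sets()

test_that("CT atrophy thresholds stratify by sex and BMI", {
  dolan <- sets$dolan_smi
  expect_true(classify_atrophy(44.0, sex = 1, bmi = 24, cutoffs = dolan))
  expect_true(classify_atrophy(44.0, sex = 1, bmi = 26, cutoffs = dolan))
  expect_false(classify_atrophy(46.0, sex = 1, bmi = 24, cutoffs = dolan))
  expect_true(classify_atrophy(40.0, sex = 0, bmi = 26, cutoffs = dolan))
  expect_false(classify_atrophy(40.0, sex = 0, bmi = 24, cutoffs = dolan))
})

test_that("BIA atrophy thresholds use the strictly-below rule", {
  mas <- sets$masanes_smi_janssen
  expect_false(classify_atrophy(8.31, sex = 1, cutoffs = mas))
  expect_true(classify_atrophy(8.30, sex = 1, cutoffs = mas))
  eur <- sets$european_smi_janssen
  expect_true(classify_atrophy(5.49, sex = 0, cutoffs = eur))
  expect_false(classify_atrophy(5.50, sex = 0, cutoffs = eur))
})

test_that("ultrasound thresholds are applied as shipped", {
  expect_true(classify_atrophy(9.5, sex = 1, cutoffs = sets$dreco_rf_mt))
  expect_false(classify_atrophy(10.0, sex = 1, cutoffs = sets$dreco_rf_mt))
  expect_true(classify_atrophy(10.0, sex = 0, cutoffs = sets$dreco_rf_mt))
  expect_true(classify_atrophy(2.3, sex = 0, cutoffs = sets$dreco_rf_csa))
  expect_false(classify_atrophy(3.0, sex = 0, cutoffs = sets$dreco_rf_csa))
})

test_that("myosteatosis thresholds are BMI-conditional", {
  smd <- sets$dolan_smd
  expect_true(classify_myosteatosis(33, bmi = 24, cutoffs = smd))
  expect_false(classify_myosteatosis(33, bmi = 26, cutoffs = smd))
  expect_true(classify_myosteatosis(31, bmi = 26, cutoffs = smd))
})

test_that("uncovered covariates raise an unclassifiable error, never a default", {
  cs <- cutoff_set("partial", "smi_ct",
                   rules = data.frame(sex = 1, threshold = 45))
  expect_error(classify_atrophy(44, sex = 0, cutoffs = cs), "no stratum")
  expect_error(classify_atrophy(44, cutoffs = sets$dolan_smi),
               "stratifies by sex")
})

test_that("overlapping strata are rejected at construction", {
  expect_error(
    cutoff_set("bad", "smi_ct",
               rules = data.frame(sex = c(1, 1), bmi_min = c(NA, 20),
                                  threshold = c(45, 50))),
    "overlap")
})

test_that("dynapenia compares handgrip against the normative 10th centile", {
  norms <- tibble::tibble(sex = c(1, 0), age_min = 50, age_max = 91,
                          p10 = c(28, 17))
  expect_true(dynapenia(27, 60, 1, norms))
  expect_false(dynapenia(28, 60, 1, norms))   # strict inequality
  expect_true(dynapenia(16.9, 70, 0, norms))
  expect_error(dynapenia(30, 95, 1, norms), "no normative")
  shipped <- read_grip_norms()
  expect_true(all(c("sex", "age_min", "age_max", "p10") %in%
                    names(shipped)))
})

test_that("sarcopenia is the conjunction of atrophy and dynapenia", {
  expect_equal(sarcopenia(c(TRUE, TRUE, FALSE, NA),
                          c(TRUE, FALSE, TRUE, TRUE)),
               c(TRUE, FALSE, FALSE, NA))
  expect_true(is.na(sarcopenia(TRUE, NA)))
})

test_that("GLIM severity follows the weight-loss and BMI phenotypic rules", {
  expect_equal(as.character(glim(age = 65, bmi = 19.5)), "moderate")
  expect_equal(as.character(glim(age = 75, bmi = 19.8)), "severe")
  expect_equal(as.character(
    glim(age = 60, bmi = 25, weight_loss_pct = 12,
         weight_loss_window = 5)), "severe")
  expect_equal(as.character(
    glim(age = 60, bmi = 25, weight_loss_pct = 12, weight_loss_window = 5,
         weight_loss_voluntary = TRUE)), "none")
  expect_equal(as.character(
    glim(age = 60, bmi = 25, weight_loss_pct = 7,
         weight_loss_window = 4)), "moderate")
  expect_equal(as.character(
    glim(age = 60, bmi = 25, weight_loss_pct = 15,
         weight_loss_window = 12)), "moderate")
  expect_equal(as.character(
    glim(age = 60, bmi = 25, weight_loss_pct = 22,
         weight_loss_window = 12)), "severe")
  # age exactly 70 falls in the older band
  expect_equal(as.character(glim(age = 70, bmi = 21.5)), "moderate")
})

test_that("any GLIM-severe input also satisfies the moderate predicate", {
  grid <- expand.grid(age = c(55, 69.9, 70, 85),
                      bmi = seq(16, 30, by = 0.5),
                      wl = c(NA, 0, 6, 11, 21),
                      win = c(3, 9))
  moderate_pred <- function(age, bmi, wl, win) {
    bmi_thr <- if (age >= 70) 22 else 20
    wl <- ifelse(is.na(wl), 0, wl)
    bmi < bmi_thr || (win <= 6 && wl > 5) || (win > 6 && wl > 10)
  }
  sev <- glim(grid$age, grid$bmi, grid$wl, grid$win)
  for (i in which(sev == "severe")) {
    expect_true(moderate_pred(grid$age[i], grid$bmi[i], grid$wl[i],
                              grid$win[i]))
  }
})

test_that("BMI bands and the obesity flag follow WHO breakpoints", {
  expect_equal(as.character(bmi_category(27.3)), "overweight")
  expect_equal(as.character(bmi_category(30.0)), "obesity grade 1")
  expect_equal(as.character(bmi_category(18.0)), "underweight")
  expect_equal(as.character(bmi_category(c(18.5, 25, 35, 40))),
               c("normal", "overweight", "obesity grade 2",
                 "obesity grade 3"))
  expect_false(is_obese(27.3))
  expect_true(is_obese(30.0))
  expect_error(bmi_category(0), "must be > 0")
})

test_that("prevalence reproduces n/N arithmetic at printed precision", {
  flags <- c(rep(TRUE, 10), rep(FALSE, 146))
  p <- prevalence(flags)
  expect_equal(p$n_positive, 10)
  expect_equal(p$n, 156)
  expect_equal(round(p$pct, 2), 6.41)
  expect_equal(round(prevalence(c(rep(TRUE, 38), rep(FALSE, 118)))$pct, 1),
               24.4)
  expect_equal(prevalence(rep(FALSE, 20))$pct, 0)
  expect_error(prevalence(logical(0)), "empty")
})

test_that("lowering a biomarker never clears an atrophy flag (monotonicity)", {
  set.seed(7)
  for (cs_name in c("dolan_smi", "masanes_smi_janssen", "dreco_rf_mt")) {
    cs <- sets[[cs_name]]
    for (rep in 1:50) {
      sex <- rbinom(1, 1, 0.5)
      bmi_v <- runif(1, 18, 35)
      v <- runif(1, 0, 60)
      f1 <- classify_atrophy(v, sex = sex, bmi = bmi_v, cutoffs = cs)
      f2 <- classify_atrophy(v * runif(1, 0.1, 0.99), sex = sex,
                             bmi = bmi_v, cutoffs = cs)
      if (isTRUE(f1)) expect_true(f2)
    }
  }
})

test_that("shipped strata are exhaustive over the declared covariate grid", {
  grid <- expand.grid(sex = c(0, 1), bmi = seq(15, 45, by = 2.5),
                      age = seq(50, 89, by = 5))
  for (cs in sets) {
    is_smd <- grepl("smd", cs$biomarker)
    expect_no_error(
      for (i in seq_len(nrow(grid))) {
        if (is_smd) {
          classify_myosteatosis(30, bmi = grid$bmi[i], cutoffs = cs)
        } else {
          classify_atrophy(30, sex = grid$sex[i], bmi = grid$bmi[i],
                           age = grid$age[i], cutoffs = cs)
        }
      }
    )
  }
})

test_that("the engine matches a brute-force rule-scan oracle on every shipped set", {
  set.seed(11)
  for (cs in sets) {
    r <- cs$rules
    # probe just under/over each threshold, inside each declared stratum
    for (i in seq_len(nrow(r))) {
      sex <- if (is.na(r$sex[i])) sample(0:1, 1) else r$sex[i]
      bmi_v <- max(min(r$bmi_min[i] + 1, r$bmi_max[i] - 1), 16)
      if (!is.finite(bmi_v)) bmi_v <- 25
      age_v <- max(min(r$age_min[i] + 1, r$age_max[i] - 1), 55)
      if (!is.finite(age_v)) age_v <- 65
      for (v in c(r$threshold[i] - 0.01, r$threshold[i],
                  r$threshold[i] + 0.01)) {
        got <- if (grepl("smd", cs$biomarker)) {
          classify_myosteatosis(v, bmi = bmi_v, cutoffs = cs)
        } else {
          classify_atrophy(v, sex = sex, bmi = bmi_v, age = age_v,
                           cutoffs = cs)
        }
        want <- classify_oracle(cs, v, sex, bmi_v, age_v)
        expect_identical(got, want,
                         info = sprintf("%s rule %d value %g", cs$name, i, v))
      }
    }
  }
})

test_that("diagnose_cohort assembles consistent per-subject flags", {
  cohort <- tiny_cohort(80, seed = 13)
  derived <- derive_biomarkers(cohort)
  dx <- diagnose_cohort(derived)
  expect_equal(nrow(dx), 80)
  # sarcopenia implies its atrophy source and dynapenia
  for (nm in grep("^sarcopenia_", names(dx), value = TRUE)) {
    src <- sub("^sarcopenia_", "atrophy_", nm)
    hit <- which(dx[[nm]])
    expect_true(all(dx[[src]][hit]))
    expect_true(all(dx$dynapenia[hit]))
  }
  expect_s3_class(dx$glim, "factor")
  expect_true(all(dx$obesity == (derived$bmi >= 30)))
})
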