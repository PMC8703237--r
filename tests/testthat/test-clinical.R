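test_that("Friedewald LDL follows the mmol/L equation and validity bound", {
  expect_equal(friedewaldLDL(6.2, 1.0, 2.2), 4.2)
  expect_equal(friedewaldLDL(1.4, 1.4, 0), 0)
  expect_true(is.na(friedewaldLDL(6.2, 1.0, 4.6)))   # above the TG bound
  expect_equal(friedewaldLDL(6.2, 1.0, 4.5), 6.2 - 1 - 4.5 / 2.2)
  expect_true(is.na(friedewaldLDL(NA, 1.0, 2.0)))
  expect_error(friedewaldLDL(6.2, -1, 2.0), "non-negative")
})

test_that("CKD-EPI eGFR matches the 2009 creatinine equation", {
  # female at the kappa kink, age 50: both power terms are 1
  expect_equal(ckdEpiEGFR(0.7 * 88.42, 50, "F"),
               141 * 0.993^50 * 1.018, tolerance = 1e-10)
  # male at the kink, age limit 0: value approaches 141
  expect_equal(ckdEpiEGFR(0.9, 0, "M", units = "mg/dL"), 141)
  # doubling creatinine above kappa strictly decreases eGFR
  e1 <- ckdEpiEGFR(1.2, 60, "M", units = "mg/dL")
  e2 <- ckdEpiEGFR(2.4, 60, "M", units = "mg/dL")
  expect_lt(e2, e1)
  # race coefficient only behind the flag
  expect_equal(ckdEpiEGFR(0.9, 40, "M", units = "mg/dL", includeRace = TRUE,
                          black = TRUE) /
                 ckdEpiEGFR(0.9, 40, "M", units = "mg/dL"), 1.159)
  expect_error(ckdEpiEGFR(0, 50, "F"), "positive")
})

test_that("the shipped spec file defines the 20 phenotypes declaratively", {
  specs <- defaultClinicalSpecs()
  expect_length(specs, 20)
  expect_setequal(
    names(specs),
    c("low_egfr", "high_triglycerides", "high_ldl_chol", "high_totchol",
      "low_hdl_chol", "diabetes", "metabolic_syndrome", "sex",
      "lipid_medication", "low_age", "high_hscrp",
      "blood_pressure_lowering_med", "high_age", "obesity", "low_hgb",
      "low_wbc", "current_smoking", "alcohol_consumption", "middle_age",
      "high_pressure"))
  expect_error(defaultClinicalSpecs("no/such/file.yaml"), "no/such")
})

test_that("binarization applies comparators exactly as declared", {
  d <- deriveClinicalVariables(toyClinical())
  # boundary inclusive for >=: trig = 2.3 is TRUE
  expect_true(d$high_triglycerides[2])
  expect_false(d$high_triglycerides[1])   # 2.2
  # strict > for hsCRP: 3.0 is FALSE, 3.1 TRUE
  expect_false(d$high_hscrp[1])
  expect_true(d$high_hscrp[2])
  # age bands: 44.9 low; 64.9 middle; 65 high
  expect_true(d$low_age[1]);  expect_false(d$middle_age[1])
  expect_true(d$middle_age[4]); expect_false(d$high_age[4])
  expect_true(d$high_age[2]);  expect_false(d$middle_age[2])
  # obesity: BMI 31 but male waist 95 < 102 is FALSE; female 95 >= 93 TRUE
  expect_false(d$obesity[1])
  expect_true(d$obesity[2])
  # high pressure: AND of both cutoffs, boundaries inclusive
  expect_true(d$high_pressure[1])    # 140 & 90
  expect_false(d$high_pressure[2])   # 139 & 95
  expect_false(d$high_pressure[3])   # 150 & 85
  # sex-specific haemoglobin thresholds as printed
  expect_true(d$low_hgb[1])    # M, 6.67 <= 6.67
  expect_true(d$low_hgb[2])    # F, 7.62 <= 7.62
  expect_false(d$low_hgb[3])   # M, 8.5
  # wbc boundary inclusive
  expect_true(d$low_wbc[1]); expect_false(d$low_wbc[2])
  # sex flag is maleness
  expect_identical(d$sex[1:4], c(TRUE, FALSE, TRUE, FALSE))
})

test_that("age bands partition non-missing ages", {
  set.seed(5)
  dat <- toyClinical()[rep(1, 50), ]
  dat$age <- runif(50, 18, 90)
  d <- deriveClinicalVariables(dat)
  expect_true(all(d$low_age + d$middle_age + d$high_age == 1))
})

test_that("missing inputs propagate to missing outputs, never FALSE", {
  d <- deriveClinicalVariables(toyClinical())
  expect_true(is.na(d$diabetes[4]))
  # TG missing: LDL missing, so high_ldl_chol missing
  expect_true(is.na(d$high_ldl_chol[5]))
  # sex missing with a sex-specific threshold: missing, not FALSE
  expect_true(is.na(d$low_hgb[5]))
  expect_true(is.na(d$obesity[5]))
  # composites with TG above the Friedewald bound are missing
  expect_true(is.na(d$high_ldl_chol[3]))
})

test_that("sex enters only through the threshold map", {
  dat <- toyClinical()[1:4, ]
  flip <- dat
  flip$sex <- c("F", "M", "F", "M")
  d1 <- deriveClinicalVariables(dat)
  d2 <- deriveClinicalVariables(flip)
  sexFree <- c("high_triglycerides", "high_totchol", "low_hdl_chol",
               "high_hscrp", "low_wbc", "high_pressure", "low_age",
               "middle_age", "high_age")
  for (ph in sexFree) expect_identical(d1[[ph]], d2[[ph]])
  # but the sex-specific ones change where thresholds differ
  expect_false(identical(d1$low_hgb, d2$low_hgb))
})

test_that("the OR variant of high pressure is available behind a flag", {
  d <- deriveClinicalVariables(toyClinical(), highPressureOr = TRUE)
  expect_true(d$high_pressure[2])   # 139 & 95: diastolic alone suffices
  expect_true(d$high_pressure[3])   # 150 & 85: systolic alone suffices
})

test_that("derived prevalences on synthetic data track the generator", {
  sim <- simulateCohorts(nCohorts = 2, cohortSizes = 1500, seed = 55)
  cd <- as.data.frame(colData(sim$dataset))
  d <- deriveClinicalVariables(cd)
  # flags pass straight through
  expect_identical(d$diabetes, cd$diabetes)
  # thresholded variables have sane, non-degenerate prevalence
  for (ph in c("high_triglycerides", "low_hdl_chol", "obesity",
               "high_pressure", "low_egfr"))
    expect_true(mean(d[[ph]], na.rm = TRUE) > 0 &&
                  mean(d[[ph]], na.rm = TRUE) < 0.7)
})
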