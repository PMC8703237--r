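test_that("Cox fit matches brute-force Newton on the Efron likelihood", {
  set.seed(23)
  for (r in 1:3) {
    n <- 40
    X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
    time <- round(rexp(n, exp(0.5 * X[, 1])), 2)   # rounding induces ties
    status <- rbinom(n, 1, 0.8)
    if (sum(status) < 5) next
    ours <- survival::coxph(survival::Surv(time, status) ~ X,
                            ties = "efron")
    oracle <- coxOracleFit(X, time, status)
    expect_equal(unname(coef(ours)), oracle, tolerance = 1e-6)
  }
})

test_that("clustered Cox association reports robust inference", {
  sim <- simulateCohorts(nCohorts = 3, cohortSizes = 500, seed = 61)
  ds <- plantSurvival(sim$dataset, logHR = c(strong_signal = log(2)),
                      censorRate = 0.2, frailtyVar = 0.5, nFamilies = 300,
                      seed = 9)
  df <- as.data.frame(colData(ds))
  res <- coxAssociation(df, "strong_signal", perSD = FALSE)
  expect_identical(res$stratum, "all")
  expect_identical(res$n, nrow(df))
  expect_gt(res$HR, 1.6)
  expect_lt(res$HR, 2.5)
  # under family frailty the sandwich SE generally exceeds the naive one
  expect_gt(res$robustSE, res$naiveSE * 0.9)

  expect_error(coxAssociation(df, "nope"), "nope")
  df$flat <- 1
  expect_error(coxAssociation(df, "flat"), "constant")
  df$time[1] <- -1
  expect_error(coxAssociation(df, "strong_signal"), "positive")
})

test_that("per-SD scaling makes hazard ratios unit-free", {
  sim <- simulateCohorts(nCohorts = 2, cohortSizes = 400, seed = 62)
  ds <- plantSurvival(sim$dataset, logHR = c(age = 0.03), censorRate = 0.3,
                      frailtyVar = 0, seed = 3)
  df <- as.data.frame(colData(ds))
  df$age10 <- df$age * 10
  a <- coxAssociation(df, "age", covariates = "sex")
  b <- coxAssociation(df, "age10", covariates = "sex")
  expect_equal(a$logHR, b$logHR, tolerance = 1e-8)
})

test_that("BH within stratum equals the step-up oracle on all orderings", {
  pset <- c(0.011, 0.02, 0.8, 0.0004, 0.43, 0.02)
  for (perm in allPerms(seq_along(pset))) {
    p <- pset[perm]
    df <- data.frame(term = letters[seq_along(p)], stratum = "all", p = p)
    got <- stratifiedFDR(df)
    expect_equal(got$fdr, bhStepUp(p))
  }
  # worked example: evenly spaced p-values collapse to the largest
  df <- data.frame(term = letters[1:4], stratum = "all",
                   p = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(stratifiedFDR(df)$fdr, rep(0.04, 4))
  # single p: FDR = p
  one <- data.frame(term = "a", stratum = "all", p = 0.2)
  expect_equal(stratifiedFDR(one)$fdr, 0.2)
})

test_that("FDR correction is stratum-wise and order-invariant", {
  df <- data.frame(term = rep(c("s1", "s2", "s3"), 2),
                   stratum = rep(c("male", "female"), each = 3),
                   p = c(0.01, 0.04, 0.9, 0.001, 0.5, 0.02))
  got <- stratifiedFDR(df)
  for (st in c("male", "female")) {
    sel <- got$stratum == st
    expect_equal(got$fdr[sel], p.adjust(df$p[sel], "BH"))
  }
  shuf <- df[sample(nrow(df)), ]
  gotS <- stratifiedFDR(shuf)
  key <- paste(got$term, got$stratum)
  keyS <- paste(gotS$term, gotS$stratum)
  expect_equal(gotS$fdr[match(key, keyS)], got$fdr)
  expect_error(stratifiedFDR(df[0, ]), "empty")
  bad <- df; bad$p[1] <- 1.5
  expect_error(stratifiedFDR(bad), "0, 1")
})

test_that("sex strata are disjoint and union to the full analysis set", {
  sim <- simulateCohorts(nCohorts = 3, cohortSizes = 300, seed = 63)
  ds <- plantSurvival(sim$dataset, logHR = c(strong_signal = log(1.8)),
                      censorRate = 0.2, seed = 4)
  df <- as.data.frame(colData(ds))
  res <- surrogateMortality(df, surrogates = c("strong_signal",
                                               "null_signal"))
  expect_setequal(unique(res$stratum), c("all", "male", "female"))
  nAll <- res$n[res$stratum == "all"][1]
  expect_identical(res$n[res$stratum == "male"][1] +
                     res$n[res$stratum == "female"][1], nAll)
  expect_true(all(c("fdr", "significant") %in% names(res)))
})

test_that("stepwise AIC keeps strong predictors and never increases AIC", {
  sim <- simulateCohorts(nCohorts = 3, cohortSizes = 600, seed = 64)
  ds <- plantSurvival(sim$dataset, logHR = c(strong_signal = log(2)),
                      censorRate = 0.2, frailtyVar = 0.3, seed = 8)
  df <- as.data.frame(colData(ds))
  cand <- c("strong_signal", "moderate_signal", "weak_signal",
            "null_signal")
  sw <- stepwiseCox(df, candidates = cand)
  expect_true("strong_signal" %in% sw$selected)
  steps <- sw$trace[sw$trace$step > 0, ]
  if (nrow(steps)) expect_true(all(steps$aicAfter < steps$aicBefore))
  expect_true(all(sw$selected %in% cand))
  # fixed covariates survive in the final fit
  expect_true("age" %in% names(coef(sw$fit)))
  expect_true(any(grepl("^sex", names(coef(sw$fit)))))
  expect_error(stepwiseCox(df, candidates = character()), "candidate")
})

test_that("stepwise selection agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  sim <- simulateCohorts(nCohorts = 2, cohortSizes = 500, seed = 65)
  ds <- plantSurvival(sim$dataset, logHR = c(strong_signal = log(2),
                                             weak_signal = log(1.5)),
                      censorRate = 0.2, frailtyVar = 0, seed = 2)
  df <- as.data.frame(colData(ds))
  cand <- c("strong_signal", "moderate_signal", "weak_signal",
            "null_signal")
  sw <- stepwiseCox(df, candidates = cand)
  full <- survival::coxph(
    as.formula(paste("survival::Surv(time, event) ~ age + sex +",
                     paste(cand, collapse = " + "))),
    data = df, ties = "efron")
  ref <- MASS::stepAIC(full, direction = "both", trace = 0,
                       scope = list(lower = ~ age + sex))
  refTerms <- intersect(cand, attr(terms(ref), "term.labels"))
  expect_setequal(sw$selected, refTerms)
})
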