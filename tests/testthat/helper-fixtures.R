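suppressPackageStartupMessages(library(SummarizedExperiment))

# shared fixtures are computed once per test run
.fixtureCache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# small multi-cohort dataset used across module tests
smallSim <- function() cached("smallSim",
  simulateCohorts(nCohorts = 4, cohortSizes = 150, seed = 101))

smallQC <- function() cached("smallQC", qcPreprocess(smallSim()$dataset))

# build a CohortExperiment from a samples-by-markers matrix
toyCE <- function(X, cohort = rep("c1", nrow(X)), extra = list()) {
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%03d", seq_len(nrow(X)))
  cd <- S4Vectors::DataFrame(sample_id = rownames(X), cohort = cohort)
  for (nm in names(extra)) cd[[nm]] <- extra[[nm]]
  se <- SummarizedExperiment(assays = list(conc = t(X)), colData = cd)
  colnames(se) <- rownames(X)
  as(se, "CohortExperiment")
}

# raw clinical data covering every derivation rule
toyClinical <- function() {
  data.frame(
    sex = c("M", "F", "M", "F", NA),
    age = c(44.9, 65, 50, 64.9, 30),
    totchol = c(6.2, 5.0, 7.0, 4.0, 5.5),
    hdl = c(1.0, 1.4, 1.2, 1.3, 1.5),
    trig = c(2.2, 2.3, 4.6, 1.0, NA),
    creatinine = c(80, 61.9, 110, 70, 90),
    bmi = c(31, 31, 29, 32, 25),
    waist = c(95, 95, 110, 92.9, 80),
    systolic = c(140, 139, 150, 135, 120),
    diastolic = c(90, 95, 85, 80, 70),
    hgb = c(6.67, 7.62, 8.5, 7.7, 9.0),
    wbc = c(4.5, 4.6, 7.0, 3.0, 5.0),
    hscrp = c(3.0, 3.1, 1.0, 10, 2.0),
    diabetes = c(TRUE, FALSE, FALSE, NA, FALSE),
    metabolic_syndrome = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    lipid_medication = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    blood_pressure_lowering_med = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    current_smoking = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    alcohol_consumption = c(TRUE, TRUE, FALSE, TRUE, FALSE))
}
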