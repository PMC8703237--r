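test_that("sample filters apply rules in order with correct counts", {
  # toy matrix: one sample with a missing cell, one with a zero, one gross
  # outlier on marker 1, plus enough clean samples that a 5-SD flag is
  # attainable (the largest z-score among n samples is (n-1)/sqrt(n))
  set.seed(42)
  n <- 63
  X <- matrix(rnorm(n * 4, mean = 10), n, 4,
              dimnames = list(sprintf("s%02d", 1:n), paste0("m", 1:4)))
  X["s01", 2] <- NA
  X["s02", 3] <- 0
  clean <- X[4:n, 1]
  X["s03", 1] <- mean(clean) + 10 * sd(clean)
  out <- filterSamples(X)
  expect_identical(out$report@nRemovedMissing, 1L)
  expect_identical(out$report@nRemovedZero, 1L)
  expect_identical(out$report@nRemovedOutlier, 1L)
  expect_identical(out$report@removed$missing, "s01")
  expect_identical(out$report@removed$zero, "s02")
  expect_identical(out$report@removed$outlier, "s03")
  expect_identical(rownames(out$dataset), sprintf("s%02d", 4:n))

  # count conservation: kept + removed = input
  expect_identical(nrow(out$dataset) + out$report@nRemovedMissing +
                     out$report@nRemovedZero + out$report@nRemovedOutlier,
                   nrow(X))

  # idempotence: a second pass removes nothing
  again <- filterSamples(out$dataset)
  expect_identical(again$report@nRemovedMissing + again$report@nRemovedZero +
                     again$report@nRemovedOutlier, 0L)
})

test_that("clean matrices pass untouched and degenerate cases are guarded", {
  X <- matrix(rnorm(30, 5), 10, 3,
              dimnames = list(paste0("s", 1:10), paste0("m", 1:3)))
  out <- filterSamples(X)
  expect_identical(out$dataset, X)
  expect_identical(out$report@nRemovedOutlier, 0L)

  # constant marker (SD = 0) never produces outliers
  X[, 2] <- 7
  expect_identical(nrow(filterSamples(X)$dataset), 10L)

  # a sample with one NA survives when the missing ceiling is relaxed
  X[1, 1] <- NA
  expect_identical(filterSamples(X, maxMissing = 1)$report@nRemovedMissing, 0L)
  expect_identical(filterSamples(X)$report@removed$missing, "s1")

  expect_error(filterSamples(X[0, , drop = FALSE]), "empty")
})

test_that("a sample is removed at the first rule it violates", {
  X <- matrix(rnorm(24, 10), 8, 3,
              dimnames = list(paste0("s", 1:8), paste0("m", 1:3)))
  X[1, 1] <- NA; X[1, 2] <- 0   # violates missing AND zero: counted once
  out <- filterSamples(X)
  expect_identical(out$report@nRemovedMissing, 1L)
  expect_identical(out$report@nRemovedZero, 0L)
})

test_that("NIPALS reconstructs deleted cells of an exact rank-1 matrix", {
  set.seed(3)
  u <- rnorm(30); v <- rnorm(8)
  M <- tcrossprod(u, v)
  Mh <- M
  Mh[5, 3] <- NA; Mh[17, 7] <- NA
  got <- imputeNIPALS(Mh, nComp = 2)
  expect_equal(got[5, 3], rank1CellOracle(M, 5, 3, 6, 4), tolerance = 1e-6)
  expect_equal(got[17, 7], rank1CellOracle(M, 17, 7, 2, 1), tolerance = 1e-6)
  expect_equal(got[5, 3], M[5, 3], tolerance = 1e-6)
  expect_identical(attr(got, "nCellsImputed"), 2L)
})

test_that("NIPALS never alters observed cells and validates its input", {
  set.seed(9)
  X <- matrix(rnorm(60 * 10), 60, 10)
  expect_identical(unclass(imputeNIPALS(X))[seq_along(X)], X[seq_along(X)])

  holes <- sample(length(X), 6)
  Xh <- X; Xh[holes] <- NA
  got <- imputeNIPALS(Xh, nComp = 5)
  expect_identical(got[-holes], X[-holes])  # bit-identical observed cells

  Xall <- X; Xall[, 2] <- NA
  expect_error(imputeNIPALS(Xall), "entirely missing")
  Xmany <- X; Xmany[sample(length(X), 100)] <- NA
  expect_error(imputeNIPALS(Xmany), "ceiling")
})

test_that("NIPALS agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  n <- 50; p <- 9
  X <- tcrossprod(rnorm(n), rnorm(p)) + tcrossprod(rnorm(n), rnorm(p))
  holes <- cbind(c(4, 17, 29, 41), c(2, 5, 8, 3))
  Xh <- X; Xh[holes] <- NA
  ours <- imputeNIPALS(Xh, nComp = 2)
  ref <- suppressWarnings(mixOmics::impute.nipals(Xh, ncomp = 2))
  # the two weighted sequential fits track each other much more closely
  # than either tracks the truth on a rank-2 pattern
  expect_lt(max(abs(ours[holes] - ref[holes])), 0.05)
  expect_lt(max(abs(ours[holes] - X[holes])), 0.2)
})

test_that("z-scaling is exact, reusable and guarded", {
  sc <- zScale(cbind(a = c(1, 2, 3), b = c(10, 20, 60)))
  expect_equal(unname(sc$scaled[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(sc$scaled), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(sc$scaled, 2, sd), c(a = 1, b = 1), tolerance = 1e-10)

  # stored parameters map the training mean vector to zero
  newx <- matrix(sc$center, 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(applyScaling(newx, sc$center, sc$scale)[1, ]),
               c(0, 0))
  # already-standardized input is unchanged
  sc2 <- zScale(sc$scaled)
  expect_equal(sc2$scaled, sc$scaled, tolerance = 1e-10)

  expect_error(zScale(cbind(a = c(1, 1, 1), b = 1:3)), "a")
  expect_error(applyScaling(newx[, 1, drop = FALSE], sc$center, sc$scale),
               "b")
})

test_that("qcPreprocess removes exactly the injected missing/zero samples", {
  sim <- simulateCohorts(nCohorts = 3, cohortSizes = 400, seed = 77)
  ds <- injectArtifacts(sim$dataset, missingRate = 8e-4, zeroRate = 8e-4,
                        outlierRate = 0, seed = 13)
  mk <- metadata(ds)$artifactMasks
  qc <- qcPreprocess(ds)
  # cells injected into excluded markers are dropped at panel selection,
  # so the oracle covers the retained markers only
  retained <- rownames(qc$dataset)
  expMissing <- sort(unique(
    mk$missing$sample_id[mk$missing$marker %in% retained]))
  expZero <- sort(setdiff(
    unique(mk$zero$sample_id[mk$zero$marker %in% retained]), expMissing))
  expect_identical(sort(qc$report@removed$missing), expMissing)
  expect_identical(sort(qc$report@removed$zero), expZero)
  # 56 retained markers after panel selection, scaling parameters stored
  expect_identical(nrow(qc$dataset), 56L)
  expect_length(qc$report@center, 56L)
  expect_equal(rowMeans(assay(qc$dataset, "scaled")),
               setNames(rep(0, 56), rownames(qc$dataset)), tolerance = 1e-10)
})

test_that("relaxed missing ceiling keeps samples and imputes their cells", {
  sim <- simulateCohorts(nCohorts = 2, cohortSizes = 250, seed = 78)
  ds <- injectArtifacts(sim$dataset, missingRate = 5e-4, zeroRate = 0,
                        outlierRate = 0, seed = 14)
  qc <- qcPreprocess(ds, maxMissing = 3)
  expect_identical(qc$report@nRemovedMissing, 0L)
  expect_gt(qc$report@nCellsImputed, 0L)
  expect_false(anyNA(concentrations(qc$dataset)))
  expect_equal(qc$report@imputedFraction,
               qc$report@nCellsImputed / (ncol(qc$dataset) * 56))
})
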