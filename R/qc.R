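#' Sample-level quality-control filters
#'
#' Applies the three sample filters of the metabolomics QC, in order:
#' (1) samples with more than \code{maxMissing} missing marker values,
#' (2) samples with one or more zero concentrations (when
#' \code{zeroForbidden}), (3) samples with any marker further than
#' \code{sdLimit} sample SDs from the marker mean. A sample is removed at
#' the first rule it violates. By default the mean/SD of the outlier rule
#' are computed on the samples surviving the first two filters
#' (\code{statsAfterFilters = TRUE}), since contaminated cells would
#' otherwise distort the SD; set it to FALSE to use all input samples.
#' Zero-variance markers produce no outliers.
#'
#' @param x a [CohortExperiment-class] or a samples-by-markers numeric
#'   matrix with rownames as sample ids.
#' @param maxMissing maximum number of missing cells a sample may carry
#'   (default 0: any missing cell removes the sample).
#' @param zeroForbidden remove samples containing zero concentrations.
#' @param sdLimit outlier cut in sample SDs (n-1 denominator).
#' @param statsAfterFilters compute outlier-rule column statistics after
#'   the missing/zero filters (default) or on the full input.
#' @return \code{list(dataset, report)} where \code{dataset} is the kept
#'   subset (same class as the input) and \code{report} a
#'   [QCReport-class].
#' @examples
#' m <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("s", 1:8), paste0("m", 1:5)))
#' m[1, 2] <- NA
#' filterSamples(m)$report
#' @export
filterSamples <- function(x, maxMissing = 0, zeroForbidden = TRUE,
                          sdLimit = 5, statsAfterFilters = TRUE) {
  mat <- if (is(x, "CohortExperiment")) concentrations(x) else as.matrix(x)
  if (nrow(mat) == 0 || ncol(mat) == 0)
    stop("empty concentration matrix", call. = FALSE)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))

  missBad <- rowSums(is.na(mat)) > maxMissing
  zeroBad <- !missBad & zeroForbidden &
    rowSums(mat == 0, na.rm = TRUE) > 0
  surv <- !missBad & !zeroBad
  base <- if (statsAfterFilters) mat[surv, , drop = FALSE] else mat
  mu <- colMeans(base, na.rm = TRUE)
  sigma <- apply(base, 2, sd, na.rm = TRUE)
  sigma[is.na(sigma)] <- 0
  dev <- abs(sweep(mat, 2, mu, "-"))
  lim <- sdLimit * sigma
  # zero-variance guard: a 0-SD marker never flags outliers
  outBad <- surv & rowSums(
    sweep(dev, 2, lim, ">") & rep(sigma > 0, each = nrow(mat)),
    na.rm = TRUE) > 0
  keep <- surv & !outBad
  if (!any(keep))
    stop("all samples removed by QC filters", call. = FALSE)

  report <- new("QCReport",
    nRemovedMissing = sum(missBad), nRemovedZero = sum(zeroBad),
    nRemovedOutlier = sum(outBad),
    removed = list(missing = ids[missBad], zero = ids[zeroBad],
                   outlier = ids[outBad]),
    nCellsImputed = 0L, imputedFraction = 0,
    center = numeric(), scale = numeric())
  kept <- if (is(x, "CohortExperiment")) x[, keep] else
    mat[keep, , drop = FALSE]
  list(dataset = kept, report = report)
}

#' NIPALS imputation of residual missing cells
#'
#' Completes a numeric matrix by NIPALS principal-component
#' reconstruction: components are fitted one at a time by alternating
#' regressions whose inner products skip missing entries, and the missing
#' cells are replaced by the rank-\code{nComp} reconstruction plus the
#' column means. Because the column means themselves depend on the
#' imputed cells, the fit is wrapped in a short refinement loop that
#' re-centres on the completed matrix until the imputed values stabilise;
#' components always see observed cells only, so a missing cell can never
#' be explained by a component of its own. On input consistent with a
#' low-rank model (e.g. an exact rank-1 matrix with one cell deleted) the
#' fixed point is the exact reconstruction. Observed cells are never
#' altered. Intended for the small residue of missingness left after
#' per-sample filtering with a relaxed \code{maxMissing}.
#'
#' @param mat samples-by-markers numeric matrix, possibly with NAs.
#' @param nComp number of components; default: enough components to explain
#'   95 percent of the variance of the complete rows, capped at 10.
#' @param maxMissingFrac ceiling on the overall missing fraction (default
#'   5 percent); more missingness than this is an error, as reconstruction
#'   quality degrades.
#' @param maxIter outer refinement iteration limit.
#' @param tol relative convergence tolerance on the imputed values.
#' @return The completed matrix, with attribute \code{"nCellsImputed"}.
#' @examples
#' u <- rnorm(20); v <- rnorm(6)
#' m <- tcrossprod(u, v)                # exact rank 1
#' m[3, 2] <- NA
#' mi <- imputeNIPALS(m, nComp = 1)
#' abs(mi[3, 2] - u[3] * v[2]) < 1e-6
#' @export
imputeNIPALS <- function(mat, nComp = NULL, maxMissingFrac = 0.05,
                         maxIter = 500, tol = 1e-9) {
  mat <- as.matrix(mat)
  miss <- is.na(mat)
  if (!any(miss)) return(structure(mat, nCellsImputed = 0L))
  if (any(colSums(!miss) == 0))
    stop("column(s) entirely missing cannot be imputed", call. = FALSE)
  frac <- mean(miss)
  if (frac > maxMissingFrac)
    stop(sprintf("missing fraction %.3f exceeds ceiling %.3f", frac,
                 maxMissingFrac), call. = FALSE)
  if (is.null(nComp)) {
    cc <- complete.cases(mat)
    nComp <- if (sum(cc) > 2) {
      ev <- prcomp(mat[cc, , drop = FALSE], scale. = FALSE)$sdev^2
      max(1L, which(cumsum(ev) / sum(ev) >= 0.95)[1])
    } else min(5L, ncol(mat))
    nComp <- min(nComp, 10L, nrow(mat) - 1L, ncol(mat))
  }
  W <- !miss
  filled <- mat
  filled[miss] <- rep(colMeans(mat, na.rm = TRUE), each = nrow(mat))[miss]
  scaleRef <- max(abs(mat), na.rm = TRUE) + .Machine$double.eps
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    # components are fitted to observed cells only; the imputed values
    # feed back solely through the column centres, so a missing cell can
    # never be "explained" by a component of its own
    center <- colMeans(filled)
    X <- sweep(mat, 2, center, "-")
    X[miss] <- 0
    recon <- nipalsMissing(X, W, nComp)
    vals <- (recon + rep(center, each = nrow(mat)))[miss]
    change <- max(abs(vals - filled[miss]))
    filled[miss] <- vals
    if (change <= tol * scaleRef) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("NIPALS imputation failed to converge in %d iterations (last change %.3g)",
                 maxIter, change), call. = FALSE)
  structure(filled, nCellsImputed = sum(miss))
}

# sequential NIPALS fit of a centred matrix with zeros at unobserved
# cells (W = observation indicator); inner products skip missing entries
nipalsMissing <- function(X, W, k, maxIter = 500, tol = 1e-10) {
  recon <- matrix(0, nrow(X), ncol(X))
  R <- X
  for (h in seq_len(k)) {
    ss <- colSums(R^2)
    if (max(ss) <= .Machine$double.eps) break   # residual exhausted
    t_ <- R[, which.max(ss)]
    for (it in seq_len(maxIter)) {
      p_ <- crossprod(R, t_) / pmax(crossprod(W, t_^2),
                                    .Machine$double.eps)
      p_ <- p_ / sqrt(sum(p_^2))
      tNew <- drop((R %*% p_) / pmax(W %*% p_^2, .Machine$double.eps))
      change <- sqrt(sum((tNew - t_)^2))
      t_ <- tNew
      if (change <= tol * max(sqrt(sum(t_^2)), .Machine$double.eps)) break
    }
    comp <- tcrossprod(t_, drop(p_))
    recon <- recon + comp
    R <- R - comp
    R[!W] <- 0
  }
  recon
}

#' Z-scale a complete marker matrix
#'
#' Centres and scales every marker to mean 0 and sample SD 1 (n-1
#' denominator), returning the parameters so that exactly the same
#' transformation can be applied to new samples at projection time.
#'
#' @param mat complete samples-by-markers numeric matrix.
#' @return \code{list(scaled, center, scale)} with named parameter vectors.
#' @seealso [applyScaling()]
#' @export
zScale <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("zScale requires a complete matrix", call. = FALSE)
  center <- colMeans(mat)
  scale <- apply(mat, 2, sd)
  zero <- scale <= 0 | !is.finite(scale)
  if (any(zero))
    stop("zero-variance marker(s): ",
         paste(colnames(mat)[zero], collapse = ", "), call. = FALSE)
  list(scaled = sweep(sweep(mat, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}

#' Apply stored scaling parameters to new data
#'
#' @param mat samples-by-markers matrix of raw values; columns are matched
#'   to the parameter names (order-insensitive), and any parameter marker
#'   absent from \code{mat} is an error naming the marker.
#' @param center,scale named numeric vectors from [zScale()].
#' @return The standardized matrix in parameter order.
#' @export
applyScaling <- function(mat, center, scale) {
  mat <- as.matrix(mat)
  absent <- setdiff(names(center), colnames(mat))
  if (length(absent))
    stop("new data is missing marker(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  m <- mat[, names(center), drop = FALSE]
  sweep(sweep(m, 2, center, "-"), 2, scale, "/")
}

#' Full metabolomics QC in one call
#'
#' Panel restriction, sample filtering, NIPALS imputation of whatever cells
#' remain missing after filtering, and z-scaling, in that order — the
#' standard pre-processing applied before surrogate training. With the
#' default \code{maxMissing = 0} the imputation step only ever sees data
#' when the missing ceiling is relaxed.
#'
#' @param dataset a [CohortExperiment-class].
#' @param panel a [MetabolitePanel-class].
#' @inheritParams filterSamples
#' @param nComp passed to [imputeNIPALS()].
#' @return \code{list(dataset, report)}: the dataset restricted and
#'   filtered, carrying assays \code{conc} (completed concentrations) and
#'   \code{scaled}; the [QCReport-class] includes imputation counts and
#'   the scaling parameters.
#' @export
qcPreprocess <- function(dataset, panel = defaultPanel(), maxMissing = 0,
                         zeroForbidden = TRUE, sdLimit = 5,
                         statsAfterFilters = TRUE, nComp = NULL) {
  dataset <- selectPanel(dataset, panel)
  flt <- filterSamples(dataset, maxMissing = maxMissing,
                       zeroForbidden = zeroForbidden, sdLimit = sdLimit,
                       statsAfterFilters = statsAfterFilters)
  ds <- flt$dataset
  rep <- flt$report
  X <- concentrations(ds)
  nImp <- 0L
  if (anyNA(X)) {
    X <- imputeNIPALS(X, nComp = nComp)
    nImp <- attr(X, "nCellsImputed")
    assays(ds)[["conc"]] <- t(X)
  }
  sc <- zScale(X)
  assays(ds)[["scaled"]] <- t(sc$scaled)
  rep@nCellsImputed <- as.integer(nImp)
  rep@imputedFraction <- nImp / (nrow(X) * ncol(X))
  rep@center <- sc$center
  rep@scale <- sc$scale
  metadata(ds)$qcReport <- rep
  list(dataset = ds, report = rep)
}
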