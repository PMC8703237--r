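#' Clustered Cox association of one surrogate with mortality
#'
#' Cox proportional-hazards fit (follow-up time as the time scale, Efron
#' tie handling) of the event on the surrogate plus fixed covariates, with
#' robust standard errors from the Huber sandwich estimator grouped by a
#' cluster variable (typically family), so that within-pedigree
#' correlation does not deflate the reported uncertainty. By default the
#' surrogate enters per 1 SD of its distribution, making hazard ratios
#' comparable across surrogates.
#'
#' @param data data.frame with the surrogate, covariate, time/event and
#'   cluster columns.
#' @param surrogate name of the surrogate column.
#' @param covariates names of adjustment columns (default age and sex).
#' @param timeVar,eventVar follow-up time (> 0) and 0/1 event columns.
#' @param clusterVar cluster id column for the sandwich grouping, or NULL
#'   for unclustered robust errors.
#' @param stratum label recorded in the result (e.g. "all", "male",
#'   "female").
#' @param perSD scale the surrogate to unit SD before fitting.
#' @return One-row data.frame: term, stratum, n, events, logHR, HR,
#'   robustSE, naiveSE, z, p.
#' @export
coxAssociation <- function(data, surrogate, covariates = c("age", "sex"),
                           timeVar = "time", eventVar = "event",
                           clusterVar = "family_id", stratum = "all",
                           perSD = TRUE) {
  data <- as.data.frame(data)
  need <- c(surrogate, covariates, timeVar, eventVar, clusterVar)
  absent <- setdiff(need, names(data))
  if (length(absent))
    stop("missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  df <- data[stats::complete.cases(data[, need, drop = FALSE]), need,
             drop = FALSE]
  if (any(df[[timeVar]] <= 0))
    stop("follow-up times must be positive", call. = FALSE)
  events <- sum(df[[eventVar]])
  if (events == 0)
    stop("zero events: degenerate survival input", call. = FALSE)
  x <- as.numeric(df[[surrogate]])
  if (sd(x) == 0)
    stop("surrogate '", surrogate, "' is constant", call. = FALSE)
  df$.surr <- if (perSD) x / sd(x) else x
  nPar <- 1 + length(covariates)
  if (events < 10 * nPar)
    warning(sprintf("only %d events for %d parameters (< 10 per parameter)",
                    events, nPar), call. = FALSE)
  rhs <- paste(c(".surr", covariates,
                 if (!is.null(clusterVar))
                   sprintf("cluster(%s)", clusterVar)),
               collapse = " + ")
  f <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", timeVar, eventVar,
                          rhs))
  fit <- survival::coxph(f, data = df, ties = "efron", robust = TRUE)
  sm <- summary(fit)$coefficients
  row <- sm[".surr", ]
  data.frame(term = surrogate, stratum = stratum, n = nrow(df),
             events = events, logHR = unname(row["coef"]),
             HR = unname(exp(row["coef"])),
             robustSE = unname(row["robust se"]),
             naiveSE = unname(row["se(coef)"]),
             z = unname(row["z"]),
             p = unname(row["Pr(>|z|)"]), row.names = NULL)
}

#' Benjamini-Hochberg correction within strata
#'
#' Applies the BH step-up procedure to the p-values of each stratum
#' independently (e.g. all individuals, men, women) and flags
#' associations at FDR < \code{fdrLimit}.
#'
#' @param associations data.frame with at least \code{p} and
#'   \code{stratum} columns (as produced by [coxAssociation()] rows).
#' @param fdrLimit significance level on the FDR scale.
#' @return The input with \code{fdr} and \code{significant} columns added.
#' @export
stratifiedFDR <- function(associations, fdrLimit = 0.05) {
  if (!nrow(associations)) stop("empty association table", call. = FALSE)
  if (anyNA(associations$p) || any(associations$p < 0 | associations$p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  associations$fdr <- stats::ave(associations$p, associations$stratum,
                                 FUN = function(p) p.adjust(p, "BH"))
  associations$significant <- associations$fdr < fdrLimit
  associations
}

#' Per-surrogate mortality associations across strata
#'
#' Runs [coxAssociation()] for every surrogate in the full sample and in
#' the male/female subsets, then applies [stratifiedFDR()] separately per
#' stratum. Sex is dropped from the covariates within the sex strata.
#'
#' @inheritParams coxAssociation
#' @param surrogates character vector of surrogate column names.
#' @param sexVar sex column ("M"/"F") used to build the strata.
#' @return data.frame of associations with FDR per stratum.
#' @export
surrogateMortality <- function(data, surrogates, covariates = c("age", "sex"),
                               timeVar = "time", eventVar = "event",
                               clusterVar = "family_id", sexVar = "sex",
                               perSD = TRUE) {
  data <- as.data.frame(data)
  sx <- normalizeSex(data[[sexVar]])
  strata <- list(all = rep(TRUE, nrow(data)), male = sx %in% "M",
                 female = sx %in% "F")
  flat <- surrogates[vapply(surrogates, function(s)
    sd(as.numeric(data[[s]]), na.rm = TRUE) == 0, logical(1))]
  if (length(flat)) {
    warning("skipping constant surrogate(s): ",
            paste(flat, collapse = ", "), call. = FALSE)
    surrogates <- setdiff(surrogates, flat)
  }
  if (!length(surrogates))
    stop("no non-degenerate surrogates to test", call. = FALSE)
  rows <- list()
  for (st in names(strata)) {
    covs <- if (st == "all") covariates else setdiff(covariates, sexVar)
    for (s in surrogates) {
      rows[[paste(st, s)]] <- coxAssociation(
        data[strata[[st]], , drop = FALSE], s, covariates = covs,
        timeVar = timeVar, eventVar = eventVar, clusterVar = clusterVar,
        stratum = st, perSD = perSD)
    }
  }
  stratifiedFDR(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Stepwise AIC selection of a multi-surrogate Cox model
#'
#' Bidirectional search starting from the model containing all candidate
#' surrogates on top of the fixed covariates: at each round every single
#' removal of an included candidate and every single addition of an
#' excluded one is scored, the move with the largest AIC decrease is
#' taken, and the search stops when no move decreases the AIC. Fixed
#' covariates are never dropped. The AIC uses the ordinary partial
#' likelihood (AIC is likelihood-based by definition); the selected model
#' is then refitted with cluster-robust standard errors for the reported
#' inference, with per-term robust p-values in the summary.
#'
#' @inheritParams coxAssociation
#' @param candidates candidate surrogate column names.
#' @param fixed covariate columns never removed (default age and sex).
#' @return List: \code{trace} (data.frame of step, action, term, AIC
#'   before/after), \code{selected} (retained candidates), \code{fit}
#'   (the robust refit), \code{summary} (per-term data.frame with robust
#'   SEs and p-values).
#' @export
stepwiseCox <- function(data, candidates, fixed = c("age", "sex"),
                        timeVar = "time", eventVar = "event",
                        clusterVar = "family_id") {
  if (!length(candidates)) stop("no candidate terms", call. = FALSE)
  data <- as.data.frame(data)
  need <- c(candidates, fixed, timeVar, eventVar, clusterVar)
  absent <- setdiff(need, names(data))
  if (length(absent))
    stop("missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  df <- data[stats::complete.cases(data[, need, drop = FALSE]), ,
             drop = FALSE]
  if (sum(df[[eventVar]]) == 0)
    stop("zero events: degenerate survival input", call. = FALSE)
  aicOf <- function(terms) {
    rhs <- paste(c(fixed, terms, "1"), collapse = " + ")
    f <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", timeVar,
                            eventVar, rhs))
    AIC(survival::coxph(f, data = df, ties = "efron"))
  }
  current <- candidates
  aicNow <- aicOf(current)
  trace <- data.frame(step = 0L, action = "start",
                      term = sprintf("full model (%d candidates)",
                                     length(candidates)),
                      aicBefore = NA_real_, aicAfter = aicNow)
  step <- 0L
  repeat {
    moves <- rbind(
      if (length(current))
        data.frame(action = "remove", term = current),
      if (length(setdiff(candidates, current)))
        data.frame(action = "add", term = setdiff(candidates, current)))
    if (is.null(moves) || !nrow(moves)) break
    aics <- mapply(function(act, trm) {
      aicOf(if (act == "remove") setdiff(current, trm) else c(current, trm))
    }, moves$action, moves$term)
    best <- which.min(aics)
    if (aics[best] >= aicNow - 1e-8) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, action = moves$action[best], term = moves$term[best],
      aicBefore = aicNow, aicAfter = aics[best]))
    current <- if (moves$action[best] == "remove")
      setdiff(current, moves$term[best]) else c(current, moves$term[best])
    aicNow <- aics[best]
  }
  rhs <- paste(c(fixed, current,
                 if (!is.null(clusterVar)) sprintf("cluster(%s)", clusterVar),
                 "1"), collapse = " + ")
  f <- as.formula(sprintf("survival::Surv(%s, %s) ~ %s", timeVar, eventVar,
                          rhs))
  fit <- survival::coxph(f, data = df, ties = "efron", robust = TRUE)
  sm <- as.data.frame(summary(fit)$coefficients)
  sm$term <- rownames(sm)
  list(trace = trace, selected = current, fit = fit,
       summary = data.frame(term = sm$term, logHR = sm$coef,
                            HR = exp(sm$coef), robustSE = sm[["robust se"]],
                            p = sm[["Pr(>|z|)"]], row.names = NULL))
}
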