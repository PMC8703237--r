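#' Friedewald estimate of LDL cholesterol
#'
#' LDL = total cholesterol - HDL - triglycerides / 2.2, all in mmol/L (the
#' mmol/L form of the Friedewald equation). The estimate is invalid at
#' high triglyceride levels, so values with triglycerides above
#' \code{tgLimit} (default 4.5 mmol/L, the standard applicability bound)
#' return NA rather than a biased number.
#'
#' @param totchol,hdl,trig numeric vectors in mmol/L (recycled).
#' @param tgLimit triglyceride validity bound in mmol/L.
#' @return Numeric vector of LDL cholesterol in mmol/L, NA where any input
#'   is missing or triglycerides exceed the bound.
#' @examples
#' friedewaldLDL(6.2, 1.0, 2.2)  # 4.2
#' @export
friedewaldLDL <- function(totchol, hdl, trig, tgLimit = 4.5) {
  if (any(c(totchol, hdl, trig) < 0, na.rm = TRUE))
    stop("concentrations must be non-negative", call. = FALSE)
  ldl <- totchol - hdl - trig / 2.2
  ldl[!is.na(trig) & trig > tgLimit] <- NA_real_
  ldl
}

#' CKD-EPI (2009, creatinine-based) estimated glomerular filtration rate
#'
#' eGFR = 141 * min(Scr/kappa, 1)^a * max(Scr/kappa, 1)^-1.209 *
#' 0.993^age * 1.018\[if female\], with serum creatinine Scr in mg/dL,
#' kappa = 0.7 (F) / 0.9 (M) and a = -0.329 (F) / -0.411 (M). Creatinine
#' given in µmol/L is converted by dividing by 88.42; units must be
#' declared, they are never guessed. The race coefficient (1.159) is
#' omitted by default and available behind \code{includeRace} for
#' generality.
#'
#' @param creatinine serum creatinine, positive.
#' @param age age in years (the equation is intended for adults).
#' @param sex "M"/"F" (or "male"/"female", case-insensitive).
#' @param units "umol/L" (default) or "mg/dL".
#' @param includeRace apply the 1.159 coefficient where \code{black} is
#'   TRUE.
#' @param black logical vector, only used with \code{includeRace}.
#' @return eGFR in mL/min/1.73 m².
#' @examples
#' ckdEpiEGFR(0.7 * 88.42, age = 50, sex = "F")  # about 101
#' @export
ckdEpiEGFR <- function(creatinine, age, sex, units = c("umol/L", "mg/dL"),
                       includeRace = FALSE, black = FALSE) {
  units <- match.arg(units)
  if (any(creatinine <= 0, na.rm = TRUE))
    stop("creatinine must be positive", call. = FALSE)
  scr <- if (units == "umol/L") creatinine / 88.42 else creatinine
  female <- normalizeSex(sex) == "F"
  kappa <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.329, -0.411)
  egfr <- 141 * pmin(scr / kappa, 1)^a * pmax(scr / kappa, 1)^-1.209 *
    0.993^age * ifelse(female, 1.018, 1)
  if (includeRace) egfr <- egfr * ifelse(rep_len(black, length(egfr)), 1.159, 1)
  egfr
}

normalizeSex <- function(sex) {
  s <- toupper(substr(as.character(sex), 1, 1))
  s[!s %in% c("M", "F")] <- NA_character_
  s
}

#' Load binary clinical-variable specifications
#'
#' Reads the versioned YAML threshold file defining the 20 dichotomous
#' clinical variables (the package default reproduces the standard
#' at-risk cutoffs: e.g. triglycerides >= 2.3 mmol/L, hsCRP > 3 mg/L,
#' eGFR <= 60 mL/min, sex-specific waist and haemoglobin cutoffs, the
#' three mutually exclusive age bands). Thresholds live in configuration,
#' not code, so the definitions are auditable and replaceable.
#'
#' @param file path to a YAML spec file; default: the shipped thresholds.
#' @return Named list of phenotype specs (fields \code{name},
#'   \code{type}, sources, comparators, thresholds).
#' @export
defaultClinicalSpecs <- function(file = system.file("extdata",
                                                    "clinical_thresholds.yaml",
                                                    package = "metaboSurrogates")) {
  if (!nzchar(file) || !file.exists(file))
    stop("clinical spec file not found: ", file, call. = FALSE)
  doc <- yaml::read_yaml(file)
  specs <- doc$phenotypes
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

applyComparator <- function(x, comparator, threshold) {
  switch(comparator,
         ">=" = x >= threshold, "<=" = x <= threshold,
         ">" = x > threshold, "<" = x < threshold,
         stop("unknown comparator: ", comparator, call. = FALSE))
}

resolveThreshold <- function(threshold, sex, n) {
  if (is.list(threshold)) {
    s <- normalizeSex(sex)
    if (!all(c("M", "F") %in% names(threshold)))
      stop("sex-specific threshold must define both M and F", call. = FALSE)
    unlist(threshold)[s]
  } else rep_len(threshold, n)
}

evalTerm <- function(data, term, sex) {
  src <- term$source
  if (!src %in% names(data))
    stop("required input column absent: ", src, call. = FALSE)
  x <- data[[src]]
  thr <- resolveThreshold(term$threshold, sex, length(x))
  out <- applyComparator(as.numeric(x), term$comparator, thr)
  out[is.na(x) | is.na(thr)] <- NA
  out
}

#' Derive one dichotomous clinical variable
#'
#' Applies a single spec from [defaultClinicalSpecs()] to a data.frame of
#' raw clinical columns. Missingness propagates: if any required input
#' (including sex, for sex-specific thresholds) is missing the result is
#' NA, never silently FALSE. Comparator boundaries are applied exactly as
#' declared (inclusive for >= / <=).
#'
#' @param data data.frame (or DataFrame) of raw clinical columns.
#' @param spec one spec entry.
#' @param sexVar name of the sex column used for sex-specific thresholds.
#' @return Logical vector with NAs.
#' @export
deriveBinary <- function(data, spec, sexVar = "sex") {
  data <- as.data.frame(data)
  sex <- if (sexVar %in% names(data)) data[[sexVar]] else
    rep(NA_character_, nrow(data))
  type <- spec$type %||% "threshold"
  switch(type,
    threshold = evalTerm(data, spec, sex),
    band = {
      x <- as.numeric(data[[spec$source]])
      out <- x >= spec$lower & x < spec$upper
      out[is.na(x)] <- NA
      out
    },
    flag = {
      if (!spec$source %in% names(data))
        stop("required input column absent: ", spec$source, call. = FALSE)
      as.logical(data[[spec$source]])
    },
    equals = {
      x <- as.character(data[[spec$source]])
      if (identical(spec$source, "sex")) x <- normalizeSex(x)
      out <- x == spec$value
      out[is.na(x)] <- NA
      out
    },
    all = ,
    any = {
      terms <- lapply(spec$terms, evalTerm, data = data, sex = sex)
      out <- Reduce(if (type == "all") `&` else `|`, terms)
      # any required input missing makes the composite missing, never a
      # silent FALSE (or TRUE) from three-valued logic
      out[Reduce(`|`, lapply(terms, is.na))] <- NA
      out
    },
    stop("unknown spec type: ", type, call. = FALSE))
}

#' Derive the full set of dichotomous clinical variables
#'
#' Computes the composed continuous inputs first — Friedewald LDL from
#' total cholesterol/HDL/triglycerides and CKD-EPI eGFR from
#' creatinine/age/sex — whenever those columns are absent but their
#' ingredients are present, then applies every binarization spec. The
#' three age bands are mutually exclusive and exhaustive for non-missing
#' age.
#'
#' @param data data.frame or DataFrame of raw clinical columns (creatinine
#'   in µmol/L unless \code{creatinineUnits} says otherwise).
#' @param specs list of specs, default [defaultClinicalSpecs()].
#' @param sexVar sex column name.
#' @param creatinineUnits declared creatinine units ("umol/L" or "mg/dL");
#'   never auto-detected.
#' @param highPressureOr use the OR of the systolic/diastolic cutoffs for
#'   \code{high_pressure} instead of the default AND.
#' @return data.frame of logical columns, one per spec, with an attribute
#'   \code{"provenance"} listing each phenotype's required input columns.
#' @export
deriveClinicalVariables <- function(data, specs = defaultClinicalSpecs(),
                                    sexVar = "sex",
                                    creatinineUnits = "umol/L",
                                    highPressureOr = FALSE) {
  data <- as.data.frame(data)
  if (!"ldl" %in% names(data) &&
      all(c("totchol", "hdl", "trig") %in% names(data)))
    data$ldl <- friedewaldLDL(data$totchol, data$hdl, data$trig)
  if (!"egfr" %in% names(data) &&
      all(c("creatinine", "age", sexVar) %in% names(data)))
    data$egfr <- ckdEpiEGFR(data$creatinine, data$age, data[[sexVar]],
                            units = creatinineUnits)
  if (highPressureOr && "high_pressure" %in% names(specs))
    specs$high_pressure$type <- "any"
  out <- lapply(specs, deriveBinary, data = data, sexVar = sexVar)
  res <- as.data.frame(out, optional = TRUE)
  rownames(res) <- rownames(data)
  attr(res, "provenance") <- lapply(specs, function(s) {
    if (!is.null(s$terms)) vapply(s$terms, `[[`, "", "source") else s$source
  })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
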