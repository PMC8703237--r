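# Tabular dialect: UTF-8, tab-separated, header row, "NA" for missing.
# Numeric columns are written with 17 significant digits so a write/read
# round-trip reproduces the doubles bit for bit.

fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
  out
}

#' Write a cohort dataset as TSV
#'
#' One row per sample: \code{sample_id}, \code{cohort}, the remaining
#' sample metadata (sex, age, clinical columns, survival follow-up), then
#' the marker concentrations by panel name. The dialect is UTF-8,
#' tab-separated, header row, "NA" for missing; numerics carry enough
#' digits for a bit-exact round-trip through [readDataset()].
#'
#' @param dataset a [CohortExperiment-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDataset <- function(dataset, path) {
  cd <- as.data.frame(colData(dataset))
  X <- concentrations(dataset)
  df <- cbind(cd, as.data.frame(X, optional = TRUE))
  front <- intersect(c("sample_id", "cohort", "family_id", "sex", "age"),
                     names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  for (j in seq_along(df)) if (is.double(df[[j]])) df[[j]] <- fmtNum(df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort dataset from TSV
#'
#' Inverse of [writeDataset()]. Columns matching the panel's markers become
#' the concentration matrix; everything else becomes sample metadata.
#'
#' @param path TSV file written by [writeDataset()].
#' @param panel a [MetabolitePanel-class] identifying the marker columns.
#' @return A [CohortExperiment-class].
#' @export
readDataset <- function(path, panel = defaultPanel()) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  mk <- intersect(markers(panel), names(df))
  if (!length(mk)) stop("no panel marker columns found in ", path,
                        call. = FALSE)
  X <- as.matrix(df[, mk, drop = FALSE])
  cd <- df[, setdiff(names(df), mk), drop = FALSE]
  rn <- as.character(cd$sample_id)
  se <- SummarizedExperiment(
    assays = list(conc = t(X)),
    rowData = DataFrame(marker = mk,
                        class = unname(markerClasses(panel)[mk]),
                        row.names = mk),
    colData = DataFrame(cd, row.names = rn))
  colnames(se) <- rn
  as(se, "CohortExperiment")
}

#' Serialize a surrogate model to JSON
#'
#' The artifact carries a schema version, the phenotype name, the panel,
#' intercept and coefficients, the penalty settings and the scaling
#' parameters — everything needed to project the surrogate onto new raw
#' data with [predictSurrogate()].
#'
#' @param model a [SurrogateModel-class].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSurrogateModel <- function(model, path) {
  obj <- list(
    schema = "metaboSurrogates/model/1",
    phenotype = model@phenotype,
    panel = names(model@beta),
    intercept = model@intercept,
    beta = as.list(model@beta),
    alpha = model@alpha,
    lambda = model@lambda,
    center = as.list(model@center),
    scale = as.list(model@scale),
    n = model@metadata$n,
    prevalence = model@metadata$prevalence,
    seed = model@metadata$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a surrogate model from JSON
#'
#' @param path JSON file written by [writeSurrogateModel()].
#' @return A [SurrogateModel-class].
#' @export
readSurrogateModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "metaboSurrogates/model/1"))
    stop("unrecognized model schema in ", path, call. = FALSE)
  new("SurrogateModel", phenotype = obj$phenotype,
      intercept = obj$intercept,
      beta = setNames(unlist(obj$beta), names(obj$beta)),
      alpha = obj$alpha, lambda = obj$lambda,
      center = if (length(obj$center)) unlist(obj$center) else numeric(),
      scale = if (length(obj$scale)) unlist(obj$scale) else numeric(),
      metadata = list(n = obj$n, prevalence = obj$prevalence,
                      seed = obj$seed))
}
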