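#' Construct a metabolite panel
#'
#' @param markers character vector of unique marker names.
#' @param classes character vector of class labels (one per marker, values
#'   from [panelClassLevels()]).
#' @param exclusions character vector of markers to drop at
#'   [selectPanel()] time (must be a subset of \code{markers}).
#' @return A [MetabolitePanel-class].
#' @examples
#' MetabolitePanel(c("Glc", "Lac"), rep("glycolysis-related", 2))
#' @export
MetabolitePanel <- function(markers, classes, exclusions = character()) {
  if (!all(exclusions %in% markers))
    stop("exclusions must be a subset of the panel markers", call. = FALSE)
  new("MetabolitePanel", markers = as.character(markers),
      classes = as.character(classes),
      exclusions = as.character(exclusions))
}

#' Default quantitative NMR marker panel
#'
#' A 62-marker panel in the style of a targeted proton-NMR metabolomics
#' platform: lipoprotein-lipid subclass and routine lipid concentrations,
#' fatty-acid composition, amino acids, glycolysis-related metabolites,
#' ketone bodies, and markers of fluid balance and inflammation. Six
#' markers that commonly fail to reach detection thresholds (the extreme
#' lipoprotein size-fraction lipids and 3-hydroxybutyrate) are listed as
#' exclusions, leaving the 56 retained markers that form the default
#' feature space of the surrogate models. Panel content is configuration,
#' not a fixed constant: supply your own [MetabolitePanel()] to work with a
#' different marker set.
#'
#' @return A [MetabolitePanel-class] with 62 markers, 56 of which survive
#'   the exclusion list.
#' @examples
#' p <- defaultPanel()
#' length(setdiff(markers(p), exclusions(p)))  # 56
#' @export
defaultPanel <- function() {
  def <- list(
    "amino acids" = c("Ala", "Gln", "Gly", "His", "Ile", "Leu", "Val",
                      "Phe", "Tyr"),
    "glycolysis-related" = c("Glc", "Lac", "Cit", "Pyr"),
    "ketone bodies" = c("AcAce", "bOHBut"),
    "fluid balance" = c("Alb", "Crea"),
    "inflammation" = c("Gp"),
    "fatty acids" = c("TotFA", "DHA", "LA", "FAw3", "FAw6", "MUFA", "PUFA",
                      "SFA", "UnSat"),
    "lipoprotein lipids" = c(
      "XXL_VLDL_L", "XL_VLDL_L", "L_VLDL_L", "M_VLDL_L", "S_VLDL_L",
      "XS_VLDL_L", "IDL_L", "L_LDL_L", "M_LDL_L", "S_LDL_L", "XL_HDL_L",
      "L_HDL_L", "M_HDL_L", "S_HDL_L", "Serum_C", "VLDL_C", "LDL_C",
      "HDL_C", "HDL2_C", "HDL3_C", "EstC", "FreeC", "Serum_TG", "VLDL_TG",
      "LDL_TG", "HDL_TG", "TotPG", "PC", "SM", "TotCho", "ApoA1", "ApoB",
      "VLDL_D", "LDL_D", "HDL_D"))
  MetabolitePanel(
    markers = unlist(def, use.names = FALSE),
    classes = rep(names(def), lengths(def)),
    exclusions = c("bOHBut", "XXL_VLDL_L", "XL_VLDL_L", "L_VLDL_L",
                   "XL_HDL_L", "L_HDL_L"))
}

#' Restrict a dataset to the retained panel markers
#'
#' Drops the panel's excluded markers and reorders the remaining ones into
#' panel order. A retained marker absent from the dataset is a hard error
#' naming the marker, mirroring the policy of excluding whole cohorts that
#' do not report the full panel rather than silently working with a
#' reduced feature space.
#'
#' @param dataset a [CohortExperiment-class].
#' @param panel a [MetabolitePanel-class].
#' @return The dataset restricted to \code{setdiff(markers(panel),
#'   exclusions(panel))}, in panel order.
#' @export
selectPanel <- function(dataset, panel) {
  stopifnot(is(dataset, "CohortExperiment"), is(panel, "MetabolitePanel"))
  keep <- setdiff(markers(panel), exclusions(panel))
  absent <- setdiff(keep, rownames(dataset))
  if (length(absent))
    stop("dataset is missing required panel marker(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  dataset[keep, ]
}
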