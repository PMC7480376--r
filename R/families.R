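#' Infer CAZy/accessory model class from a model name
#'
#' Maps an HMM model name to its functional class using the naming conventions
#' of the dbCAN family HMMs extended with the cellulosome and PUL marker models
#' (cohesin, dockerin, SusD, SusC/TIGR04056). Subfamily suffixes (e.g.
#' \code{GH5_4}, \code{dockerin_I}) are ignored for class inference but always
#' preserved in the model name itself.
#'
#' Mapping: \code{GH*} -> GH, \code{GT*} -> GT, \code{CE*} -> CE, \code{PL*}
#' -> PL, \code{AA*} -> AA, \code{CBM*} -> CBM, \code{SLH*} -> SLH,
#' \code{cohesin*} -> COHESIN, \code{dockerin*} -> DOCKERIN, \code{SusD} ->
#' SUSD, \code{SusC} or \code{TIGR04056} -> SUSC, \code{DUF*} -> DUF,
#' anything else -> OTHER. Matching of cohesin/dockerin/SusC/SusD is
#' case-insensitive (annotation tables mix e.g. \code{Dockerin_I} and
#' \code{dockerin_I}).
#'
#' @param model_name character vector of model names.
#' @return character vector of classes, one of \code{GH, GT, CE, PL, AA, CBM,
#'   SLH, COHESIN, DOCKERIN, SUSC, SUSD, DUF, OTHER}.
#' @examples
#' model_class(c("GH5_4", "CBM22", "dockerin_I", "TIGR04056", "DUF4832"))
#' @export
model_class <- function(model_name) {
  stopifnot(is.character(model_name))
  cls <- rep("OTHER", length(model_name))
  cls[grepl("^GH[0-9]", model_name)] <- "GH"
  cls[grepl("^GT[0-9]", model_name)] <- "GT"
  cls[grepl("^CE[0-9]", model_name)] <- "CE"
  cls[grepl("^PL[0-9]", model_name)] <- "PL"
  cls[grepl("^AA[0-9]", model_name)] <- "AA"
  cls[grepl("^CBM[0-9]", model_name)] <- "CBM"
  cls[grepl("^SLH", model_name)] <- "SLH"
  cls[grepl("^cohesin", model_name, ignore.case = TRUE)] <- "COHESIN"
  cls[grepl("^dockerin", model_name, ignore.case = TRUE)] <- "DOCKERIN"
  cls[grepl("^SusD", model_name, ignore.case = TRUE)] <- "SUSD"
  cls[grepl("^SusC", model_name, ignore.case = TRUE) |
        model_name == "TIGR04056"] <- "SUSC"
  cls[grepl("^DUF[0-9]", model_name)] <- "DUF"
  cls
}

#' Strip the trailing subfamily token from a model name
#'
#' \code{GH5_4 -> GH5}, \code{dockerin_I -> dockerin}, \code{GH13_9 -> GH13}.
#' Used for family-level lookups (substrate categories, heatmap rows); the
#' subfamily-resolved name is kept everywhere architectures are compared.
#'
#' @param model_name character vector.
#' @return character vector of base family names.
#' @export
base_family <- function(model_name) {
  sub("_[0-9IVXivx]+$", "", model_name)
}

classes_catalytic <- c("GH", "CE", "PL", "AA", "GT")
classes_accessory <- c("CBM", "SLH", "DOCKERIN", "COHESIN")
classes_cazy      <- c("GH", "GT", "CE", "PL", "AA", "CBM")

#' Default substrate-category map for CAZy families
#'
#' Groups CAZy families by their action on plant cell-wall components:
#' cellulases (GH5, GH9, GH30, GH51, GH74, GH94), hemicellulases, pectinases,
#' amylases and oligosaccharide-degrading enzymes. Families not listed map to
#' \code{"other"}; the map is total over family names.
#'
#' @return named character vector, family (subfamily-stripped) -> category.
#' @export
default_function_map <- function() {
  m <- c(
    GH5 = "cellulase", GH9 = "cellulase", GH30 = "cellulase",
    GH51 = "cellulase", GH74 = "cellulase", GH94 = "cellulase",
    GH10 = "hemicellulase", GH11 = "hemicellulase", GH16 = "hemicellulase",
    GH26 = "hemicellulase", GH43 = "hemicellulase", GH53 = "hemicellulase",
    GH67 = "hemicellulase", GH115 = "hemicellulase",
    CE1 = "hemicellulase", CE2 = "hemicellulase", CE3 = "hemicellulase",
    CE6 = "hemicellulase",
    GH28 = "pectinase", GH78 = "pectinase", GH88 = "pectinase",
    GH105 = "pectinase", PL1 = "pectinase", PL9 = "pectinase",
    PL10 = "pectinase", PL11 = "pectinase",
    GH13 = "amylase", GH77 = "amylase",
    GH1 = "oligosaccharide-degrading", GH2 = "oligosaccharide-degrading",
    GH3 = "oligosaccharide-degrading", GH29 = "oligosaccharide-degrading",
    GH31 = "oligosaccharide-degrading", GH35 = "oligosaccharide-degrading",
    GH36 = "oligosaccharide-degrading", GH38 = "oligosaccharide-degrading",
    GH39 = "oligosaccharide-degrading", GH42 = "oligosaccharide-degrading",
    GH97 = "oligosaccharide-degrading"
  )
  m
}

#' Look up substrate categories for model names
#'
#' @param model_name character vector of (possibly subfamily-resolved) model
#'   names.
#' @param function_map named vector as returned by
#'   \code{\link{default_function_map}}.
#' @return character vector of categories (\code{"other"} for unknown).
#' @export
substrate_category <- function(model_name, function_map = default_function_map()) {
  fam <- base_family(model_name)
  out <- unname(function_map[fam])
  out[is.na(out)] <- "other"
  out
}

# Gene-level functional label from the model names seen on its protein.
# Regulator HMM names recognised by the locus caller.
regulator_models <- c("HTH_AraC", "AraC", "GntR", "LacI", "MarR", "HTCS")

functional_label_one <- function(models) {
  if (length(models) == 0L) return("OTHER")
  cls <- model_class(models)
  if (any(cls == "SUSC")) return("SUSC")
  if (any(cls == "SUSD")) return("SUSD")
  if (any(cls %in% classes_cazy)) return("CAZYME")
  if (any(grepl("^Peptidase", models))) return("PEPTIDASE")
  if (any(models %in% regulator_models)) return("REGULATOR")
  if (any(cls == "COHESIN")) return("COHESIN")
  if (any(cls == "DOCKERIN")) return("DOCKERIN")
  "OTHER"
}
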