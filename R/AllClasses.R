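#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   rowData<- colData colData<-
NULL

#' Container for morphological profiles
#'
#' A \code{MorphologyProfiles} object holds a features-by-observations matrix
#' of morphology measurements (observations are single cells or wells)
#' together with per-observation platemap metadata in \code{colData} and
#' per-feature annotation (e.g. ground-truth roles for simulated data) in
#' \code{rowData}.  It extends
#' \linkS4class{SummarizedExperiment} with a \code{level} slot distinguishing
#' cell-level from well-level tables.
#'
#' @slot level character, either \code{"cell"} or \code{"well"}.
#'
#' @section Validity:
#' Feature (row) names must be present and unique; the \code{"features"}
#' assay must be numeric.  Well-level objects must carry \code{plate_id} and
#' \code{well_id} metadata columns with unique (plate, well) pairs.
#'
#' @seealso [MorphologyProfiles()] for the constructor,
#'   [aggregateWells()], [normalizeProfiles()], [selectFeatures()].
#' @name MorphologyProfiles-class
#' @aliases MorphologyProfiles-class
#' @exportClass MorphologyProfiles
setClass("MorphologyProfiles",
    contains = "SummarizedExperiment",
    slots = c(level = "character"),
    prototype = prototype(level = "well")
)

setValidity("MorphologyProfiles", function(object) {
    msg <- NULL
    if (length(object@level) != 1L || !object@level %in% c("cell", "well"))
        msg <- c(msg, "'level' must be \"cell\" or \"well\"")
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is missing")
    else if (!is.numeric(assay(object, "features")))
        msg <- c(msg, "assay 'features' must be numeric")
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "feature (row) names must be present and unique")
    if (identical(object@level, "well")) {
        cd <- colData(object)
        need <- c("plate_id", "well_id")
        if (!all(need %in% colnames(cd)))
            msg <- c(msg, "well-level profiles need 'plate_id' and 'well_id' metadata")
        else if (anyDuplicated(paste(cd$plate_id, cd$well_id)))
            msg <- c(msg, "(plate_id, well_id) pairs must be unique at well level")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MorphologyProfiles object
#'
#' @param features numeric matrix, features in rows (named), observations in
#'   columns.
#' @param colData \code{DataFrame} or \code{data.frame} of per-observation
#'   platemap metadata (plate_id, well_id, clone_id, resistance_status,
#'   treatment, incubation_time_h, batch, cell_count as available).
#' @param level \code{"cell"} or \code{"well"}.
#' @param rowData optional per-feature annotation.
#'
#' @return A \linkS4class{MorphologyProfiles} object.
#' @examples
#' m <- matrix(rnorm(20), nrow = 4,
#'             dimnames = list(paste0("f", 1:4), NULL))
#' cd <- S4Vectors::DataFrame(plate_id = "p1", well_id = paste0("A", 1:5))
#' MorphologyProfiles(m, cd, level = "well")
#' @export
MorphologyProfiles <- function(features, colData, level = c("well", "cell"),
                               rowData = NULL) {
    level <- match.arg(level)
    features <- as.matrix(features)
    if (!is.numeric(features))
        stop("feature values must be numeric")
    colData <- as(colData, "DataFrame")
    se <- SummarizedExperiment(
        assays = SimpleList(features = features),
        colData = colData
    )
    if (!is.null(rowData))
        rowData(se) <- as(rowData, "DataFrame")
    new("MorphologyProfiles", se, level = level)
}

#' @describeIn MorphologyProfiles-class level ("cell" or "well") of a profiles
#'   object.
#' @param x a \code{MorphologyProfiles} object.
#' @export
profileLevel <- function(x) {
    stopifnot(is(x, "MorphologyProfiles"))
    x@level
}

#' @describeIn MorphologyProfiles-class feature names.
#' @export
featureNames <- function(x) rownames(x)

#' @describeIn MorphologyProfiles-class ground-truth feature role table
#'   (simulated data), or the \code{rowData} annotation generally.
#' @export
featureRoles <- function(x) rowData(x)

setMethod("show", "MorphologyProfiles", function(object) {
    cat("MorphologyProfiles (", object@level, "-level): ",
        nrow(object), " features x ", ncol(object), " ",
        if (object@level == "cell") "cells" else "wells", "\n", sep = "")
    callNextMethod()
})

#' Directional morphological signature
#'
#' Holds the result of signature discovery: the ordered sets of features with
#' higher (\code{up}) and lower (\code{down}) values in resistant clones, the
#' per-feature discovery statistics, and the Bonferroni-adjusted significance
#' threshold that defined membership.
#'
#' @slot upFeatures character, features higher in resistant clones (ordered by
#'   increasing status p-value).
#' @slot downFeatures character, features lower in resistant clones.
#' @slot stats \code{DataFrame} of per-feature discovery statistics
#'   (status difference, Tukey-adjusted p-values, exclusion attribution).
#' @slot alpha numeric, the Bonferroni-adjusted per-feature threshold
#'   actually applied.
#'
#' @seealso [buildSignature()], [scoreProfiles()].
#' @name MorphSignature-class
#' @exportClass MorphSignature
setClass("MorphSignature",
    slots = c(
        upFeatures = "character",
        downFeatures = "character",
        stats = "DataFrame",
        alpha = "numeric"
    )
)

setValidity("MorphSignature", function(object) {
    msg <- NULL
    if (length(intersect(object@upFeatures, object@downFeatures)))
        msg <- c(msg, "up and down feature sets must be disjoint")
    if (anyDuplicated(object@upFeatures) || anyDuplicated(object@downFeatures))
        msg <- c(msg, "feature sets must not contain duplicates")
    if (length(object@alpha) != 1L ||
        (!is.na(object@alpha) && object@alpha < 0))
        msg <- c(msg, "'alpha' must be a single nonnegative number")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MorphSignature
#'
#' Usually produced by [buildSignature()]; the constructor is exported so
#' externally defined signatures (e.g. read from file) can be scored.
#'
#' @param up,down character vectors of feature names (disjoint).
#' @param stats optional per-feature statistics \code{DataFrame}.
#' @param alpha the per-feature significance threshold that defined the
#'   signature (informational when constructing by hand).
#' @return A \linkS4class{MorphSignature}.
#' @export
MorphSignature <- function(up, down, stats = DataFrame(), alpha = NA_real_) {
    new("MorphSignature",
        upFeatures = as.character(up), downFeatures = as.character(down),
        stats = as(stats, "DataFrame"), alpha = as.numeric(alpha))
}

#' @describeIn MorphSignature-class features higher in resistant clones.
#' @param x a \code{MorphSignature}.
#' @export
upFeatures <- function(x) x@upFeatures

#' @describeIn MorphSignature-class features lower in resistant clones.
#' @export
downFeatures <- function(x) x@downFeatures

#' @describeIn MorphSignature-class per-feature discovery statistics.
#' @export
signatureStats <- function(x) x@stats

#' @describeIn MorphSignature-class the applied per-feature threshold.
#' @export
signatureAlpha <- function(x) x@alpha

setMethod("length", "MorphSignature", function(x)
    length(x@upFeatures) + length(x@downFeatures))

setMethod("show", "MorphSignature", function(object) {
    cat("MorphSignature: ", length(object@upFeatures), " up + ",
        length(object@downFeatures), " down features",
        if (!is.na(object@alpha))
            paste0(" (alpha* = ", signif(object@alpha, 3), ")"),
        "\n", sep = "")
    if (length(object@upFeatures))
        cat("  up:   ", paste(utils::head(object@upFeatures, 4), collapse = ", "),
            if (length(object@upFeatures) > 4) ", ...", "\n", sep = "")
    if (length(object@downFeatures))
        cat("  down: ", paste(utils::head(object@downFeatures, 4), collapse = ", "),
            if (length(object@downFeatures) > 4) ", ...", "\n", sep = "")
})

#' Per-feature covariate model fits
#'
#' Result of [fitCovariateModel()]: for every feature, the OLS fit of the
#' covariate model (resistance status + batch + incubation time + clone) and
#' per-covariate Tukey HSD post-hoc families.
#'
#' @slot features character, feature names.
#' @slot rSquared numeric, per-feature goodness of fit.
#' @slot coefficients matrix (model terms x features); aliased terms are NA.
#' @slot residualVariance numeric, per-feature residual variance of the OLS
#'   fit.
#' @slot tukey named list, one element per categorical covariate; each element
#'   has \code{levels}, \code{n} (group sizes), \code{pairs} (2 x npairs level
#'   labels), \code{diff} and \code{padj} (features x npairs matrices of mean
#'   differences and FWER-adjusted p-values).
#' @slot nobs integer, number of wells used.
#' @slot covariates character, covariates included.
#' @name FeatureModelFit-class
#' @exportClass FeatureModelFit
setClass("FeatureModelFit",
    slots = c(
        features = "character",
        rSquared = "numeric",
        coefficients = "matrix",
        residualVariance = "numeric",
        tukey = "list",
        nobs = "integer",
        covariates = "character"
    )
)

setMethod("show", "FeatureModelFit", function(object) {
    cat("FeatureModelFit: ", length(object@features), " features, ",
        object@nobs, " wells\n", sep = "")
    cat("  covariates: ", paste(object@covariates, collapse = ", "), "\n",
        sep = "")
    cat("  Tukey families: ", paste(names(object@tukey), collapse = ", "),
        "\n", sep = "")
})

#' @describeIn FeatureModelFit-class per-feature R-squared.
#' @param x a \code{FeatureModelFit}.
#' @export
modelRSquared <- function(x) x@rSquared

#' @describeIn FeatureModelFit-class Tukey HSD families (list by covariate).
#' @export
tukeyFamilies <- function(x) x@tukey
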