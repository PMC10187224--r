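#' Median-aggregate single cells into well-level profiles
#'
#' Collapses a cell-level table to one profile per (plate, well): each
#' feature becomes the median over that well's cells, a \code{cell_count}
#' metadata column records how many cells were aggregated, and metadata that
#' is constant within a well is carried through.  The result is independent
#' of cell row order.
#'
#' @param cells cell-level \linkS4class{MorphologyProfiles}.
#' @param platemap optional platemap; wells present in the platemap but
#'   containing zero cells are reported with a warning (they cannot appear in
#'   the output).
#' @return well-level \linkS4class{MorphologyProfiles} with per-feature
#'   \code{rowData} carried over.
#' @examples
#' cfg <- syntheticConfig(n_features = 10, n_signature_up = 1,
#'                        n_signature_down = 1, n_batch_confounded = 0,
#'                        n_time_confounded = 0, n_count_confounded = 0,
#'                        n_clone_idiosyncratic = 0, n_correlated_block = 0,
#'                        n_wt_clones = 1, n_res_clones = 1,
#'                        replicates_per_clone = 2, n_batches = 1,
#'                        cells_per_well_range = c(3L, 5L))
#' pm <- generatePlatemap(cfg)
#' wells <- aggregateWells(simulateCells(pm, cfg))
#' @importFrom matrixStats rowMedians
#' @export
aggregateWells <- function(cells, platemap = NULL) {
    stopifnot(is(cells, "MorphologyProfiles"))
    if (profileLevel(cells) != "cell")
        stop("aggregateWells() expects a cell-level table")
    if (ncol(cells) == 0L)
        stop("cell table is empty")
    cd <- colData(cells)
    if (!all(c("plate_id", "well_id") %in% colnames(cd)))
        stop("cell table lacks 'plate_id'/'well_id' metadata")
    key <- paste(cd$plate_id, cd$well_id, sep = "\r")
    groups <- split(seq_len(ncol(cells)), key)

    if (!is.null(platemap)) {
        pm_key <- paste(platemap$plate_id, platemap$well_id, sep = "\r")
        empty <- setdiff(pm_key, names(groups))
        if (length(empty))
            warning("omitting ", length(empty), " platemap well(s) with zero ",
                    "cells: ", paste(gsub("\r", ":", empty), collapse = ", "))
    }

    X <- assay(cells, "features")
    M <- vapply(groups, function(idx)
        matrixStats::rowMedians(X, cols = idx, na.rm = FALSE),
        numeric(nrow(X)))
    if (nrow(X) == 1L) M <- matrix(M, nrow = 1L)
    rownames(M) <- rownames(X)

    meta_cols <- setdiff(colnames(cd), "cell_id")
    well_cd <- do.call(rbind, lapply(groups, function(idx) {
        sub <- cd[idx, meta_cols, drop = FALSE]
        for (nm in meta_cols) {
            u <- unique(sub[[nm]])
            if (length(u) > 1L)
                stop("integrity error: metadata column '", nm,
                     "' is not constant within well ",
                     unique(sub$plate_id), ":", unique(sub$well_id))
        }
        sub[1L, , drop = FALSE]
    }))
    well_cd$cell_count <- lengths(groups)
    rownames(well_cd) <- paste(well_cd$plate_id, well_cd$well_id, sep = ":")
    colnames(M) <- rownames(well_cd)

    out <- MorphologyProfiles(M, well_cd, level = "well",
                              rowData = rowData(cells))
    metadata(out) <- metadata(cells)
    out
}

#' Annotate well profiles with platemap metadata
#'
#' Joins per-well experimental annotations (clone, resistance status, batch,
#' incubation time, treatment) onto well-level profiles by (plate, well).
#' Row count is unchanged; existing metadata columns of the same name are
#' replaced by the platemap's values.
#'
#' @param wells well-level \linkS4class{MorphologyProfiles}.
#' @param platemap \code{DataFrame} with \code{plate_id}, \code{well_id} and
#'   annotation columns; (plate, well) must be unique.
#' @return annotated well-level \linkS4class{MorphologyProfiles}.
#' @export
annotateProfiles <- function(wells, platemap) {
    stopifnot(is(wells, "MorphologyProfiles"))
    if (profileLevel(wells) != "well")
        stop("annotateProfiles() expects a well-level table")
    pm <- as(platemap, "DataFrame")
    pm_key <- paste(pm$plate_id, pm$well_id, sep = ":")
    if (anyDuplicated(pm_key))
        stop("integrity error: platemap has duplicated (plate, well) entries: ",
             paste(unique(pm_key[duplicated(pm_key)]), collapse = ", "))
    cd <- colData(wells)
    key <- paste(cd$plate_id, cd$well_id, sep = ":")
    hit <- match(key, pm_key)
    if (anyNA(hit))
        stop("profile well(s) absent from platemap: ",
             paste(key[is.na(hit)], collapse = ", "))
    add <- pm[hit, setdiff(colnames(pm), c("plate_id", "well_id")),
              drop = FALSE]
    keep <- cd[, setdiff(colnames(cd), colnames(add)), drop = FALSE]
    colData(wells) <- cbind(keep, add)
    wells
}

#' Per-plate z-score normalization
#'
#' Standardizes every feature within each plate to zero mean and unit
#' variance, so features are comparable across plates and on a common scale.
#' The population standard deviation (divide by \eqn{n}) is used, the common
#' convention in image-based profiling pipelines; set
#' \code{sd_type = "sample"} for the \eqn{n-1} denominator.  Features with
#' zero spread on a plate cannot be standardized there and are passed
#' through as NA, to be removed by the missing-value rule of
#' [selectFeatures()].
#'
#' @param wells annotated well-level \linkS4class{MorphologyProfiles}.
#' @param sd_type \code{"population"} (default) or \code{"sample"}.
#' @return well-level \linkS4class{MorphologyProfiles} of z-scores.
#' @export
normalizeProfiles <- function(wells, sd_type = c("population", "sample")) {
    sd_type <- match.arg(sd_type)
    stopifnot(is(wells, "MorphologyProfiles"))
    if (profileLevel(wells) != "well")
        stop("normalizeProfiles() expects a well-level table")
    X <- assay(wells, "features")
    plate <- colData(wells)$plate_id
    for (p in unique(plate)) {
        idx <- which(plate == p)
        if (length(idx) < 2L)
            stop("plate '", p, "' has a single well; ",
                 "standard deviation is undefined")
        sub <- X[, idx, drop = FALSE]
        mu <- rowMeans(sub)
        if (sd_type == "population") {
            sdv <- sqrt(rowMeans((sub - mu)^2))
        } else {
            sdv <- matrixStats::rowSds(sub)
        }
        z <- (sub - mu) / sdv
        z[sdv == 0 | is.na(sdv), ] <- NA_real_
        X[, idx] <- z
    }
    assay(wells, "features") <- X
    wells
}

#' Feature-selection configuration
#'
#' Thresholds and options for the five-rule feature selection of
#' [selectFeatures()], applied in the fixed order blocklist, missing values,
#' low variance, outliers, correlation.
#'
#' @param correlation_threshold drop one of each feature pair with
#'   \eqn{|r| >} this Pearson correlation (default 0.9).
#' @param outlier_sd_threshold drop features with any value exceeding this
#'   many standard deviations on the normalized scale (default 15).
#' @param low_variance_unique_ratio drop features whose most frequent value
#'   occupies more than this fraction of wells (default 0.95); features with
#'   variance below \code{variance_epsilon} are also dropped.
#' @param variance_epsilon absolute variance floor (default 1e-12).
#' @param blocklist character vector of feature-name regular expressions
#'   excluded a priori (default empty).
#' @param drop_missing drop features containing missing values (default
#'   TRUE).
#' @return classed list of selection settings.
#' @export
featureSelectionConfig <- function(correlation_threshold = 0.9,
                                   outlier_sd_threshold = 15,
                                   low_variance_unique_ratio = 0.95,
                                   variance_epsilon = 1e-12,
                                   blocklist = character(),
                                   drop_missing = TRUE) {
    if (correlation_threshold <= 0 || correlation_threshold > 1)
        stop("'correlation_threshold' must lie in (0, 1]")
    if (outlier_sd_threshold <= 0)
        stop("'outlier_sd_threshold' must be positive")
    structure(list(
        correlation_threshold = correlation_threshold,
        outlier_sd_threshold = outlier_sd_threshold,
        low_variance_unique_ratio = low_variance_unique_ratio,
        variance_epsilon = variance_epsilon,
        blocklist = as.character(blocklist),
        drop_missing = isTRUE(drop_missing)
    ), class = "FeatureSelectionConfig")
}

#' Rule-based feature selection on normalized well profiles
#'
#' Removes unreliable features in a fixed rule order so every dropped
#' feature is attributed to exactly one rule:
#' \enumerate{
#'   \item \strong{blocklist} — name matches a blocklist pattern;
#'   \item \strong{missing} — any missing value (when \code{drop_missing});
#'   \item \strong{low_variance} — near-constant (most frequent value above
#'     the unique-ratio threshold, or variance below the epsilon);
#'   \item \strong{outlier} — any |value| above the outlier threshold on the
#'     normalized scale (suspected measurement error);
#'   \item \strong{correlation} — for each remaining pair with |Pearson r|
#'     above the threshold, the member with the larger mean absolute
#'     correlation to all other features is dropped (ties broken by feature
#'     name), keeping the less redundant feature.
#' }
#' Selection is computed on the union of all plates present in the table
#' (the analytical dataset), not per plate.
#'
#' @param wells normalized well-level \linkS4class{MorphologyProfiles}.
#' @param config a [featureSelectionConfig()].
#' @return the profiles restricted to surviving features; the report (a
#'   \code{DataFrame} with columns \code{feature}, \code{rule},
#'   \code{statistic}) is stored in \code{metadata()$selection_report} and
#'   retrievable with [selectionReport()].
#' @export
selectFeatures <- function(wells, config = featureSelectionConfig()) {
    stopifnot(is(wells, "MorphologyProfiles"),
              is(config, "FeatureSelectionConfig"))
    if (profileLevel(wells) != "well")
        stop("selectFeatures() expects a well-level table")
    X <- assay(wells, "features")
    if (!is.numeric(X)) stop("non-numeric feature values")
    feats <- rownames(X)
    dropped <- DataFrame(feature = character(), rule = character(),
                         statistic = numeric())
    drop <- function(nms, rule, stat) {
        if (!length(nms)) return()
        dropped <<- rbind(dropped,
                          DataFrame(feature = nms, rule = rule,
                                    statistic = as.numeric(stat)))
        feats <<- setdiff(feats, nms)
    }

    if (length(config$blocklist)) {
        hit <- feats[Reduce(`|`, lapply(config$blocklist, grepl, x = feats))]
        drop(hit, "blocklist", NA_real_)
    }
    if (config$drop_missing) {
        nmiss <- rowSums(is.na(X[feats, , drop = FALSE]))
        drop(feats[nmiss > 0], "missing", nmiss[nmiss > 0])
    }
    if (length(feats)) {
        sub <- X[feats, , drop = FALSE]
        vars <- matrixStats::rowVars(sub)
        uratio <- apply(sub, 1L, function(v) max(table(v)) / length(v))
        low <- vars < config$variance_epsilon |
            uratio > config$low_variance_unique_ratio
        drop(feats[low], "low_variance", uratio[low])
    }
    if (length(feats)) {
        mx <- matrixStats::rowMaxs(abs(X[feats, , drop = FALSE]))
        out <- mx > config$outlier_sd_threshold
        drop(feats[out], "outlier", mx[out])
    }
    if (length(feats) > 1L) {
        C <- stats::cor(t(X[feats, , drop = FALSE]))
        diag(C) <- 0
        repeat {
            aC <- abs(C)
            aC[is.na(aC)] <- 0
            mx <- max(aC)
            if (is.na(mx) || mx <= config$correlation_threshold) break
            hit <- which(aC == mx, arr.ind = TRUE)
            ## deterministic pair choice: lexicographically first pair
            pair <- sort(rownames(C)[hit[1L, ]])
            means <- rowMeans(aC[pair, , drop = FALSE])
            victim <- if (abs(diff(means)) > .Machine$double.eps^0.5) {
                pair[which.max(means)]
            } else pair[2L]  # lexicographic tie-break: keep the first name
            drop(victim, "correlation", mx)
            keep <- setdiff(rownames(C), victim)
            C <- C[keep, keep, drop = FALSE]
            if (nrow(C) < 2L) break
        }
    }
    if (!length(feats))
        stop("feature selection removed every feature")

    out <- wells[feats, ]
    metadata(out)$selection_report <- dropped
    metadata(out)$selection_config <- config
    out
}

#' Retrieve the feature-selection report
#'
#' @param x a \linkS4class{MorphologyProfiles} returned by
#'   [selectFeatures()].
#' @return \code{DataFrame} attributing each dropped feature to one rule.
#' @export
selectionReport <- function(x) {
    rep <- metadata(x)$selection_report
    if (is.null(rep))
        stop("no selection report attached; run selectFeatures() first")
    rep
}
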