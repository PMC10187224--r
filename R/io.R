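#' Read and write profile tables, platemaps, signatures and reports
#'
#' Delimited-text I/O in the conventions of image-based profiling:
#' profile CSVs carry one row per observation with metadata columns prefixed
#' \code{Metadata_} and feature columns named after the features; platemaps
#' are plain CSVs with columns \code{plate_id}, \code{well_id},
#' \code{clone_id}, \code{resistance_status}, \code{treatment},
#' \code{incubation_time_h}, \code{batch}; signatures are two-column CSVs
#' (\code{feature}, \code{direction}) with a JSON statistics sidecar.
#'
#' @param x object to write.
#' @param path file path.
#' @return readers return the parsed object; writers return \code{path}
#'   invisibly.
#' @name morphosig-io
NULL

#' @rdname morphosig-io
#' @param profiles a \linkS4class{MorphologyProfiles}.
#' @importFrom data.table fwrite fread
#' @export
writeProfiles <- function(profiles, path) {
    stopifnot(is(profiles, "MorphologyProfiles"))
    cd <- as.data.frame(colData(profiles))
    colnames(cd) <- paste0("Metadata_", colnames(cd))
    tab <- cbind(cd, as.data.frame(t(assay(profiles, "features"))))
    data.table::fwrite(tab, path, row.names = FALSE)
    invisible(path)
}

#' @rdname morphosig-io
#' @param level level of the stored table (\code{"well"} or \code{"cell"}).
#' @export
readProfiles <- function(path, level = c("well", "cell")) {
    level <- match.arg(level)
    tab <- as.data.frame(data.table::fread(path))
    is_meta <- startsWith(colnames(tab), "Metadata_")
    cd <- tab[, is_meta, drop = FALSE]
    colnames(cd) <- sub("^Metadata_", "", colnames(cd))
    X <- t(as.matrix(tab[, !is_meta, drop = FALSE]))
    MorphologyProfiles(X, DataFrame(cd), level = level)
}

#' @rdname morphosig-io
#' @param platemap a platemap \code{DataFrame}.
#' @export
writePlatemap <- function(platemap, path) {
    data.table::fwrite(as.data.frame(platemap), path, row.names = FALSE)
    invisible(path)
}

#' @rdname morphosig-io
#' @export
readPlatemap <- function(path) {
    pm <- DataFrame(as.data.frame(data.table::fread(path)))
    need <- c("plate_id", "well_id", "clone_id", "resistance_status")
    miss <- setdiff(need, colnames(pm))
    if (length(miss))
        stop("platemap lacks column(s): ", paste(miss, collapse = ", "))
    st <- unique(pm[, c("clone_id", "resistance_status")])
    if (anyDuplicated(st$clone_id))
        stop("clone(s) mapped to more than one resistance status: ",
             paste(unique(st$clone_id[duplicated(st$clone_id)]),
                   collapse = ", "))
    pm
}

#' @rdname morphosig-io
#' @param signature a \linkS4class{MorphSignature}.
#' @param stats_path optional path for the JSON statistics sidecar.
#' @importFrom jsonlite write_json read_json
#' @export
writeSignature <- function(signature, path, stats_path = NULL) {
    tab <- data.frame(
        feature = c(upFeatures(signature), downFeatures(signature)),
        direction = c(rep("up", length(upFeatures(signature))),
                      rep("down", length(downFeatures(signature)))))
    data.table::fwrite(tab, path, row.names = FALSE)
    if (!is.null(stats_path)) {
        st <- signatureStats(signature)
        jsonlite::write_json(
            list(alpha = signatureAlpha(signature),
                 n_up = length(upFeatures(signature)),
                 n_down = length(downFeatures(signature)),
                 stats = as.data.frame(st)),
            stats_path, auto_unbox = TRUE, digits = NA, na = "null")
    }
    invisible(path)
}

#' @rdname morphosig-io
#' @export
readSignature <- function(path, stats_path = NULL) {
    tab <- as.data.frame(data.table::fread(path))
    if (!all(c("feature", "direction") %in% colnames(tab)))
        stop("signature file needs 'feature' and 'direction' columns")
    alpha <- NA_real_
    if (!is.null(stats_path)) {
        js <- jsonlite::read_json(stats_path, simplifyVector = TRUE)
        alpha <- js$alpha
    }
    MorphSignature(up = tab$feature[tab$direction == "up"],
                   down = tab$feature[tab$direction == "down"],
                   alpha = alpha)
}

#' @rdname morphosig-io
#' @param reports per-split evaluation list from [evaluateSplits()].
#' @export
writeEvaluation <- function(reports, path) {
    slim <- lapply(reports, function(r) {
        r$roc <- if (!is.null(r$roc)) as.data.frame(r$roc)
        r$min_threshold_point <- as.list(r$min_threshold_point)
        r
    })
    jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
}

#' @rdname morphosig-io
#' @param report a \code{DataFrame}/data.frame (e.g. a selection report or
#'   score table).
#' @export
writeTable <- function(report, path) {
    data.table::fwrite(as.data.frame(report), path, row.names = FALSE)
    invisible(path)
}
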