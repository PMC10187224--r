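#' Configuration for the synthetic plate simulator
#'
#' Defines the experimental design and planted effect structure of a
#' simulated Cell Painting style experiment: clonal cell lines that are
#' either drug-sensitive or drug-resistant, plated in a repeating serpentine
#' pattern across one plate per batch (imaging day), with single-cell
#' morphology features carrying planted resistance effects and nuisance
#' (batch, incubation-time, cell-count, clone-identity) effects.
#'
#' Feature roles are drawn disjointly: \code{n_signature_up} features are
#' shifted \eqn{+d} in resistant cells, \code{n_signature_down} shifted
#' \eqn{-d} (with \eqn{d} = \code{effect_size_status} in units of the
#' unit-variance cell-level noise); batch-, time- and count-confounded
#' features shift with the corresponding nuisance covariate by
#' \code{effect_size_nuisance}; clone-idiosyncratic features receive a
#' per-clone shift drawn from \eqn{N(0,
#' \code{effect_size_nuisance}^2)} (wild-type clones included, so the
#' within-wild-type exclusion rule is exercised); correlated-block features
#' share a single latent per-cell factor at pairwise correlation
#' \code{correlated_block_rho}; all remaining features are inert.
#'
#' On top of the unit Gaussian cell noise every non-block feature receives a
#' per-well random effect with standard deviation \code{well_effect_sd},
#' representing well-to-well biological variability that does not average
#' away with cell number.
#'
#' \code{outlier_rate} and \code{missing_rate} are per-feature affliction
#' probabilities applied to inert features: an outlier-afflicted feature has
#' one whole well's cells displaced 25 raw standard deviations (a
#' staining/measurement artifact); a missing-afflicted feature has a small
#' random fraction (1\%) of its cell values set to NA, which propagates to
#' NA well medians and exercises the missing-value filter.
#'
#' @param n_features total number of raw features.
#' @param n_signature_up,n_signature_down planted signature feature counts.
#' @param n_batch_confounded,n_time_confounded,n_count_confounded,n_clone_idiosyncratic
#'   nuisance-confounded feature counts.
#' @param n_correlated_block number of features in the shared-factor block.
#' @param correlated_block_rho pairwise correlation within the block, in
#'   \[0, 1\].
#' @param effect_size_status standardized status shift (Cohen's d at cell
#'   level).
#' @param effect_size_nuisance standardized shift per nuisance covariate.
#' @param n_wt_clones,n_res_clones number of sensitive / resistant clones.
#' @param replicates_per_clone replicate wells per clone (across batches).
#' @param n_batches number of batches (one plate per batch).
#' @param incubation_levels incubation durations in hours.
#' @param cells_per_well_range integer interval for per-well cell counts.
#' @param outlier_rate,missing_rate per-feature affliction probabilities.
#' @param well_effect_sd SD of the per-well random effect.
#' @param plate_rows,plate_cols plate geometry (default 96-well, 8 x 12).
#' @param seed RNG seed; identical config + seed gives byte-identical output.
#'
#' @return A validated \code{SyntheticConfig} (a classed list).
#' @seealso [generatePlatemap()], [simulateCells()]
#' @export
syntheticConfig <- function(
    n_features = 500L,
    n_signature_up = 10L,
    n_signature_down = 10L,
    n_batch_confounded = 5L,
    n_time_confounded = 5L,
    n_count_confounded = 5L,
    n_clone_idiosyncratic = 5L,
    n_correlated_block = 20L,
    correlated_block_rho = 0.95,
    effect_size_status = 1.5,
    effect_size_nuisance = 1.0,
    n_wt_clones = 5L,
    n_res_clones = 5L,
    replicates_per_clone = 20L,
    n_batches = 3L,
    incubation_levels = c(4, 13),
    cells_per_well_range = c(40L, 120L),
    outlier_rate = 0.01,
    missing_rate = 0.01,
    well_effect_sd = 0.5,
    plate_rows = 8L,
    plate_cols = 12L,
    seed = 42L) {
    cfg <- list(
        n_features = as.integer(n_features),
        n_signature_up = as.integer(n_signature_up),
        n_signature_down = as.integer(n_signature_down),
        n_batch_confounded = as.integer(n_batch_confounded),
        n_time_confounded = as.integer(n_time_confounded),
        n_count_confounded = as.integer(n_count_confounded),
        n_clone_idiosyncratic = as.integer(n_clone_idiosyncratic),
        n_correlated_block = as.integer(n_correlated_block),
        correlated_block_rho = as.numeric(correlated_block_rho),
        effect_size_status = as.numeric(effect_size_status),
        effect_size_nuisance = as.numeric(effect_size_nuisance),
        n_wt_clones = as.integer(n_wt_clones),
        n_res_clones = as.integer(n_res_clones),
        replicates_per_clone = as.integer(replicates_per_clone),
        n_batches = as.integer(n_batches),
        incubation_levels = as.numeric(incubation_levels),
        cells_per_well_range = as.integer(cells_per_well_range),
        outlier_rate = as.numeric(outlier_rate),
        missing_rate = as.numeric(missing_rate),
        well_effect_sd = as.numeric(well_effect_sd),
        plate_rows = as.integer(plate_rows),
        plate_cols = as.integer(plate_cols),
        seed = as.integer(seed)
    )
    class(cfg) <- "SyntheticConfig"
    validateSyntheticConfig(cfg)
    cfg
}

validateSyntheticConfig <- function(cfg) {
    counts <- c("n_features", "n_signature_up", "n_signature_down",
                "n_batch_confounded", "n_time_confounded", "n_count_confounded",
                "n_clone_idiosyncratic", "n_correlated_block",
                "n_wt_clones", "n_res_clones", "replicates_per_clone",
                "n_batches")
    for (nm in counts)
        if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
            stop("'", nm, "' must be a single nonnegative integer")
    special <- cfg$n_signature_up + cfg$n_signature_down +
        cfg$n_batch_confounded + cfg$n_time_confounded +
        cfg$n_count_confounded + cfg$n_clone_idiosyncratic +
        cfg$n_correlated_block
    if (special > cfg$n_features)
        stop("special feature roles (", special,
             ") exceed n_features (", cfg$n_features, ")")
    for (nm in c("effect_size_status", "effect_size_nuisance",
                 "well_effect_sd"))
        if (!is.finite(cfg[[nm]]))
            stop("'", nm, "' must be finite")
    for (nm in c("outlier_rate", "missing_rate"))
        if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
            stop("'", nm, "' must lie in [0, 1]")
    if (cfg$correlated_block_rho < 0 || cfg$correlated_block_rho > 1)
        stop("'correlated_block_rho' must lie in [0, 1]")
    if (length(cfg$cells_per_well_range) != 2L ||
        any(cfg$cells_per_well_range < 1L) ||
        diff(cfg$cells_per_well_range) < 0L)
        stop("'cells_per_well_range' must be an increasing positive interval")
    if (length(cfg$incubation_levels) < 1L)
        stop("at least one incubation level is required")
    invisible(cfg)
}

#' Generate a serpentine platemap for the simulated experiment
#'
#' Lays out every clone's replicate wells across one plate per batch.  Within
#' a plate, wells are filled along a serpentine path (row A left-to-right,
#' row B right-to-left, ...) and clones are assigned in a repeating cycle
#' along that path, so each clone occupies multiple dispersed positions on
#' every plate — the same guard against well-position artifacts used when
#' plating real clones.  Incubation time alternates between the configured
#' levels across each clone's replicates.
#'
#' @param config a [syntheticConfig()] object.
#' @return \code{DataFrame} with columns \code{plate_id}, \code{well_id},
#'   \code{clone_id}, \code{resistance_status}, \code{treatment},
#'   \code{incubation_time_h}, \code{batch}.
#' @examples
#' pm <- generatePlatemap(syntheticConfig(n_wt_clones = 2, n_res_clones = 2,
#'                                        replicates_per_clone = 4,
#'                                        n_batches = 1))
#' head(pm)
#' @export
generatePlatemap <- function(config) {
    validateSyntheticConfig(config)
    clones <- c(sprintf("WT%02d", seq_len(config$n_wt_clones)),
                sprintf("BZ%02d", seq_len(config$n_res_clones)))
    status <- c(rep("sensitive", config$n_wt_clones),
                rep("resistant", config$n_res_clones))
    names(status) <- clones
    nclone <- length(clones)
    if (nclone == 0L || config$replicates_per_clone == 0L)
        stop("design has no wells: need at least one clone and one replicate")

    ## replicate r of each clone goes to batch ((r-1) mod n_batches) + 1 and
    ## incubation level ((r-1) mod n_levels) + 1
    rep_idx <- seq_len(config$replicates_per_clone)
    rows <- do.call(rbind, lapply(seq_along(clones), function(ci) {
        data.frame(
            clone_id = clones[ci],
            replicate = rep_idx,
            batch_i = ((rep_idx - 1L) %% config$n_batches) + 1L,
            ## incubation alternates on a longer cycle than batch so the two
            ## assignments stay linearly independent
            incubation_time_h = config$incubation_levels[
                (((rep_idx - 1L) %/% config$n_batches) %%
                     length(config$incubation_levels)) + 1L],
            stringsAsFactors = FALSE
        )
    }))

    capacity <- config$plate_rows * config$plate_cols
    out <- lapply(seq_len(config$n_batches), function(b) {
        sub <- rows[rows$batch_i == b, , drop = FALSE]
        if (nrow(sub) == 0L) return(NULL)
        if (nrow(sub) > capacity)
            stop("plate capacity exceeded on batch ", b, ": ", nrow(sub),
                 " wells requested but plate holds ", capacity,
                 " (deficit ", nrow(sub) - capacity, ")")
        ## serpentine path over the plate
        path <- serpentinePath(config$plate_rows, config$plate_cols)
        ## repeating clone cycle along the path: order rows by replicate then
        ## clone so consecutive wells cycle through clones
        sub <- sub[order(sub$replicate, match(sub$clone_id, clones)), ,
                   drop = FALSE]
        sub$plate_id <- sprintf("plate%d", b)
        sub$batch <- sprintf("batch%d", b)
        sub$well_id <- path[seq_len(nrow(sub))]
        sub
    })
    out <- do.call(rbind, out)
    pm <- DataFrame(
        plate_id = out$plate_id,
        well_id = out$well_id,
        clone_id = out$clone_id,
        resistance_status = unname(status[out$clone_id]),
        treatment = "DMSO 0.1%",
        incubation_time_h = out$incubation_time_h,
        batch = out$batch
    )
    if (anyDuplicated(paste(pm$plate_id, pm$well_id)))
        stop("internal error: duplicated (plate, well) pair")
    pm[order(pm$plate_id, pm$well_id), , drop = FALSE]
}

serpentinePath <- function(nrow, ncol) {
    unlist(lapply(seq_len(nrow), function(r) {
        cols <- if (r %% 2L == 1L) seq_len(ncol) else rev(seq_len(ncol))
        sprintf("%s%02d", LETTERS[r], cols)
    }))
}

cellProfilerNames <- function(n) {
    comps <- c("Cells", "Nuclei", "Cytoplasm")
    groups <- c("Intensity", "Texture", "AreaShape", "Correlation",
                "Granularity")
    chans <- c("DNA", "RNA", "ER", "AGP", "Mito")
    i <- seq_len(n) - 1L
    sprintf("%s_%s_%s_%04d",
            comps[(i %% length(comps)) + 1L],
            groups[((i %/% 3L) %% length(groups)) + 1L],
            chans[((i %/% 15L) %% length(chans)) + 1L],
            i + 1L)
}

#' Simulate single-cell morphology profiles
#'
#' Draws a cell-level feature table over a platemap: each well receives a
#' cell count uniform on \code{cells_per_well_range}, and each cell's feature
#' vector is unit Gaussian noise plus the planted effects described in
#' [syntheticConfig()].  Ground-truth feature roles (and planted per-clone
#' shifts) are recorded in the \code{rowData} of the returned object so
#' recovery can be measured without re-deriving them; the per-clone
#' idiosyncratic shift matrix is stored in \code{metadata()$clone_effects}.
#'
#' @param platemap output of [generatePlatemap()] (or a compatible
#'   \code{DataFrame}).
#' @param config the same [syntheticConfig()].
#' @return A cell-level \linkS4class{MorphologyProfiles}.
#' @examples
#' cfg <- syntheticConfig(n_features = 20, n_signature_up = 2,
#'                        n_signature_down = 2, n_batch_confounded = 1,
#'                        n_time_confounded = 1, n_count_confounded = 1,
#'                        n_clone_idiosyncratic = 1, n_correlated_block = 3,
#'                        n_wt_clones = 2, n_res_clones = 2,
#'                        replicates_per_clone = 4, n_batches = 2,
#'                        cells_per_well_range = c(5L, 10L))
#' cells <- simulateCells(generatePlatemap(cfg), cfg)
#' @export
simulateCells <- function(platemap, config) {
    validateSyntheticConfig(config)
    if (is.null(platemap) || nrow(platemap) == 0L)
        stop("platemap is empty")
    set.seed(config$seed)

    nf <- config$n_features
    fnames <- cellProfilerNames(nf)
    roles <- rep("inert", nf)
    special_n <- c(
        signature_up = config$n_signature_up,
        signature_down = config$n_signature_down,
        batch_confounded = config$n_batch_confounded,
        time_confounded = config$n_time_confounded,
        count_confounded = config$n_count_confounded,
        clone_idiosyncratic = config$n_clone_idiosyncratic,
        correlated_block = config$n_correlated_block
    )
    pick <- sample.int(nf, sum(special_n))
    roles[pick] <- rep(names(special_n), special_n)

    nwell <- nrow(platemap)
    counts <- sample(seq(config$cells_per_well_range[1],
                         config$cells_per_well_range[2]),
                     nwell, replace = TRUE)
    ncell <- sum(counts)
    well_of_cell <- rep(seq_len(nwell), counts)

    X <- matrix(stats::rnorm(nf * ncell), nrow = nf,
                dimnames = list(fnames, NULL))

    d <- config$effect_size_status
    e <- config$effect_size_nuisance
    res_cell <- platemap$resistance_status[well_of_cell] == "resistant"
    up <- roles == "signature_up"; dn <- roles == "signature_down"
    if (any(up)) X[up, res_cell] <- X[up, res_cell] + d
    if (any(dn)) X[dn, res_cell] <- X[dn, res_cell] - d

    ## batch shifts: centered integer offsets per batch level
    bfeat <- roles == "batch_confounded"
    if (any(bfeat)) {
        blev <- sort(unique(platemap$batch))
        boff <- (seq_along(blev) - (length(blev) + 1) / 2) * e
        shift <- boff[match(platemap$batch[well_of_cell], blev)]
        X[bfeat, ] <- sweep(X[bfeat, , drop = FALSE], 2, shift, "+")
    }
    tfeat <- roles == "time_confounded"
    if (any(tfeat)) {
        tmax <- max(platemap$incubation_time_h)
        shift <- e * (platemap$incubation_time_h[well_of_cell] == tmax)
        X[tfeat, ] <- sweep(X[tfeat, , drop = FALSE], 2, shift, "+")
    }
    cfeat <- roles == "count_confounded"
    if (any(cfeat)) {
        ## linear in the well's cell count, standardized by the theoretical
        ## moments of the uniform count distribution
        a <- config$cells_per_well_range[1]; b <- config$cells_per_well_range[2]
        mu <- (a + b) / 2
        sdv <- sqrt(((b - a + 1)^2 - 1) / 12)
        if (sdv == 0) sdv <- 1
        shift <- e * (counts[well_of_cell] - mu) / sdv
        X[cfeat, ] <- sweep(X[cfeat, , drop = FALSE], 2, shift, "+")
    }
    kfeat <- which(roles == "clone_idiosyncratic")
    clones <- sort(unique(platemap$clone_id))
    clone_eff <- matrix(0, length(kfeat), length(clones),
                        dimnames = list(fnames[kfeat], clones))
    if (length(kfeat)) {
        clone_eff[] <- stats::rnorm(length(clone_eff), sd = e)
        ci <- match(platemap$clone_id[well_of_cell], clones)
        X[kfeat, ] <- X[kfeat, , drop = FALSE] +
            clone_eff[, ci, drop = FALSE]
    }

    ## per-well random effect on all non-block features
    nb <- roles != "correlated_block"
    if (config$well_effect_sd > 0 && any(nb)) {
        W <- matrix(stats::rnorm(sum(nb) * nwell, sd = config$well_effect_sd),
                    nrow = sum(nb))
        X[nb, ] <- X[nb, , drop = FALSE] + W[, well_of_cell, drop = FALSE]
    }

    ## correlated block: shared latent factor with both a per-cell and a
    ## per-well component (redundant features co-vary at the well level
    ## too, so the correlation survives median aggregation)
    blk <- which(roles == "correlated_block")
    if (length(blk)) {
        rho <- config$correlated_block_rho
        ws <- config$well_effect_sd
        latent <- (stats::rnorm(ncell) +
                       ws * stats::rnorm(nwell)[well_of_cell]) /
            sqrt(1 + ws^2)
        X[blk, ] <- sqrt(rho) * matrix(latent, length(blk), ncell,
                                       byrow = TRUE) +
            sqrt(1 - rho) * matrix(stats::rnorm(length(blk) * ncell),
                                   length(blk), ncell)
    }

    ## artifact injection into inert features
    inert <- which(roles == "inert")
    outlier_f <- inert[stats::runif(length(inert)) < config$outlier_rate]
    for (f in outlier_f) {
        w <- sample.int(nwell, 1L)
        X[f, well_of_cell == w] <- X[f, well_of_cell == w] + 25
    }
    missing_f <- inert[stats::runif(length(inert)) < config$missing_rate]
    for (f in missing_f) {
        idx <- which(stats::runif(ncell) < 0.01)
        if (!length(idx)) idx <- sample.int(ncell, 1L)
        X[f, idx] <- NA_real_
    }

    planted <- numeric(nf)
    planted[up] <- d
    planted[dn] <- -d
    planted[bfeat | tfeat | cfeat] <- e
    rd <- DataFrame(
        feature = fnames,
        role = roles,
        planted_effect = planted,
        outlier_afflicted = seq_len(nf) %in% outlier_f,
        missing_afflicted = seq_len(nf) %in% missing_f
    )
    cd <- DataFrame(
        cell_id = sprintf("cell%07d", seq_len(ncell)),
        platemap[well_of_cell, , drop = FALSE],
        cell_count = counts[well_of_cell]
    )
    rownames(cd) <- cd$cell_id
    out <- MorphologyProfiles(X, cd, level = "cell", rowData = rd)
    metadata(out)$clone_effects <- clone_eff
    metadata(out)$config <- config
    out
}
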