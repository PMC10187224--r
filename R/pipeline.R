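#' Configuration for an end-to-end pipeline run
#'
#' Bundles the stage parameters of the whole workflow (simulation design,
#' feature selection, discovery threshold, scoring permutations, shuffled
#' baselines, dataset splits) with one master seed from which every
#' stochastic stage derives a documented substream.  Configurations
#' round-trip unchanged through YAML ([writeRunConfig()] /
#' [readRunConfig()]).
#'
#' @param synthetic list of [syntheticConfig()] arguments (the simulation
#'   seed is derived from \code{seed} and must not be set here).
#' @param selection list of [featureSelectionConfig()] arguments.
#' @param alpha_base base significance level for the Bonferroni threshold.
#' @param n_permutations permutations for the per-well score null.
#' @param n_shuffles shuffled-baseline repeats per evaluation split.
#' @param splits dataset split definitions (see [assembleSplits()]);
#'   \code{NULL} selects a default design: discovery on all but the last
#'   clone of each status, one replicate well in four of those clones held
#'   out as validation, the last clone of each status as test.
#' @param write_cells write the (large) cell-level table to the run
#'   directory (default TRUE).
#' @param seed master seed.
#' @return classed list.
#' @export
runConfig <- function(synthetic = list(), selection = list(),
                      alpha_base = 0.05, n_permutations = 0L,
                      n_shuffles = 0L, splits = NULL, write_cells = TRUE,
                      seed = 1L) {
    if (!is.null(synthetic$seed))
        stop("set the master 'seed'; the simulation seed is derived from it")
    cfg <- list(synthetic = synthetic, selection = selection,
                alpha_base = as.numeric(alpha_base),
                n_permutations = as.integer(n_permutations),
                n_shuffles = as.integer(n_shuffles),
                splits = splits, write_cells = isTRUE(write_cells),
                seed = as.integer(seed))
    ## validate stage parameter lists eagerly so a bad config fails before
    ## any computation
    do.call(syntheticConfig, cfg$synthetic)
    do.call(featureSelectionConfig, cfg$selection)
    if (cfg$alpha_base < 0) stop("'alpha_base' must be nonnegative")
    if (cfg$n_permutations < 0L || cfg$n_shuffles < 0L)
        stop("permutation/shuffle counts must be nonnegative")
    class(cfg) <- "RunConfig"
    cfg
}

#' @rdname runConfig
#' @param config a \code{RunConfig}.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    do.call(runConfig, raw)
}

defaultSplits <- function(platemap) {
    clones <- sort(unique(platemap$clone_id))
    status <- platemap$resistance_status[match(clones, platemap$clone_id)]
    test_clones <- c(utils::tail(clones[status == "sensitive"], 1L),
                     utils::tail(clones[status == "resistant"], 1L))
    train_clones <- setdiff(clones, test_clones)
    ## every 4th replicate well of a training clone is held out as
    ## validation (same clones, same plates — the wells just never enter
    ## discovery)
    wkey <- paste(platemap$plate_id, platemap$well_id, sep = ":")
    val_wells <- unlist(lapply(train_clones, function(cl) {
        w <- which(platemap$clone_id == cl)
        w <- w[order(platemap$plate_id[w], platemap$well_id[w])]
        w[seq_along(w) %% 4L == 0L]
    }))
    train_wells <- setdiff(which(platemap$clone_id %in% train_clones),
                           val_wells)
    list(validation = list(wells = wkey[val_wells]),
         training = list(wells = wkey[train_wells]),
         test = list(clones = test_clones))
}

#' Run the full pipeline: simulate, process, discover, score, evaluate
#'
#' Executes every stage in order on simulated data, writing all
#' intermediate artifacts to \code{out_dir}: the platemap, (optionally) the
#' cell-level table, ground-truth feature roles, raw/normalized/selected
#' well profiles, the selection report, the signature (CSV + JSON stats),
#' per-well scores, per-split evaluation reports and a manifest recording
#' the configuration, derived seeds and per-stage row/feature counts —
#' everything needed to reproduce the run exactly.  Stage progress and the
#' feature counts after each transformation are reported via
#' \code{message()}.
#'
#' Note that split assignment in \code{splits} is interpreted against the
#' platemap; discovery uses only the wells of the \code{training} split
#' (or all wells when no split is named \code{training}).
#'
#' @param config a [runConfig()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with the main in-memory objects
#'   (\code{platemap}, \code{profiles}, \code{signature}, \code{scores},
#'   \code{evaluation}, \code{manifest}) and \code{paths} to every file
#'   written.
#' @export
runPipeline <- function(config, out_dir) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    paths <- list()

    sim_seed <- deriveSeed(config$seed, "simulate")
    scfg <- do.call(syntheticConfig,
                    c(config$synthetic, list(seed = sim_seed)))
    message("simulate: ", scfg$n_features, " features, ",
            (scfg$n_wt_clones + scfg$n_res_clones) *
                scfg$replicates_per_clone, " wells")
    platemap <- generatePlatemap(scfg)
    cells <- simulateCells(platemap, scfg)
    writePlatemap(platemap, paths$platemap <- p("platemap.csv"))
    writeTable(featureRoles(cells), paths$ground_truth <- p("ground_truth.csv"))
    if (config$write_cells)
        writeProfiles(cells, paths$cells <- p("cells.csv"))

    wells <- aggregateWells(cells, platemap)
    message("aggregate: ", ncol(wells), " well profiles")
    writeProfiles(wells, paths$wells_raw <- p("wells_raw.csv"))
    norm <- normalizeProfiles(wells)
    writeProfiles(norm, paths$wells_normalized <- p("wells_normalized.csv"))
    sel <- selectFeatures(norm, do.call(featureSelectionConfig,
                                        config$selection))
    message("select: ", nrow(cells), " -> ", nrow(sel), " features")
    writeProfiles(sel, paths$wells_selected <- p("wells_selected.csv"))
    writeTable(selectionReport(sel),
               paths$selection_report <- p("selection_report.csv"))

    splits <- if (is.null(config$splits)) defaultSplits(platemap)
              else config$splits
    split_of <- assembleSplits(sel, splits)
    train <- if ("training" %in% split_of)
                 !is.na(split_of) & split_of == "training"
             else rep(TRUE, ncol(sel))
    signature <- discoverSignature(sel[, train],
                                   alpha_base = config$alpha_base)
    message("discover: ", length(upFeatures(signature)), " up + ",
            length(downFeatures(signature)), " down features")
    writeSignature(signature, paths$signature <- p("signature.csv"),
                   stats_path = paths$signature_stats <-
                       p("signature_stats.json"))

    eval_reports <- list()
    if (length(signature) > 0L) {
        scores <- scoreProfiles(sel, signature,
                                n_permutations = config$n_permutations,
                                seed = deriveSeed(config$seed, "score"))
        scores$split <- split_of
        writeTable(scores, paths$scores <- p("scores.csv"))
        message("score: ", nrow(scores), " wells")
        eval_reports <- evaluateSplits(
            scores, split_of,
            profiles = if (config$n_shuffles >= 1L) sel,
            signature = if (config$n_shuffles >= 1L) signature,
            n_shuffles = config$n_shuffles,
            seed = deriveSeed(config$seed, "shuffle"))
        writeEvaluation(eval_reports,
                        paths$evaluation <- p("evaluation.json"))
        for (nm in names(eval_reports))
            message("evaluate [", nm, "]: accuracy ",
                    signif(eval_reports[[nm]]$accuracy, 3), ", AUROC ",
                    signif(eval_reports[[nm]]$auroc, 3))
    } else {
        scores <- NULL
        message("score: skipped (empty signature)")
    }

    manifest <- list(
        package_version = as.character(utils::packageVersion("morphosig")),
        config = unclass(config),
        derived_seeds = list(simulate = sim_seed,
                             score = deriveSeed(config$seed, "score"),
                             shuffle = deriveSeed(config$seed, "shuffle")),
        counts = list(
            wells = ncol(wells),
            cells = ncol(cells),
            features_raw = nrow(cells),
            features_selected = nrow(sel),
            signature_up = length(upFeatures(signature)),
            signature_down = length(downFeatures(signature)),
            splits = as.list(table(split_of, useNA = "no"))
        )
    )
    jsonlite::write_json(manifest, paths$manifest <- p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")

    invisible(list(platemap = platemap, profiles = sel,
                   signature = signature, scores = scores,
                   evaluation = eval_reports, manifest = manifest,
                   paths = paths))
}
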