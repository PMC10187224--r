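## shared fixtures: small synthetic configurations and hand-built tables

tinyConfig <- function(...) {
    args <- list(...)
    defaults <- list(
        n_features = 30L, n_signature_up = 3L, n_signature_down = 3L,
        n_batch_confounded = 2L, n_time_confounded = 2L,
        n_count_confounded = 2L, n_clone_idiosyncratic = 2L,
        n_correlated_block = 4L, correlated_block_rho = 0.95,
        effect_size_status = 1.5, effect_size_nuisance = 1,
        n_wt_clones = 2L, n_res_clones = 2L, replicates_per_clone = 8L,
        n_batches = 2L, cells_per_well_range = c(10L, 20L),
        outlier_rate = 0, missing_rate = 0, seed = 7L)
    defaults[names(args)] <- args
    do.call(syntheticConfig, defaults)
}

## well-level profiles straight from a features x wells matrix
makeWells <- function(X, plate = "p1", clone = NULL, status = NULL,
                      batch = NULL, time = NULL, count = NULL) {
    n <- ncol(X)
    if (is.null(rownames(X)))
        rownames(X) <- sprintf("f%03d", seq_len(nrow(X)))
    if (length(plate) == 1L) plate <- rep(plate, n)
    cd <- S4Vectors::DataFrame(
        plate_id = plate,
        well_id = sprintf("%s%03d",
                          rep(LETTERS[1:8], length.out = n),
                          seq_len(n))
    )
    if (!is.null(clone)) cd$clone_id <- clone
    if (!is.null(status)) cd$resistance_status <- status
    if (!is.null(batch)) cd$batch <- batch
    if (!is.null(time)) cd$incubation_time_h <- time
    if (!is.null(count)) cd$cell_count <- count
    MorphologyProfiles(X, cd, level = "well")
}

## cell-level profiles from a features x cells matrix and a well index
makeCells <- function(X, well_of_cell, plate = "p1", extra = list()) {
    if (is.null(rownames(X)))
        rownames(X) <- sprintf("f%03d", seq_len(nrow(X)))
    cd <- S4Vectors::DataFrame(
        cell_id = sprintf("c%05d", seq_len(ncol(X))),
        plate_id = rep(plate, ncol(X)),
        well_id = sprintf("A%02d", well_of_cell)
    )
    for (nm in names(extra)) cd[[nm]] <- extra[[nm]]
    MorphologyProfiles(X, cd, level = "cell")
}
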