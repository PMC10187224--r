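test_that("platemap lays clones out in serpentine order and validates capacity", {
    cfg <- tinyConfig(n_wt_clones = 1L, n_res_clones = 1L,
                      replicates_per_clone = 2L, n_batches = 1L)
    pm <- generatePlatemap(cfg)
    expect_equal(nrow(pm), 4L)
    first_row <- pm[order(pm$well_id), ]
    expect_equal(first_row$well_id, c("A01", "A02", "A03", "A04"))
    ## clones alternate along the serpentine path
    expect_equal(first_row$clone_id, c("WT01", "BZ01", "WT01", "BZ01"))

    ## (plate, well) unique, clone -> status single-valued
    expect_false(anyDuplicated(paste(pm$plate_id, pm$well_id)) > 0)
    map <- unique(pm[, c("clone_id", "resistance_status")])
    expect_false(anyDuplicated(map$clone_id) > 0)

    ## 200 wells cannot fit one 96-well plate
    expect_error(
        generatePlatemap(tinyConfig(n_wt_clones = 5L, n_res_clones = 5L,
                                    replicates_per_clone = 20L,
                                    n_batches = 1L)),
        "capacity")
})

test_that("serpentine layout disperses every clone across plate rows", {
    cfg <- syntheticConfig(seed = 3L)  # 10 clones x 20 replicates, 3 batches
    pm <- generatePlatemap(cfg)
    expect_equal(nrow(pm), 200L)
    expect_equal(as.vector(table(pm$clone_id)), rep(20L, 10L))
    rows_per_clone <- tapply(substr(pm$well_id, 1, 1), pm$clone_id,
                             function(r) length(unique(r)))
    expect_true(all(rows_per_clone >= 3L))
    ## every clone appears in every batch
    expect_true(all(table(pm$clone_id, pm$batch) > 0))
})

test_that("generator is deterministic in config+seed and seed-sensitive", {
    cfg <- tinyConfig(seed = 5L)
    pm <- generatePlatemap(cfg)
    a <- simulateCells(pm, cfg)
    b <- simulateCells(pm, cfg)
    expect_identical(SummarizedExperiment::assay(a),
                     SummarizedExperiment::assay(b))
    cfg2 <- tinyConfig(seed = 6L)
    c <- simulateCells(generatePlatemap(cfg2), cfg2)
    expect_false(identical(SummarizedExperiment::assay(a)[1, 1],
                           SummarizedExperiment::assay(c)[1, 1]))
})

test_that("every feature carries exactly one ground-truth role", {
    cfg <- tinyConfig()
    cells <- simulateCells(generatePlatemap(cfg), cfg)
    rd <- as.data.frame(featureRoles(cells))
    expect_equal(nrow(rd), cfg$n_features)
    counts <- table(rd$role)
    expect_equal(unname(counts["signature_up"]), cfg$n_signature_up)
    expect_equal(unname(counts["signature_down"]), cfg$n_signature_down)
    expect_equal(unname(counts["batch_confounded"]), cfg$n_batch_confounded)
    expect_equal(unname(counts["correlated_block"]), cfg$n_correlated_block)
    expect_equal(sum(counts), cfg$n_features)
})

test_that("degenerate designs behave as forced", {
    cfg <- tinyConfig(n_wt_clones = 1L, n_res_clones = 0L,
                      replicates_per_clone = 1L, n_batches = 1L,
                      cells_per_well_range = c(1L, 1L))
    cells <- simulateCells(generatePlatemap(cfg), cfg)
    expect_equal(ncol(cells), 1L)

    ## rho = 1 with shared noise: block features identical up to tolerance
    cfg <- tinyConfig(correlated_block_rho = 1, n_correlated_block = 3L)
    cells <- simulateCells(generatePlatemap(cfg), cfg)
    blk <- which(featureRoles(cells)$role == "correlated_block")
    X <- SummarizedExperiment::assay(cells)[blk, ]
    expect_true(all(abs(cor(t(X)) - 1) < 1e-12))

    expect_error(simulateCells(generatePlatemap(tinyConfig())[0, ],
                               tinyConfig()), "empty")
    expect_error(syntheticConfig(outlier_rate = 1.5), "\\[0, 1\\]")
    expect_error(syntheticConfig(n_features = 10, n_signature_up = 20),
                 "exceed")
})

test_that("zero status effect gives null well-level group differences", {
    ## Monte Carlo type-I control: with no planted effect, a two-sample t
    ## on well medians of the first designated signature feature should be
    ## non-significant at alpha = 0.01 in >= 98 of 100 seeded repeats
    hits <- 0L
    for (s in 1:100) {
        cfg <- tinyConfig(effect_size_status = 0, n_features = 6L,
                          n_signature_up = 1L, n_signature_down = 1L,
                          n_batch_confounded = 0L, n_time_confounded = 0L,
                          n_count_confounded = 0L,
                          n_clone_idiosyncratic = 0L,
                          n_correlated_block = 0L,
                          replicates_per_clone = 6L,
                          cells_per_well_range = c(8L, 12L), seed = s)
        pm <- generatePlatemap(cfg)
        wells <- aggregateWells(simulateCells(pm, cfg))
        f <- which(featureRoles(wells)$role == "signature_up")[1]
        y <- SummarizedExperiment::assay(wells)[f, ]
        g <- SummarizedExperiment::colData(wells)$resistance_status
        if (stats::t.test(y[g == "resistant"], y[g == "sensitive"],
                          var.equal = TRUE)$p.value < 0.01)
            hits <- hits + 1L
    }
    expect_lte(hits, 2L)
})

test_that("planted signature effects carry the planted sign at well level", {
    ok <- 0L; tot <- 0L
    for (s in 1:10) {
        cfg <- tinyConfig(effect_size_status = 1.0,
                          replicates_per_clone = 20L, seed = 100L + s)
        wells <- aggregateWells(simulateCells(generatePlatemap(cfg), cfg))
        rd <- as.data.frame(featureRoles(wells))
        X <- SummarizedExperiment::assay(wells)
        res <- SummarizedExperiment::colData(wells)$resistance_status ==
            "resistant"
        dif <- rowMeans(X[, res, drop = FALSE]) -
            rowMeans(X[, !res, drop = FALSE])
        sig <- rd$role %in% c("signature_up", "signature_down")
        want <- ifelse(rd$role[sig] == "signature_up", 1, -1)
        ok <- ok + sum(sign(dif[sig]) == want)
        tot <- tot + sum(sig)
    }
    expect_gte(ok / tot, 0.95)
})
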