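test_that("well aggregation takes per-well medians and counts cells", {
    ## singleton well and a {0, 2} pair
    X <- rbind(f1 = c(5, 0, 2), f2 = c(-1, 4, 6))
    cells <- makeCells(X, well_of_cell = c(1L, 2L, 2L))
    wells <- aggregateWells(cells)
    A <- SummarizedExperiment::assay(wells)
    cd <- SummarizedExperiment::colData(wells)
    w1 <- which(cd$well_id == "A01"); w2 <- which(cd$well_id == "A02")
    expect_equal(unname(A["f1", w1]), 5)
    expect_equal(unname(cd$cell_count[w1]), 1L)
    expect_equal(unname(A["f1", w2]), 1)       # median of {0, 2}
    expect_equal(unname(A["f2", w2]), 5)       # median of {4, 6}
})

test_that("aggregation matches a sort-and-pick-middle oracle and ignores row order", {
    set.seed(21)
    nwell <- 10L; ncell_per <- 5L
    X <- matrix(rnorm(3 * nwell * ncell_per), nrow = 3,
                dimnames = list(c("fa", "fb", "fc"), NULL))
    wix <- rep(seq_len(nwell), each = ncell_per)
    wells <- aggregateWells(makeCells(X, wix))
    midOracle <- function(v) sort(v)[(length(v) + 1) / 2]
    for (w in seq_len(nwell)) {
        expected <- apply(X[, wix == w, drop = FALSE], 1L, midOracle)
        got <- SummarizedExperiment::assay(wells)[,
            SummarizedExperiment::colData(wells)$well_id ==
                sprintf("A%02d", w)]
        expect_equal(unname(got), unname(expected))
    }
    ## permuting cell rows changes nothing
    perm <- sample(ncol(X))
    wells2 <- aggregateWells(makeCells(X[, perm], wix[perm]))
    ord <- order(SummarizedExperiment::colData(wells)$well_id)
    ord2 <- order(SummarizedExperiment::colData(wells2)$well_id)
    expect_equal(SummarizedExperiment::assay(wells)[, ord],
                 SummarizedExperiment::assay(wells2)[, ord2])
})

test_that("aggregation enforces metadata integrity and reports empty wells", {
    X <- rbind(f1 = c(1, 2))
    cells <- makeCells(X, c(1L, 1L), extra = list(clone_id = c("WT01", "WT02")))
    expect_error(aggregateWells(cells), "not constant")

    pm <- S4Vectors::DataFrame(plate_id = "p1", well_id = c("A01", "A09"))
    expect_warning(aggregateWells(makeCells(X, c(1L, 1L),
                                            extra = list(clone_id = "WT01")),
                                  platemap = pm),
                   "zero cells")
})

test_that("annotation joins platemap metadata and validates both sides", {
    X <- matrix(rnorm(8), 2, dimnames = list(c("f1", "f2"), NULL))
    wells <- makeWells(X)
    pm <- S4Vectors::DataFrame(
        plate_id = "p1",
        well_id = SummarizedExperiment::colData(wells)$well_id,
        clone_id = c("WT01", "WT01", "BZ01", "BZ01"),
        resistance_status = rep(c("sensitive", "resistant"), each = 2))
    ann <- annotateProfiles(wells, pm)
    expect_equal(ncol(ann), 4L)
    expect_equal(SummarizedExperiment::colData(ann)$clone_id,
                 pm$clone_id)

    expect_error(annotateProfiles(wells, pm[1:3, ]), "absent from platemap")
    expect_error(annotateProfiles(wells, rbind(pm, pm[1, ])), "duplicated")
})

test_that("per-plate z-scores have zero mean and unit variance", {
    X <- rbind(fsym = c(-1, 1, -1, 1), f2 = c(3, 9, 1, 7))
    wells <- makeWells(X)
    z <- SummarizedExperiment::assay(normalizeProfiles(wells))
    expect_equal(unname(z["fsym", ]), c(-1, 1, -1, 1))  # population SD
    expect_lt(max(abs(rowMeans(z))), 1e-8)
    expect_lt(max(abs(sqrt(rowMeans(z^2)) - 1)), 1e-8)

    ## two plates that are shifted/scaled copies normalize identically
    set.seed(4)
    Y <- matrix(rnorm(3 * 6), 3, dimnames = list(paste0("f", 1:3), NULL))
    both <- makeWells(cbind(Y, 5 + 3 * Y),
                      plate = rep(c("p1", "p2"), each = 6))
    zz <- SummarizedExperiment::assay(normalizeProfiles(both))
    expect_equal(zz[, 1:6], zz[, 7:12], ignore_attr = TRUE,
                 tolerance = 1e-12)

    ## a single-well plate has no spread to standardize by
    expect_error(normalizeProfiles(makeWells(Y[, 1, drop = FALSE])),
                 "single well")

    ## zero-spread features become NA for the missing filter
    flat <- makeWells(rbind(fconst = rep(2, 4), fvar = rnorm(4)))
    expect_true(all(is.na(
        SummarizedExperiment::assay(normalizeProfiles(flat))["fconst", ])))
})

test_that("feature selection applies its five rules in order with unique attribution", {
    set.seed(9)
    n <- 24L
    base <- rnorm(n)
    X <- rbind(
        keep1 = rnorm(n),
        keep2 = rnorm(n),
        dup_a = base,
        dup_b = base,                       # r = 1 with dup_a
        blocked_Eccentricity = rnorm(n),
        holey = replace(rnorm(n), 3, NA),
        flat = rep(1.5, n),
        spiky = replace(rnorm(n), 5, 20)    # 20-SD outlier on z scale
    )
    wells <- makeWells(X)
    cfg <- featureSelectionConfig(blocklist = "Eccentricity")
    sel <- selectFeatures(wells, cfg)
    rep <- as.data.frame(selectionReport(sel))
    rule_of <- setNames(rep$rule, rep$feature)

    expect_equal(unname(rule_of["blocked_Eccentricity"]), "blocklist")
    expect_equal(unname(rule_of["holey"]), "missing")
    expect_equal(unname(rule_of["flat"]), "low_variance")
    expect_equal(unname(rule_of["spiky"]), "outlier")
    ## exactly one of the duplicated pair dropped, by the correlation rule
    expect_equal(sum(c("dup_a", "dup_b") %in% rep$feature), 1L)
    expect_equal(unname(rule_of[intersect(c("dup_a", "dup_b"),
                                          rep$feature)]), "correlation")
    expect_false(anyDuplicated(rep$feature) > 0)
    expect_true(all(c("keep1", "keep2") %in% rownames(sel)))
})

test_that("selection is idempotent and bounds surviving correlations", {
    set.seed(10)
    n <- 40L
    Z <- matrix(rnorm(12 * n), 12)
    Z[2, ] <- Z[1, ] * 0.98 + rnorm(n, sd = 0.05)   # high-correlation pair
    Z[4, ] <- -Z[3, ] * 0.99 + rnorm(n, sd = 0.03)  # negative high correlation
    rownames(Z) <- sprintf("f%02d", 1:12)
    sel <- selectFeatures(makeWells(Z))
    C <- cor(t(SummarizedExperiment::assay(sel)))
    diag(C) <- 0
    expect_lte(max(abs(C)), 0.9)

    again <- selectFeatures(sel)
    expect_equal(rownames(again), rownames(sel))
    expect_equal(nrow(selectionReport(again)), 0L)

    expect_error(selectFeatures(makeWells(rbind(f1 = rep(1, 4)))),
                 "every feature")
})

test_that("an injected whole-well artifact is caught by the outlier rule on the normalized scale", {
    ## simulated artifact: one well of one feature displaced far beyond the
    ## rest of the dataset, presented on an already-normalized scale
    set.seed(11)
    X <- matrix(rnorm(6 * 30), 6, dimnames = list(paste0("f", 1:6), NULL))
    X[4, 17] <- 20
    sel <- selectFeatures(makeWells(X))
    rep <- as.data.frame(selectionReport(sel))
    expect_true("f4" %in% rep$feature[rep$rule == "outlier"])
    expect_false("f4" %in% rownames(sel))
})
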