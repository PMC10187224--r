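test_that("Tukey family matches stats::TukeyHSD on unbalanced fixtures", {
    set.seed(31)
    for (rep in 1:4) {
        g <- factor(sample(rep(c("a", "b", "c", "d"),
                               times = c(4, 7, 5, 9))))
        Y <- cbind(y1 = rnorm(length(g)) + as.integer(g) * 0.4,
                   y2 = rnorm(length(g)))
        fam <- tukeyHSDPairs(Y, g)
        for (j in 1:2) {
            ref <- stats::TukeyHSD(stats::aov(Y[, j] ~ g))$g
            key <- paste(fam$pairs[2, ], fam$pairs[1, ], sep = "-")
            expect_equal(unname(fam$padj[j, ]),
                         unname(ref[key, "p adj"]), tolerance = 1e-6)
            expect_equal(unname(fam$diff[j, ]),
                         unname(ref[key, "diff"]), tolerance = 1e-10)
        }
    }
})

test_that("a two-group Tukey family equals the pooled two-sample t-test", {
    set.seed(32)
    for (rep in 1:8) {
        n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
        y <- c(rnorm(n1), rnorm(n2, mean = runif(1, -1, 1)))
        g <- rep(c("s", "r"), c(n1, n2))
        fam <- tukeyHSDPairs(matrix(y, dimnames = list(NULL, "f")), g)
        tt <- stats::t.test(y[g == "r"], y[g == "s"], var.equal = TRUE)
        expect_equal(unname(fam$padj[1, 1]), tt$p.value, tolerance = 1e-6)
    }
})

test_that("a pure batch confounder is flagged by batch and not by status", {
    batch <- rep(c("b1", "b2", "b3"), each = 4)
    status <- rep(c("sensitive", "resistant"), 6)  # balanced within batch
    y <- c(b1 = 0, b2 = 1, b3 = 2)[batch]          # exact, zero noise
    Y <- matrix(y, dimnames = list(NULL, "f"))
    expect_equal(unname(tukeyHSDPairs(Y, batch)$padj[1, ]), c(0, 0, 0))
    expect_gt(min(tukeyHSDPairs(Y, status)$padj), 0.99)
})

test_that("Tukey status p-values are uniform under the null (type-I control)", {
    set.seed(33)
    n <- 40L
    status <- rep(c("sensitive", "resistant"), each = n / 2)
    Y <- matrix(rnorm(n * 1000), nrow = n,
                dimnames = list(NULL, sprintf("f%04d", 1:1000)))
    fam <- tukeyHSDPairs(Y, status)
    expect_lte(sum(fam$padj[, 1] < 6.4e-5), 1L)
    ## and roughly uniform overall
    expect_gt(stats::ks.test(fam$padj[, 1], "punif")$p.value, 1e-4)
})

test_that("the covariate model fits all features with clone aliasing handled", {
    cfg <- tinyConfig(replicates_per_clone = 12L)
    wells <- normalizeProfiles(aggregateWells(
        simulateCells(generatePlatemap(cfg), cfg)))
    fit <- fitCovariateModel(wells)
    expect_s4_class(fit, "FeatureModelFit")
    expect_equal(length(fit@features), cfg$n_features)
    expect_true(all(fit@rSquared >= 0 & fit@rSquared <= 1))
    expect_setequal(names(tukeyFamilies(fit)),
                    c("resistance_status", "batch", "incubation_time_h",
                      "clone_id"))
    ## clone dummies aliased with status are dropped silently; an aliased
    ## non-clone covariate is an error naming the column
    cd <- SummarizedExperiment::colData(wells)
    cd$batch_copy <- cd$batch
    SummarizedExperiment::colData(wells) <- cd
    expect_error(
        fitCovariateModel(wells, covariates = c("resistance_status", "batch",
                                                "batch_copy", "clone_id")),
        "batch_copy")
    expect_error(fitCovariateModel(wells, covariates = "resistance_status"),
                 NA)
})

test_that("model preconditions are enforced", {
    X <- matrix(rnorm(12), 2, dimnames = list(c("f1", "f2"), NULL))
    wells <- makeWells(X, clone = rep("WT01", 6),
                       status = rep("sensitive", 6),
                       batch = rep(c("b1", "b2"), 3),
                       time = rep(4, 6))
    expect_error(fitCovariateModel(wells,
                                   covariates = c("resistance_status",
                                                  "batch")),
                 "fewer than 2 levels")
    wells2 <- makeWells(X, status = c("sensitive", rep("resistant", 5)),
                        batch = rep("b1", 6))
    expect_error(fitCovariateModel(wells2,
                                   covariates = c("resistance_status",
                                                  "batch")),
                 "fewer than 2")
})

test_that("confluence model recovers a planted cell-count slope", {
    set.seed(34)
    n <- 120L
    count <- sample(40:200, n, replace = TRUE)
    status <- rep(c("sensitive", "resistant"), each = n / 2)
    X <- rbind(
        linked = 0.5 * count + rnorm(n, sd = 0.01),
        free = rnorm(n),
        const = rep(3, n))
    wells <- makeWells(X, status = status, count = count)
    m2 <- fitConfluenceModel(wells)
    m2 <- m2[match(rownames(X), m2$feature), ]
    expect_lt(abs(m2$beta_cellcount[1] - 0.5), 0.05)
    expect_lt(m2$p_cellcount[1], 1e-10)
    expect_gt(m2$p_cellcount[2], 6.4e-5)
    expect_equal(m2$beta_cellcount[3], 0)
    expect_equal(m2$p_cellcount[3], 1)

    expect_error(fitConfluenceModel(makeWells(X, status = status,
                                              count = rep(50, n))),
                 "constant")
})

test_that("signature building filters, excludes and signs features correctly", {
    cfg <- tinyConfig(n_features = 40L, n_signature_up = 4L,
                      n_signature_down = 4L, replicates_per_clone = 16L,
                      n_wt_clones = 3L, n_res_clones = 3L, n_batches = 2L,
                      n_clone_idiosyncratic = 0L)
    wells <- selectFeatures(normalizeProfiles(aggregateWells(
        simulateCells(generatePlatemap(cfg), cfg))))
    m1 <- fitCovariateModel(wells)
    m2 <- fitConfluenceModel(wells)
    sig <- buildSignature(m1, m2)
    rd <- as.data.frame(featureRoles(wells))
    role_of <- setNames(rd$role, rd$feature)
    ## all planted features recovered with the planted direction
    expect_true(all(rd$feature[rd$role == "signature_up"] %in%
                        upFeatures(sig)))
    expect_true(all(rd$feature[rd$role == "signature_down"] %in%
                        downFeatures(sig)))
    ## no nuisance-confounded feature admitted; at most one chance admit
    ## from the null features (a Bonferroni test keeps the expected number
    ## of false positives at alpha_base, not at zero)
    got <- role_of[c(upFeatures(sig), downFeatures(sig))]
    expect_equal(sum(got %in% c("batch_confounded", "time_confounded",
                                "count_confounded")), 0L)
    expect_lte(sum(got == "inert"), 1L)

    ## alpha_base = 0 admits nothing
    expect_warning(empty <- buildSignature(m1, m2, alpha_base = 0),
                   "empty")
    expect_equal(length(empty), 0L)

    ## exclusion monotonicity: removing a rule never shrinks the signature
    sig_nocount <- buildSignature(m1, NULL)
    sig_nowt <- buildSignature(m1, m2, min_wt_pairs = .Machine$integer.max)
    both <- function(s) c(upFeatures(s), downFeatures(s))
    expect_true(all(both(sig) %in% both(sig_nocount)))
    expect_true(all(both(sig) %in% both(sig_nowt)))
})

test_that("features varying between wild-type clones are excluded", {
    set.seed(35)
    clones <- rep(c("WT01", "WT02", "WT03", "BZ01", "BZ02", "BZ03"),
                  each = 8)
    status <- ifelse(startsWith(clones, "WT"), "sensitive", "resistant")
    batch <- rep(rep(c("b1", "b2"), 4), 6)
    time <- rep(rep(c(4, 13), each = 2), 12)
    count <- sample(50:60, 48, replace = TRUE)
    n <- length(clones)
    shift <- (status == "resistant") * 2
    wt_stair <- c(WT01 = 0, WT02 = 2, WT03 = 4, BZ01 = 0, BZ02 = 0,
                  BZ03 = 0)[clones]
    X <- rbind(
        clean = shift + rnorm(n, sd = 0.3),
        staircase = shift + wt_stair + rnorm(n, sd = 0.3),
        inert = rnorm(n))
    wells <- makeWells(X, clone = clones, status = status, batch = batch,
                       time = time, count = count)
    sig <- buildSignature(fitCovariateModel(wells),
                          fitConfluenceModel(wells))
    st <- as.data.frame(signatureStats(sig))
    expect_true("clean" %in% upFeatures(sig))
    expect_false("staircase" %in% c(upFeatures(sig), downFeatures(sig)))
    expect_equal(st$excluded_by[st$feature == "staircase"],
                 "wt_clone_pairs")
    expect_false("inert" %in% c(upFeatures(sig), downFeatures(sig)))
})

test_that("the Bonferroni threshold is alpha divided by the feature count", {
    cfg <- tinyConfig(n_features = 25L)
    wells <- normalizeProfiles(aggregateWells(
        simulateCells(generatePlatemap(cfg), cfg)))
    sig <- suppressWarnings(buildSignature(fitCovariateModel(wells),
                                           alpha_base = 0.2))
    expect_equal(signatureAlpha(sig), 0.2 / 25)
})
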