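#' All-pairs Tukey HSD family for one grouping, vectorized over features
#'
#' Computes Tukey's honestly-significant-difference post-hoc comparisons of
#' group means for every feature at once.  For groups \eqn{i, j} with sizes
#' \eqn{n_i, n_j} the studentized-range statistic is
#' \deqn{q = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}}
#' (the Tukey–Kramer form, which accounts for unequal group sizes) and the
#' family-wise-adjusted p-value is the upper tail of the studentized range
#' distribution with \eqn{k} means and \eqn{N - k} residual degrees of
#' freedom, where MSE is the one-way ANOVA mean squared error of that
#' grouping.  For a two-group family this reduces exactly to the pooled
#' two-sample t-test (\eqn{q = |t|\sqrt 2}).
#'
#' @param Y numeric matrix, observations x features.
#' @param g grouping vector (coerced to factor; empty levels dropped).
#' @return list with \code{levels}, \code{n} (group sizes), \code{pairs}
#'   (2 x npairs matrix of level labels), \code{diff} and \code{padj}
#'   (features x npairs matrices; differences are level2 − level1), and
#'   \code{df} (residual degrees of freedom).  NULL (with a warning) when
#'   fewer than two groups are present.
#' @examples
#' y <- cbind(f1 = rnorm(12), f2 = rnorm(12))
#' tukeyHSDPairs(y, rep(c("a", "b", "c"), each = 4))$padj
#' @importFrom stats ptukey
#' @export
tukeyHSDPairs <- function(Y, g) {
    Y <- as.matrix(Y)
    g <- droplevels(factor(g))
    k <- nlevels(g)
    if (k < 2L) {
        warning("fewer than 2 groups; Tukey family skipped")
        return(NULL)
    }
    n <- as.vector(table(g))
    N <- nrow(Y)
    df <- N - k
    if (df < 1L) stop("no residual degrees of freedom for Tukey family")
    gm <- rowsum(Y, g) / n                         # k x p group means
    mu <- colMeans(Y)
    ss_tot <- colSums(Y^2) - N * mu^2
    ss_btw <- colSums(gm^2 * n) - N * mu^2
    mse <- pmax(ss_tot - ss_btw, 0) / df
    pr <- utils::combn(seq_len(k), 2L)
    np <- ncol(pr)
    dmat <- t(gm[pr[2L, ], , drop = FALSE] - gm[pr[1L, ], , drop = FALSE])
    se2 <- outer(mse / 2, 1 / n[pr[1L, ]] + 1 / n[pr[2L, ]])
    q <- abs(dmat) / sqrt(se2)
    padj <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    ## degenerate 0/0 (zero difference with zero residual variance): no
    ## evidence of a difference
    padj[!is.finite(q)] <- ifelse(dmat[!is.finite(q)] == 0, 1, 0)
    padj[se2 == 0 & dmat != 0] <- 0
    padj[se2 == 0 & dmat == 0] <- 1
    dimnames(dmat) <- dimnames(padj) <-
        list(colnames(Y), paste(levels(g)[pr[2L, ]], levels(g)[pr[1L, ]],
                                sep = "-"))
    list(levels = levels(g), n = stats::setNames(n, levels(g)),
         pairs = matrix(levels(g)[pr], nrow = 2L), diff = dmat, padj = padj,
         df = df)
}

#' Fit the per-feature covariate model with Tukey post-hoc families
#'
#' For every feature \eqn{Y_j}, fits by ordinary least squares the model
#' \deqn{Y_j = \beta_0 + \beta_{status} X_{status} + \beta_{batch} X_{batch}
#'   + \beta_{time} X_{time} + \beta_{clone} X_{clone} + \varepsilon,}
#' with dummy-coded factors, quantifying how much feature variance each
#' technical covariate (batch, incubation time, clone identity) and the
#' biological variable of interest (resistance status) contributes.  Because
#' clones nest within resistance status, clone dummies aliased with status
#' are dropped automatically to restore full rank; any \emph{other} aliased
#' column is an error.  Inference about each covariate comes from its Tukey
#' HSD family on the feature values grouped by that covariate's levels
#' ([tukeyHSDPairs()]), which is well defined regardless of the nesting.
#'
#' @param wells annotated (typically normalized and feature-selected)
#'   well-level \linkS4class{MorphologyProfiles}.
#' @param covariates metadata columns to include, in model order; the first
#'   must be the resistance status column.
#' @return A \linkS4class{FeatureModelFit}.
#' @seealso [fitConfluenceModel()], [buildSignature()]
#' @importFrom stats lm model.matrix as.formula
#' @export
fitCovariateModel <- function(wells,
                              covariates = c("resistance_status", "batch",
                                             "incubation_time_h",
                                             "clone_id")) {
    stopifnot(is(wells, "MorphologyProfiles"))
    if (profileLevel(wells) != "well")
        stop("fitCovariateModel() expects well-level profiles")
    cd <- as.data.frame(colData(wells))
    miss <- setdiff(covariates, colnames(cd))
    if (length(miss))
        stop("missing design columns: ", paste(miss, collapse = ", "))
    Y <- t(assay(wells, "features"))
    if (anyNA(Y))
        stop("feature matrix contains missing values; run selectFeatures()")

    dat <- cd[, covariates, drop = FALSE]
    for (nm in covariates) dat[[nm]] <- droplevels(factor(dat[[nm]]))
    for (nm in covariates) {
        tab <- table(dat[[nm]])
        if (length(tab) < 2L)
            stop("covariate '", nm, "' has fewer than 2 levels")
        if (min(tab) < 2L)
            stop("covariate '", nm, "' has a level with fewer than 2 replicates")
    }

    fml <- as.formula(paste("Y ~", paste(covariates, collapse = " + ")))
    fit <- lm(fml, data = dat)
    cf <- stats::coef(fit)                       # terms x features
    aliased <- rownames(cf)[is.na(cf[, 1L])]
    clone_cov <- covariates[length(covariates)]
    unexpected <- aliased[!startsWith(aliased, clone_cov)]
    if (length(unexpected))
        stop("rank-deficient design: aliased columns ",
             paste(unexpected, collapse = ", "))

    res <- stats::residuals(fit)
    rss <- colSums(res^2)
    tss <- colSums(scale(Y, scale = FALSE)^2)
    r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
    dfres <- fit$df.residual

    tk <- lapply(covariates, function(nm) tukeyHSDPairs(Y, dat[[nm]]))
    names(tk) <- covariates
    tk <- tk[!vapply(tk, is.null, logical(1L))]

    new("FeatureModelFit",
        features = colnames(Y),
        rSquared = stats::setNames(r2, colnames(Y)),
        coefficients = cf,
        residualVariance = stats::setNames(rss / max(dfres, 1L), colnames(Y)),
        tukey = tk,
        nobs = nrow(Y),
        covariates = covariates)
}

#' Fit the per-feature confluence (cell-count) model
#'
#' Dense wells are expected to shift certain morphology features, which must
#' be kept out of a resistance signature.  For every feature \eqn{Y_j} this
#' fits \deqn{Y_j = \beta_0 + \beta_{status} X_{status} +
#'   \beta_{count} X_{count} + \varepsilon} by OLS and returns the
#' cell-count coefficient with its two-sided t-test p-value.  A feature with
#' no variance gets coefficient 0 and p = 1.
#'
#' @param wells annotated well-level \linkS4class{MorphologyProfiles} with a
#'   \code{cell_count} metadata column.
#' @param status_col,count_col metadata column names.
#' @return \code{DataFrame} with columns \code{feature},
#'   \code{beta_cellcount}, \code{p_cellcount}, \code{beta_status}.
#' @importFrom stats pt
#' @export
fitConfluenceModel <- function(wells, status_col = "resistance_status",
                               count_col = "cell_count") {
    stopifnot(is(wells, "MorphologyProfiles"))
    cd <- as.data.frame(colData(wells))
    if (!count_col %in% colnames(cd))
        stop("no '", count_col, "' metadata column")
    count <- as.numeric(cd[[count_col]])
    if (length(unique(count)) < 2L)
        stop("cell_count is constant; the confluence coefficient is ",
             "unidentifiable")
    Y <- t(assay(wells, "features"))
    if (anyNA(Y)) stop("feature matrix contains missing values")
    status <- droplevels(factor(cd[[status_col]]))
    X <- cbind(1, as.integer(status) - 1L, count)
    colnames(X) <- c("(Intercept)", "status", "cell_count")
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("rank-deficient confluence design")
    cf <- qr.coef(qrX, Y)
    res <- Y - X %*% cf
    dfres <- nrow(X) - ncol(X)
    s2 <- colSums(res^2) / dfres
    xtxinv <- chol2inv(qr.R(qrX))
    se <- sqrt(s2 * xtxinv[3L, 3L])
    tval <- cf["cell_count", ] / se
    p <- 2 * stats::pt(-abs(tval), df = dfres)
    ## constant features: zero coefficient, no evidence
    const <- matrixStats::colVars(Y) == 0
    cf["cell_count", const] <- 0
    p[const] <- 1
    p[!const & se == 0] <- 0
    DataFrame(feature = colnames(Y),
              beta_cellcount = unname(cf["cell_count", ]),
              p_cellcount = unname(p),
              beta_status = unname(cf["status", ]))
}

#' Build the directional resistance signature
#'
#' Applies the discovery filters to the per-feature model results: a feature
#' enters the signature when its resistance-status Tukey comparison passes
#' the Bonferroni-adjusted threshold \eqn{\alpha^* = \alpha_{base} / n}
#' (computed across all \eqn{n} tested features) \emph{and} no exclusion
#' rule fires.  The exclusion rules remove features whose variance tracks a
#' technical covariate rather than resistance:
#' \itemize{
#'   \item any batch-pair Tukey comparison significant at \eqn{\alpha^*};
#'   \item any incubation-time comparison significant at \eqn{\alpha^*};
#'   \item confluence-model cell-count p-value below \eqn{\alpha^*};
#'   \item two or more significant wild-type-clone pairwise comparisons
#'     (generic inter-clone differences not specific to resistance).
#' }
#' Survivors split by the sign of the resistant-minus-sensitive mean
#' difference into up (higher in resistant) and down (lower in resistant)
#' feature sets, each ordered by increasing status p-value.
#'
#' @param model1 a \linkS4class{FeatureModelFit} from [fitCovariateModel()].
#' @param model2 confluence results from [fitConfluenceModel()] (optional;
#'   when NULL the cell-count exclusion is skipped).
#' @param alpha_base base significance level before the Bonferroni division
#'   (default 0.05).
#' @param status_covariate,clone_covariate names of the Tukey families to
#'   use for the status test and the clone exclusion.
#' @param wt_clones character vector identifying wild-type clone labels; by
#'   default clones whose label starts with "WT".
#' @param min_wt_pairs number of significant wild-type pairs that triggers
#'   exclusion (default 2).
#' @return A \linkS4class{MorphSignature}; empty (with a warning) when no
#'   feature survives.
#' @export
buildSignature <- function(model1, model2 = NULL, alpha_base = 0.05,
                           status_covariate = "resistance_status",
                           clone_covariate = "clone_id",
                           wt_clones = NULL, min_wt_pairs = 2L) {
    stopifnot(is(model1, "FeatureModelFit"))
    feats <- model1@features
    nfeat <- length(feats)
    if (!is.null(model2)) {
        if (!setequal(model2$feature, feats))
            stop("model 1 and model 2 cover different feature sets")
        model2 <- model2[match(feats, model2$feature), ]
    }
    alpha_star <- alpha_base / nfeat

    st <- model1@tukey[[status_covariate]]
    if (is.null(st))
        stop("no Tukey family for '", status_covariate, "'")
    if (length(st$levels) != 2L)
        stop("resistance status must have exactly 2 levels")
    ## orient the difference as resistant - sensitive
    flip <- if (st$levels[2L] == "resistant") 1 else -1
    status_diff <- flip * st$diff[, 1L]
    status_p <- st$padj[, 1L]

    excl <- rep(NA_character_, nfeat)
    sig_any <- function(fam) {
        if (is.null(fam)) return(rep(FALSE, nfeat))
        rowSums(fam$padj < alpha_star) > 0
    }
    batch_hit <- sig_any(model1@tukey[["batch"]])
    time_hit <- sig_any(model1@tukey[["incubation_time_h"]])
    count_hit <- if (!is.null(model2)) model2$p_cellcount < alpha_star
                 else rep(FALSE, nfeat)

    cl <- model1@tukey[[clone_covariate]]
    wt_hit <- rep(FALSE, nfeat)
    if (!is.null(cl)) {
        if (is.null(wt_clones))
            wt_clones <- grep("^WT", cl$levels, value = TRUE)
        is_wt_pair <- cl$pairs[1L, ] %in% wt_clones &
            cl$pairs[2L, ] %in% wt_clones
        if (any(is_wt_pair))
            wt_hit <- rowSums(cl$padj[, is_wt_pair, drop = FALSE] <
                                  alpha_star) >= min_wt_pairs
    }
    excl[wt_hit] <- "wt_clone_pairs"
    excl[count_hit] <- "cell_count"
    excl[time_hit] <- "incubation_time"
    excl[batch_hit] <- "batch"

    selected <- status_p < alpha_star & is.na(excl)
    stats <- DataFrame(
        feature = feats,
        status_diff = unname(status_diff),
        status_p = unname(status_p),
        r_squared = unname(model1@rSquared),
        excluded_by = excl,
        selected = selected
    )
    if (!any(selected)) {
        warning("no feature passed the signature filters; empty signature")
        return(MorphSignature(character(), character(), stats = stats,
                              alpha = alpha_star))
    }
    up <- feats[selected & status_diff > 0]
    dn <- feats[selected & status_diff < 0]
    up <- up[order(status_p[match(up, feats)])]
    dn <- dn[order(status_p[match(dn, feats)])]
    MorphSignature(up, dn, stats = stats, alpha = alpha_star)
}

#' Discover a signature from annotated profiles in one call
#'
#' Convenience wrapper running [fitCovariateModel()],
#' [fitConfluenceModel()] and [buildSignature()] on a (typically normalized
#' and feature-selected) well-level table.
#'
#' @inheritParams fitCovariateModel
#' @inheritParams buildSignature
#' @param use_confluence include the cell-count exclusion (default TRUE).
#' @return A \linkS4class{MorphSignature}.
#' @export
discoverSignature <- function(wells, alpha_base = 0.05,
                              covariates = c("resistance_status", "batch",
                                             "incubation_time_h", "clone_id"),
                              use_confluence = TRUE, wt_clones = NULL) {
    m1 <- fitCovariateModel(wells, covariates = covariates)
    m2 <- if (use_confluence) fitConfluenceModel(wells) else NULL
    buildSignature(m1, m2, alpha_base = alpha_base, wt_clones = wt_clones)
}
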