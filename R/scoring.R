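#' Rank a profile's feature values
#'
#' Ascending ranks 1..N (largest value gets rank N); ties receive the mean
#' of the tied ranks.  Missing values are refused because a rank-based score
#' over an incomplete universe is not comparable across profiles.
#'
#' @param values named numeric vector of feature values (length >= 2).
#' @return numeric vector of ranks, same names and order.
#' @examples
#' rankFeatures(c(a = 0.1, b = 0.5, c = 0.3))  # 1, 3, 2
#' @export
rankFeatures <- function(values) {
    if (length(values) < 2L)
        stop("need at least 2 finite values to rank")
    if (anyNA(values) || any(!is.finite(values)))
        stop("missing or non-finite value in scored features: ",
             paste(names(values)[!is.finite(values)], collapse = ", "))
    rank(values, ties.method = "average")
}

## closed-form singscore components from a rank vector
.singscoreFromRanks <- function(ranks, up, down) {
    N <- length(ranks)
    comp <- function(r, n) {
        ## normalized mean rank: min possible (n+1)/2, max possible
        ## (2N-n+1)/2, centered to [-0.5, 0.5]
        (mean(r) - (n + 1) / 2) / (N - n) - 0.5
    }
    upc <- if (length(up)) comp(ranks[up], length(up)) else 0
    dnc <- if (length(down)) comp((N + 1 - ranks)[down], length(down)) else 0
    c(up = upc, down = dnc, total = upc + dnc)
}

#' Single-sample rank-based signature score (singscore)
#'
#' Computes the two-part directional concordance score of one profile
#' against a signature.  Features are ranked within the profile; the up
#' component is the mean rank of the up-set, normalized to
#' \eqn{[-0.5, 0.5]} by its attainable extremes; the down component is
#' computed identically on reversed ranks (\eqn{N + 1 - rank}); the total is
#' their sum, bounded in \eqn{[-1, 1]} and equal to \eqn{\pm 1} exactly at
#' full concordance/discordance.  Being rank-based, the score is invariant
#' to any strictly monotone transform of the profile and therefore
#' comparable across profiles normalized in different ways.
#'
#' The rank universe is the full feature vector supplied (all measured
#' features after selection, not just signature members).
#'
#' @param values named numeric vector: one profile over all N features.
#' @param signature a \linkS4class{MorphSignature} (or anything with
#'   [upFeatures()] / [downFeatures()]); must be nonempty and fully present
#'   among \code{names(values)}, with N greater than the signature size.
#' @return named numeric vector with \code{up}, \code{down}, \code{total}.
#' @examples
#' v <- c(f1 = .2, f2 = .9, f3 = .1, f4 = .5, f5 = .3, f6 = .4)
#' singscore(v, MorphSignature(up = "f5", down = "f2"))
#' @export
singscore <- function(values, signature) {
    up <- upFeatures(signature)
    down <- downFeatures(signature)
    if (!length(up) && !length(down))
        stop("refusing to score an empty signature")
    absent <- setdiff(c(up, down), names(values))
    if (length(absent))
        stop("signature feature(s) absent from profile: ",
             paste(absent, collapse = ", "))
    if (length(values) <= length(up) + length(down))
        stop("rank universe must be larger than the signature")
    ranks <- rankFeatures(values)
    .singscoreFromRanks(ranks, up, down)
}

#' Score well profiles against a signature, with permutation null
#'
#' Applies [singscore()] to every well of a (normalized, feature-selected)
#' profile table, optionally attaching an empirical permutation null per
#' well: feature ranks are randomly shuffled \code{n_permutations} times
#' with the signature held fixed, and the 2.5th/97.5th percentiles of the
#' permuted total scores give the interval within which a well could score
#' by chance.  A dataset-pooled interval over all wells' permuted scores is
#' stored in \code{metadata(result)$pooled_null}.
#'
#' @param profiles well-level \linkS4class{MorphologyProfiles}; every
#'   signature feature must be present and no scored value may be missing.
#' @param signature a \linkS4class{MorphSignature}.
#' @param n_permutations permutations per well (0 = no null; default 0).
#' @param seed RNG seed making the null reproducible.
#' @return \code{DataFrame} with one row per well: available platemap
#'   metadata, \code{score} (total), \code{up_component},
#'   \code{down_component}, and (when permuted) \code{null_lo},
#'   \code{null_hi}, \code{n_permutations}.
#' @export
scoreProfiles <- function(profiles, signature, n_permutations = 0L,
                          seed = 1L) {
    stopifnot(is(profiles, "MorphologyProfiles"))
    if (profileLevel(profiles) != "well")
        stop("scoreProfiles() expects well-level profiles")
    if (n_permutations < 0L) stop("'n_permutations' must be >= 0")
    up <- upFeatures(signature); down <- downFeatures(signature)
    if (!length(up) && !length(down))
        stop("refusing to score an empty signature")
    X <- assay(profiles, "features")
    absent <- setdiff(c(up, down), rownames(X))
    if (length(absent))
        stop("signature feature(s) absent from profiles: ",
             paste(absent, collapse = ", "))

    R <- apply(X, 2L, rankFeatures)       # features x wells
    rownames(R) <- rownames(X)
    sc <- apply(R, 2L, .singscoreFromRanks, up = up, down = down)

    cd <- colData(profiles)
    keep <- intersect(c("plate_id", "well_id", "clone_id",
                        "resistance_status", "batch", "incubation_time_h",
                        "cell_count"), colnames(cd))
    out <- DataFrame(cd[, keep, drop = FALSE],
                     score = sc["total", ],
                     up_component = sc["up", ],
                     down_component = sc["down", ])
    rownames(out) <- colnames(X)

    if (n_permutations >= 1L) {
        N <- nrow(X)
        null_all <- matrix(NA_real_, n_permutations, ncol(X))
        withSeed(seed, {
            for (w in seq_len(ncol(X))) {
                rw <- R[, w]
                null_all[, w] <- vapply(seq_len(n_permutations), function(b) {
                    pr <- rw[sample.int(N)]
                    names(pr) <- rownames(R)
                    .singscoreFromRanks(pr, up, down)[["total"]]
                }, numeric(1L))
            }
        })
        qs <- apply(null_all, 2L, stats::quantile, probs = c(0.025, 0.975),
                    names = FALSE)
        out$null_lo <- qs[1L, ]
        out$null_hi <- qs[2L, ]
        out$n_permutations <- n_permutations
        metadata(out)$pooled_null <- stats::quantile(
            null_all, probs = c(0.025, 0.975), names = FALSE)
    }
    out
}

#' Permutation null for a single profile
#'
#' Randomly shuffles the profile's feature rankings \code{n_permutations}
#' times with the signature fixed and returns the permuted total scores plus
#' their empirical 95\% interval.  Deterministic given \code{seed}.
#'
#' @inheritParams singscore
#' @param n_permutations number of shuffles (>= 1).
#' @param seed RNG seed.
#' @return list with \code{scores} (length \code{n_permutations}),
#'   \code{null_lo}, \code{null_hi}.
#' @export
permutationNull <- function(values, signature, n_permutations = 1000L,
                            seed = 1L) {
    if (n_permutations < 1L)
        stop("'n_permutations' must be at least 1")
    up <- upFeatures(signature); down <- downFeatures(signature)
    ranks <- rankFeatures(values)
    N <- length(ranks)
    scores <- withSeed(seed, vapply(seq_len(n_permutations), function(b) {
        pr <- ranks[sample.int(N)]
        names(pr) <- names(values)
        .singscoreFromRanks(pr, up, down)[["total"]]
    }, numeric(1L)))
    ci <- stats::quantile(scores, probs = c(0.025, 0.975), names = FALSE)
    list(scores = scores, null_lo = ci[1L], null_hi = ci[2L])
}
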