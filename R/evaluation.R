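#' Classify wells from signature scores
#'
#' A profile is called resistant when its signature score is strictly
#' greater than zero and sensitive otherwise (a score of exactly zero gives
#' no positive evidence of resistance).
#'
#' @param score numeric vector of total signature scores (finite).
#' @return character vector of \code{"resistant"} / \code{"sensitive"}.
#' @examples
#' classifyScores(c(0.3, -0.2, 0))  # resistant, sensitive, sensitive
#' @export
classifyScores <- function(score) {
    if (any(!is.finite(score)))
        stop("non-finite score(s) cannot be classified")
    ifelse(score > 0, "resistant", "sensitive")
}

#' Classification metrics for signature scores
#'
#' Computes, with resistant as the positive class:
#' \itemize{
#'   \item \strong{accuracy} of the [classifyScores()] rule
#'     (correct / total);
#'   \item \strong{average precision}, the step-interpolated area under the
#'     precision-recall curve, \eqn{\sum_k (R_k - R_{k-1}) P_k} over the
#'     score-ranked predictions (thresholds at distinct scores, so ties are
#'     grouped);
#'   \item the \strong{ROC curve} from a threshold sweep over distinct
#'     observed scores (predicted positive when score >= threshold), plus
#'     the operating point at the minimum observed score;
#'   \item \strong{AUROC} via the rank (Mann-Whitney) statistic: the
#'     probability that a random resistant well outscores a random sensitive
#'     well, ties counting one half.
#' }
#' With a single-class truth the rank-based metrics are undefined and
#' returned as NA (accuracy is still computed).
#'
#' @param score numeric vector of total signature scores.
#' @param truth true statuses (\code{"resistant"} / \code{"sensitive"}).
#' @return list with \code{accuracy}, \code{average_precision},
#'   \code{auroc}, \code{roc} (DataFrame of threshold, fpr, tpr),
#'   \code{min_threshold_point}, \code{n}, \code{n_positive}.
#' @export
computeMetrics <- function(score, truth) {
    if (length(score) != length(truth))
        stop("'score' and 'truth' lengths differ")
    if (length(score) < 1L) stop("no profiles to evaluate")
    truth <- as.character(truth)
    bad <- setdiff(unique(truth), c("resistant", "sensitive"))
    if (length(bad))
        stop("unknown status label(s): ", paste(bad, collapse = ", "))
    pos <- truth == "resistant"
    acc <- mean(classifyScores(score) == truth)
    if (!any(pos) || all(pos)) {
        return(list(accuracy = acc, average_precision = NA_real_,
                    auroc = NA_real_, roc = NULL,
                    min_threshold_point = NULL,
                    n = length(score), n_positive = sum(pos)))
    }

    ## AUROC: Mann-Whitney rank statistic
    r <- rank(score, ties.method = "average")
    nP <- sum(pos); nN <- sum(!pos)
    auroc <- (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)

    ## threshold sweep over distinct scores, descending; positive iff
    ## score >= threshold
    th <- sort(unique(score), decreasing = TRUE)
    tp <- vapply(th, function(t) sum(pos & score >= t), numeric(1L))
    fp <- vapply(th, function(t) sum(!pos & score >= t), numeric(1L))
    tpr <- tp / nP
    fpr <- fp / nN
    prec <- tp / (tp + fp)
    ap <- sum(diff(c(0, tpr)) * prec)
    roc <- DataFrame(threshold = c(Inf, th),
                     fpr = c(0, fpr), tpr = c(0, tpr))
    list(accuracy = acc,
         average_precision = ap,
         auroc = auroc,
         roc = roc,
         min_threshold_point = c(fpr = fpr[length(fpr)],
                                 tpr = tpr[length(tpr)]),
         n = length(score), n_positive = nP)
}

#' Feature-shuffled baseline metrics
#'
#' Estimates chance-level performance for a signature by repeatedly
#' reassigning its feature identities at random: each repeat draws
#' replacement up/down sets of the same sizes from the surviving feature
#' pool, rescoring every well and recomputing the metrics.  A real signature
#' should beat the mean of this baseline by a wide margin.
#'
#' @param profiles well-level \linkS4class{MorphologyProfiles} (normalized,
#'   feature-selected).
#' @param signature the real \linkS4class{MorphSignature} (defines set
#'   sizes).
#' @param truth true statuses per well; defaults to the
#'   \code{resistance_status} metadata column.
#' @param n_repeats number of shuffles (default 1000, matching the
#'   permutation convention of the scoring null).
#' @param seed RNG seed.
#' @return list with per-repeat \code{metrics} (DataFrame of accuracy,
#'   average_precision, auroc) and summary means/SDs
#'   (\code{accuracy_mean}, \code{accuracy_sd}, ..., \code{auroc_mean},
#'   \code{auroc_sd}).  With \code{n_repeats = 1} the SDs are NA.
#' @export
shuffledBaseline <- function(profiles, signature, truth = NULL,
                             n_repeats = 1000L, seed = 1L) {
    if (n_repeats < 1L) stop("'n_repeats' must be at least 1")
    up_n <- length(upFeatures(signature))
    dn_n <- length(downFeatures(signature))
    if (up_n + dn_n == 0L) stop("empty signature")
    X <- assay(profiles, "features")
    pool <- rownames(X)
    if (length(pool) < up_n + dn_n + 1L)
        stop("feature pool (", length(pool),
             ") is too small for a shuffled signature of size ", up_n + dn_n)
    if (is.null(truth)) truth <- colData(profiles)$resistance_status
    truth <- as.character(truth)

    R <- apply(X, 2L, rankFeatures)
    rownames(R) <- pool
    mets <- withSeed(seed, {
        do.call(rbind, lapply(seq_len(n_repeats), function(b) {
            idx <- sample(pool, up_n + dn_n)
            up <- idx[seq_len(up_n)]
            dn <- idx[up_n + seq_len(dn_n)]
            sc <- apply(R, 2L, function(rw)
                .singscoreFromRanks(rw, up, dn)[["total"]])
            m <- computeMetrics(sc, truth)
            data.frame(accuracy = m$accuracy,
                       average_precision = m$average_precision,
                       auroc = m$auroc)
        }))
    })
    sd_or_na <- function(v) if (length(v) > 1L) stats::sd(v) else NA_real_
    list(metrics = DataFrame(mets),
         accuracy_mean = mean(mets$accuracy),
         accuracy_sd = sd_or_na(mets$accuracy),
         average_precision_mean = mean(mets$average_precision),
         average_precision_sd = sd_or_na(mets$average_precision),
         auroc_mean = mean(mets$auroc),
         auroc_sd = sd_or_na(mets$auroc),
         n_repeats = n_repeats)
}

#' Route wells into disjoint evaluation splits
#'
#' Mirrors the train/validation/test/holdout design used to evaluate a
#' signature: each split is defined by the clones, plates and/or explicit
#' wells it may contain, and every well is assigned to at most one split.  A
#' well matching several splits is an error; a well matching none is left
#' unassigned (NA).
#'
#' @param profiles well-level \linkS4class{MorphologyProfiles} (or a
#'   platemap \code{DataFrame} with plate_id/well_id/clone_id).
#' @param splits named list; each element is a list with optional members
#'   \code{clones}, \code{plates}, \code{wells} (character vectors; a well
#'   matches a split when it satisfies every member given).  An empty
#'   \code{splits} assigns every well to a single \code{"all"} split.
#' @return character vector (one entry per well) of split names, NA for
#'   unassigned wells.
#' @examples
#' pm <- generatePlatemap(syntheticConfig(n_wt_clones = 2, n_res_clones = 2,
#'                                        replicates_per_clone = 4,
#'                                        n_batches = 2))
#' assembleSplits(pm, list(training = list(clones = c("WT01", "BZ01")),
#'                         test = list(clones = c("WT02", "BZ02"))))
#' @export
assembleSplits <- function(profiles, splits = list()) {
    cd <- if (is(profiles, "MorphologyProfiles")) colData(profiles)
          else as(profiles, "DataFrame")
    n <- nrow(cd)
    if (!length(splits)) return(rep("all", n))
    if (is.null(names(splits)) || any(names(splits) == ""))
        stop("'splits' must be a fully named list")
    wkey <- paste(cd$plate_id, cd$well_id, sep = ":")
    assign <- rep(NA_character_, n)
    for (nm in names(splits)) {
        sp <- splits[[nm]]
        hit <- rep(TRUE, n)
        if (!is.null(sp$clones)) hit <- hit & cd$clone_id %in% sp$clones
        if (!is.null(sp$plates)) hit <- hit & cd$plate_id %in% sp$plates
        if (!is.null(sp$wells)) hit <- hit & wkey %in% sp$wells
        clash <- hit & !is.na(assign)
        if (any(clash))
            stop("well(s) assigned to both '", assign[which(clash)[1L]],
                 "' and '", nm, "': ",
                 paste(utils::head(wkey[clash], 5L), collapse = ", "))
        assign[hit] <- nm
    }
    assign
}

#' Evaluate scored wells split by split
#'
#' Runs [computeMetrics()] within each dataset split and, optionally,
#' attaches feature-shuffled baselines.
#'
#' @param scores \code{DataFrame} from [scoreProfiles()] (needs
#'   \code{score} and \code{resistance_status} columns).
#' @param split character vector of split names aligned with \code{scores}
#'   rows (see [assembleSplits()]); NA rows are skipped.
#' @param profiles,signature,n_shuffles,seed when all supplied, a shuffled
#'   baseline ([shuffledBaseline()]) is computed per split.
#' @return named list of per-split evaluation reports.
#' @export
evaluateSplits <- function(scores, split = rep("all", nrow(scores)),
                           profiles = NULL, signature = NULL,
                           n_shuffles = 0L, seed = 1L) {
    stopifnot(nrow(scores) == length(split))
    out <- list()
    for (nm in unique(split[!is.na(split)])) {
        idx <- which(!is.na(split) & split == nm)
        rep <- computeMetrics(scores$score[idx],
                              scores$resistance_status[idx])
        if (!is.null(profiles) && !is.null(signature) && n_shuffles >= 1L) {
            bl <- shuffledBaseline(profiles[, idx], signature,
                                   truth = scores$resistance_status[idx],
                                   n_repeats = n_shuffles, seed = seed)
            rep$shuffled <- bl[c("accuracy_mean", "accuracy_sd",
                                 "average_precision_mean",
                                 "average_precision_sd",
                                 "auroc_mean", "auroc_sd", "n_repeats")]
        }
        out[[nm]] <- rep
    }
    out
}
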