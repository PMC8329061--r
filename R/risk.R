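## Risk distance: signed projection of 2-D SPLS-DA coordinates onto the
## explained-variance-weighted direction, and PPV evaluation at
## SD-multiple cutoffs above the training-control mean.

#' Build a risk-distance model from a fitted 2-component SPLS-DA
#'
#' The risk axis is the unit vector along `(v1, v2)`, the per-component
#' explained variances.  Each sample's risk distance is the signed
#' scalar projection of its 2-D coordinates onto this axis; the
#' orientation sign is chosen so training cases have a larger mean
#' distance than training controls (controls then tend to negative
#' values).  The training controls' distance mean and SD (divisor n-1)
#' anchor the classification cutoffs.
#'
#' @param splsda a fitted 2-component [SplsdaModel-class].
#' @param trainCoords training samples x 2 score matrix; defaults to the
#'   model's fitted scores.
#' @param trainLabels binary 0/1 training labels aligned to the rows.
#' @return a [RiskModel-class].
#' @export
buildRiskModel <- function(splsda, trainLabels, trainCoords = NULL) {
    if (splsda@nComponents < 2L)
        stop("risk distance requires a 2-component model")
    if (is.null(trainCoords)) trainCoords <- splsda@scores[, 1:2]
    trainLabels <- as.integer(trainLabels)
    stopifnot(nrow(trainCoords) == length(trainLabels))
    if (!all(c(0L, 1L) %in% trainLabels))
        stop("both classes are required in training labels")
    v <- splsda@explainedVariance[1:2]
    nv <- sqrt(sum(v^2))
    if (nv == 0)
        stop("degenerate direction: both explained variances are zero")
    u <- v / nv
    proj <- drop(trainCoords[, 1:2] %*% u)
    s <- if (mean(proj[trainLabels == 1]) >= mean(proj[trainLabels == 0]))
        1 else -1
    d <- s * proj
    methods::new("RiskModel", splsda = splsda, direction = u,
                 orientationSign = s,
                 controlMean = mean(d[trainLabels == 0]),
                 controlSd = sd(d[trainLabels == 0]))
}

#' @rdname riskDistance
#' @param scores set `TRUE` when `newdata` is already a samples x 2
#'   score matrix rather than a design matrix.
#' @export
setMethod("riskDistance", "RiskModel",
    function(object, newdata, scores = FALSE) {
        coords <- if (scores) as.matrix(newdata)
                  else predictScores(object@splsda, newdata)[, 1:2,
                                                             drop = FALSE]
        d <- object@orientationSign * drop(coords[, 1:2] %*%
                                           object@direction)
        names(d) <- rownames(coords)
        d
    })

setMethod("show", "RiskModel", function(object) {
    cat("RiskModel\n")
    cat(sprintf("  direction: (%.4f, %.4f), orientation %+d\n",
                object@direction[1], object@direction[2],
                as.integer(object@orientationSign)))
    cat(sprintf("  training controls: mean %.4f, sd %.4f\n",
                object@controlMean, object@controlSd))
    invisible(object)
})

#' Rank-statistic AUROC
#'
#' Mann-Whitney AUROC with midranks for ties: the probability that a
#' randomly chosen case scores above a randomly chosen control, counting
#' ties as one half.
#'
#' @param distances numeric scores (higher = more case-like).
#' @param labels binary 0/1 labels.
#' @return proportion in \[0, 1\].
#' @export
auroc <- function(distances, labels) {
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes are required to compute AUROC")
    r <- rank(distances, ties.method = "average")
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate risk-distance cutoffs at SD multiples
#'
#' For each multiple `m` of the grid, samples with risk distance
#' strictly above `controlMean + m * controlSd` (training-control
#' statistics) are called positive.  Reports positives, true/false
#' positives and PPV per cutoff, the overall AUROC, and the smallest SD
#' multiple `mStar` achieving the target PPV by piecewise-linear
#' interpolation over the grid (undefined when no grid interval brackets
#' the target).
#'
#' @param model a [RiskModel-class].
#' @param testDistances risk distances of the evaluation samples.
#' @param testLabels their true 0/1 labels.
#' @param multiples SD-multiple grid (default `c(1, 1.5, 2, 2.5, 3)`).
#' @param targetPpv PPV target for interpolation (default 0.80).
#' @return an [EvaluationTable-class].
#' @export
evaluateCutoffs <- function(model, testDistances, testLabels,
                            multiples = c(1, 1.5, 2, 2.5, 3),
                            targetPpv = 0.80) {
    testLabels <- as.integer(testLabels)
    stopifnot(length(testDistances) == length(testLabels))
    multiples <- sort(multiples)
    cutoffs <- model@controlMean + multiples * model@controlSd
    rows <- lapply(seq_along(multiples), function(i) {
        pos <- testDistances > cutoffs[i]     # strict inequality
        tp <- sum(pos & testLabels == 1L)
        fp <- sum(pos & testLabels == 0L)
        data.frame(m = multiples[i], cutoff = cutoffs[i],
                   n_positive = tp + fp, tp = tp, fp = fp,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
    })
    tab <- do.call(rbind, rows)
    ## interpolated m*: smallest m on the piecewise-linear PPV curve
    ## reaching the target
    mStar <- NA_real_
    ok <- !is.na(tab$ppv)
    mm <- tab$m[ok]; pp <- tab$ppv[ok]
    for (i in seq_along(mm)) {
        if (pp[i] >= targetPpv) { mStar <- mm[i]; break }
        if (i < length(mm) && pp[i] < targetPpv && pp[i + 1] >= targetPpv) {
            mStar <- mm[i] + (targetPpv - pp[i]) / (pp[i + 1] - pp[i]) *
                (mm[i + 1] - mm[i])
            break
        }
    }
    if (!is.na(mStar)) {
        cutStar <- model@controlMean + mStar * model@controlSd
        posStar <- testDistances > cutStar
        nPosStar <- sum(posStar)
        tpStar <- sum(posStar & testLabels == 1L)
    } else {
        nPosStar <- NA_real_; tpStar <- NA_real_
    }
    methods::new("EvaluationTable", table = tab,
                 auroc = auroc(testDistances, testLabels),
                 targetPpv = targetPpv, mStar = mStar,
                 nPositiveAtMStar = as.numeric(nPosStar),
                 tpAtMStar = as.numeric(tpStar))
}

#' @rdname EvaluationTable-class
#' @param object an `EvaluationTable`.
#' @export
evaluationTable <- function(object) object@table

#' @rdname EvaluationTable-class
#' @export
evaluationSummary <- function(object) list(
    auroc = object@auroc, target_ppv = object@targetPpv,
    m_star = object@mStar,
    n_positive_at_m_star = object@nPositiveAtMStar,
    tp_at_m_star = object@tpAtMStar)

setMethod("show", "EvaluationTable", function(object) {
    cat("EvaluationTable\n")
    print(object@table, row.names = FALSE)
    cat(sprintf("  AUROC: %.4f\n", object@auroc))
    if (is.na(object@mStar))
        cat(sprintf("  target PPV %.0f%% not reached on the grid\n",
                    100 * object@targetPpv))
    else
        cat(sprintf(
            "  target PPV %.0f%% at m* = %.3f (%d positives, %d true)\n",
            100 * object@targetPpv, object@mStar,
            as.integer(object@nPositiveAtMStar),
            as.integer(object@tpAtMStar)))
    invisible(object)
})
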