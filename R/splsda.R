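## Sparse PLS-DA: NIPALS-style PLS regression onto centered/scaled class
## dummies, with per-component soft-thresholding of the X weight vector
## (LASSO-style selection, exactly `keep` nonzero loadings per component)
## and regression deflation of both blocks.

.softThreshKeep <- function(a, keep) {
    nz <- sum(a != 0)
    if (keep >= nz) return(a)
    lambda <- sort(abs(a), decreasing = TRUE)[keep + 1L]
    sign(a) * pmax(abs(a) - lambda, 0)
}

#' Fit a sparse PLS-DA model
#'
#' Centers and unit-variance-scales the design matrix and the
#' dummy-coded class matrix, then extracts `nComponents` latent
#' components.  Per component, the X weight vector is soft-thresholded so
#' that exactly `keep[h]` variables have nonzero weight, shrinking the
#' coefficients of unrelated variables to zero; both blocks are deflated
#' by regression on the component score.  Missing values are imputed by
#' training column means (stored in the model so test-time imputation
#' reuses them).
#'
#' @param x samples x variables design matrix with column names.
#' @param y binary labels (0/1, factor or two-level vector).
#' @param nComponents number of components (default 2).
#' @param keep variables retained per component; a single value is
#'   recycled.  Default 50 per component.
#' @param tol convergence tolerance on the max absolute change of the
#'   weight vector (default 1e-6).
#' @param maxIter iteration cap per component (default 500).
#' @return a [SplsdaModel-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 20, dimnames = list(NULL, paste0("v", 1:10)))
#' y <- rep(0:1, each = 10)
#' x[y == 1, 1] <- x[y == 1, 1] + 3
#' m <- fitSplsda(x, y, nComponents = 2, keep = c(2, 2))
#' selectedVariables(m)
#' @export
fitSplsda <- function(x, y, nComponents = 2L, keep = 50L,
                      tol = 1e-6, maxIter = 500L) {
    x <- as.matrix(x)
    if (is.null(colnames(x)))
        colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
    y <- as.integer(as.factor(y)) - 1L
    classes <- sort(unique(y))
    if (length(classes) != 2L)
        stop("exactly two classes are required")
    nComponents <- as.integer(nComponents)
    keep <- rep_len(as.integer(keep), nComponents)

    imputation <- colMeans(x, na.rm = TRUE)
    nai <- which(is.na(x), arr.ind = TRUE)
    if (nrow(nai)) x[nai] <- imputation[nai[, 2L]]

    sds <- apply(x, 2L, sd)
    dropped <- colnames(x)[is.na(sds) | sds == 0]
    if (length(dropped)) {
        warning("dropping zero-variance variables: ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) " ..." else "")
        x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
        imputation <- imputation[colnames(x)]
        sds <- sds[colnames(x)]
    }
    p <- ncol(x)
    if (any(keep > p))
        stop("keep exceeds the number of usable variables")
    mus <- colMeans(x)
    xs <- scale(x, center = mus, scale = sds)

    ydum <- cbind(`0` = as.numeric(y == 0L), `1` = as.numeric(y == 1L))
    ys <- scale(ydum)

    vn <- colnames(x)
    W <- matrix(0, p, nComponents, dimnames = list(vn, NULL))
    C <- matrix(0, p, nComponents, dimnames = list(vn, NULL))
    Tm <- matrix(0, nrow(x), nComponents)
    ev <- numeric(nComponents)
    iters <- integer(nComponents)
    deltas <- numeric(nComponents)
    converged <- logical(nComponents)
    totalVar <- sum(xs^2)
    Xh <- xs; Yh <- ys

    for (h in seq_len(nComponents)) {
        M <- crossprod(Xh, Yh)                   # p x 2
        b <- svd(M, nu = 0, nv = 1)$v[, 1]       # dominant Y-side weight
        a <- rep(0, p)
        for (it in seq_len(maxIter)) {
            aNew <- drop(M %*% b)
            aNew <- .softThreshKeep(aNew, keep[h])
            nrm <- sqrt(sum(aNew^2))
            if (nrm == 0)
                stop(sprintf("component %d collapsed to the zero vector", h))
            aNew <- aNew / nrm
            tvec <- drop(Xh %*% aNew)
            bNew <- drop(crossprod(Yh, tvec))
            bNew <- bNew / sqrt(sum(bNew^2))
            delta <- max(abs(aNew - a))
            a <- aNew; b <- bNew
            if (delta < tol) break
        }
        iters[h] <- it; deltas[h] <- delta; converged[h] <- delta < tol
        if (!converged[h])
            warning(sprintf(
                "component %d did not converge in %d iterations (delta %.2e)",
                h, maxIter, delta))
        tvec <- drop(Xh %*% a)
        tt <- sum(tvec^2)
        cvec <- drop(crossprod(Xh, tvec)) / tt
        dvec <- drop(crossprod(Yh, tvec)) / tt
        ## sign convention: largest-|entry| weight made positive
        sgn <- sign(a[which.max(abs(a))])
        if (sgn < 0) { a <- -a; tvec <- -tvec; cvec <- -cvec; dvec <- -dvec }
        W[, h] <- a; C[, h] <- cvec; Tm[, h] <- tvec
        ev[h] <- tt * sum(cvec^2) / totalVar
        Xh <- Xh - tcrossprod(tvec, cvec)
        Yh <- Yh - tcrossprod(tvec, dvec)
    }

    methods::new("SplsdaModel",
        nComponents = nComponents, keep = keep,
        variableNames = vn,
        columnMeans = setNames(as.numeric(mus), vn),
        columnScales = setNames(as.numeric(sds), vn),
        imputationMeans = setNames(as.numeric(imputation), vn),
        weights = W, xLoadings = C, scores = Tm,
        classEncoding = c(`0` = 1, `1` = 2),
        explainedVariance = ev,
        selectedVariables = lapply(seq_len(nComponents),
                                   function(h) vn[W[, h] != 0]),
        convergence = list(iterations = iters, final_deltas = deltas,
                           converged = converged),
        droppedVariables = dropped)
}

#' @rdname predictScores
#' @export
setMethod("predictScores", "SplsdaModel", function(object, newdata) {
    if (methods::is(newdata, "BetaSet")) newdata <- t(betaValues(newdata))
    newdata <- as.matrix(newdata)
    miss <- setdiff(object@variableNames, colnames(newdata))
    if (length(miss))
        stop("new data lacks model variables: ",
             paste(head(miss, 10), collapse = ", "),
             if (length(miss) > 10) " ..." else "")
    xn <- newdata[, object@variableNames, drop = FALSE]
    nai <- which(is.na(xn), arr.ind = TRUE)
    if (nrow(nai)) xn[nai] <- object@imputationMeans[nai[, 2L]]
    xs <- scale(xn, center = object@columnMeans,
                scale = object@columnScales)
    R <- object@weights %*%
        solve(crossprod(object@xLoadings, object@weights))
    scores <- xs %*% R
    rownames(scores) <- rownames(newdata)
    scores
})

#' @rdname SplsdaModel-class
#' @export
setMethod("explainedVariance", "SplsdaModel",
          function(object) object@explainedVariance)

#' @rdname SplsdaModel-class
#' @export
setMethod("selectedVariables", "SplsdaModel",
          function(object) object@selectedVariables)

setMethod("show", "SplsdaModel", function(object) {
    cat(sprintf("SplsdaModel: %d components over %d variables\n",
                object@nComponents, length(object@variableNames)))
    cat(sprintf("  keep per component: %s\n",
                paste(object@keep, collapse = ", ")))
    cat(sprintf("  explained variance: %s\n",
                paste(sprintf("%.3f", object@explainedVariance),
                      collapse = ", ")))
    cat(sprintf("  selected (union): %d variables\n",
                length(unique(unlist(object@selectedVariables)))))
    if (!all(object@convergence$converged))
        cat("  WARNING: not all components converged\n")
    invisible(object)
})

#' Variable importance of a fitted SPLS-DA model
#'
#' `importance(v) = sum_h |W[v, h]| * explainedVariance[h]`: variables
#' are credited by their absolute weight in each component, weighted by
#' how much design-matrix variance the component captures.  Ranked in
#' decreasing importance with lexicographic tie-break.
#'
#' @param model a [SplsdaModel-class].
#' @param keepZero include variables with zero importance (default
#'   `FALSE`).
#' @return `data.frame` with columns `variable`, `importance`, `rank`.
#' @export
variableImportance <- function(model, keepZero = FALSE) {
    raw <- drop(abs(model@weights) %*% model@explainedVariance)
    out <- data.frame(variable = model@variableNames,
                      importance = as.numeric(raw),
                      stringsAsFactors = FALSE)
    if (!keepZero) out <- out[out$importance > 0, , drop = FALSE]
    ord <- order(-out$importance, out$variable)
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

# Stratified fold assignment: shuffles within each class, then deals
# samples round-robin so every fold holds both classes.
.stratifiedFolds <- function(y, k) {
    folds <- integer(length(y))
    for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
}

#' Cross-validated AUROC of a sparse PLS-DA classifier
#'
#' Stratified k-fold cross-validation: each fold's model is fitted on
#' the remaining folds and held-out samples are scored by their signed
#' risk-axis projection (explained-variance-weighted component
#' projection, oriented by the training fold).  AUROC is the
#' Mann-Whitney rank statistic; the confidence interval is the normal
#' approximation over fold AUROCs.
#'
#' @param x samples x variables design matrix.
#' @param y binary labels.
#' @param nComponents,keep,tol passed to [fitSplsda()].
#' @param kFolds number of folds (default 10).
#' @param seed integer seed for the fold split.
#' @return list with `mean_auroc`, `fold_aurocs`, `ci` (95% normal
#'   approximation), `k_folds`, `seed`.
#' @export
cvAuroc <- function(x, y, nComponents = 2L, keep = 50L, kFolds = 10L,
                    seed = 1L, tol = 1e-6) {
    y <- as.integer(as.factor(y)) - 1L
    set.seed(seed %% 2147483647L)
    folds <- .stratifiedFolds(y, kFolds)
    if (any(vapply(seq_len(kFolds),
                   function(f) length(unique(y[folds == f])) < 2L,
                   logical(1))))
        stop("a fold lacks one class; use fewer folds or more samples")
    fold_aurocs <- vapply(seq_len(kFolds), function(f) {
        tr <- folds != f
        m <- suppressWarnings(
            fitSplsda(x[tr, , drop = FALSE], y[tr],
                      nComponents = nComponents,
                      keep = pmin(keep, ncol(x)), tol = tol))
        ## held-out samples scored by the signed first-axis projection,
        ## oriented so training-fold cases sit higher
        trainProj <- m@scores[, 1]
        s <- if (mean(trainProj[y[tr] == 1]) >= mean(trainProj[y[tr] == 0]))
            1 else -1
        proj <- s * predictScores(m, x[!tr, , drop = FALSE])[, 1]
        auroc(proj, y[!tr])
    }, numeric(1))
    m <- mean(fold_aurocs)
    se <- sd(fold_aurocs) / sqrt(kFolds)
    list(mean_auroc = m, fold_aurocs = fold_aurocs,
         ci = c(lower = m - 1.96 * se, upper = m + 1.96 * se),
         k_folds = kFolds, seed = seed)
}
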