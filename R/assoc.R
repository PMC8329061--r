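## Supporting inferential analyses: cross-tissue correlation screening,
## logistic mediation of PRS -> case status through methylation, and
## permutation enrichment of SNP-probe colocalization.

# Row-wise Pearson correlation between two probes x samples matrices
# with matched columns.  Zero-variance rows give NA.
.rowCor <- function(a, b) {
    a <- a - rowMeans(a); b <- b - rowMeans(b)
    num <- rowSums(a * b)
    den <- sqrt(rowSums(a^2) * rowSums(b^2))
    out <- num / den
    out[den == 0] <- NA_real_
    out
}

#' Per-probe cross-tissue methylation correlation
#'
#' For each probe, the Pearson correlation of methylation between a
#' reference tissue (e.g. whole blood) and every other tissue, over
#' individuals matched across all tissues.  Systemically variable
#' (CoRSIV-like) probes are expected to correlate positively across
#' tissues; tissue-specific probes are not.
#'
#' @param matrices named list of [BetaSet-class] (or probes x samples
#'   matrices), one per tissue; sample IDs identify individuals.
#' @param referenceTissue name of the reference tissue in `matrices`.
#' @return `data.frame` with `probe_id`, one `r_<tissue>` column per
#'   non-reference tissue, `min_r`, `mean_r`, `n_pairs`, and a logical
#'   `flagged` for probes with zero variance in some tissue.
#' @export
crossTissueCorrelation <- function(matrices, referenceTissue) {
    if (!referenceTissue %in% names(matrices))
        stop("reference tissue '", referenceTissue, "' not in matrices")
    mats <- lapply(matrices, function(m)
        if (methods::is(m, "BetaSet")) betaValues(m) else as.matrix(m))
    probes <- Reduce(intersect, lapply(mats, rownames))
    inds <- Reduce(intersect, lapply(mats, colnames))
    if (length(inds) < 3)
        stop("fewer than 3 matched individuals across tissues")
    if (!length(probes)) stop("no shared probes across tissues")
    mats <- lapply(mats, function(m) m[probes, inds, drop = FALSE])
    ref <- mats[[referenceTissue]]
    others <- setdiff(names(mats), referenceTissue)
    rs <- vapply(others, function(tis) .rowCor(ref, mats[[tis]]),
                 numeric(length(probes)))
    rs <- matrix(rs, nrow = length(probes),
                 dimnames = list(NULL, paste0("r_", others)))
    out <- data.frame(probe_id = probes, rs,
                      min_r = apply(rs, 1L, function(z)
                          if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE)),
                      mean_r = rowMeans(rs, na.rm = TRUE),
                      n_pairs = rowSums(!is.na(rs)),
                      flagged = rowSums(is.na(rs)) > 0,
                      row.names = NULL, stringsAsFactors = FALSE)
    out$mean_r[out$n_pairs == 0] <- NA_real_
    out
}

# Normalized Gauss-Hermite rule for E[f(Z)], Z ~ N(0,1): Golub-Welsch on
# the Jacobi matrix of the probabilists' Hermite polynomials.
.gaussHermite <- function(n = 21L) {
    J <- diag(0, n)
    off <- sqrt(seq_len(n - 1L))
    J[cbind(seq_len(n - 1L), 2:n)] <- off
    J[cbind(2:n, seq_len(n - 1L))] <- off
    e <- eigen(J, symmetric = TRUE)
    list(nodes = e$values, weights = e$vectors[1L, ]^2)
}

# Fit a logistic regression, treating numerical separation (fitted
# probabilities of 0/1, runaway coefficients, non-convergence) as an
# error naming the fit.
.fitLogistic <- function(formula, data, name) {
    sep <- FALSE
    fit <- withCallingHandlers(
        glm(formula, data = data, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (sep || !fit$converged || any(abs(coef(fit)) > 20))
        stop("logistic fit '", name,
             "' did not converge (possible separation)")
    fit
}

# Point estimates of all mediation quantities on one data set.
.mediationPoint <- function(y, x, m, gh) {
    dat <- data.frame(y = y, x = x, m = m)
    fitTotal <- .fitLogistic(y ~ x, dat, "outcome~exposure")
    fitDirect <- .fitLogistic(y ~ x + m, dat,
                              "outcome~exposure+mediator")
    fitMed <- lm(m ~ x)
    a0 <- coef(fitMed)[1]; a1 <- coef(fitMed)[2]
    sigma <- summary(fitMed)$sigma
    b <- coef(fitDirect)
    ## counterfactual effects for a unit (1 SD) exposure contrast 0 -> 1,
    ## integrating the mediator error by Gauss-Hermite quadrature
    pbar <- function(t, tm) {
        mu <- a0 + a1 * tm
        sum(gh$weights * plogis(b[1] + b[2] * t + b[3] * (mu + sigma * gh$nodes)))
    }
    acme <- mean(c(pbar(0, 1) - pbar(0, 0), pbar(1, 1) - pbar(1, 0)))
    ade <- mean(c(pbar(1, 0) - pbar(0, 0), pbar(1, 1) - pbar(0, 1)))
    total <- acme + ade
    c(beta_total = unname(coef(fitTotal)[2]),
      beta_direct = unname(b[2]),
      alpha = unname(a1),
      prop_mediated_diff = 1 - unname(b[2] / coef(fitTotal)[2]),
      acme = acme, ade = ade,
      prop_mediated_acme = if (total != 0) acme / total else NA_real_)
}

#' Mediation of a binary outcome by a continuous mediator
#'
#' Tests whether the association between a continuous exposure (e.g.
#' PRS) and a binary outcome (e.g. case status) is mediated by a
#' continuous mediator (e.g. a methylation risk score).  Exposure and
#' mediator are standardized internally.  Two proportion-mediated
#' estimators are reported: the coefficient-difference ratio
#' `1 - beta_direct / beta_total` from the logistic fits, and the
#' counterfactual (potential-outcomes) estimator
#' `ACME / (ACME + ADE)`, where the average causal mediation and direct
#' effects are predicted-probability contrasts for a 1-SD exposure
#' change, integrating over the mediator's error distribution.
#' Percentile bootstrap confidence intervals are computed over samples.
#'
#' @param outcome binary 0/1 vector.
#' @param exposure,mediator numeric vectors.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list with point estimates (`beta_total`, `beta_direct`,
#'   `alpha`, `acme`, `ade`, `prop_mediated_diff`,
#'   `prop_mediated_acme`), a `ci` matrix of percentile intervals, the
#'   number of complete cases `n`, `n_boot`, `seed`, and an `unstable`
#'   flag raised when the total effect is indistinguishable from zero.
#' @export
mediation <- function(outcome, exposure, mediator, nBoot = 1000L,
                      seed = 1L, conf = 0.95) {
    keep <- stats::complete.cases(outcome, exposure, mediator)
    y <- as.integer(outcome[keep])
    if (!all(y %in% c(0L, 1L))) stop("outcome must be binary 0/1")
    x <- as.numeric(scale(exposure[keep]))
    m <- as.numeric(scale(mediator[keep]))
    n <- length(y)
    gh <- .gaussHermite(21L)
    pt <- .mediationPoint(y, x, m, gh)
    se_total <- summary(suppressWarnings(
        glm(y ~ x, family = binomial())))$coefficients[2, 2]
    unstable <- abs(pt["beta_total"]) < 2 * se_total
    set.seed(seed %% 2147483647L)
    boot <- matrix(NA_real_, nBoot, length(pt),
                   dimnames = list(NULL, names(pt)))
    for (i in seq_len(nBoot)) {
        idx <- sample.int(n, n, replace = TRUE)
        boot[i, ] <- tryCatch(.mediationPoint(y[idx], x[idx], m[idx], gh),
                              error = function(e) rep(NA_real_, length(pt)))
    }
    alpha2 <- (1 - conf) / 2
    ci <- t(apply(boot, 2L, quantile, probs = c(alpha2, 1 - alpha2),
                  na.rm = TRUE))
    out <- as.list(pt)
    out$ci <- ci
    out$n <- n
    out$n_boot <- nBoot
    out$seed <- seed
    out$unstable <- unname(unstable)
    out
}

#' Permutation enrichment of SNPs near model probes
#'
#' Tests whether the probes selected by a classification model lie
#' closer to trait-associated SNPs than expected for an equally sized
#' random draw from the probe background.  The observed statistic is
#' the number of model probes whose interval, extended by `windowBp` on
#' both sides, overlaps at least one SNP; the null is `nPerm` draws of
#' the same number of probes uniformly without replacement from the
#' background.  Coordinates are 0-based half-open.
#'
#' @param modelProbes probe annotation rows of the model's probes (must
#'   be a subset of the background by `probe_id`).
#' @param backgroundProbes probe annotation of all candidate probes.
#' @param snps SNP table (`chrom`, `start`, `end`, `trait`); the test is
#'   run per trait.
#' @param windowBp window half-width in base pairs (default 50000).
#' @param nPerm permutation draws (default 10000).
#' @param seed integer seed.
#' @return `data.frame` with one row per trait: `trait`, `observed`,
#'   `expected`, `fold`, `p_empirical` (add-one corrected, never 0),
#'   `window_bp`, `n_perm`, `seed`.
#' @export
proximityEnrichment <- function(modelProbes, backgroundProbes, snps,
                                windowBp = 50000L, nPerm = 10000L,
                                seed = 1L) {
    if (!all(modelProbes$probe_id %in% backgroundProbes$probe_id))
        stop("model probes must be a subset of the background")
    if (nrow(modelProbes) > nrow(backgroundProbes))
        stop("background smaller than the model probe set")
    bg <- backgroundProbes[order(backgroundProbes$probe_id), , drop = FALSE]
    gr <- probeRanges(bg)
    grWin <- suppressWarnings(
        GenomicRanges::trim(GenomicRanges::resize(
            gr, width = GenomicRanges::width(gr) + 2L * windowBp,
            fix = "center")))
    isModel <- bg$probe_id %in% modelProbes$probe_id
    nModel <- sum(isModel)
    set.seed(seed %% 2147483647L)
    out <- lapply(sort(unique(snps$trait)), function(tr) {
        s <- snps[snps$trait == tr, , drop = FALSE]
        snpGr <- GenomicRanges::GRanges(
            seqnames = s$chrom,
            ranges = IRanges::IRanges(start = s$start + 1L, end = s$end))
        hit <- IRanges::overlapsAny(grWin, snpGr)
        observed <- sum(hit[isModel])
        nullCounts <- vapply(seq_len(nPerm), function(i)
            sum(hit[sample.int(length(hit), nModel)]), numeric(1))
        expected <- mean(nullCounts)
        data.frame(trait = tr, observed = observed, expected = expected,
                   fold = if (expected > 0) observed / expected
                          else NA_real_,
                   p_empirical = (1 + sum(nullCounts >= observed)) /
                       (nPerm + 1),
                   window_bp = windowBp, n_perm = nPerm, seed = seed,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
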