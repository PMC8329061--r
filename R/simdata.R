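## Synthetic methylation cohorts with CoRSIV-like structure.
##
## The generator draws, per individual, a latent "epiallele" methylation
## level for every CoRSIV region from a 3-state mixture; all probes of a
## region share that latent, and observed betas add Beta-distributed
## measurement noise around it.  Case status follows a liability-threshold
## model combining PRS and the mean latent deviation of the informative
## regions, so that a known fraction of the PRS effect on status is
## mediated by methylation.

# Exponentially tilted epiallele state probabilities: p_k(theta) is
# proportional to p_k * exp(theta * mu_k).  The expected latent mean
# m(theta) is then monotone increasing in theta with slope Var_p(mu),
# which gives a closed-form local slope for the mediation bookkeeping.
.tiltProbs <- function(probs, means, theta) {
    w <- sweep(exp(outer(theta, means)), 2L, probs, "*")
    w / rowSums(w)
}

.tiltMean <- function(probs, means, theta) {
    p <- .tiltProbs(probs, means, theta)
    drop(p %*% means)
}

# Average, over PRS ~ N(0,1), of the expected latent mean under the tilt
# kappa*PRS + extra.  Used both to solve the case-effect tilt and to
# compute the realised PRS -> latent slope.
.avgTiltMean <- function(probs, means, kappa, extra = 0, nGrid = 201) {
    z <- seq(-5, 5, length.out = nGrid)
    w <- stats::dnorm(z)
    w <- w / sum(w)
    sum(w * .tiltMean(probs, means, kappa * z + extra))
}

# Tilt offset theta* such that the PRS-averaged expected latent mean
# increases by exactly deltaBeta.
.solveCaseTilt <- function(probs, means, kappa, deltaBeta) {
    if (deltaBeta == 0) return(0)
    base <- .avgTiltMean(probs, means, kappa)
    f <- function(th) .avgTiltMean(probs, means, kappa, th) - base - deltaBeta
    upper <- 1
    while (f(upper) < 0 && upper < 512) upper <- upper * 2
    if (f(upper) < 0)
        stop("deltaBeta too large for the epiallele mixture")
    stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

# Average d E[latent mean] / d PRS over PRS ~ N(0,1): the slope through
# which PRS moves methylation in the liability.
.avgTiltSlope <- function(probs, means, kappa, nGrid = 201) {
    z <- seq(-5, 5, length.out = nGrid)
    w <- stats::dnorm(z)
    w <- w / sum(w)
    p <- .tiltProbs(probs, means, kappa * z)
    m <- drop(p %*% means)
    v <- drop(p %*% means^2) - m^2
    kappa * sum(w * v)
}

.rdirichlet <- function(n, alpha) {
    g <- matrix(rgamma(n * length(alpha), shape = alpha, rate = 1),
                nrow = n, byrow = TRUE)
    g / rowSums(g)
}

# Beta observation noise around a latent mean, concentration phi.
# Latents are clamped away from 0/1 so shape parameters stay positive.
.rbetaNoise <- function(mu, phi) {
    mu <- pmin(pmax(mu, 0.005), 0.995)
    matrix(rbeta(length(mu), mu * phi, (1 - mu) * phi),
           nrow = nrow(mu), ncol = ncol(mu))
}

# Independent deterministic RNG sub-streams derived from one seed, so
# that e.g. adding probes never perturbs sample labels.
.makeStreams <- function(seed, n) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    streams <- lapply(seq_len(n), function(i) {
        set.seed((seed %% 599999999L) * 3L + i)
        get(".Random.seed", envir = globalenv())
    })
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    env <- new.env()
    env$streams <- streams
    env
}

.withStream <- function(env, i, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$streams[[i]], envir = globalenv())
    on.exit({
        env$streams[[i]] <- get(".Random.seed", envir = globalenv())
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    force(expr)
}

#' Configure a synthetic methylation cohort
#'
#' Builds a validated [SimConfig-class].  Defaults emulate the structure
#' of whole-blood HM450 case-control cohorts: a few hundred cases and
#' controls, CoRSIV regions of correlated probes whose latent methylation
#' follows a tri-modal epiallele mixture, unimodal noise probes,
#' smoking-responsive probes, cell-composition-driven probes, and a
#' liability-threshold disease model coupling PRS and methylation.
#'
#' @param nCases,nControls cohort quotas (defaults 414/433, the shape of
#'   a typical training cohort).
#' @param nProbes total number of probes.
#' @param nCorsivRegions,probesPerRegion CoRSIV layout.
#' @param nInformative number of CoRSIV regions carrying the case-control
#'   effect.
#' @param deltaBeta expected case-minus-control methylation difference at
#'   informative probes (state-probability tilt, preserving bimodality).
#' @param epialleleMeans,epialleleProbs 3-state epiallele mixture; default
#'   means (0.15, 0.50, 0.85) reproduce tri/bimodal beta distributions.
#' @param precisionBlood Beta noise concentration around the latent.
#' @param prsLiabilityWeight,methylationLiabilityWeight liability weights
#'   of PRS and of the mean informative-region latent deviation.
#' @param prsMethylationCoupling tilt of informative epiallele states per
#'   unit PRS; routes part of the PRS effect through methylation.
#' @param smokingCaseOddsRatio odds ratio of smoking in cases.
#' @param nSmokingProbes,nCellProbes structured nuisance probe counts.
#' @param cellDirichletAlpha named Dirichlet concentration for leukocyte
#'   fractions; default approximates whole-blood composition dominated by
#'   granulocytes.
#' @param seed integer seed; all randomness derives from it.
#' @param arraySeed integer seeding the per-probe array constants
#'   (baselines of noise, smoking and cell probes).  Leave it fixed when
#'   simulating matched training and testing cohorts so both come from
#'   the same "array"; `seed` alone varies the individuals.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nCases = 414L, nControls = 433L,
                      nProbes = 5000L,
                      nCorsivRegions = 200L, probesPerRegion = 3L,
                      nInformative = 100L,
                      deltaBeta = 0.10,
                      epialleleMeans = c(0.15, 0.50, 0.85),
                      epialleleProbs = c(0.25, 0.50, 0.25),
                      precisionBlood = 50,
                      prsLiabilityWeight = 0.5,
                      methylationLiabilityWeight = 0,
                      prsMethylationCoupling = 0.1,
                      smokingCaseOddsRatio = 3,
                      nSmokingProbes = 10L, nCellProbes = 50L,
                      cellDirichletAlpha = c(Gran = 60, CD4T = 15,
                                             CD8T = 10, Bcell = 5,
                                             Mono = 7, NK = 3),
                      seed = 1L, arraySeed = 20240101L) {
    methods::new("SimConfig",
        nCases = as.integer(nCases), nControls = as.integer(nControls),
        nProbes = as.integer(nProbes),
        nCorsivRegions = as.integer(nCorsivRegions),
        probesPerRegion = as.integer(probesPerRegion),
        nInformative = as.integer(nInformative),
        deltaBeta = deltaBeta,
        epialleleMeans = epialleleMeans, epialleleProbs = epialleleProbs,
        precisionBlood = precisionBlood,
        prsLiabilityWeight = prsLiabilityWeight,
        methylationLiabilityWeight = methylationLiabilityWeight,
        prsMethylationCoupling = prsMethylationCoupling,
        smokingCaseOddsRatio = smokingCaseOddsRatio,
        nSmokingProbes = as.integer(nSmokingProbes),
        nCellProbes = as.integer(nCellProbes),
        cellDirichletAlpha = cellDirichletAlpha,
        seed = as.integer(seed), arraySeed = as.integer(arraySeed))
}

#' Generative mediated fraction implied by a configuration
#'
#' Fraction of the PRS effect on disease liability that flows through
#' methylation: `w_m * c / (w_g + w_m * c)`, where `c` is the realised
#' average slope of the informative-region latent mean with respect to
#' PRS under the configured state tilt.
#'
#' @param config a [SimConfig-class].
#' @return proportion in \[0, 1\].
#' @export
generativeMediatedFraction <- function(config) {
    if (config@nInformative == 0L) return(0)
    cc <- .avgTiltSlope(config@epialleleProbs, config@epialleleMeans,
                        config@prsMethylationCoupling)
    wm <- config@methylationLiabilityWeight
    wg <- config@prsLiabilityWeight
    tot <- wg + wm * cc
    if (tot <= 0) return(0)
    max(0, min(1, wm * cc / tot))
}

#' Liability weights achieving a target mediated fraction
#'
#' Convenience inverse of [generativeMediatedFraction()]: given a target
#' fraction `f` and a total PRS liability effect, returns the PRS and
#' methylation weights such that `w_m * c` carries fraction `f` of the
#' total.
#'
#' @param fraction target mediated fraction in \[0, 1).  `1` is allowed
#'   and sets the direct PRS weight to zero.
#' @param totalEffect total liability slope of PRS (direct + mediated).
#' @param config a [SimConfig-class] supplying the epiallele mixture and
#'   coupling (its weights are ignored).
#' @return named list with `prsLiabilityWeight` and
#'   `methylationLiabilityWeight`.
#' @export
liabilityWeightsForFraction <- function(fraction, totalEffect = 1,
                                        config = simConfig()) {
    stopifnot(fraction >= 0, fraction <= 1, totalEffect > 0)
    cc <- .avgTiltSlope(config@epialleleProbs, config@epialleleMeans,
                        config@prsMethylationCoupling)
    list(prsLiabilityWeight = (1 - fraction) * totalEffect,
         methylationLiabilityWeight = fraction * totalEffect / cc)
}

# Draw epiallele states (n x R) under per-individual tilt theta (length n).
.drawStates <- function(n, R, probs, means, theta) {
    p <- .tiltProbs(probs, means, theta)    # n x 3
    u <- matrix(runif(n * R), n, R)
    1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])
}

#' Simulate a single-tissue case-control methylation cohort
#'
#' Draws a cohort under the generative model of [simConfig()]: latent
#' epiallele states per CoRSIV region shared by the region's probes, Beta
#' observation noise, a liability-threshold disease model with rejection
#' sampling to the case/control quotas, a post-label state-probability
#' tilt giving informative probes an expected case-control difference of
#' `deltaBeta`, smoking and cell-composition nuisance probes, and the
#' derived smoking-score covariate.  Identical seeds give bit-identical
#' output.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `beta` (a [BetaSet-class] carrying the
#'   sample sheet and probe annotation) and `truth` (a
#'   [SimTruth-class]).
#' @examples
#' sim <- simulateCohort(simConfig(nCases = 30, nControls = 30,
#'                                 nProbes = 400, nCorsivRegions = 40,
#'                                 nInformative = 10, seed = 7))
#' sim$beta
#' @export
simulateCohort <- function(config) {
    methods::validObject(config)
    probs <- config@epialleleProbs
    means <- config@epialleleMeans
    kappa <- config@prsMethylationCoupling
    wg <- config@prsLiabilityWeight
    wm <- config@methylationLiabilityWeight
    nInf <- config@nInformative
    n <- config@nCases + config@nControls
    env <- .makeStreams(config@seed, 4L)

    baseMean <- .avgTiltMean(probs, means, if (nInf > 0) kappa else 0)

    ## --- candidate sampling to quotas (streams 1 = samples, 2 = latents)
    nCase <- 0L; nCtrl <- 0L; drawn <- 0L
    prs <- numeric(0); labels <- integer(0)
    infState <- matrix(0L, 0, max(nInf, 1L))
    block <- max(2L * n, 512L)
    while ((nCase < config@nCases || nCtrl < config@nControls)) {
        if (drawn >= 1e6)
            stop("liability model could not meet the case/control quota ",
                 "within 1e6 draws; adjust prsLiabilityWeight or ",
                 "methylationLiabilityWeight")
        p <- .withStream(env, 1L, rnorm(block))
        st <- if (nInf > 0)
            .withStream(env, 2L, .drawStates(block, nInf, probs, means,
                                             kappa * p))
        else matrix(0L, block, 1L)
        D <- if (nInf > 0)
            rowMeans(matrix(means[st], nrow = block)) - baseMean
        else numeric(block)
        eps <- .withStream(env, 1L, rnorm(block))
        L <- wg * p + wm * D + eps
        lab <- as.integer(L > 0)
        keep <- (lab == 1L & nCase + cumsum(lab == 1L) <= config@nCases) |
                (lab == 0L & nCtrl + cumsum(lab == 0L) <= config@nControls)
        prs <- c(prs, p[keep]); labels <- c(labels, lab[keep])
        if (nInf > 0) infState <- rbind(infState, st[keep, , drop = FALSE])
        nCase <- sum(labels == 1L); nCtrl <- sum(labels == 0L)
        drawn <- drawn + block
    }
    ord <- order(labels, decreasing = TRUE)    # cases first, stable
    prs <- prs[ord]; labels <- labels[ord]
    if (nInf > 0) infState <- infState[ord, , drop = FALSE]
    methFactor <- if (nInf > 0)
        rowMeans(matrix(means[infState], nrow = n)) - baseMean
    else numeric(n)

    ## --- planted case effect: re-draw informative states for cases with
    ## an extra tilt solved so the expected case-control mean difference
    ## equals deltaBeta (stream 2)
    if (nInf > 0 && config@deltaBeta > 0) {
        thetaStar <- .solveCaseTilt(probs, means, kappa, config@deltaBeta)
        isCase <- labels == 1L
        infState[isCase, ] <- .withStream(env, 2L,
            .drawStates(sum(isCase), nInf, probs, means,
                        kappa * prs[isCase] + thetaStar))
    }

    ## --- sample-level covariates (stream 3)
    pSmokeCtrl <- 0.3
    oddsCase <- pSmokeCtrl / (1 - pSmokeCtrl) * config@smokingCaseOddsRatio
    pSmoke <- ifelse(labels == 1L, oddsCase / (1 + oddsCase), pSmokeCtrl)
    smoking <- .withStream(env, 3L, as.integer(rbinom(n, 1L, pSmoke)))
    cellFrac <- .withStream(env, 3L,
                            .rdirichlet(n, config@cellDirichletAlpha))
    colnames(cellFrac) <- names(config@cellDirichletAlpha)

    ## --- probe layout
    nCorsivProbes <- config@nCorsivRegions * config@probesPerRegion
    nNoise <- config@nProbes - nCorsivProbes - config@nSmokingProbes -
        config@nCellProbes
    regionIdx <- rep(seq_len(config@nCorsivRegions),
                     each = config@probesPerRegion)
    probeIds <- sprintf("cg%07d", seq_len(config@nProbes))
    regionIds <- sprintf("CoRSIV_%04d", seq_len(config@nCorsivRegions))
    kind <- rep(c("corsiv", "noise", "smoking", "cell"),
                c(nCorsivProbes, nNoise, config@nSmokingProbes,
                  config@nCellProbes))

    ## --- per-probe array constants (array stream: shared by cohorts
    ## simulated with the same arraySeed, so train/test probes match)
    arrayEnv <- .makeStreams(config@arraySeed, 1L)
    consts <- .withStream(arrayEnv, 1L, list(
        noiseMu = if (nNoise > 0) runif(nNoise, 0.05, 0.95) else numeric(0),
        smokingMu = if (config@nSmokingProbes > 0)
            runif(config@nSmokingProbes, 0.4, 0.8) else numeric(0),
        cellWeights = if (config@nCellProbes > 0)
            matrix(runif(config@nCellProbes *
                         length(config@cellDirichletAlpha), 0.1, 0.9),
                   length(config@cellDirichletAlpha),
                   config@nCellProbes) else NULL))

    ## --- probe betas (stream 4); matrices are samples x probes here
    beta <- matrix(NA_real_, n, config@nProbes)
    phi <- config@precisionBlood
    .withStream(env, 4L, {
        state <- matrix(0L, n, config@nCorsivRegions)
        if (config@nCorsivRegions > nInf)
            state[, (nInf + 1L):config@nCorsivRegions] <-
                .drawStates(n, config@nCorsivRegions - nInf, probs, means,
                            rep(0, n))
        if (nInf > 0) state[, seq_len(nInf)] <- infState
        latent <- matrix(means[state], nrow = n)
        beta[, seq_len(nCorsivProbes)] <-
            .rbetaNoise(latent[, regionIdx, drop = FALSE], phi)
        if (nNoise > 0)
            beta[, nCorsivProbes + seq_len(nNoise)] <-
                .rbetaNoise(matrix(consts$noiseMu, n, nNoise,
                                   byrow = TRUE), phi)
        if (config@nSmokingProbes > 0) {
            m <- matrix(consts$smokingMu, n, config@nSmokingProbes,
                        byrow = TRUE) - 0.15 * smoking
            beta[, nCorsivProbes + nNoise +
                   seq_len(config@nSmokingProbes)] <- .rbetaNoise(m, phi)
        }
        if (config@nCellProbes > 0)
            beta[, config@nProbes - config@nCellProbes +
                   seq_len(config@nCellProbes)] <-
                .rbetaNoise(cellFrac %*% consts$cellWeights, phi)
    })

    ## smoking score: fixed weighted sum of hypomethylation at the
    ## designated smoking probes (weights fixed by probe order)
    smokingScore <- if (config@nSmokingProbes > 0) {
        w <- rev(seq_len(config@nSmokingProbes))
        w <- w / sum(w)
        sIdx <- which(kind == "smoking")
        drop((0.6 - beta[, sIdx, drop = FALSE]) %*% w)
    } else rep(0, n)

    sampleIds <- sprintf("S%04d", seq_len(n))
    dimnames(beta) <- list(sampleIds, probeIds)

    ## annotation: regions laid out along chr1..chr22, probes 200 bp apart
    chrom <- paste0("chr", (seq_len(config@nProbes) - 1L) %% 22L + 1L)
    start <- 10000L + 1000L * (seq_len(config@nProbes) - 1L)
    annotation <- data.frame(
        probe_id = probeIds, chrom = chrom,
        start = start, end = start + 2L,
        region_id = c(regionIds[regionIdx],
                      rep(NA_character_, config@nProbes - nCorsivProbes)),
        smoking_flag = as.integer(kind == "smoking"),
        stringsAsFactors = FALSE)

    sheet <- data.frame(
        sample_id = sampleIds, status = labels, prs = prs,
        smoking_score = smokingScore,
        as.data.frame(cellFrac),
        tissue = "blood", cohort = "synthetic",
        stringsAsFactors = FALSE)

    infRegions <- if (nInf > 0) regionIds[seq_len(nInf)] else character(0)
    truth <- methods::new("SimTruth",
        labels = labels,
        informativeProbeIds =
            probeIds[seq_len(nCorsivProbes)][regionIdx <= nInf],
        informativeRegionIds = infRegions,
        effect = rep(config@deltaBeta, nInf),
        prs = prs,
        methylationFactor = methFactor,
        generativeMediatedFraction = generativeMediatedFraction(config),
        smokingStatus = smoking,
        cellFractions = cellFrac)

    list(beta = BetaSet(t(beta), annotation = annotation, samples = sheet),
         truth = truth)
}

#' Simulate matched multi-tissue methylation panels
#'
#' Emulates a multi-tissue design (e.g. blood plus several brain regions
#' from the same individuals): a configurable fraction of probes is
#' "systemic" -- the per-individual epiallele latent is shared across all
#' tissues, with independent Beta noise per tissue -- while the remaining
#' probes draw independent latents per tissue.
#'
#' @param nIndividuals number of matched individuals (>= 3).
#' @param tissues character vector of >= 2 tissue names.
#' @param systemicFraction fraction of probes with a shared latent.
#' @param nProbes number of probes (IDs identical across tissues).
#' @param seed integer seed.
#' @param precision Beta noise concentration.
#' @param epialleleMeans,epialleleProbs latent mixture, as in
#'   [simConfig()].
#' @return named list of [BetaSet-class], one per tissue, matched by
#'   sample ID; each carries a logical `systemic` column in its probe
#'   annotation.
#' @export
simulateMultiTissue <- function(nIndividuals, tissues,
                                systemicFraction = 0.5,
                                nProbes = 1000L, seed = 1L,
                                precision = 50,
                                epialleleMeans = c(0.15, 0.50, 0.85),
                                epialleleProbs = c(0.25, 0.50, 0.25)) {
    if (nIndividuals < 3)
        stop("nIndividuals must be >= 3 (correlation undefined below)")
    if (length(tissues) < 2)
        stop("at least 2 tissues are required")
    stopifnot(systemicFraction >= 0, systemicFraction <= 1)
    nProbes <- as.integer(nProbes)
    nSys <- as.integer(round(systemicFraction * nProbes))
    probeIds <- sprintf("cg%07d", seq_len(nProbes))
    sampleIds <- sprintf("I%04d", seq_len(nIndividuals))
    set.seed(seed %% 2147483647L)
    sysLatent <- matrix(epialleleMeans[
        .drawStates(nIndividuals, max(nSys, 1L), epialleleProbs,
                    epialleleMeans, rep(0, nIndividuals))],
        nrow = nIndividuals)
    chrom <- paste0("chr", (seq_len(nProbes) - 1L) %% 22L + 1L)
    start <- 10000L + 1000L * (seq_len(nProbes) - 1L)
    annotation <- data.frame(
        probe_id = probeIds, chrom = chrom, start = start, end = start + 2L,
        region_id = NA_character_, smoking_flag = 0L,
        systemic = seq_len(nProbes) <= nSys,
        stringsAsFactors = FALSE)
    out <- lapply(tissues, function(tis) {
        lat <- matrix(NA_real_, nIndividuals, nProbes)
        if (nSys > 0)
            lat[, seq_len(nSys)] <- sysLatent[, seq_len(nSys), drop = FALSE]
        if (nSys < nProbes)
            lat[, (nSys + 1L):nProbes] <- matrix(epialleleMeans[
                .drawStates(nIndividuals, nProbes - nSys, epialleleProbs,
                            epialleleMeans, rep(0, nIndividuals))],
                nrow = nIndividuals)
        b <- .rbetaNoise(lat, precision)
        dimnames(b) <- list(sampleIds, probeIds)
        sheet <- data.frame(sample_id = sampleIds, status = NA_integer_,
                            tissue = tis, stringsAsFactors = FALSE)
        BetaSet(t(b), annotation = annotation, samples = sheet)
    })
    names(out) <- tissues
    out
}

setMethod("show", "SimTruth", function(object) {
    cat(sprintf(
        "SimTruth: %d samples (%d cases), %d informative probes\n",
        length(object@labels), sum(object@labels),
        length(object@informativeProbeIds)))
    cat(sprintf("  generative mediated fraction: %.3f\n",
                object@generativeMediatedFraction))
    invisible(object)
})

#' @rdname SimTruth-class
#' @param object a `SimTruth`.
#' @export
simLabels <- function(object) object@labels

#' @rdname SimTruth-class
#' @export
simTruthList <- function(object) list(
    labels = object@labels,
    informative_probe_ids = object@informativeProbeIds,
    informative_region_ids = object@informativeRegionIds,
    effect = object@effect,
    prs = object@prs,
    methylation_factor = object@methylationFactor,
    generative_mediated_fraction = object@generativeMediatedFraction,
    smoking_status = object@smokingStatus,
    cell_fractions = object@cellFractions)
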