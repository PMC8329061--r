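#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom stats var sd cor quantile rnorm runif rbeta rbinom qnorm
#'   pnorm dnorm plogis glm lm binomial coef vcov rgamma uniroot
#'   complete.cases setNames na.omit
#' @importFrom utils head read.delim read.csv write.csv packageVersion
NULL

#' BetaSet: a probes-by-samples methylation matrix
#'
#' `BetaSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single assay `"beta"` holding proportional methylation (beta values) in
#' \[0, 1\].  Probe annotation (genomic coordinates, CoRSIV region
#' membership, smoking flag) lives in `rowData`; the sample sheet (case
#' status, PRS, smoking score, cell fractions) lives in `colData`.
#'
#' Validity enforces unique probe and sample identifiers and beta values in
#' \[0, 1\] (missing values allowed).
#'
#' @seealso [BetaSet()], [betaValues()], [probeAnnotation()], [sampleSheet()]
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
    msg <- NULL
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        bad <- which(!is.na(b) & (b < 0 | b > 1))
        if (length(bad)) {
            ij <- arrayInd(bad[1], dim(b))
            msg <- c(msg, sprintf(
                "beta values must lie in [0,1]; first offender: probe '%s', sample '%s' (%g)",
                rownames(b)[ij[1]], colnames(b)[ij[2]], b[bad[1]]))
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate probe IDs")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample IDs")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "probe and sample IDs are required as dimnames")
    if (is.null(msg)) TRUE else msg
})

#' Configuration of a synthetic methylation cohort
#'
#' Holds every knob of the single-tissue cohort generator: cohort sizes,
#' probe layout (CoRSIV regions, smoking probes, cell-composition probes,
#' unimodal noise probes), the epiallele mixture, the case-control effect
#' size, and the liability model coupling polygenic risk (PRS) and
#' methylation to case status.  Construct with [simConfig()], which
#' supplies the defaults.
#'
#' @slot nCases,nControls cohort quotas.
#' @slot nProbes total probe count on the simulated array.
#' @slot nCorsivRegions,probesPerRegion CoRSIV layout; region variables are
#'   per-region probe averages downstream.
#' @slot nInformative number of CoRSIV regions carrying the case-control
#'   effect (must not exceed `nCorsivRegions`).
#' @slot deltaBeta expected case-minus-control mean methylation difference
#'   at informative regions, achieved by tilting epiallele state
#'   probabilities.
#' @slot epialleleMeans,epialleleProbs 3-state mixture of latent
#'   methylation levels and its state probabilities (must sum to 1).
#' @slot precisionBlood concentration of the Beta observation noise around
#'   the latent per-individual mean.
#' @slot prsLiabilityWeight,methylationLiabilityWeight,prsMethylationCoupling
#'   liability-threshold model: case status is thresholded
#'   `w_g*PRS + w_m*D + e`, where `D` is the mean latent deviation of the
#'   informative regions and the coupling parameter tilts informative
#'   epiallele states by PRS so part of the PRS effect flows through
#'   methylation.
#' @slot smokingCaseOddsRatio odds ratio of smoking in cases vs controls.
#' @slot nSmokingProbes,nCellProbes counts of smoking-responsive and
#'   cell-composition-driven probes.
#' @slot cellDirichletAlpha Dirichlet concentration of the simulated
#'   leukocyte fractions (named vector, one entry per cell type).
#' @slot seed single integer; all randomness derives from it.
#' @slot arraySeed integer seeding the per-probe array constants
#'   (baseline means of noise, smoking and cell probes); shared between
#'   cohorts so that training and testing data come from the same
#'   "array", while `seed` varies the individuals.
#' @export
setClass("SimConfig", representation(
    nCases = "integer", nControls = "integer",
    nProbes = "integer", nCorsivRegions = "integer",
    probesPerRegion = "integer", nInformative = "integer",
    deltaBeta = "numeric",
    epialleleMeans = "numeric", epialleleProbs = "numeric",
    precisionBlood = "numeric",
    prsLiabilityWeight = "numeric", methylationLiabilityWeight = "numeric",
    prsMethylationCoupling = "numeric",
    smokingCaseOddsRatio = "numeric",
    nSmokingProbes = "integer", nCellProbes = "integer",
    cellDirichletAlpha = "numeric",
    seed = "integer", arraySeed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (abs(sum(object@epialleleProbs) - 1) > 1e-12)
        msg <- c(msg, "epialleleProbs must sum to 1 (tolerance 1e-12)")
    if (length(object@epialleleMeans) != 3L ||
        length(object@epialleleProbs) != 3L)
        msg <- c(msg, "epiallele mixture must have exactly 3 states")
    if (any(object@epialleleMeans < 0) || any(object@epialleleMeans > 1))
        msg <- c(msg, "epialleleMeans must lie in [0,1]")
    if (object@nInformative > object@nCorsivRegions)
        msg <- c(msg, "nInformative must not exceed nCorsivRegions")
    if (object@deltaBeta < 0 || object@deltaBeta > 1)
        msg <- c(msg, "deltaBeta must lie in [0,1]")
    mu <- sum(object@epialleleProbs * object@epialleleMeans)
    if (mu + object@deltaBeta > 0.99 || mu - object@deltaBeta < 0.01)
        msg <- c(msg, "deltaBeta pushes informative-probe means outside [0.01, 0.99]")
    if (object@precisionBlood <= 0)
        msg <- c(msg, "precisionBlood must be > 0")
    if (object@smokingCaseOddsRatio <= 0)
        msg <- c(msg, "smokingCaseOddsRatio must be > 0")
    if (any(object@cellDirichletAlpha <= 0))
        msg <- c(msg, "cellDirichletAlpha must be positive")
    nStruct <- object@nCorsivRegions * object@probesPerRegion +
        object@nSmokingProbes + object@nCellProbes
    if (nStruct > object@nProbes)
        msg <- c(msg, sprintf(
            "nProbes (%d) smaller than structured probes (%d)",
            object@nProbes, nStruct))
    if (is.null(msg)) TRUE else msg
})

#' Ground truth of a synthetic cohort
#'
#' Returned alongside the simulated data so recovery tests can compare
#' estimates against the generative truth.
#'
#' @slot labels integer 0/1 per sample (1 = case).
#' @slot informativeProbeIds probe IDs of the effect-carrying CoRSIV
#'   members.
#' @slot informativeRegionIds region IDs carrying the planted effect.
#' @slot effect expected case-minus-control methylation shift per
#'   informative probe.
#' @slot prs per-sample simulated polygenic risk score.
#' @slot methylationFactor per-sample mean latent deviation of informative
#'   regions (the liability mediator).
#' @slot generativeMediatedFraction fraction of the PRS-to-status liability
#'   effect routed through methylation, computed from the weights actually
#'   used.
#' @slot smokingStatus integer 0/1 per sample.
#' @slot cellFractions samples-by-cell-types matrix, rows on the simplex.
#' @export
setClass("SimTruth", representation(
    labels = "integer",
    informativeProbeIds = "character",
    informativeRegionIds = "character",
    effect = "numeric",
    prs = "numeric",
    methylationFactor = "numeric",
    generativeMediatedFraction = "numeric",
    smokingStatus = "integer",
    cellFractions = "matrix"))

setValidity("SimTruth", function(object) {
    msg <- NULL
    if (!all(object@labels %in% c(0L, 1L)))
        msg <- c(msg, "labels must be 0/1")
    if (length(object@prs) != length(object@labels))
        msg <- c(msg, "prs length must match labels")
    f <- object@generativeMediatedFraction
    if (length(f) != 1L || f < 0 || f > 1)
        msg <- c(msg, "generativeMediatedFraction must be a proportion")
    if (is.null(msg)) TRUE else msg
})

#' A fitted sparse PLS-DA model
#'
#' Sparse partial least squares discriminant analysis: PLS regression of a
#' centered/scaled design matrix onto centered/scaled class-indicator
#' columns, with per-component soft-thresholding of the X weight vector so
#' that exactly `keep[h]` variables carry nonzero loadings in component
#' `h`.
#'
#' @slot nComponents number of latent components.
#' @slot keep integer vector, variables retained per component.
#' @slot variableNames column names of the training design matrix (after
#'   dropping zero-variance columns).
#' @slot columnMeans,columnScales training centering/scaling parameters.
#' @slot imputationMeans training-split probe/variable means used to fill
#'   missing values at transform time (leakage-free test-time imputation).
#' @slot weights variables x components matrix W of sparse X weights, each
#'   column unit-norm.
#' @slot xLoadings variables x components matrix C of regression loadings
#'   (`X^T t / t^T t`).
#' @slot scores training samples x components component scores.
#' @slot classEncoding named vector mapping class label to dummy column.
#' @slot explainedVariance per-component fraction of total (scaled) X
#'   variance captured.
#' @slot selectedVariables list of per-component selected variable names.
#' @slot convergence list with per-component iteration counts, final
#'   deltas, and a `converged` flag.
#' @slot droppedVariables zero-variance columns removed before fitting.
#' @export
setClass("SplsdaModel", representation(
    nComponents = "integer", keep = "integer",
    variableNames = "character",
    columnMeans = "numeric", columnScales = "numeric",
    imputationMeans = "numeric",
    weights = "matrix", xLoadings = "matrix",
    scores = "matrix",
    classEncoding = "numeric",
    explainedVariance = "numeric",
    selectedVariables = "list",
    convergence = "list",
    droppedVariables = "character"))

setValidity("SplsdaModel", function(object) {
    msg <- NULL
    for (h in seq_len(object@nComponents)) {
        w <- object@weights[, h]
        if (abs(sqrt(sum(w^2)) - 1) > 1e-8)
            msg <- c(msg, sprintf("weight vector %d is not unit norm", h))
        if (sum(w != 0) != object@keep[h])
            msg <- c(msg, sprintf(
                "component %d has %d nonzero weights, expected %d",
                h, sum(w != 0), object@keep[h]))
    }
    ev <- object@explainedVariance
    if (any(ev < 0 | ev > 1))
        msg <- c(msg, "explainedVariance entries must lie in [0,1]")
    if (is.null(msg)) TRUE else msg
})

#' A risk-distance model
#'
#' Wraps a two-component [SplsdaModel-class] with the direction vector of
#' the risk axis (the per-component explained variances, normalised to
#' unit length), an orientation sign making cases score higher than
#' controls, and the training-control risk-distance mean and SD used to
#' place classification cutoffs.
#'
#' @slot splsda the underlying fitted SPLS-DA model.
#' @slot direction unit 2-vector along which 2-D scores are projected.
#' @slot orientationSign +1 or -1; chosen so training cases have larger
#'   mean risk distance than training controls.
#' @slot controlMean,controlSd risk-distance mean and SD (divisor n-1) of
#'   the training controls.
#' @export
setClass("RiskModel", representation(
    splsda = "SplsdaModel",
    direction = "numeric",
    orientationSign = "numeric",
    controlMean = "numeric",
    controlSd = "numeric"))

setValidity("RiskModel", function(object) {
    msg <- NULL
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
        msg <- c(msg, "direction must be unit length")
    if (!object@orientationSign %in% c(-1, 1))
        msg <- c(msg, "orientationSign must be +1 or -1")
    if (object@controlSd <= 0)
        msg <- c(msg, "controlSd must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' Cutoff-by-cutoff classifier evaluation
#'
#' One row per standard-deviation multiple of the risk-distance cutoff
#' grid, with positive counts, true/false positives and positive
#' predictive value, plus the overall AUROC and the interpolated SD
#' multiple achieving a target PPV.
#'
#' @slot table data.frame with columns `m`, `cutoff`, `n_positive`, `tp`,
#'   `fp`, `ppv` (PPV is `NA` where no sample is called positive).
#' @slot auroc rank-statistic AUROC of the risk distances.
#' @slot targetPpv the PPV target used for interpolation.
#' @slot mStar smallest SD multiple achieving the target PPV by piecewise
#'   linear interpolation over the grid (`NA` if never reached).
#' @slot nPositiveAtMStar,tpAtMStar counts when classifying at the
#'   interpolated cutoff (`NA` when `mStar` is undefined).
#' @export
setClass("EvaluationTable", representation(
    table = "data.frame",
    auroc = "numeric",
    targetPpv = "numeric",
    mStar = "numeric",
    nPositiveAtMStar = "numeric",
    tpAtMStar = "numeric"))

setValidity("EvaluationTable", function(object) {
    tab <- object@table
    msg <- NULL
    need <- c("m", "cutoff", "n_positive", "tp", "fp", "ppv")
    if (!all(need %in% names(tab)))
        msg <- c(msg, "table must have columns m, cutoff, n_positive, tp, fp, ppv")
    else {
        if (is.unsorted(rev(tab$n_positive)) && is.unsorted(-tab$n_positive))
            msg <- c(msg, "n_positive must be non-increasing in m")
        ok <- !is.na(tab$ppv)
        if (any(abs(tab$ppv[ok] - tab$tp[ok] / (tab$tp[ok] + tab$fp[ok])) > 1e-12))
            msg <- c(msg, "ppv must equal tp/(tp+fp)")
    }
    if (is.null(msg)) TRUE else msg
})
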