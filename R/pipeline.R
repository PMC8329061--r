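## End-to-end train/predict glue: feature-space construction on the
## training cohort only, SPLS-DA fit, risk model, and a serializable
## bundle of model + feature specification.

#' Build a design matrix for a feature specification
#'
#' Applies a [featureSpec()] to a cohort: averages CoRSIV regions,
#' extracts the selected probes, appends covariates.  Used identically
#' at train and test time; the specification itself is always derived
#' from training data only.
#'
#' @param beta a [BetaSet-class] carrying probe annotation and sample
#'   sheet.
#' @param spec a [featureSpec()].
#' @return as [assembleFeatures()].
#' @export
buildDesign <- function(beta, spec) {
    regionMatrix <- if (length(spec$corsiv_region_ids))
        averageCorsiv(beta) else NULL
    assembleFeatures(regionMatrix, beta, spec, sampleSheet(beta))
}

#' Train the full risk-classification pipeline
#'
#' On a labelled training cohort: excludes smoking-associated probes,
#' averages CoRSIV regions into one variable each, ranks the remaining
#' probes by range 2-98% and keeps the top `kTopRange`, appends
#' cell-fraction and smoking-score covariates (and optionally PRS),
#' fits a 2-component sparse PLS-DA, and anchors the risk-distance
#' cutoffs on the training controls.
#'
#' @param beta training [BetaSet-class] with annotation and labelled
#'   sample sheet (`status` column).
#' @param kTopRange number of top range 2-98% probes (default 2500;
#'   scale down for small simulated arrays).
#' @param covariates sample-sheet covariate columns; defaults to the
#'   six cell fractions plus smoking score.
#' @param usePrs include the PRS covariate (default `FALSE`).
#' @param nComponents,keep,tol passed to [fitSplsda()].
#' @param targetPpv retained for the evaluation stage default.
#' @return list of class `riskPipeline`: `riskModel`, `featureSpec`,
#'   `params`.
#' @export
trainRiskPipeline <- function(beta, kTopRange = 2500L,
                              covariates = c("Gran", "CD4T", "CD8T",
                                             "Bcell", "Mono", "NK",
                                             "smoking_score"),
                              usePrs = FALSE,
                              nComponents = 2L, keep = 50L,
                              tol = 1e-6, targetPpv = 0.80) {
    annotation <- probeAnnotation(beta)
    sheet <- sampleSheet(beta)
    if (!"status" %in% names(sheet) || all(is.na(sheet$status)))
        stop("training requires a labelled sample sheet (status column)")
    smoking <- excludeSmokingProbes(annotation)
    corsivMembers <- annotation$probe_id[!is.na(annotation$region_id)]
    regionMatrix <- averageCorsiv(beta, annotation)
    stats <- rangeQuantile(beta)
    kTopRange <- min(kTopRange,
                     sum(!stats$probe_id %in% c(smoking, corsivMembers) &
                         !is.na(stats$range_2_98)))
    top <- selectTopRange(stats, k = kTopRange,
                          exclude = c(smoking, corsivMembers))
    covariates <- c(covariates, if (usePrs) "prs")
    spec <- featureSpec(
        corsivRegionIds = rownames(regionMatrix),
        topRangeProbeIds = top,
        covariateNames = covariates,
        excludedProbeIds = setNames(smoking,
                                    rep("smoking", length(smoking))))
    design <- assembleFeatures(regionMatrix, beta, spec, sheet)
    model <- fitSplsda(design$x, design$labels,
                       nComponents = nComponents, keep = keep, tol = tol)
    risk <- buildRiskModel(model, design$labels)
    structure(list(riskModel = risk, featureSpec = spec,
                   params = list(k_top_range = kTopRange,
                                 n_components = nComponents,
                                 keep = rep_len(keep, nComponents),
                                 use_prs = usePrs,
                                 target_ppv = targetPpv)),
              class = "riskPipeline")
}

#' Risk distances of a new cohort under a trained pipeline
#'
#' @param pipeline a `riskPipeline` from [trainRiskPipeline()] or
#'   [readPipeline()].
#' @param beta new-cohort [BetaSet-class] (labels not required).
#' @return named numeric vector of signed risk distances.
#' @export
predictRisk <- function(pipeline, beta) {
    design <- buildDesign(beta, pipeline$featureSpec)
    riskDistance(pipeline$riskModel, design$x)
}

#' Serialize a trained pipeline (model + feature spec) to JSON
#'
#' @param pipeline a `riskPipeline`.
#' @param path JSON path.
#' @export
writePipeline <- function(pipeline, path) {
    rm <- pipeline$riskModel
    payload <- list(schema_version = .MODEL_SCHEMA,
                    model_class = "riskPipeline",
                    feature_spec = unclass(pipeline$featureSpec),
                    params = pipeline$params,
                    risk = list(direction = rm@direction,
                                orientation_sign = rm@orientationSign,
                                control_mean = rm@controlMean,
                                control_sd = rm@controlSd),
                    splsda = .splsdaToList(rm@splsda))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writePipeline
#' @export
readPipeline <- function(path) {
    l <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
    if (!identical(l$schema_version, .MODEL_SCHEMA) ||
        !identical(l$model_class, "riskPipeline"))
        stop("not a pipeline JSON: ", path)
    spl <- .splsdaFromList(l$splsda)
    risk <- methods::new("RiskModel", splsda = spl,
                         direction = as.numeric(l$risk$direction),
                         orientationSign = as.numeric(l$risk$orientation_sign),
                         controlMean = as.numeric(l$risk$control_mean),
                         controlSd = as.numeric(l$risk$control_sd))
    fs <- l$feature_spec
    spec <- featureSpec(
        corsivRegionIds = as.character(fs$corsiv_region_ids),
        topRangeProbeIds = as.character(fs$top_range_probe_ids),
        covariateNames = as.character(fs$covariate_names),
        excludedProbeIds = unlist(fs$excluded_probe_ids))
    structure(list(riskModel = risk, featureSpec = spec,
                   params = l$params),
              class = "riskPipeline")
}
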