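#' @rdname BetaSet
#' @param object,x a package object.
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname BetaSet
#' @export
setGeneric("probeAnnotation",
           function(object) standardGeneric("probeAnnotation"))

#' @rdname BetaSet
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' Project new samples onto fitted SPLS-DA components
#'
#' Applies the training imputation means, centering and scaling stored in
#' the model, then rotates into component space with
#' `T = X_scaled W (C^T W)^{-1}`, the standard PLS rotation under which
#' training samples reproduce their fitted scores.
#'
#' @param object a fitted [SplsdaModel-class].
#' @param newdata samples x variables matrix (or [BetaSet-class]) whose
#'   columns cover the model's variables; matched by name, order-free.
#' @return samples x components score matrix.
#' @export
setGeneric("predictScores",
           function(object, newdata) standardGeneric("predictScores"))

#' Risk distance of samples under a fitted risk model
#'
#' Signed scalar projection of a sample's 2-D SPLS-DA coordinates onto the
#' explained-variance-weighted direction, oriented so training cases score
#' higher than training controls.
#'
#' @param object a [RiskModel-class].
#' @param newdata samples x variables matrix covering the model variables,
#'   or a precomputed samples x 2 score matrix (see `scores=`).
#' @param ... passed to methods.
#' @return named numeric vector of signed risk distances.
#' @export
setGeneric("riskDistance",
           function(object, newdata, ...) standardGeneric("riskDistance"))

#' @rdname SplsdaModel-class
#' @param object a fitted model.
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))

#' @rdname SplsdaModel-class
#' @export
setGeneric("selectedVariables",
           function(object) standardGeneric("selectedVariables"))
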