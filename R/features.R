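## Feature construction: CoRSIV region averaging, range 2-98% and top-K
## selection, smoking-probe exclusion, covariate assembly.

#' Average probes within CoRSIV regions
#'
#' Collapses the probes of each annotated CoRSIV region to their
#' per-sample mean beta (missing values excluded from the mean), giving
#' one variable per region.
#'
#' @param beta a [BetaSet-class] or probes x samples matrix.
#' @param annotation probe annotation with `probe_id` and `region_id`
#'   columns; defaults to the annotation carried by `beta`.
#' @return regions x samples matrix, rownames = region IDs (sorted).
#' @export
averageCorsiv <- function(beta, annotation = NULL) {
    if (methods::is(beta, "BetaSet")) {
        if (is.null(annotation)) annotation <- probeAnnotation(beta)
        beta <- betaValues(beta)
    }
    if (is.null(annotation) || !"region_id" %in% names(annotation))
        stop("probe annotation with a region_id column is required")
    idx <- match(rownames(beta), annotation$probe_id)
    region <- annotation$region_id[idx]
    keep <- !is.na(region)
    if (!any(keep))
        stop("no probe carries a region_id")
    b <- beta[keep, , drop = FALSE]
    region <- region[keep]
    regions <- sort(unique(region))
    out <- matrix(NA_real_, length(regions), ncol(beta),
                  dimnames = list(regions, colnames(beta)))
    present <- !is.na(b)
    sums <- rowsum(ifelse(present, b, 0), region)
    counts <- rowsum(present + 0, region)
    out[] <- (sums / counts)[regions, , drop = FALSE]
    out[counts[regions, , drop = FALSE] == 0] <- NA_real_
    out
}

#' Inter-percentile range (range 2-98%) per probe
#'
#' For each probe, the difference between the `upper` and `lower`
#' quantiles of its beta values across samples, with quantiles by linear
#' interpolation between order statistics at positions `p*(n-1)` (the
#' "type 7" convention).  A robust spread metric that, unlike variance,
#' rewards bi/trimodal probes with well-separated modes.  Variance is
#' reported alongside for comparison.
#'
#' @param beta a [BetaSet-class] or probes x samples matrix.
#' @param lower,upper quantile bounds (defaults 0.02 and 0.98).
#' @return `data.frame` with columns `probe_id`, `range_2_98`,
#'   `variance`, `n_used`, and a logical `flagged` marking probes with
#'   fewer than 3 non-missing values (statistics `NA`).
#' @export
rangeQuantile <- function(beta, lower = 0.02, upper = 0.98) {
    if (methods::is(beta, "BetaSet")) beta <- betaValues(beta)
    stopifnot(lower >= 0, upper <= 1, lower < upper)
    nUsed <- rowSums(!is.na(beta))
    rng <- rep(NA_real_, nrow(beta))
    vr <- rep(NA_real_, nrow(beta))
    ok <- nUsed >= 3L
    if (any(ok)) {
        qs <- apply(beta[ok, , drop = FALSE], 1L, quantile,
                    probs = c(lower, upper), na.rm = TRUE, names = FALSE,
                    type = 7)
        rng[ok] <- qs[2L, ] - qs[1L, ]
        vr[ok] <- apply(beta[ok, , drop = FALSE], 1L, var, na.rm = TRUE)
    }
    data.frame(probe_id = rownames(beta), range_2_98 = rng,
               variance = vr, n_used = nUsed, flagged = !ok,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the top-K probes by range 2-98%
#'
#' Ranks eligible probes by decreasing `range_2_98` and returns the top
#' `k`.  Ties at the boundary are broken by lexicographic probe ID so
#' selection is deterministic.
#'
#' @param stats output of [rangeQuantile()].
#' @param k number of probes to select (default 2500).
#' @param exclude character vector of probe IDs removed before ranking
#'   (typically CoRSIV members and smoking-associated probes).
#' @return character vector of `k` probe IDs, in rank order.
#' @export
selectTopRange <- function(stats, k = 2500L, exclude = character(0)) {
    eligible <- stats[!stats$probe_id %in% exclude &
                      !is.na(stats$range_2_98), , drop = FALSE]
    if (k > nrow(eligible))
        stop(sprintf("k = %d exceeds the %d eligible probes",
                     k, nrow(eligible)))
    ord <- order(-eligible$range_2_98, eligible$probe_id)
    eligible$probe_id[ord[seq_len(k)]]
}

#' Smoking-associated probe IDs
#'
#' Probes flagged as smoking-associated must be excluded before any
#' selection or model fitting, to keep smoking-driven methylation out of
#' the classifier's feature space.
#'
#' @param annotation probe annotation with a `smoking_flag` column.
#' @return character vector of flagged probe IDs (possibly empty).
#' @export
excludeSmokingProbes <- function(annotation) {
    if (!"smoking_flag" %in% names(annotation))
        stop("annotation lacks a smoking_flag column")
    annotation$probe_id[annotation$smoking_flag == 1L]
}

#' A feature-space specification
#'
#' @param corsivRegionIds CoRSIV region variables, in order.
#' @param topRangeProbeIds top range 2-98% probes, in order.
#' @param covariateNames sample-sheet covariates (cell fractions,
#'   smoking score, optionally PRS).
#' @param excludedProbeIds named character vector of excluded probes;
#'   names are reason tags (e.g. "smoking", "corsiv").
#' @return a `featureSpec` list.
#' @export
featureSpec <- function(corsivRegionIds = character(0),
                        topRangeProbeIds = character(0),
                        covariateNames = character(0),
                        excludedProbeIds = character(0)) {
    if (is.null(excludedProbeIds)) excludedProbeIds <- character(0)
    overlap <- intersect(topRangeProbeIds, excludedProbeIds)
    if (length(overlap))
        stop("selected and excluded probe sets overlap: ",
             paste(head(overlap, 5), collapse = ", "))
    structure(list(corsiv_region_ids = as.character(corsivRegionIds),
                   top_range_probe_ids = as.character(topRangeProbeIds),
                   covariate_names = as.character(covariateNames),
                   excluded_probe_ids = excludedProbeIds),
              class = "featureSpec")
}

#' Assemble the design matrix
#'
#' Builds the samples x variables matrix fed to the SPLS-DA fit: CoRSIV
#' region averages first, then top range 2-98% probes, then sample-sheet
#' covariates, with column names preserved for importance reporting.
#' Samples are intersected and ordered by the beta matrix's sample IDs,
#' so input order never affects results.
#'
#' @param regionMatrix regions x samples matrix from [averageCorsiv()]
#'   (or `NULL` when the spec uses no region variables).
#' @param beta a [BetaSet-class] or probes x samples matrix holding the
#'   top-range probes.
#' @param spec a [featureSpec()].
#' @param sheet sample sheet `data.frame` supplying covariates.
#' @return list with `x` (samples x variables design matrix), `labels`
#'   (0/1 or `NA` vector aligned to rows) and `sample_ids`.
#' @export
assembleFeatures <- function(regionMatrix, beta, spec, sheet) {
    if (methods::is(beta, "BetaSet")) beta <- betaValues(beta)
    al <- alignSamples(beta, sheet)
    beta <- al$beta; sheet <- al$sheet
    ids <- colnames(beta)
    parts <- list()
    if (length(spec$corsiv_region_ids)) {
        miss <- setdiff(spec$corsiv_region_ids, rownames(regionMatrix))
        if (length(miss))
            stop("region variables absent from region matrix: ",
                 paste(head(miss, 5), collapse = ", "))
        parts$regions <- t(regionMatrix[spec$corsiv_region_ids, ids,
                                        drop = FALSE])
    }
    if (length(spec$top_range_probe_ids)) {
        miss <- setdiff(spec$top_range_probe_ids, rownames(beta))
        if (length(miss))
            stop("selected probes absent from beta matrix: ",
                 paste(head(miss, 5), collapse = ", "))
        parts$probes <- t(beta[spec$top_range_probe_ids, , drop = FALSE])
    }
    if (length(spec$covariate_names)) {
        miss <- setdiff(spec$covariate_names, names(sheet))
        if (length(miss))
            stop("covariates absent from sample sheet: ",
                 paste(miss, collapse = ", "))
        cov <- as.matrix(sheet[, spec$covariate_names, drop = FALSE])
        storage.mode(cov) <- "double"
        rownames(cov) <- ids
        parts$covariates <- cov
    }
    if (!length(parts)) stop("feature specification is empty")
    x <- do.call(cbind, unname(parts))
    rownames(x) <- ids
    labels <- if ("status" %in% names(sheet))
        as.integer(sheet$status) else rep(NA_integer_, length(ids))
    list(x = x, labels = labels, sample_ids = ids)
}
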