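#' Construct a BetaSet
#'
#' @param beta probes x samples numeric matrix of beta values in \[0,1\]
#'   with probe IDs as rownames and sample IDs as colnames.
#' @param annotation optional probe annotation `data.frame` with columns
#'   `probe_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `region_id` (`NA` outside CoRSIVs) and `smoking_flag`; matched to
#'   rows by `probe_id`.
#' @param samples optional sample sheet `data.frame` with a `sample_id`
#'   column; matched to columns by `sample_id`.
#' @return a [BetaSet-class].
#' @examples
#' b <- matrix(c(.1, .9, .5, .4), 2, dimnames = list(c("p1", "p2"),
#'                                                   c("s1", "s2")))
#' bs <- BetaSet(b)
#' betaValues(bs)
#' @export
BetaSet <- function(beta, annotation = NULL, samples = NULL) {
    beta <- as.matrix(beta)
    storage.mode(beta) <- "double"
    rowdat <- S4Vectors::DataFrame(row.names = rownames(beta))
    if (!is.null(annotation)) {
        stopifnot("probe_id" %in% names(annotation))
        idx <- match(rownames(beta), annotation$probe_id)
        if (anyNA(idx))
            stop("annotation is missing probes: ",
                 paste(head(rownames(beta)[is.na(idx)], 5), collapse = ", "))
        rowdat <- S4Vectors::DataFrame(
            annotation[idx, setdiff(names(annotation), "probe_id"),
                       drop = FALSE],
            row.names = rownames(beta))
    }
    coldat <- S4Vectors::DataFrame(row.names = colnames(beta))
    if (!is.null(samples)) {
        stopifnot("sample_id" %in% names(samples))
        idx <- match(colnames(beta), samples$sample_id)
        if (anyNA(idx))
            stop("sample sheet is missing samples: ",
                 paste(head(colnames(beta)[is.na(idx)], 5), collapse = ", "))
        coldat <- S4Vectors::DataFrame(
            samples[idx, setdiff(names(samples), "sample_id"),
                    drop = FALSE],
            row.names = colnames(beta))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta), rowData = rowdat, colData = coldat)
    methods::new("BetaSet", se)
}

#' @rdname BetaSet
#' @export
setMethod("betaValues", "BetaSet", function(object)
    SummarizedExperiment::assay(object, "beta"))

#' @rdname BetaSet
#' @export
setMethod("probeAnnotation", "BetaSet", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    out <- data.frame(probe_id = rownames(object),
                      as.data.frame(rd),
                      row.names = NULL,
                      check.names = FALSE)
    out
})

#' @rdname BetaSet
#' @export
setMethod("sampleSheet", "BetaSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    data.frame(sample_id = colnames(object), as.data.frame(cd),
               row.names = NULL, check.names = FALSE)
})

#' Probe intervals as a GRanges
#'
#' Builds a [GenomicRanges::GRanges] from the probe annotation.  Internal
#' coordinates are 0-based half-open; GRanges is 1-based closed, so start
#' is shifted by one.
#'
#' @param annotation probe annotation `data.frame` (columns `probe_id`,
#'   `chrom`, `start`, `end`).
#' @return `GRanges` with `probe_id` metadata column.
#' @export
probeRanges <- function(annotation) {
    stopifnot(all(c("probe_id", "chrom", "start", "end") %in%
                  names(annotation)))
    GenomicRanges::GRanges(
        seqnames = annotation$chrom,
        ranges = IRanges::IRanges(start = annotation$start + 1L,
                                  end = annotation$end),
        probe_id = annotation$probe_id)
}

setMethod("show", "BetaSet", function(object) {
    cat(sprintf("BetaSet: %d probes x %d samples\n",
                nrow(object), ncol(object)))
    b <- betaValues(object)
    cat(sprintf("  beta range: [%.3f, %.3f]; %d missing\n",
                suppressWarnings(min(b, na.rm = TRUE)),
                suppressWarnings(max(b, na.rm = TRUE)), sum(is.na(b))))
    rd <- SummarizedExperiment::rowData(object)
    if ("region_id" %in% names(rd))
        cat(sprintf("  CoRSIV regions: %d\n",
                    length(unique(na.omit(rd$region_id)))))
    cd <- SummarizedExperiment::colData(object)
    if ("status" %in% names(cd))
        cat(sprintf("  cases/controls: %d/%d\n",
                    sum(cd$status == 1, na.rm = TRUE),
                    sum(cd$status == 0, na.rm = TRUE)))
    invisible(object)
})

# Intersect and order a beta matrix and sample sheet by sample_id so that
# input file order never affects results.
alignSamples <- function(beta, sheet) {
    common <- intersect(colnames(beta), sheet$sample_id)
    if (!length(common))
        stop("no samples shared between beta matrix and sample sheet")
    missing <- setdiff(colnames(beta), sheet$sample_id)
    if (length(missing))
        warning("samples absent from sheet dropped: ",
                paste(head(missing, 5), collapse = ", "))
    common <- colnames(beta)[colnames(beta) %in% common]
    list(beta = beta[, common, drop = FALSE],
         sheet = sheet[match(common, sheet$sample_id), , drop = FALSE])
}
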