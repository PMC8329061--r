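## On-disk formats: TSV beta matrix, CSV sample sheet, BED-like probe
## annotation, 4-column SNP BED, JSON model files.  All readers validate;
## all writers produce the exact dialect the readers expect.

.fmtBeta <- function(x) {
    out <- sprintf("%.6g", x)    # 6 significant digits, fixed dialect
    out[is.na(x)] <- "NA"
    out
}

#' Read / write a beta matrix as TSV
#'
#' The dialect is a header line `probe_id<TAB>sample...` followed by one
#' row per probe; values are proportions in \[0, 1\] formatted at 6
#' significant digits, missing values as `NA`.  Gzipped files are read
#' transparently.
#'
#' @param path file path (`.gz` accepted on read).
#' @param annotation,samples optional tables attached to the returned
#'   [BetaSet-class], as in [BetaSet()].
#' @return `readBetaMatrix`: a [BetaSet-class]; `writeBetaMatrix`: the
#'   path, invisibly.
#' @export
readBetaMatrix <- function(path, annotation = NULL, samples = NULL) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "probe_id")
        stop("first column of a beta matrix must be 'probe_id'")
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
        stop("duplicate probe IDs: ",
             paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample IDs in beta matrix header")
    storage.mode(m) <- "double"
    rownames(m) <- ids
    bad <- which(!is.na(m) & (m < 0 | m > 1))
    if (length(bad)) {
        ij <- arrayInd(bad[1], dim(m))
        stop(sprintf(
            "beta value out of [0,1] at probe '%s', sample '%s': %g",
            ids[ij[1]], colnames(m)[ij[2]], m[bad[1]]))
    }
    BetaSet(m, annotation = annotation, samples = samples)
}

#' @rdname readBetaMatrix
#' @param x a [BetaSet-class] or probes x samples matrix.
#' @export
writeBetaMatrix <- function(x, path) {
    m <- if (methods::is(x, "BetaSet")) betaValues(x) else as.matrix(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], .fmtBeta(m[i, ])), collapse = "\t"),
        character(1))
    writeLines(body, con)
    invisible(path)
}

#' Read a sample sheet (CSV)
#'
#' Required column: `sample_id`.  Recognised columns: `status` (0/1),
#' `prs`, `smoking_score`, cell-fraction columns, `tissue`, `cohort`.
#' Cell fractions, when present and complete, must sum to 1 within 1e-6
#' per sample.  Unknown columns are kept with a warning.
#'
#' @param path CSV file.
#' @param cellTypes column names holding cell fractions; defaults to the
#'   standard six leukocyte types when present.
#' @return `data.frame` keyed by unique `sample_id`.
#' @export
readSampleSheet <- function(path,
                            cellTypes = c("Gran", "CD4T", "CD8T",
                                          "Bcell", "Mono", "NK")) {
    tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"sample_id" %in% names(tab))
        stop("sample sheet lacks required column 'sample_id'")
    if (anyDuplicated(tab$sample_id))
        stop("duplicate sample_id in sample sheet")
    known <- c("sample_id", "status", "prs", "smoking_score",
               "tissue", "cohort", cellTypes)
    unknown <- setdiff(names(tab), known)
    if (length(unknown))
        warning("unknown sample sheet columns kept as-is: ",
                paste(unknown, collapse = ", "))
    cells <- intersect(cellTypes, names(tab))
    if (length(cells)) {
        fr <- as.matrix(tab[, cells, drop = FALSE])
        tot <- rowSums(fr)
        bad <- which(!is.na(tot) & abs(tot - 1) > 1e-6)
        if (length(bad))
            stop(sprintf(
                "cell fractions of sample '%s' sum to %.6f, not 1",
                tab$sample_id[bad[1]], tot[bad[1]]))
    }
    tab
}

#' @rdname readSampleSheet
#' @param sheet a sample sheet `data.frame`.
#' @export
writeSampleSheet <- function(sheet, path) {
    write.csv(sheet, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read / write probe annotation (BED-like TSV)
#'
#' Six headerless columns: chrom, start, end (0-based half-open),
#' probe_id, region_id (`.` when the probe is outside any CoRSIV),
#' smoking_flag (0/1).
#'
#' @param path file path.
#' @return `data.frame` with columns `probe_id`, `chrom`, `start`, `end`,
#'   `region_id` (`NA` outside regions), `smoking_flag`.
#' @export
readProbeAnnotation <- function(path) {
    tab <- read.delim(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "probe_id",
                                    "region_id", "smoking_flag"))
    if (any(tab$start >= tab$end))
        stop(sprintf("invalid interval (start >= end) for probe '%s'",
                     tab$probe_id[which(tab$start >= tab$end)[1]]))
    if (anyDuplicated(tab$probe_id))
        stop("duplicate probe_id in annotation")
    tab$region_id[tab$region_id == "."] <- NA_character_
    data.frame(probe_id = tab$probe_id, chrom = tab$chrom,
               start = tab$start, end = tab$end,
               region_id = tab$region_id,
               smoking_flag = as.integer(tab$smoking_flag),
               stringsAsFactors = FALSE)
}

#' @rdname readProbeAnnotation
#' @param annotation an annotation `data.frame` (extra columns dropped).
#' @export
writeProbeAnnotation <- function(annotation, path) {
    out <- data.frame(annotation$chrom, annotation$start, annotation$end,
                      annotation$probe_id,
                      ifelse(is.na(annotation$region_id), ".",
                             annotation$region_id),
                      as.integer(annotation$smoking_flag))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a SNP position BED (4 columns)
#'
#' Headerless: chrom, start, end (0-based half-open), trait.  One file
#' can mix several traits; enrichment runs per trait.
#'
#' @param path file path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `trait`.
#' @export
readSnpBed <- function(path) {
    tab <- read.delim(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "trait"))
    if (any(tab$start >= tab$end))
        stop("invalid SNP interval (start >= end) at row ",
             which(tab$start >= tab$end)[1])
    tab
}

## ---- model JSON -----------------------------------------------------

.MODEL_SCHEMA <- "methRisk-model-1"

.splsdaToList <- function(m) list(
    n_components = m@nComponents,
    keep = m@keep,
    variable_names = m@variableNames,
    column_means = m@columnMeans,
    column_scales = m@columnScales,
    imputation_means = m@imputationMeans,
    weights = m@weights,
    x_loadings = m@xLoadings,
    scores = m@scores,
    class_encoding = as.list(m@classEncoding),
    explained_variance = m@explainedVariance,
    selected_variables = m@selectedVariables,
    convergence = m@convergence,
    dropped_variables = m@droppedVariables)

.splsdaFromList <- function(l) {
    toMat <- function(x, nm) {
        m <- if (is.matrix(x)) x else do.call(rbind, x)
        storage.mode(m) <- "double"
        rownames(m) <- nm
        m
    }
    vn <- as.character(l$variable_names)
    methods::new("SplsdaModel",
        nComponents = as.integer(l$n_components),
        keep = as.integer(l$keep),
        variableNames = vn,
        columnMeans = setNames(as.numeric(l$column_means), vn),
        columnScales = setNames(as.numeric(l$column_scales), vn),
        imputationMeans = setNames(as.numeric(l$imputation_means), vn),
        weights = toMat(l$weights, vn),
        xLoadings = toMat(l$x_loadings, vn),
        scores = toMat(l$scores, NULL),
        classEncoding = unlist(l$class_encoding),
        explainedVariance = as.numeric(l$explained_variance),
        selectedVariables = lapply(l$selected_variables, as.character),
        convergence = l$convergence,
        droppedVariables = as.character(l$dropped_variables))
}

#' Serialize models to JSON and back
#'
#' Numbers are written at full precision so a round-trip reproduces
#' predictions bit-identically.  The file carries a `schema_version`
#' field.
#'
#' @param model a [SplsdaModel-class] or [RiskModel-class].
#' @param path JSON file path.
#' @return `writeModel`: path invisibly; `readModel`: the model object.
#' @export
writeModel <- function(model, path) {
    if (methods::is(model, "RiskModel")) {
        payload <- list(schema_version = .MODEL_SCHEMA,
                        model_class = "RiskModel",
                        splsda = .splsdaToList(model@splsda),
                        direction = model@direction,
                        orientation_sign = model@orientationSign,
                        control_mean = model@controlMean,
                        control_sd = model@controlSd)
    } else if (methods::is(model, "SplsdaModel")) {
        payload <- list(schema_version = .MODEL_SCHEMA,
                        model_class = "SplsdaModel",
                        splsda = .splsdaToList(model))
    } else stop("unsupported model class: ", class(model))
    # I(17) = 17 significant digits: doubles survive the text round-trip
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = TRUE)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
    l <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
    if (!identical(l$schema_version, .MODEL_SCHEMA))
        stop("unrecognised model schema: ", l$schema_version)
    spl <- .splsdaFromList(l$splsda)
    if (identical(l$model_class, "SplsdaModel")) return(spl)
    methods::new("RiskModel", splsda = spl,
                 direction = as.numeric(l$direction),
                 orientationSign = as.numeric(l$orientation_sign),
                 controlMean = as.numeric(l$control_mean),
                 controlSd = as.numeric(l$control_sd))
}
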