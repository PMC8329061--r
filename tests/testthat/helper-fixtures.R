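# Small in-code fixtures shared across test files.

# A tiny deterministic beta matrix with dimnames.
tinyBeta <- function(nProbes = 6, nSamples = 4, seed = 1) {
    set.seed(seed)
    m <- matrix(runif(nProbes * nSamples, 0.05, 0.95), nProbes, nSamples,
                dimnames = list(sprintf("cg%07d", seq_len(nProbes)),
                                sprintf("S%03d", seq_len(nSamples))))
    m
}

# Annotation for tinyBeta: first half of the probes grouped in regions
# of two, one smoking probe at the end.
tinyAnnotation <- function(nProbes = 6) {
    ids <- sprintf("cg%07d", seq_len(nProbes))
    region <- rep(NA_character_, nProbes)
    nReg <- nProbes %/% 2
    region[seq_len(nReg)] <- sprintf("CoRSIV_%04d", rep(seq_len((nReg + 1) %/% 2),
                                                        each = 2)[seq_len(nReg)])
    data.frame(probe_id = ids, chrom = "chr1",
               start = seq_len(nProbes) * 100L,
               end = seq_len(nProbes) * 100L + 2L,
               region_id = region,
               smoking_flag = as.integer(seq_len(nProbes) == nProbes),
               stringsAsFactors = FALSE)
}

# A small labelled cohort with planted signal: fast enough for unit
# tests, strong enough to separate classes.
quickConfig <- function(seed = 1, ...) {
    args <- list(nCases = 60L, nControls = 60L, nProbes = 400L,
                 nCorsivRegions = 40L, probesPerRegion = 3L,
                 nInformative = 15L, deltaBeta = 0.12,
                 nSmokingProbes = 5L, nCellProbes = 20L, seed = seed)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(simConfig, args)
}

# Design matrix with one clearly separating variable among noise.
separableDesign <- function(n = 40, p = 10, seed = 3) {
    set.seed(seed)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("v%02d", seq_len(p))))
    y <- rep(0:1, length.out = n)
    x[y == 1, 1] <- x[y == 1, 1] + 8
    list(x = x, y = y)
}
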