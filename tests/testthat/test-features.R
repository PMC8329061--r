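# Independent brute-force oracle: sort and linearly interpolate order
# statistics at p*(n-1), no calls into the package's own path.
bruteRange <- function(v, lower = 0.02, upper = 0.98) {
    v <- sort(v[!is.na(v)])
    n <- length(v)
    interp <- function(p) {
        h <- p * (n - 1)
        lo <- floor(h) + 1
        hi <- ceiling(h) + 1
        v[lo] + (h - floor(h)) * (v[hi] - v[lo])
    }
    interp(upper) - interp(lower)
}

test_that("range 2-98% equals the brute-force oracle to 1e-12", {
    set.seed(7)
    for (n in c(5, 17, 100)) {
        m <- matrix(runif(50 * n), 50, n,
                    dimnames = list(sprintf("p%02d", 1:50), NULL))
        colnames(m) <- sprintf("s%03d", seq_len(n))
        got <- rangeQuantile(m)
        want <- apply(m, 1, bruteRange)
        expect_equal(got$range_2_98, unname(want), tolerance = 1e-12)
    }
})

test_that("range 2-98% handles the stated edge cases", {
    m <- rbind(const = rep(0.5, 101),
               grid = seq(0, 1, by = 0.01))
    colnames(m) <- sprintf("s%03d", 1:101)
    got <- rangeQuantile(m)
    expect_equal(got$range_2_98[got$probe_id == "const"], 0)
    expect_equal(got$range_2_98[got$probe_id == "grid"], 0.96)
    # too few values -> flagged, NA statistic
    m2 <- matrix(c(0.1, NA, NA, NA), 1, 4,
                 dimnames = list("sparse", sprintf("s%d", 1:4)))
    got2 <- rangeQuantile(m2)
    expect_true(got2$flagged)
    expect_true(is.na(got2$range_2_98))
})

test_that("range never exceeds max minus min and ignores sample order", {
    set.seed(8)
    m <- matrix(rbeta(40 * 30, 0.5, 0.5), 40, 30,
                dimnames = list(sprintf("p%02d", 1:40),
                                sprintf("s%02d", 1:30)))
    got <- rangeQuantile(m)
    spread <- apply(m, 1, function(v) max(v) - min(v))
    expect_true(all(got$range_2_98 <= spread + 1e-12))
    perm <- m[, sample(ncol(m))]
    expect_equal(rangeQuantile(perm)$range_2_98, got$range_2_98)
})

test_that("CoRSIV averaging is the per-region mean, probe-order invariant", {
    m <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2,
                dimnames = list(c("cgA", "cgB"), c("s1", "s2")))
    ann <- data.frame(probe_id = c("cgA", "cgB"), chrom = "chr1",
                      start = c(0, 10), end = c(2, 12),
                      region_id = "R1", smoking_flag = 0L)
    out <- averageCorsiv(m, ann)
    expect_equal(out["R1", ], c(s1 = 0.3, s2 = 0.7))
    # single-probe region is the identity
    ann2 <- ann; ann2$region_id <- c("R1", "R2")
    out2 <- averageCorsiv(m, ann2)
    expect_equal(out2["R2", ], m["cgB", ])
    # probe order inside a region does not matter
    out3 <- averageCorsiv(m[c("cgB", "cgA"), ], ann)
    expect_equal(out3, out)
    # missing values drop out of the mean; all-missing gives NA
    m[1, 1] <- NA
    out4 <- averageCorsiv(m, ann)
    expect_equal(out4["R1", "s1"], 0.4)
    m[2, 1] <- NA
    expect_true(is.na(averageCorsiv(m, ann)["R1", "s1"]))
})

test_that("region count equals the number of distinct region IDs", {
    set.seed(9)
    ids <- sprintf("cg%03d", 1:30)
    ann <- data.frame(probe_id = ids, chrom = "chr1",
                      start = 1:30 * 10, end = 1:30 * 10 + 2,
                      region_id = rep(sprintf("R%02d", 1:10), each = 3),
                      smoking_flag = 0L)
    m <- matrix(runif(30 * 4), 30, 4,
                dimnames = list(ids, sprintf("s%d", 1:4)))
    expect_equal(nrow(averageCorsiv(m, ann)), 10)
})

test_that("top-range selection respects exclusions, ties and planted signal", {
    stats <- data.frame(probe_id = c("b", "a", "c", "d"),
                        range_2_98 = c(0.5, 0.5, 0.9, 0.1),
                        variance = 0.01, n_used = 10, flagged = FALSE)
    # tie at the boundary: lexicographically smaller ID wins
    expect_equal(selectTopRange(stats, k = 2), c("c", "a"))
    expect_equal(sort(selectTopRange(stats, k = 4)), c("a", "b", "c", "d"))
    expect_error(selectTopRange(stats, k = 5), "exceeds")
    expect_equal(selectTopRange(stats, k = 1, exclude = "c"), "a")
    # planted high-range probes always make the cut
    set.seed(10)
    lowVar <- matrix(rbeta(200 * 60, 40, 40), 200, 60)
    high <- matrix(rbeta(100 * 60, 0.3, 0.3), 100, 60)
    m <- rbind(high, lowVar)
    rownames(m) <- sprintf("cg%04d", seq_len(nrow(m)))
    colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
    top <- selectTopRange(rangeQuantile(m), k = 100)
    expect_setequal(top, rownames(m)[1:100])
})

test_that("smoking probes are identified and excluded from selection", {
    ann <- tinyAnnotation(6)
    expect_equal(excludeSmokingProbes(ann), "cg0000006")
    ann$smoking_flag <- 0L
    expect_length(excludeSmokingProbes(ann), 0)
    expect_error(excludeSmokingProbes(ann[, -6]), "smoking_flag")
})

test_that("design assembly orders columns, aligns samples, checks covariates", {
    sim <- simulateCohort(quickConfig(seed = 61))
    ann <- probeAnnotation(sim$beta)
    sheet <- sampleSheet(sim$beta)
    rm <- averageCorsiv(sim$beta)
    top <- selectTopRange(rangeQuantile(sim$beta), k = 20,
                          exclude = c(excludeSmokingProbes(ann),
                                      ann$probe_id[!is.na(ann$region_id)]))
    spec <- featureSpec(rownames(rm), top,
                        c("Gran", "CD4T", "smoking_score"))
    d <- assembleFeatures(rm, sim$beta, spec, sheet)
    expect_equal(ncol(d$x), 40 + 20 + 3)
    expect_identical(colnames(d$x),
                     c(rownames(rm), top, c("Gran", "CD4T", "smoking_score")))
    # adding PRS adds exactly one column
    specPrs <- featureSpec(rownames(rm), top,
                           c("Gran", "CD4T", "smoking_score", "prs"))
    expect_equal(ncol(assembleFeatures(rm, sim$beta, specPrs, sheet)$x),
                 ncol(d$x) + 1)
    # shuffled sheet order gives the identical matrix
    d2 <- assembleFeatures(rm, sim$beta, spec,
                           sheet[sample(nrow(sheet)), ])
    expect_identical(d$x, d2$x)
    expect_error(assembleFeatures(rm, sim$beta,
                                  featureSpec(rownames(rm), top, "age"),
                                  sheet),
                 "covariates absent")
    expect_error(featureSpec(topRangeProbeIds = "a",
                             excludedProbeIds = "a"), "overlap")
})

test_that("top-k by range is enriched for multimodal CoRSIV-like probes", {
    sim <- simulateCohort(quickConfig(seed = 71, nCellProbes = 0L,
                                      nSmokingProbes = 0L))
    ann <- probeAnnotation(sim$beta)
    stats <- rangeQuantile(sim$beta)
    top <- selectTopRange(stats, k = 60)
    isCorsiv <- !is.na(ann$region_id[match(stats$probe_id, ann$probe_id)])
    inTop <- stats$probe_id %in% top
    tab <- table(corsiv = isCorsiv, top = inTop)
    orr <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
    expect_gt(orr, 1)
})
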