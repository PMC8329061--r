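test_that("cross-tissue correlation: identity, null and systemic cases", {
    m <- tinyBeta(10, 8)
    # identical matrices correlate perfectly at every probe
    r <- crossTissueCorrelation(list(a = m, b = m, c = m), "a")
    expect_true(all(abs(r$min_r - 1) < 1e-12))
    # independent matrices: mean r near zero at n = 67
    mt <- simulateMultiTissue(67, c("blood", "brain"),
                              systemicFraction = 0, nProbes = 300,
                              seed = 17)
    r0 <- crossTissueCorrelation(mt, "blood")
    expect_lt(abs(mean(r0$mean_r)), 0.2)
    # zero-variance probes are flagged, not propagated as numbers
    m2 <- m; m2[1, ] <- 0.5
    r2 <- crossTissueCorrelation(list(a = m2, b = m), "a")
    expect_true(r2$flagged[r2$probe_id == rownames(m)[1]])
    expect_true(is.na(r2$min_r[r2$probe_id == rownames(m)[1]]))
    expect_error(crossTissueCorrelation(list(a = m[, 1:2], b = m[, 1:2]),
                                        "a"), "3 matched")
})

test_that("systemic probes recover high correlation over several seeds", {
    fracHigh <- vapply(1:5, function(s) {
        mt <- simulateMultiTissue(67, c("blood", "PFC", "CER"),
                                  systemicFraction = 0.5, nProbes = 200,
                                  seed = s)
        ct <- crossTissueCorrelation(mt, "blood")
        sys <- probeAnnotation(mt$blood)$systemic
        mean(ct$min_r[sys] >= 0.5)
    }, numeric(1))
    expect_true(all(fracHigh >= 0.9))
})

test_that("logistic fits satisfy their score equations", {
    set.seed(41)
    n <- 400
    x <- rnorm(n); m <- 0.5 * x + rnorm(n)
    y <- rbinom(n, 1, plogis(0.8 * x + 0.6 * m))
    res <- mediation(y, x, m, nBoot = 5, seed = 1)
    # gradient of the logistic log-likelihood is zero at the estimates
    xs <- as.numeric(scale(x)); ms <- as.numeric(scale(m))
    X <- cbind(1, xs, ms)
    eta <- X %*% c(coef(glm(y ~ xs + ms, family = binomial())))
    expect_lt(max(abs(crossprod(X, y - plogis(eta)))), 1e-6)
    # the package's direct coefficient agrees with glm
    expect_equal(res$beta_direct,
                 unname(coef(glm(y ~ xs + ms, family = binomial()))[2]),
                 tolerance = 1e-8)
})

test_that("mediation null and full-mediation limits behave", {
    set.seed(42)
    n <- 2000
    x <- rnorm(n)
    # mediator unrelated to anything: both proportions near 0, CI covers 0
    m0 <- rnorm(n)
    y0 <- rbinom(n, 1, plogis(0.8 * x))
    r0 <- mediation(y0, x, m0, nBoot = 120, seed = 2)
    expect_lt(abs(r0$prop_mediated_acme), 0.05)
    expect_lte(r0$ci["prop_mediated_acme", 1], 0)
    expect_gte(r0$ci["prop_mediated_acme", 2], 0)
    # exposure acts only through the mediator: proportion near 1
    m1 <- x + 0.3 * rnorm(n)
    y1 <- rbinom(n, 1, plogis(1.5 * scale(m1)))
    r1 <- mediation(y1, x, m1, nBoot = 5, seed = 3)
    expect_gte(r1$prop_mediated_acme, 0.9)
    # diff and ACME estimators agree for small effects / rare outcome
    set.seed(43)
    xr <- rnorm(5000); mr <- 0.4 * xr + rnorm(5000)
    yr <- rbinom(5000, 1, plogis(-2.5 + 0.25 * xr + 0.25 * mr))
    rr <- mediation(yr, xr, mr, nBoot = 5, seed = 4)
    expect_lt(abs(rr$prop_mediated_diff - rr$prop_mediated_acme), 0.05)
})

test_that("mediation flags separation and unstable totals", {
    set.seed(45)
    x <- c(rnorm(50, -6), rnorm(50, 6))    # complete separation
    y <- rep(0:1, each = 50)
    expect_error(mediation(y, x, rnorm(100), nBoot = 2, seed = 1),
                 "converge|separation")
    set.seed(44)
    xw <- rnorm(300); yw <- rbinom(300, 1, 0.5)
    rw <- mediation(yw, xw, rnorm(300), nBoot = 5, seed = 1)
    expect_true(rw$unstable)
})

test_that("enrichment finds planted colocalization and stays calibrated", {
    ann <- data.frame(probe_id = sprintf("cg%04d", 1:200),
                      chrom = rep(c("chr1", "chr2"), each = 100),
                      start = rep(seq(0, 99) * 100000L, 2),
                      end = rep(seq(0, 99) * 100000L, 2) + 2L,
                      region_id = NA_character_, smoking_flag = 0L,
                      stringsAsFactors = FALSE)
    model <- ann[1:30, ]
    # SNPs adjacent to every model probe, none near the others
    snps <- data.frame(chrom = model$chrom, start = model$start + 10L,
                       end = model$start + 11L, trait = "SZ")
    res <- proximityEnrichment(model, ann, snps, windowBp = 100L,
                               nPerm = 999L, seed = 7)
    expect_equal(res$observed, 30)
    expect_gt(res$fold, 1)
    expect_equal(res$p_empirical, 1 / 1000)
    # window 0 with SNPs strictly outside all probe intervals
    far <- data.frame(chrom = "chr1", start = 50L, end = 51L,
                      trait = "SZ")
    res0 <- proximityEnrichment(model, ann, far, windowBp = 0L,
                                nPerm = 99L, seed = 7)
    expect_equal(res0$observed, 0)
    expect_gt(res0$p_empirical, 0)
    # row order of inputs does not change fold
    resShuf <- proximityEnrichment(model[sample(nrow(model)), ],
                                   ann[sample(nrow(ann)), ], snps,
                                   windowBp = 100L, nPerm = 999L, seed = 7)
    expect_equal(resShuf$fold, res$fold)
    expect_error(proximityEnrichment(ann, model, snps), "subset")
})

test_that("enrichment p-values are approximately uniform under the null", {
    ann <- data.frame(probe_id = sprintf("cg%04d", 1:1000),
                      chrom = "chr1",
                      start = seq_len(1000) * 50000L,
                      end = seq_len(1000) * 50000L + 2L,
                      region_id = NA_character_, smoking_flag = 0L,
                      stringsAsFactors = FALSE)
    set.seed(99)
    model <- ann[sample(1000, 100), ]
    ps <- vapply(1:200, function(i) {
        snps <- data.frame(chrom = "chr1",
                           start = sample.int(1000 * 50000L, 700))
        snps$end <- snps$start + 1L
        snps$trait <- "X"
        proximityEnrichment(model, ann, snps, windowBp = 10000L,
                            nPerm = 499L, seed = i)$p_empirical
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
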