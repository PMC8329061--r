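test_that("dense one-component fit matches the SVD of the scaled cross-covariance", {
    set.seed(21)
    for (i in 1:5) {
        x <- matrix(rnorm(50 * 20), 50, 20,
                    dimnames = list(NULL, sprintf("v%02d", 1:20)))
        y <- rbinom(50, 1, 0.5)
        if (length(unique(y)) < 2) y[1:2] <- 0:1
        m <- fitSplsda(x, y, nComponents = 1, keep = 20)
        xs <- scale(x)
        ys <- scale(cbind(y == 0, y == 1))
        sv <- svd(crossprod(xs, ys))$u[, 1]
        expect_gte(abs(sum(m@weights[, 1] * sv)), 0.999)
    }
})

test_that("sparsity contract: exactly keep nonzero loadings per component", {
    set.seed(22)
    x <- matrix(rnorm(80 * 60), 80, 60,
                dimnames = list(NULL, sprintf("v%02d", 1:60)))
    y <- rep(0:1, 40)
    for (keep in list(c(5, 9), c(1, 1), c(60, 60))) {
        m <- fitSplsda(x, y, nComponents = 2, keep = keep)
        expect_equal(colSums(m@weights != 0), keep)
        expect_equal(sqrt(colSums(m@weights^2)), c(1, 1), tolerance = 1e-10)
    }
})

test_that("a perfectly separating variable is the sole selection at keep = 1", {
    d <- separableDesign()
    m <- fitSplsda(d$x, d$y, nComponents = 1, keep = 1)
    expect_identical(selectedVariables(m)[[1]], "v01")
})

test_that("transform reproduces fitted scores and centers on column means", {
    d <- separableDesign(50, 12)
    m <- fitSplsda(d$x, d$y, nComponents = 2, keep = c(4, 4))
    sc <- predictScores(m, d$x)
    expect_equal(unname(sc), unname(m@scores), tolerance = 1e-8)
    # a sample at the training means projects to the origin
    mu <- matrix(m@columnMeans, 1,
                 dimnames = list("avg", m@variableNames))
    expect_equal(unname(predictScores(m, mu))[1, ], c(0, 0),
                 tolerance = 1e-10)
    # duplicated samples get duplicated coordinates; column order is free
    dup <- d$x[c(3, 3), ]
    scd <- predictScores(m, dup[, sample(ncol(dup))])
    expect_equal(scd[1, ], scd[2, ])
    expect_error(predictScores(m, d$x[, -1]), "lacks model variables")
})

test_that("component scores are orthogonal and scale-equivariant", {
    set.seed(23)
    x <- matrix(rnorm(70 * 25), 70, 25,
                dimnames = list(NULL, sprintf("v%02d", 1:25)))
    y <- rep(0:1, 35)
    m <- fitSplsda(x, y, nComponents = 2, keep = c(8, 8))
    expect_lt(abs(cor(m@scores[, 1], m@scores[, 2])), 1e-8)
    x2 <- x; x2[, 5] <- x2[, 5] * 13
    m2 <- fitSplsda(x2, y, nComponents = 2, keep = c(8, 8))
    expect_equal(predictScores(m2, x2), predictScores(m, x),
                 tolerance = 1e-8)
})

test_that("dense two-component fit agrees with an independent sparse PLS-DA", {
    d <- separableDesign(60, 30, seed = 24)
    d$x[d$y == 1, 2] <- d$x[d$y == 1, 2] + 4
    m <- fitSplsda(d$x, d$y, nComponents = 2, keep = c(5, 5))
    mo <- mixOmics::splsda(d$x, factor(d$y), ncomp = 2, keepX = c(5, 5))
    sel <- rownames(mo$loadings$X)[mo$loadings$X[, 1] != 0]
    expect_setequal(selectedVariables(m)[[1]], sel)
    # loading agreement up to sign on component 1
    w <- m@weights[, 1]
    v <- mo$loadings$X[names(w), 1]
    expect_gte(abs(sum(w * v) / sqrt(sum(w^2) * sum(v^2))), 0.99)
})

test_that("variable importance follows the weighted-loading formula", {
    d <- separableDesign(50, 10)
    m <- fitSplsda(d$x, d$y, nComponents = 2, keep = c(3, 3))
    imp <- variableImportance(m, keepZero = TRUE)
    want <- drop(abs(m@weights) %*% m@explainedVariance)
    expect_equal(imp$importance[match(m@variableNames, imp$variable)],
                 unname(want))
    expect_identical(imp$rank, seq_len(nrow(imp)))
    # zero-loading variables have zero importance
    zero <- setdiff(m@variableNames, unique(unlist(selectedVariables(m))))
    expect_true(all(imp$importance[imp$variable %in% zero] == 0))
    # single component: ranking equals ranking by |loading|
    m1 <- fitSplsda(d$x, d$y, nComponents = 1, keep = 5)
    imp1 <- variableImportance(m1)
    expect_identical(imp1$variable[1],
                     m1@variableNames[which.max(abs(m1@weights[, 1]))])
})

test_that("a dominant planted covariate ranks first in importance", {
    sim <- simulateCohort(quickConfig(seed = 81, smokingCaseOddsRatio = 12,
                                      deltaBeta = 0.04))
    pipe <- trainRiskPipeline(sim$beta, kTopRange = 30, keep = 15)
    imp <- variableImportance(pipe$riskModel@splsda)
    expect_identical(imp$variable[1], "smoking_score")
})

test_that("zero-variance columns are dropped with a warning", {
    d <- separableDesign(40, 8)
    d$x[, 4] <- 1
    expect_warning(m <- fitSplsda(d$x, d$y, nComponents = 1, keep = 3),
                   "zero-variance")
    expect_false("v04" %in% m@variableNames)
})

test_that("cross-validated AUROC behaves at the null and separable limits", {
    set.seed(25)
    xn <- matrix(rnorm(400 * 40), 400, 40,
                 dimnames = list(NULL, sprintf("n%02d", 1:40)))
    yn <- rep(0:1, each = 200)
    cvNull <- cvAuroc(xn, yn, nComponents = 2, keep = 10, seed = 9)
    expect_gte(cvNull$mean_auroc, 0.4)
    expect_lte(cvNull$mean_auroc, 0.6)
    d <- separableDesign(100, 10)
    cvSep <- cvAuroc(d$x, d$y, nComponents = 2, keep = 3, seed = 9,
                     kFolds = 5)
    expect_gte(cvSep$mean_auroc, 0.99)
    # determinism: same seed, same folds, same numbers
    cv2 <- cvAuroc(d$x, d$y, nComponents = 2, keep = 3, seed = 9,
                   kFolds = 5)
    expect_identical(cvSep$fold_aurocs, cv2$fold_aurocs)
})

test_that("permuted labels change selection and give chance-level CV AUROC", {
    sim <- simulateCohort(quickConfig(seed = 91, nCases = 100L,
                                      nControls = 100L))
    design <- buildDesign(sim$beta, local({
        ann <- probeAnnotation(sim$beta)
        rmx <- averageCorsiv(sim$beta)
        featureSpec(rownames(rmx), character(0), character(0))
    }))
    y <- simLabels(sim$truth)
    m <- fitSplsda(design$x, y, nComponents = 2, keep = 10)
    set.seed(1)
    yp <- sample(y)
    mp <- fitSplsda(design$x, yp, nComponents = 2, keep = 10)
    expect_false(setequal(selectedVariables(m)[[1]],
                          selectedVariables(mp)[[1]]))
    cvp <- cvAuroc(design$x, yp, nComponents = 2, keep = 10, seed = 3,
                   kFolds = 5)
    expect_gte(cvp$mean_auroc, 0.35)
    expect_lte(cvp$mean_auroc, 0.65)
})
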