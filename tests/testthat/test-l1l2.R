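test_that("soft thresholding follows its closed form", {
    expect_equal(softThreshold(3, 1), 2)
    expect_equal(softThreshold(-0.5, 1), 0)
    z <- rnorm(20)
    expect_equal(softThreshold(z, 0), z)
    expect_equal(softThreshold(c(-3, 3), 1.5), c(-1.5, 1.5))
    expect_error(softThreshold(1, -1), ">= 0")
})

test_that("the full-shrinkage bound returns the zero vector", {
    set.seed(1)
    X <- scale(matrix(rnorm(8 * 6), 8, 6))
    y <- rep(c(-1, 1), each = 4)
    tauMax <- 2 * max(abs(crossprod(X, y))) / nrow(X)
    beta <- l1l2Solve(X, y, tau = tauMax * 1.0001, mu = 0)
    expect_identical(unname(beta), rep(0, 6))
})

test_that("orthonormal designs recover the soft-thresholded OLS solution", {
    set.seed(2)
    X <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    y <- rnorm(4)
    tau <- 0.2
    beta <- l1l2Solve(X, y, tau, mu = 0, tol = 1e-12, maxIter = 50000)
    closed <- softThreshold(drop(crossprod(X, y)), nrow(X) * tau / 2)
    expect_lt(max(abs(beta - closed)), 1e-8)
})

test_that("the solver objective matches a refined lattice search", {
    set.seed(3)
    X <- matrix(rnorm(30), 6, 5)
    y <- rnorm(6)
    beta <- l1l2Solve(X, y, tau = 0.3, mu = 0.1, tol = 1e-10, maxIter = 50000)
    lat <- latticeMin(X, y, 0.3, 0.1, unname(beta))
    expect_lte(l1l2Objective(X, y, unname(beta), 0.3, 0.1),
               lat$objective + 1e-6)
})

test_that("the objective trace is non-increasing at every iteration", {
    set.seed(4)
    X <- matrix(rnorm(200), 10, 20)
    y <- rep(c(-1, 1), 5)
    beta <- l1l2Solve(X, y, tau = 0.05, mu = 0.02, trace = TRUE)
    obj <- attr(beta, "objective")
    expect_gt(length(obj), 2)
    expect_true(all(diff(obj) <= 1e-12))
})

test_that("non-convergence raises a classed condition carrying the iterate", {
    set.seed(5)
    X <- matrix(rnorm(60), 6, 10)
    y <- rnorm(6)
    err <- tryCatch(l1l2Solve(X, y, tau = 1e-4, mu = 0, maxIter = 2),
                    l1l2ConvergenceError = function(e) e)
    expect_s3_class(err, "l1l2ConvergenceError")
    expect_length(err$beta, 10)
})

test_that("the solver agrees with an independent elastic-net implementation", {
    skip_if_not_installed("glmnet")
    set.seed(6)
    X <- matrix(rnorm(400), 40, 10)
    y <- rnorm(40)
    tau <- 0.3; mu <- 0.1
    beta <- l1l2Solve(X, y, tau, mu, tol = 1e-10, maxIter = 1e5)
    lam <- tau / 2 + mu
    g <- glmnet::glmnet(X, y, alpha = (tau / 2) / lam, lambda = lam,
                        standardize = FALSE, intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(beta - as.numeric(g$beta))), 1e-3)
})

test_that("ridge de-biasing matches the normal equations and its limits", {
    set.seed(7)
    X <- matrix(rnorm(24), 8, 3)
    y <- rnorm(8)
    ## lambda = 0, full rank: OLS
    expect_equal(unname(debiasRls(X, y, 1:3, ridgeLambda = 0)),
                 unname(coef(lm.fit(X, y))), tolerance = 1e-10)
    ## direct normal-equations oracle
    lam <- 0.37
    oracle <- solve(crossprod(X) + lam * diag(3), crossprod(X, y))
    expect_lt(max(abs(debiasRls(X, y, 1:3, lam) - oracle)), 1e-10)
    ## lambda -> Inf drives coefficients to zero
    expect_lt(max(abs(debiasRls(X, y, 1:3, 1e9))), 1e-6)
    ## dual form (support > n) equals the primal normal equations
    set.seed(8)
    Xw <- matrix(rnorm(5 * 12), 5, 12)
    oracle2 <- solve(crossprod(Xw) + 0.1 * diag(12), crossprod(Xw, y[1:5]))
    expect_lt(max(abs(debiasRls(Xw, y[1:5], 1:12, 0.1) - oracle2)), 1e-8)
    expect_error(debiasRls(X, y, integer(0)), "empty support")
})

test_that("inner LOO picks a zero-error tau on separable data and honors the grid", {
    sim <- tinyPlanted(seed = 1)
    ds <- labeledDataset(log2Transform(normalizeChain(sim$expr)), sim$design)
    sel <- selectTauLoocv(ds$X, ds$y)
    expect_equal(min(sel$errorCurve), 0)
    expect_equal(sel$errorCurve[which(sel$tauGrid == sel$fractionStar)], 0)
    ## a one-point grid is returned as-is
    one <- suppressWarnings(
        selectTauLoocv(ds$X, ds$y, l1l2Control(tauGrid = 0.05)))
    expect_equal(one$tauStar, 0.05)
})

test_that("permuted labels push the inner error to chance", {
    sim <- tinyPlanted(seed = 2)
    ds <- labeledDataset(log2Transform(normalizeChain(sim$expr)), sim$design)
    set.seed(99)
    errs <- replicate(15, {
        yp <- sample(ds$y)
        sel <- suppressWarnings(selectTauLoocv(ds$X, yp))
        min(sel$errorCurve)
    })
    ## chance is 0.5; minimizing over the grid biases downward, so allow a
    ## generous Monte-Carlo band -- the point is the contrast with the
    ## separable case's exact 0
    expect_gt(mean(errs), 0.2)
    expect_lt(mean(errs), 0.75)
})

test_that("a perfectly discriminative feature is selected in every outer loop", {
    set.seed(10)
    X <- cbind(f1 = c(-1, -1, 1, 1) + rnorm(4, 0, 0.01),
               f2 = rnorm(4))
    ds <- list(X = X, y = c(-1, -1, 1, 1), featureIds = c("f1", "f2"))
    tab <- suppressWarnings(outerLooSelection(ds))
    expect_identical(nLoops(tab), 4L)
    expect_identical(unname(freqCounts(tab)["f1"]), 4L)
    expect_equal(looError(tab), 0)
})

test_that("duplicated samples yield identical per-loop lists across the copies", {
    sim <- tinyPlanted(seed = 3)
    ds <- labeledDataset(log2Transform(normalizeChain(sim$expr)), sim$design)
    n <- nrow(ds$X)
    dup <- list(X = rbind(ds$X, ds$X), y = c(ds$y, ds$y),
                featureIds = ds$featureIds)
    tab <- suppressWarnings(outerLooSelection(dup))
    for (i in seq_len(n))
        expect_identical(loopLists(tab)[[i]], loopLists(tab)[[i + n]])
})

test_that("an outer loop never sees its held-out sample", {
    sim <- tinyPlanted(seed = 4)
    ds <- labeledDataset(log2Transform(normalizeChain(sim$expr)), sim$design)
    tab1 <- suppressWarnings(outerLooSelection(ds))
    poisoned <- ds
    poisoned$X[3, ] <- poisoned$X[3, ] + rnorm(ncol(ds$X), 0, 5)
    tab2 <- suppressWarnings(outerLooSelection(poisoned))
    expect_identical(loopLists(tab1)[[3]], loopLists(tab2)[[3]])
})

test_that("frequency thresholding follows the counts", {
    loops <- c(rep(list("a"), 11), rep(list(c("a", "b")), 10),
               list(c("a", "b", "c")))
    tab <- new("SelectionFrequencyTable",
               counts = c(a = 22L, b = 11L, c = 1L), L = 22L,
               looError = 0.1, loopLists = loops, tauStar = numeric(22))
    expect_identical(sigProbesets(frequencySignature(tab, 0.5)), c("a", "b"))
    expect_identical(sigProbesets(frequencySignature(tab, 1)), "a")
    expect_identical(sigProbesets(frequencySignature(tab, 1 / 22)),
                     c("a", "b", "c"))
    expect_warning(empty <- frequencySignature(
        new("SelectionFrequencyTable", counts = c(a = 1L), L = 22L,
            looError = 0, loopLists = c(list("a"), rep(list(character()), 21)),
            tauStar = numeric(22)), 0.5), "no feature")
    expect_length(sigProbesets(empty), 0)
})

test_that("larger epsilon admits more probesets on average", {
    sizes <- matrix(NA_real_, 10, 2)
    for (s in seq_len(10)) {
        sim <- simulateCellLinePairs(nLines = 5, nProbesets = 100,
                                     nResponsive = 12, seed = 100 + s)
        ds <- labeledDataset(log2Transform(normalizeChain(sim$expr)),
                             sim$design)
        for (k in 1:2) {
            eps <- c(1, 100)[k]
            tab <- suppressWarnings(outerLooSelection(
                ds, l1l2Control(epsilon = eps, tol = 1e-5, maxIter = 6000)))
            sizes[s, k] <- length(freqCounts(tab))
        }
    }
    expect_gte(mean(sizes[, 2]), mean(sizes[, 1]))
})

test_that("the incremental dual holdout scoring equals the primal re-fit route", {
    set.seed(20)
    n <- 8; p <- 30
    Xs <- hypoSig:::.standardize(matrix(rnorm(n * p), n, p))$X
    ytr <- rep(c(-1, 1), each = 4)
    betas <- sapply(1:6, function(k) {
        b <- numeric(p); b[sample(p, k * 4)] <- rnorm(k * 4); b
    })
    xte <- rnorm(p); lam <- 1e-3
    fast <- hypoSig:::.pathHoldoutErrors(betas, Xs, ytr, xte, 1, lam)
    maj <- hypoSig:::.majority(ytr)
    slow <- apply(betas, 2, function(b) {
        s <- which(b != 0)
        bs <- debiasRls(Xs, ytr, s, lam)
        hypoSig:::.predictClass(sum(xte[s] * bs), maj) != 1
    })
    expect_identical(fast, unname(slow))
})

test_that("constant probesets are dropped before selection", {
    sim <- tinyPlanted(seed = 5)
    e <- log2Transform(normalizeChain(sim$expr))
    v <- exprValues(e)
    v[1, ] <- 3
    flat <- ProbesetExperiment(v, "log2")
    expect_warning(ds <- labeledDataset(flat, sim$design), "constant")
    expect_false(rownames(v)[1] %in% ds$featureIds)
})
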