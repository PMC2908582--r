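#' @useDynLib hypoSig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Soft-thresholding operator
#'
#' The proximal operator of the l1 penalty:
#' `sign(z) * max(|z| - lam, 0)`, applied elementwise.
#'
#' @param z numeric vector.
#' @param lam threshold, `>= 0`.
#' @return numeric vector of the same length.
#' @export
softThreshold <- function(z, lam) {
    if (any(lam < 0)) stop("lam must be >= 0")
    sign(z) * pmax(abs(z) - lam, 0)
}

#' Tuning parameters for l1-l2 selection
#'
#' `epsilon` is the correlation parameter: the l2 weight is
#' `mu = epsilon * mu0` with the data-driven baseline
#' `mu0 = mu0Scale * sigma_max`, `sigma_max` being the largest squared
#' singular value of `X / sqrt(n)` of the (standardized) training design.
#' Larger `epsilon` admits more correlated features into the selected
#' support. The tau grid spans `nTau` log-spaced values from
#' `tau_max = 2 ||X'y||_inf / n` (the full-shrinkage bound) down to
#' `tauMinRatio * tau_max`. By default the grid is relative: the log-spaced
#' fractions of `tau_max` are fixed and `tau_max` is recomputed on every
#' training set (each cross-validation fold included), so a grid position
#' describes the same model complexity on every fold and the top of the grid
#' is always the empty (majority-class) model. Supplying an explicit
#' `tauGrid` switches to that absolute grid, shared across folds.
#'
#' @param epsilon l2 multiplier (default 100, the correlation-aware setting).
#' @param nTau,tauMinRatio tau grid geometry.
#' @param tauGrid optional explicit descending grid of positive absolute tau
#'   values.
#' @param mu0Scale scale of the data-driven l2 baseline.
#' @param ridgeLambda ridge weight of the de-biasing (second optimization)
#'   stage.
#' @param tol,maxIter ISTA stopping rule: converged when the max absolute
#'   coefficient change falls below `tol * max(1, ||beta||_inf)`.
#' @param frequencyThreshold default selection-frequency cutoff used by
#'   [frequencySignature()].
#' @return a list of class `l1l2Control`.
#' @export
l1l2Control <- function(epsilon = 100, nTau = 30, tauMinRatio = 1e-3,
                        tauGrid = NULL, mu0Scale = 1e-3, ridgeLambda = 1e-3,
                        tol = 1e-6, maxIter = 3000,
                        frequencyThreshold = 0.5) {
    if (epsilon < 0) stop("epsilon must be >= 0")
    if (!is.null(tauGrid)) {
        if (!length(tauGrid) || any(tauGrid <= 0) ||
            is.unsorted(rev(tauGrid), strictly = FALSE))
            stop("tauGrid must be a non-empty descending grid of positive values")
    }
    if (tol <= 0 || maxIter < 1) stop("tol and maxIter must be positive")
    if (frequencyThreshold <= 0 || frequencyThreshold > 1)
        stop("frequencyThreshold must lie in (0, 1]")
    structure(list(epsilon = epsilon, nTau = nTau, tauMinRatio = tauMinRatio,
                   tauGrid = tauGrid, mu0Scale = mu0Scale,
                   ridgeLambda = ridgeLambda, tol = tol, maxIter = maxIter,
                   frequencyThreshold = frequencyThreshold),
              class = "l1l2Control")
}

## centre each column and scale it to unit l2 norm; fold-constant columns get
## a unit norm so they map to all-zero columns and can never be selected
.standardize <- function(X, center = NULL, norms = NULL) {
    if (is.null(center)) center <- colMeans(X)
    Xc <- sweep(X, 2L, center, "-")
    if (is.null(norms)) {
        norms <- sqrt(colSums(Xc^2))
        norms[norms < .Machine$double.eps] <- 1
    }
    list(X = sweep(Xc, 2L, norms, "/"), center = center, norms = norms)
}

## largest squared singular value of X/sqrt(n), via the smaller Gram matrix
.sigmaMax <- function(X) {
    n <- nrow(X)
    G <- if (n <= ncol(X)) tcrossprod(X) else crossprod(X)
    max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) / n
}

.tauMax <- function(Xs, y) {
    tm <- 2 * max(abs(crossprod(Xs, y))) / nrow(Xs)
    if (tm <= 0) stop("degenerate design: X'y is identically zero")
    tm
}

.tauFractions <- function(nTau, minRatio) {
    if (nTau == 1L) return(1)
    exp(seq(0, log(minRatio), length.out = nTau))
}

#' Solve one l1-l2 regularization problem
#'
#' Minimizes `(1/n) ||y - X beta||^2 + tau ||beta||_1 + mu ||beta||_2^2`
#' by damped iterative soft-thresholding (thresholded Landweber iteration
#' with step `1/sigma_max` and the l2 term absorbed exactly into the
#' proximal step). The objective is non-increasing across iterations. `X` is
#' used as given; standardize beforehand if required (the cross-validation
#' drivers standardize within every training fold).
#'
#' @param X design matrix, n x p.
#' @param y response (class labels coded -1/+1 for selection).
#' @param tau l1 weight, `> 0`.
#' @param mu l2 weight, `>= 0`.
#' @param tol,maxIter stopping rule (see [l1l2Control()]).
#' @param beta0 optional warm start.
#' @param trace if `TRUE`, attach the per-iteration objective values as
#'   attribute `"objective"`.
#' @return named coefficient vector; non-convergence raises a condition of
#'   class `l1l2ConvergenceError` carrying the last iterate in its `beta`
#'   field.
#' @export
l1l2Solve <- function(X, y, tau, mu = 0, tol = 1e-6, maxIter = 3000,
                      beta0 = NULL, trace = FALSE) {
    if (tau <= 0) stop("tau must be > 0")
    if (mu < 0) stop("mu must be >= 0")
    X <- as.matrix(X)
    if (is.null(beta0)) beta0 <- numeric(ncol(X))
    sigma <- .sigmaMax(X)
    fit <- .ista_solve_cpp(X, y, tau, mu, sigma, tol, as.integer(maxIter),
                           beta0, trace)
    beta <- as.numeric(fit$beta)
    names(beta) <- colnames(X)
    if (!fit$converged) {
        cond <- structure(
            class = c("l1l2ConvergenceError", "error", "condition"),
            list(message = sprintf(
                     "l1-l2 solver did not reach tol = %g within %d iterations",
                     tol, maxIter),
                 call = sys.call(-1), beta = beta))
        stop(cond)
    }
    if (trace) attr(beta, "objective") <- fit$objective
    beta
}

#' Ridge (regularized least squares) re-fit on a selected support
#'
#' The second stage of the double optimization: having selected a support,
#' the prediction weights are re-estimated by ridge regression restricted to
#' the support columns (ordinary least squares when `ridgeLambda = 0` and the
#' restricted design has full rank). The support itself is never changed.
#' When the support is larger than the sample count the equivalent dual
#' (kernel) form is solved so the linear system stays n x n.
#'
#' @param X design matrix (same column space the support indexes into).
#' @param y response.
#' @param support integer or character index of the selected columns;
#'   must be non-empty.
#' @param ridgeLambda ridge weight `>= 0`.
#' @return named coefficient vector over the support columns.
#' @export
debiasRls <- function(X, y, support, ridgeLambda = 1e-3) {
    if (!length(support)) stop("empty support: nothing to de-bias")
    if (ridgeLambda < 0) stop("ridgeLambda must be >= 0")
    Z <- X[, support, drop = FALSE]
    s <- ncol(Z)
    n <- nrow(Z)
    if (s <= n) {
        A <- crossprod(Z)
        diag(A) <- diag(A) + ridgeLambda
        beta <- drop(solve(A, crossprod(Z, y)))
    } else {
        K <- tcrossprod(Z)
        diag(K) <- diag(K) + ridgeLambda
        beta <- drop(crossprod(Z, solve(K, y)))
    }
    names(beta) <- colnames(Z)
    beta
}

.predictClass <- function(score, majority) {
    ifelse(score == 0, majority, sign(score))
}

.majority <- function(y) if (sum(y > 0) * 2L >= length(y)) 1 else -1

## error of the de-biased classifier for every tau of a fitted path,
## evaluated on one held-out (already fold-standardized) sample. The ridge
## re-fit is evaluated in its dual form, x'beta = (Z_s x_s)' (Z_s Z_s' +
## lambda I)^{-1} y, with the support Gram matrix and the test kernel vector
## updated incrementally along the (largely nested) path, so the cost per
## tau is one n x n solve regardless of the support size.
.pathHoldoutErrors <- function(betas, Xs, ytr, xte, yte, ridgeLambda) {
    maj <- .majority(ytr)
    if (ridgeLambda <= 0) {            # dual form needs lambda > 0
        T <- ncol(betas)
        errs <- logical(T)
        for (k in seq_len(T)) {
            s <- which(betas[, k] != 0)
            pred <- if (!length(s)) maj else {
                bs <- debiasRls(Xs, ytr, s, ridgeLambda)
                .predictClass(sum(xte[s] * bs), maj)
            }
            errs[k] <- pred != yte
        }
        return(errs)
    }
    as.logical(.path_holdout_cpp(betas, Xs, ytr, xte, yte, ridgeLambda, maj))
}

#' Inner leave-one-out selection of the l1 weight tau
#'
#' For every position of the tau grid the de-biased classifier
#' `sign(x . beta_debiased)` is scored by leave-one-out within the given
#' training set; standardization, tau scale, l2 weight, solution path and
#' ridge re-fit are all redone inside every inner fold, so no held-out
#' information leaks into any fit. `tauStar` minimizes the inner error
#' curve, ties broken towards the largest tau (the sparsest model; the top
#' of the relative grid is the empty, majority-class model). The returned
#' `tauStar` lives on the scale of the full training set handed in, ready
#' for the final fit on it.
#'
#' @param X raw (unstandardized) training design, n x p with n >= 3 (so the
#'   outer loops can hand in their n - 1 remaining samples down to n = 4).
#' @param y class labels in \{-1, +1\}, both classes present.
#' @param control an [l1l2Control()] list.
#' @return list with `tauStar`, `fractionStar` (position as a fraction of
#'   `tau_max`), `errorCurve`, `tauGrid` (fractions, or the absolute grid if
#'   one was supplied) and `mu` (the l2 weight on the full training set).
#' @export
selectTauLoocv <- function(X, y, control = l1l2Control()) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (n < 3L) stop("need at least 3 samples")
    if (length(unique(sign(y))) < 2L) stop("both classes must be present")
    absolute <- !is.null(control$tauGrid)
    grid <- if (absolute) control$tauGrid
            else .tauFractions(control$nTau, control$tauMinRatio)
    errs <- matrix(NA, n, length(grid))
    for (i in seq_len(n)) {
        str <- .standardize(X[-i, , drop = FALSE])
        ytr <- y[-i]
        sigma <- .sigmaMax(str$X)
        mu <- control$epsilon * control$mu0Scale * sigma
        taus <- if (absolute) grid else grid * .tauMax(str$X, ytr)
        path <- .ista_path_cpp(str$X, ytr, taus, mu, sigma,
                               control$tol, as.integer(control$maxIter))
        xte <- (X[i, ] - str$center) / str$norms
        errs[i, ] <- .pathHoldoutErrors(path$beta, str$X, ytr, xte, y[i],
                                        control$ridgeLambda)
    }
    curve <- colMeans(errs)
    if (length(unique(curve)) == 1L)
        warning("inner LOO errors are identical across the tau grid; ",
                "returning the largest (sparsest) tau")
    kStar <- which.min(curve)
    sFull <- .standardize(X)
    mu <- control$epsilon * control$mu0Scale * .sigmaMax(sFull$X)
    tauMaxFull <- .tauMax(sFull$X, y)
    tauStar <- if (absolute) grid[kStar] else grid[kStar] * tauMaxFull
    list(tauStar = tauStar,
         fractionStar = if (absolute) grid[kStar] / tauMaxFull else grid[kStar],
         errorCurve = curve, tauGrid = grid, mu = mu)
}

#' Build a labeled dataset from a paired design
#'
#' Rows are samples (all normoxic arrays, then all hypoxic arrays, in design
#' order), columns are probesets; labels code hypoxic as `+1` and normoxic as
#' `-1`. Probesets constant across all samples are dropped with a warning
#' (they cannot survive per-fold standardization).
#'
#' @param expr a log2-scale [ProbesetExperiment-class].
#' @param design a [PairedDesign-class] whose samples exist in `expr`.
#' @return list of class `LabeledDataset` with `X`, `y`, `featureIds`.
#' @export
labeledDataset <- function(expr, design) {
    if (exprScale(expr) != "log2")
        stop("labeledDataset() expects log2-scale expression; see log2Transform()")
    validatePairing(expr, design)
    e <- designEntries(design)
    samples <- c(e$normoxic, e$hypoxic)
    X <- t(exprValues(expr))[samples, , drop = FALSE]
    y <- rep(c(-1, 1), each = nrow(e))
    const <- apply(X, 2L, function(v) max(v) - min(v) < .Machine$double.eps)
    if (any(const)) {
        warning(sum(const), " constant probeset(s) dropped before selection")
        X <- X[, !const, drop = FALSE]
    }
    structure(list(X = X, y = y, featureIds = colnames(X)),
              class = "LabeledDataset")
}

#' Outer leave-one-out loops: selection frequency and predictive error
#'
#' Runs `L = n` outer loops. Loop `i` holds sample `i` out completely:
#' the tau grid, the l2 weight, the feature standardization, the inner
#' leave-one-out tau selection and the final l1-l2 + ridge fit are all
#' computed on the remaining `n - 1` samples only (with the default relative
#' grid even the tau values themselves are re-derived per loop); the
#' held-out sample is then predicted by the de-biased classifier. The
#' per-loop selected supports
#' are aggregated into a selection-frequency table ("common list" = union of
#' the `L` lists), and the fraction of misclassified held-out samples is the
#' outer leave-one-out error.
#'
#' @param dataset a `LabeledDataset` from [labeledDataset()], or any list
#'   with elements `X` (n x p matrix), `y` (-1/+1), `featureIds`.
#' @param control an [l1l2Control()] list.
#' @return a [SelectionFrequencyTable-class].
#' @export
outerLooSelection <- function(dataset, control = l1l2Control()) {
    X <- as.matrix(dataset$X)
    y <- dataset$y
    ids <- dataset$featureIds
    if (is.null(ids)) ids <- colnames(X)
    colnames(X) <- ids
    n <- nrow(X)
    if (n < 4L) stop("need at least 4 samples")
    loopLists <- vector("list", n)
    tauStar <- numeric(n)
    wrong <- logical(n)
    for (i in seq_len(n)) {
        Xtr <- X[-i, , drop = FALSE]
        ytr <- y[-i]
        inner <- selectTauLoocv(Xtr, ytr, control)
        str <- .standardize(Xtr)
        beta <- tryCatch(
            l1l2Solve(str$X, ytr, inner$tauStar, inner$mu,
                      tol = control$tol, maxIter = control$maxIter),
            l1l2ConvergenceError = function(e)
                stop("outer loop ", i, ": ", conditionMessage(e), call. = FALSE))
        sel <- which(beta != 0)
        loopLists[[i]] <- ids[sel]
        tauStar[i] <- inner$tauStar
        xte <- (X[i, ] - str$center) / str$norms
        maj <- .majority(ytr)
        pred <- if (!length(sel)) maj else {
            bs <- debiasRls(str$X, ytr, sel, control$ridgeLambda)
            .predictClass(sum(xte[sel] * bs), maj)
        }
        wrong[i] <- pred != y[i]
    }
    counts <- table(unlist(loopLists, use.names = FALSE))
    counts <- stats::setNames(as.integer(counts), names(counts))
    new("SelectionFrequencyTable", counts = counts, L = n,
        looError = mean(wrong), loopLists = loopLists, tauStar = tauStar)
}

#' Threshold a selection-frequency table into a signature
#'
#' Keeps the features selected in at least `threshold * L` of the outer
#' loops, ordered by descending count and then by feature id.
#'
#' @param freqTable a [SelectionFrequencyTable-class].
#' @param threshold selection-frequency cutoff in (0, 1].
#' @param name name for the resulting signature.
#' @return a [GeneSignature-class] (empty, with a warning, when nothing
#'   reaches the threshold).
#' @export
frequencySignature <- function(freqTable, threshold = 0.5,
                               name = "l1l2-frequency") {
    if (threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]")
    cnt <- freqCounts(freqTable)
    keep <- cnt[cnt / nLoops(freqTable) >= threshold]
    if (!length(keep)) {
        warning("no feature reaches the frequency threshold; empty signature")
        return(GeneSignature(name, character()))
    }
    ord <- order(-keep, names(keep))
    GeneSignature(name, names(keep)[ord])
}

#' Export a selection-frequency table as TSV
#'
#' Columns `feature`, `count`, `L`, descending by count.
#'
#' @param freqTable a [SelectionFrequencyTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFrequencyTable <- function(freqTable, path) {
    cnt <- sort(freqCounts(freqTable), decreasing = TRUE)
    utils::write.table(
        data.frame(feature = names(cnt), count = as.integer(cnt),
                   L = nLoops(freqTable)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
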