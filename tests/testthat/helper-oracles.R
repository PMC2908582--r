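## Independent oracles and small fixture builders used across the suite.
## Each oracle re-derives the quantity from its definition, without touching
## the package's implementation path.

## the three normalization steps, written out naively
naiveNormalizeChain <- function(v, target = 500) {
    for (j in seq_len(ncol(v))) v[, j] <- v[, j] * target / mean(v[, j])
    for (j in seq_len(ncol(v))) v[, j] <- v[, j] / stats::median(v[, j])
    for (i in seq_len(nrow(v))) v[i, ] <- v[i, ] / stats::median(v[i, ])
    v
}

## Benjamini-Hochberg by the literal step-up definition
bhStepUp <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    adj <- numeric(n)
    for (k in seq_len(n)) adj[k] <- min(1, min(q[k:n]))
    out <- numeric(n)
    out[o] <- adj
    out
}

## misclassification distance by explicit enumeration of label pairings
bruteMisclass <- function(a, b) {
    perms <- list(c(1, 2), c(2, 1))
    min(vapply(perms, function(pm) mean(a != pm[b]), numeric(1)))
}

## global minimum within-cluster SS over every 2-partition (both non-empty)
exhaustiveKmeansWss <- function(M) {
    n <- nrow(M)
    best <- Inf
    for (code in seq_len(2^(n - 1) - 1)) {
        lab <- as.integer(intToBits(code))[seq_len(n)]
        wss <- 0
        for (g in 0:1) {
            rows <- M[lab == g, , drop = FALSE]
            ctr <- colMeans(rows)
            wss <- wss + sum(sweep(rows, 2, ctr)^2)
        }
        if (wss < best) best <- wss
    }
    best
}

## naive O(n^3) complete-linkage agglomeration; returns merge heights and the
## member sets created by each merge
naiveCompleteLinkage <- function(rows) {
    n <- nrow(rows)
    D <- as.matrix(stats::dist(rows))
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    merges <- list()
    while (length(clusters) > 1L) {
        best <- c(Inf, NA, NA)
        for (i in seq_len(length(clusters) - 1L))
            for (j in (i + 1):length(clusters)) {
                h <- max(D[clusters[[i]], clusters[[j]]])
                if (h < best[1]) best <- c(h, i, j)
            }
        i <- best[2]; j <- best[3]
        merged <- sort(c(clusters[[i]], clusters[[j]]))
        heights <- c(heights, best[1])
        merges <- c(merges, list(merged))
        clusters[[j]] <- NULL
        clusters[[i]] <- merged
    }
    list(heights = heights, merges = merges)
}

## member sets created by each merge of an hclust tree
hclustMerges <- function(hc) {
    sets <- vector("list", nrow(hc$merge))
    for (k in seq_len(nrow(hc$merge))) {
        members <- unlist(lapply(hc$merge[k, ], function(m)
            if (m < 0) -m else sets[[m]]))
        sets[[k]] <- sort(members)
    }
    sets
}

## Cox log partial likelihood for a single covariate, no ties, coded from
## the definition (risk-set sums only)
coxLoglik1d <- function(beta, z, times, events) {
    ll <- 0
    for (i in which(events == 1)) {
        risk <- which(times >= times[i])
        ll <- ll + z[i] * beta - log(sum(exp(z[risk] * beta)))
    }
    ll
}

## lattice search for the l1-l2 objective minimum: a coarse box around the
## candidate refined repeatedly (valid because the objective is convex)
l1l2Objective <- function(X, y, b, tau, mu) {
    sum((y - X %*% b)^2) / nrow(X) + tau * sum(abs(b)) + mu * sum(b^2)
}

latticeMin <- function(X, y, tau, mu, center, halfwidth = 1, npts = 5,
                       passes = 12) {
    p <- length(center)
    best <- center
    bestObj <- l1l2Objective(X, y, best, tau, mu)
    for (pass in seq_len(passes)) {
        grid <- lapply(seq_len(p), function(j)
            seq(best[j] - halfwidth, best[j] + halfwidth, length.out = npts))
        combos <- as.matrix(expand.grid(grid))
        for (r in seq_len(nrow(combos))) {
            obj <- l1l2Objective(X, y, combos[r, ], tau, mu)
            if (obj < bestObj) {
                bestObj <- obj
                best <- combos[r, ]
            }
        }
        halfwidth <- halfwidth / 2
    }
    list(beta = best, objective = bestObj)
}

## small helpers -------------------------------------------------------------

randomExpr <- function(nProbesets, nSamples, seed = 1, mean = 8, sd = 1.5) {
    set.seed(seed)
    v <- matrix(2^rnorm(nProbesets * nSamples, mean, sd), nProbesets, nSamples,
                dimnames = list(sprintf("P%04d", seq_len(nProbesets)),
                                sprintf("S%03d", seq_len(nSamples))))
    ProbesetExperiment(v, scale = "linear")
}

## a small, clearly separable paired dataset for the selection unit tests
tinyPlanted <- function(nLines = 6, nProbesets = 60, nResponsive = 8,
                        effect = 2, noise = 0.3, seed = 1) {
    simulateCellLinePairs(nLines = nLines, nProbesets = nProbesets,
                          nResponsive = nResponsive, effectLog2 = effect,
                          lineSd = 0.1, noiseSd = noise, seed = seed)
}
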