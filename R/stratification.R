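#' Two-group k-means clustering with random restarts
#'
#' Lloyd's algorithm with euclidean distance, `k = 2`, run to convergence
#' from `restarts` random initializations; the solution with the smallest
#' total within-cluster sum of squares is kept. Deterministic under `seed`.
#'
#' @param M samples x features numeric matrix (row names = sample ids).
#' @param restarts number of random restarts.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a [ClusterAssignment-class].
#' @export
kmeans2 <- function(M, restarts = 100, seed = NULL) {
    M <- as.matrix(M)
    if (nrow(M) < 2L) stop("need at least 2 samples")
    if (is.null(rownames(M))) rownames(M) <- paste0("sample", seq_len(nrow(M)))
    if (all(abs(sweep(M, 2L, M[1L, ], "-")) < .Machine$double.eps))
        stop("degenerate input: all points are identical")
    ## fast path: restarts handled inside stats::kmeans; if a restart dies on
    ## a degenerate initialization (coincident sampled centers -> empty
    ## cluster), fall back to managing the restarts ourselves and skipping
    ## the failing ones
    run <- function() {
        tryCatch(stats::kmeans(M, centers = 2L, nstart = restarts,
                               iter.max = 100L, algorithm = "Lloyd"),
                 error = function(e) .kmeansManualRestarts(M, restarts))
    }
    km <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    new("ClusterAssignment",
        cluster = stats::setNames(as.integer(km$cluster), rownames(M)),
        wss = sum(km$withinss), prognosis = character())
}

.kmeansManualRestarts <- function(M, restarts) {
    best <- NULL
    for (r in seq_len(restarts)) {
        idx <- sample.int(nrow(M), 2L)
        if (all(M[idx[1L], ] == M[idx[2L], ])) next
        km <- tryCatch(stats::kmeans(M, centers = M[idx, , drop = FALSE],
                                     iter.max = 100L, algorithm = "Lloyd"),
                       error = function(e) NULL)
        if (is.null(km)) next
        if (is.null(best) || sum(km$withinss) < sum(best$withinss)) best <- km
    }
    if (is.null(best)) stop("k-means failed on every restart")
    best
}

#' Label clusters as poor / good prognosis
#'
#' The cluster with the greater mean signature expression is the hypoxic,
#' poor-prognosis one; the other is labeled good. An exact tie is a
#' measure-zero degeneracy and raises an error.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param sigExpr samples x signature-features matrix the clustering was run
#'   on (same sample ids).
#' @return the assignment with its prognosis labels filled in.
#' @export
labelPrognosis <- function(assignment, sigExpr) {
    cl <- clusterLabels(assignment)
    sigExpr <- as.matrix(sigExpr)
    if (!all(names(cl) %in% rownames(sigExpr)))
        stop("sigExpr must cover all clustered samples")
    m <- vapply(1:2, function(k)
        mean(sigExpr[names(cl)[cl == k], , drop = FALSE]), numeric(1))
    if (m[1] == m[2])
        stop("exact tie in cluster mean expression; re-run with another seed")
    prog <- if (m[1] > m[2]) c("poor", "good") else c("good", "poor")
    methods::initialize(assignment, prognosis = prog)
}

#' Misclassification distance between two 2-group labelings
#'
#' The minimum, over the two possible cluster-label pairings, of the
#' disagreement fraction; `0` iff the labelings are identical up to
#' relabeling, at most `0.5` for two clusters.
#'
#' @param a,b [ClusterAssignment-class] objects, or named/plain vectors of
#'   labels in \{1, 2\}, over the same samples.
#' @return numeric in \[0, 0.5\].
#' @export
misclassificationDistance <- function(a, b) {
    a <- if (is(a, "ClusterAssignment")) clusterLabels(a) else a
    b <- if (is(b, "ClusterAssignment")) clusterLabels(b) else b
    if (!is.null(names(a)) && !is.null(names(b))) {
        if (!setequal(names(a), names(b)))
            stop("labelings cover different sample sets")
        b <- b[names(a)]
    } else if (length(a) != length(b)) {
        stop("labelings cover different sample sets")
    }
    d <- mean(a != b)
    min(d, 1 - d)
}

## exact chance-agreement baseline: expected misclassification distance
## between a fixed labeling with n1 cluster-1 members and an independent
## exchangeable labeling with m1 cluster-1 members (overlap hypergeometric)
.chanceDistance <- function(n, n1, m1) {
    k <- max(0L, n1 + m1 - n):min(n1, m1)
    pk <- stats::dhyper(k, m1, n - m1, n1)
    d <- (n1 + m1 - 2 * k) / n
    sum(pk * pmin(d, 1 - d))
}

#' Random-signature permutation test of clustering stability
#'
#' The reference labeling comes from [kmeans2()] on the signature's
#' expression; then, `nPerm` times, a random signature of the same size is
#' drawn uniformly without replacement from all probesets on the chip
#' (including the signature's own), the clustering is repeated, and the
#' misclassification distance to the reference labeling is recorded. Each
#' distance is compared with its exact chance-agreement expectation (the
#' expected distance between the reference labeling and an independent
#' exchangeable 2-labeling with the observed cluster proportions), and a
#' one-sample two-sided t-test of the differences against zero summarizes
#' whether random gene sets reproduce (or avoid) the signature clustering
#' beyond chance. A pure function of `(expr, sig, nPerm, restarts, seed)`.
#'
#' @param expr a [ProbesetExperiment-class] of the cohort (linear or log2).
#' @param sig a [GeneSignature-class]; its probesets must exist in `expr`.
#' @param nPerm number of random signatures (`>= 2`).
#' @param restarts k-means restarts per clustering.
#' @param seed integer seed.
#' @param scaleFeatures z-score each probeset across samples before
#'   clustering (as for the heatmap); on by default.
#' @return a [StabilityResult-class]; the reference assignment is attached
#'   as attribute `"reference"`.
#' @export
permutationStability <- function(expr, sig, nPerm = 300, restarts = 100,
                                 seed = 1, scaleFeatures = TRUE) {
    if (nPerm < 2L) stop("nPerm must be >= 2")
    probesets <- sigProbesets(sig)
    if (!length(probesets)) stop("empty signature")
    M <- .clusterMatrix(expr, scaleFeatures)
    if (!all(probesets %in% colnames(M)))
        stop("signature probesets missing from the matrix")
    if (length(probesets) > ncol(M))
        stop("signature larger than the chip")
    n <- nrow(M)
    withr::with_seed(seed, {
        ref <- kmeans2(M[, probesets, drop = FALSE], restarts = restarts)
        refLab <- clusterLabels(ref)
        n1 <- sum(refLab == 1L)
        distances <- numeric(nPerm)
        baseline <- numeric(nPerm)
        for (j in seq_len(nPerm)) {
            draw <- sample(colnames(M), length(probesets))
            perm <- kmeans2(M[, draw, drop = FALSE], restarts = restarts)
            distances[j] <- misclassificationDistance(ref, perm)
            m1 <- sum(clusterLabels(perm) == 1L)
            baseline[j] <- .chanceDistance(n, n1, m1)
        }
    })
    diffs <- distances - baseline
    if (stats::sd(diffs) < 1e-12 * max(1, abs(mean(diffs)))) {
        ## degenerate: every permutation lands at the same offset from chance
        ## (e.g. the reference clustering is reproduced exactly every time)
        tstat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
        pval <- if (mean(diffs) == 0) 1 else 0
    } else {
        tt <- stats::t.test(diffs)
        tstat <- unname(tt$statistic)
        pval <- tt$p.value
    }
    out <- new("StabilityResult", distances = distances, baseline = baseline,
               tStatistic = tstat, pValue = pval,
               nPerm = as.integer(nPerm))
    attr(out, "reference") <- ref
    out
}

## samples x probesets matrix on log2 scale, optionally z-scored per probeset
.clusterMatrix <- function(expr, scaleFeatures = TRUE) {
    v <- exprValues(expr)
    if (exprScale(expr) == "linear") v <- log2(v)
    M <- t(v)
    if (scaleFeatures) {
        M <- scale(M)
        M[, attr(M, "scaled:scale") == 0] <- 0  # flat probesets carry no signal
        attributes(M)[c("scaled:center", "scaled:scale")] <- NULL
    }
    M
}

#' Complete-linkage hierarchical clustering of probesets
#'
#' Agglomerative clustering on euclidean distances between the rows
#' (probesets), complete linkage, as used to order the heatmap rows.
#'
#' @param rows features x samples numeric matrix.
#' @return list with `order` (row ids in leaf order), `merge`, `height`
#'   (the merge tree) and the underlying `hclust` object.
#' @export
hclusterComplete <- function(rows) {
    rows <- as.matrix(rows)
    if (nrow(rows) < 2L) stop("need at least 2 rows")
    hc <- stats::hclust(stats::dist(rows, method = "euclidean"),
                        method = "complete")
    ids <- rownames(rows)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(rows)))
    list(order = ids[hc$order], merge = hc$merge, height = hc$height,
         hclust = hc)
}
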