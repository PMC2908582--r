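test_that("well-separated blobs split perfectly for any seed", {
    set.seed(1)
    M <- rbind(matrix(rnorm(20 * 3, 0, 1), 20, 3),
               matrix(rnorm(20 * 3, 10, 1), 20, 3))
    rownames(M) <- sprintf("s%02d", 1:40)
    for (seed in c(1, 7, 99)) {
        cl <- clusterLabels(kmeans2(M, seed = seed))
        expect_length(unique(cl[1:20]), 1L)
        expect_length(unique(cl[21:40]), 1L)
        expect_false(cl[1] == cl[40])
    }
    expect_error(kmeans2(matrix(1, 5, 2)), "identical")
})

test_that("duplicated rows are co-assigned in the retained optimum", {
    set.seed(2)
    M <- rbind(matrix(rnorm(10 * 2), 10, 2),
               matrix(rnorm(10 * 2, 6), 10, 2))
    M <- rbind(M, M[c(1, 15), ])  # exact duplicates
    rownames(M) <- sprintf("s%02d", seq_len(nrow(M)))
    cl <- clusterLabels(kmeans2(M, seed = 3))
    expect_identical(cl[["s21"]], cl[["s01"]])
    expect_identical(cl[["s22"]], cl[["s15"]])
})

test_that("100 restarts reach the exhaustive-partition optimum", {
    hits <- 0L
    for (seed in 1:40) {
        set.seed(seed)
        M <- matrix(rnorm(10 * 2), 10, 2)
        rownames(M) <- sprintf("s%02d", 1:10)
        a <- kmeans2(M, restarts = 100, seed = seed)
        if (a@wss <= exhaustiveKmeansWss(M) + 1e-8) hits <- hits + 1L
    }
    expect_gte(hits, 38L)
})

test_that("prognosis labeling picks the high-expression cluster as poor", {
    cl <- new("ClusterAssignment",
              cluster = setNames(c(1L, 1L, 2L, 2L), paste0("s", 1:4)),
              wss = 1, prognosis = character())
    M <- matrix(c(2, 2, 0.5, 0.5, 2, 2, 0.5, 0.5), 4, 2,
                dimnames = list(paste0("s", 1:4), c("f1", "f2")))
    lab <- labelPrognosis(cl, M)
    expect_identical(unname(prognosisLabels(lab)[c("s1", "s3")]),
                     c("poor", "good"))
    ## invariant under swapping cluster indices
    cl2 <- methods::initialize(cl, cluster = setNames(c(2L, 2L, 1L, 1L),
                                                      paste0("s", 1:4)))
    expect_identical(prognosisLabels(labelPrognosis(cl2, M)),
                     prognosisLabels(lab))
    ## exact tie errors
    expect_error(labelPrognosis(cl, matrix(1, 4, 2,
        dimnames = list(paste0("s", 1:4), NULL))), "tie")
})

test_that("misclassification distance matches brute-force enumeration", {
    expect_equal(misclassificationDistance(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0.5)
    expect_equal(misclassificationDistance(c(1, 1, 2), c(1, 1, 2)), 0)
    expect_equal(misclassificationDistance(c(1, 1, 2), c(2, 2, 1)), 0)
    set.seed(5)
    for (i in 1:100) {
        n <- sample(4:30, 1)
        a <- sample(1:2, n, replace = TRUE)
        b <- sample(1:2, n, replace = TRUE)
        d <- misclassificationDistance(a, b)
        expect_equal(d, bruteMisclass(a, b))
        expect_equal(d, misclassificationDistance(b, a))
        expect_lte(d, 0.5)
    }
    expect_error(misclassificationDistance(
        setNames(c(1, 2), c("a", "b")), setNames(c(1, 2), c("a", "c"))),
        "different sample sets")
})

test_that("the stability test is deterministic and sized correctly", {
    e <- randomExpr(150, 40, seed = 6)
    sig <- GeneSignature("s", probesetIds(e)[1:15])
    s1 <- permutationStability(e, sig, nPerm = 25, restarts = 20, seed = 11)
    s2 <- permutationStability(e, sig, nPerm = 25, restarts = 20, seed = 11)
    expect_identical(stabilityDistances(s1), stabilityDistances(s2))
    expect_identical(stabilityP(s1), stabilityP(s2))
    expect_length(stabilityDistances(s1), 25L)
    expect_true(all(stabilityDistances(s1) >= 0 & stabilityDistances(s1) <= 0.5))
    expect_error(permutationStability(e, sig, nPerm = 1), ">= 2")
})

test_that("a strongly planted signature is reproduced beyond chance", {
    sig <- GeneSignature("s", sprintf("SIG%03d", 1:40))
    ## most of the chip carries the latent structure: random draws reproduce
    ## the reference clustering, so distances fall far below chance
    co <- simulateTumorCohort(sig, nPatients = 60, nProbesets = 60,
                              sigEffectLog2 = 2, seed = 2)
    st <- permutationStability(co$expr, sig, nPerm = 50, restarts = 20,
                               seed = 3)
    expect_lt(stabilityP(st), 0.001)
    expect_lt(mean(stabilityDistances(st)), mean(st@baseline))
})

test_that("complete-linkage clustering matches a naive agglomeration oracle", {
    ## 3 points with pairwise distances 1, 2, 3: first merge joins the
    ## closest pair
    rows <- matrix(c(0, 1, 3), 3, 1,
                   dimnames = list(c("a", "b", "c"), NULL))
    hc <- hclusterComplete(rows)
    expect_identical(sort(hclustMerges(hc$hclust)[[1]]), c(1L, 2L))
    expect_true(all(diff(hc$height) >= 0))
    set.seed(8)
    rows8 <- matrix(rnorm(8 * 4), 8, 4,
                    dimnames = list(sprintf("p%d", 1:8), NULL))
    hc8 <- hclusterComplete(rows8)
    oracle <- naiveCompleteLinkage(rows8)
    expect_equal(hc8$height, oracle$heights, tolerance = 1e-10)
    got <- lapply(hclustMerges(hc8$hclust), as.integer)
    expect_identical(got, lapply(oracle$merges, as.integer))
    expect_true(all(diff(hc8$height) >= -1e-12))
})
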