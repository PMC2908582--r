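#' Cell-line stage: derive a hypoxia signature
#'
#' Runs the full derivation on a paired cell-line dataset: the three-step
#' normalization chain, then (a) the l1-l2 outer leave-one-out loops and the
#' selection-frequency signature, and (b) the per-line fold-change filter
#' with the BH-corrected paired t-test; the final signature is the
#' intersection of the two lists. The l1-l2 branch works on log2-scale
#' normalized values (standardized per fold), the differential-expression
#' branch on the linear-scale normalized values.
#'
#' By default the l1-l2 list entering the intersection is the common list:
#' the union of the per-loop selections, every feature the loops concur on
#' at least once. Setting `frequencyThreshold` (e.g. 0.5) restricts it to
#' features selected in at least that fraction of the loops.
#'
#' @param expr linear-scale [ProbesetExperiment-class] of the paired
#'   cell-line arrays.
#' @param design a [PairedDesign-class].
#' @param control an [l1l2Control()] list.
#' @param fcThreshold,alpha,fcRule differential-expression settings, see
#'   [deSelect()].
#' @param frequencyThreshold selection-frequency cutoff, see
#'   [frequencySignature()]; `NULL` (default) keeps the whole common list
#'   (union of the per-loop selections).
#' @param normalize apply [normalizeChain()] first (disable when the input
#'   is already normalized).
#' @param outDir optional directory; when given, the two lists, the
#'   intersection, the frequency table and the DE table are written there.
#' @return list with `signature` (the intersection), `l1l2`, `de`,
#'   `frequencyTable`, `foldChanges` and `counts` (probesets surviving each
#'   stage).
#' @export
runDerivation <- function(expr, design, control = l1l2Control(),
                          fcThreshold = 2, alpha = 0.05,
                          fcRule = c("mean", "all-lines"),
                          frequencyThreshold = NULL,
                          normalize = TRUE, outDir = NULL) {
    fcRule <- match.arg(fcRule)
    validatePairing(expr, design)
    norm <- if (normalize) normalizeChain(expr) else expr
    dataset <- labeledDataset(log2Transform(norm), design)
    freqTable <- outerLooSelection(dataset, control)
    if (is.null(frequencyThreshold))
        frequencyThreshold <- 1 / nLoops(freqTable)   # common list (union)
    l1l2Sig <- frequencySignature(freqTable, frequencyThreshold)
    fc <- foldChanges(norm, design)
    deSig <- deSelect(fc, fcThreshold = fcThreshold, alpha = alpha,
                      fcRule = fcRule)
    sig <- intersectSignatures(l1l2Sig, deSig, name = "hypoxia-signature")
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeSignature(l1l2Sig, file.path(outDir, "l1l2_signature.txt"))
        writeSignature(deSig, file.path(outDir, "de_signature.txt"))
        writeSignature(sig, file.path(outDir, "hypoxia_signature.txt"))
        writeFrequencyTable(freqTable, file.path(outDir, "frequency_table.tsv"))
        writeDeTable(fc, deSig, file.path(outDir, "de_table.tsv"))
    }
    list(signature = sig, l1l2 = l1l2Sig, de = deSig,
         frequencyTable = freqTable, foldChanges = fc,
         counts = c(l1l2 = length(sigProbesets(l1l2Sig)),
                    de = length(sigProbesets(deSig)),
                    intersection = length(sigProbesets(sig))),
         looError = looError(freqTable))
}

#' Tumor stage: evaluate a signature as a prognostic factor
#'
#' Stratifies the cohort by k-means (k = 2, euclidean, `restarts` random
#' restarts) on the signature's per-probeset z-scored log2 expression,
#' labels the high-expression cluster poor prognosis, measures clustering
#' stability against `nPerm` random signatures of the same size, and runs
#' the survival report (Kaplan-Meier, log-rank, multivariate Cox; full
#' cohort and MYCN-not-amplified subgroup). Deterministic under `seed`.
#'
#' @param expr linear-scale [ProbesetExperiment-class] of the tumor cohort.
#' @param clinical clinical table matching the cohort samples.
#' @param signature non-empty [GeneSignature-class] whose probesets exist in
#'   `expr`.
#' @param restarts,nPerm,seed stratification settings.
#' @param normalize apply [normalizeChain()] to the tumor matrix first (the
#'   tumor dataset is normalized on its own, independently of the cell-line
#'   one).
#' @param stability run the permutation stability test (skip to save time
#'   in repeated simulations).
#' @return list with `assignment`, `stability` (or `NULL`), `survival` and
#'   the signature expression matrix used for clustering (`sigMatrix`,
#'   samples x probesets).
#' @export
runEvaluation <- function(expr, clinical, signature, restarts = 100,
                          nPerm = 300, seed = 1, normalize = TRUE,
                          stability = TRUE) {
    probesets <- sigProbesets(signature)
    if (!length(probesets))
        stop("validation error: empty signature")
    missing <- setdiff(probesets, probesetIds(expr))
    if (length(missing))
        stop("signature probesets absent from the cohort matrix: ",
             paste(missing, collapse = ", "))
    clinical <- validateClinicalTable(clinical)
    if (!setequal(clinical$id, sampleIds(expr)))
        stop("clinical table and expression matrix cover different samples")
    norm <- if (normalize) normalizeChain(expr) else expr
    M <- .clusterMatrix(norm, scaleFeatures = TRUE)
    sigM <- M[, probesets, drop = FALSE]
    assignment <- kmeans2(sigM, restarts = restarts, seed = seed)
    assignment <- labelPrognosis(assignment, sigM)
    stab <- if (stability)
        permutationStability(norm, signature, nPerm = nPerm,
                             restarts = restarts, seed = seed + 1L)
    else NULL
    report <- survivalReport(clinical, assignment)
    list(assignment = assignment, stability = stab, survival = report,
         sigMatrix = sigM)
}
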