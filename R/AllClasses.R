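#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors metadata DataFrame SimpleList
NULL

#' Probeset-level expression container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `exprs` assay of probesets (rows) by samples (columns), plus a scale
#' flag (`"linear"` or `"log2"`) recorded in the object metadata. Linear-scale
#' objects must be strictly positive and no missing values are tolerated on
#' either scale: loaders reject incomplete matrices rather than imputing.
#'
#' @export
setClass("ProbesetExperiment", contains = "SummarizedExperiment")

.validProbesetExperiment <- function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    sc <- metadata(object)$scale
    if (is.null(sc) || !is.character(sc) || length(sc) != 1L ||
        !sc %in% c("linear", "log2"))
        msg <- c(msg, "metadata(object)$scale must be 'linear' or 'log2'")
    ids <- rownames(object)
    smp <- colnames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "probeset ids must be present and unique")
    if (is.null(smp) || anyDuplicated(smp))
        msg <- c(msg, "sample ids must be present and unique")
    if (length(msg)) return(msg)
    v <- assay(object, "exprs")
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
        msg <- c(msg, "expression values must be finite and non-missing")
    else if (identical(sc, "linear") && any(v <= 0))
        msg <- c(msg, "linear-scale expression values must be strictly positive")
    if (is.null(msg)) TRUE else msg
}
setValidity("ProbesetExperiment", .validProbesetExperiment)

#' Construct a ProbesetExperiment
#'
#' @param values numeric matrix, probesets x samples, with unique dimnames.
#' @param scale `"linear"` or `"log2"`; the scale the values live on.
#' @param colData optional per-sample annotation (e.g. a clinical table whose
#'   row names match the sample ids).
#' @return A [ProbesetExperiment-class] object.
#' @examples
#' m <- matrix(2^rnorm(12, 8), 4, 3,
#'             dimnames = list(paste0("ps", 1:4), paste0("s", 1:3)))
#' pe <- ProbesetExperiment(m, scale = "linear")
#' exprScale(pe)
#' @export
ProbesetExperiment <- function(values, scale = c("linear", "log2"),
                               colData = NULL) {
    scale <- match.arg(scale)
    if (!is.matrix(values))
        stop("'values' must be a matrix")
    storage.mode(values) <- "double"
    args <- list(assays = SimpleList(exprs = values),
                 metadata = list(scale = scale))
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment, args)
    new("ProbesetExperiment", se)
}

#' @describeIn ProbesetExperiment the expression matrix (probesets x samples)
#' @param x a `ProbesetExperiment`
#' @export
exprValues <- function(x) assay(x, "exprs")

#' @describeIn ProbesetExperiment the scale flag, `"linear"` or `"log2"`
#' @export
exprScale <- function(x) metadata(x)$scale

#' @describeIn ProbesetExperiment probeset identifiers (row names)
#' @export
probesetIds <- function(x) rownames(x)

#' @describeIn ProbesetExperiment sample identifiers (column names)
#' @export
sampleIds <- function(x) colnames(x)

#' Paired normoxic/hypoxic design
#'
#' Maps each cell line to its normoxic and hypoxic array. A valid design has
#' at least two lines, no sample used twice and unique line names; sample
#' membership in a given expression matrix is checked by [validatePairing()]
#' at the point of use.
#'
#' @slot entries data.frame with columns `cell_line`, `normoxic`, `hypoxic`.
#' @export
setClass("PairedDesign", representation(entries = "data.frame"))

setValidity("PairedDesign", function(object) {
    e <- object@entries
    msg <- NULL
    need <- c("cell_line", "normoxic", "hypoxic")
    if (!all(need %in% names(e)))
        return(sprintf("entries must have columns %s",
                       paste(need, collapse = ", ")))
    if (nrow(e) < 2L)
        msg <- c(msg, "a paired design needs at least 2 cell lines")
    if (anyDuplicated(e$cell_line))
        msg <- c(msg, "cell line names must be unique")
    smp <- c(e$normoxic, e$hypoxic)
    if (anyDuplicated(smp))
        msg <- c(msg, "no sample may appear twice in the design")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PairedDesign
#'
#' @param cell_line,normoxic,hypoxic character vectors of equal length giving,
#'   per cell line, the normoxic and hypoxic sample ids.
#' @return A [PairedDesign-class] object.
#' @export
PairedDesign <- function(cell_line, normoxic, hypoxic) {
    new("PairedDesign",
        entries = data.frame(cell_line = as.character(cell_line),
                             normoxic = as.character(normoxic),
                             hypoxic = as.character(hypoxic),
                             stringsAsFactors = FALSE))
}

#' @describeIn PairedDesign the design table
#' @param x a `PairedDesign`
#' @export
designEntries <- function(x) x@entries

#' @describeIn PairedDesign number of cell lines
#' @export
nCellLines <- function(x) nrow(x@entries)

#' Check that a design refers only to samples of a matrix
#'
#' @param expr a [ProbesetExperiment-class]
#' @param design a [PairedDesign-class]
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validatePairing <- function(expr, design) {
    smp <- c(designEntries(design)$normoxic, designEntries(design)$hypoxic)
    missing <- setdiff(smp, sampleIds(expr))
    if (length(missing))
        stop("design refers to samples absent from the matrix: ",
             paste(missing, collapse = ", "))
    invisible(TRUE)
}

#' Named probeset signature
#'
#' An ordered, de-duplicated list of probeset ids with an optional gene-symbol
#' mapping. (Named `GeneSignature` because the methods package reserves the
#' class name "signature".)
#'
#' @slot name single non-empty string.
#' @slot probesets character vector, unique.
#' @slot genes character vector of unique symbols (may be empty).
#' @export
setClass("GeneSignature",
         representation(name = "character", probesets = "character",
                        genes = "character"))

setValidity("GeneSignature", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (anyDuplicated(object@probesets))
        msg <- c(msg, "probeset ids must be unique")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene symbols must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneSignature
#'
#' @param name signature name.
#' @param probesets character vector of probeset ids (order preserved).
#' @param genes optional character vector of gene symbols.
#' @return A [GeneSignature-class].
#' @export
GeneSignature <- function(name, probesets, genes = character()) {
    new("GeneSignature", name = as.character(name),
        probesets = as.character(probesets), genes = as.character(genes))
}

#' @describeIn GeneSignature the probeset ids
#' @param x a `GeneSignature`
#' @export
sigProbesets <- function(x) x@probesets

#' @describeIn GeneSignature the mapped gene symbols
#' @export
sigGenes <- function(x) x@genes

#' @describeIn GeneSignature the signature name
#' @export
sigName <- function(x) x@name

#' Selection-frequency table from the outer leave-one-out loops
#'
#' Records, for every feature selected at least once, in how many of the `L`
#' outer leave-one-out loops it entered the fitted model, together with the
#' per-loop selected lists and the outer leave-one-out misclassification rate.
#'
#' @slot counts named integer vector (features selected at least once).
#' @slot L number of outer loops.
#' @slot looError outer leave-one-out error in \[0, 1\].
#' @slot loopLists list of length `L` of per-loop selected feature ids.
#' @slot tauStar numeric vector of the per-loop selected tau values.
#' @export
setClass("SelectionFrequencyTable",
         representation(counts = "integer", L = "integer",
                        looError = "numeric", loopLists = "list",
                        tauStar = "numeric"))

setValidity("SelectionFrequencyTable", function(object) {
    msg <- NULL
    if (length(object@L) != 1L || object@L < 1L)
        msg <- c(msg, "L must be a positive integer")
    if (length(object@looError) != 1L || object@looError < 0 ||
        object@looError > 1)
        msg <- c(msg, "looError must lie in [0, 1]")
    if (length(object@loopLists) != object@L)
        msg <- c(msg, "one selected list per outer loop is required")
    if (length(object@counts) &&
        (is.null(names(object@counts)) || anyDuplicated(names(object@counts))))
        msg <- c(msg, "counts must be uniquely named")
    if (any(object@counts > object@L) || any(object@counts < 1L))
        msg <- c(msg, "counts must lie in [1, L]")
    un <- unique(unlist(object@loopLists, use.names = FALSE))
    if (!setequal(un, names(object@counts)))
        msg <- c(msg, "counts must cover exactly the union of the loop lists")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SelectionFrequencyTable named per-feature selection counts
#' @param x a `SelectionFrequencyTable`
#' @export
freqCounts <- function(x) x@counts

#' @describeIn SelectionFrequencyTable number of outer loops
#' @export
nLoops <- function(x) x@L

#' @describeIn SelectionFrequencyTable outer leave-one-out error
#' @export
looError <- function(x) x@looError

#' @describeIn SelectionFrequencyTable per-loop selected feature lists
#' @export
loopLists <- function(x) x@loopLists

#' Two-group clustering of a patient cohort
#'
#' @slot cluster named integer vector in \{1, 2\} (names = sample ids).
#' @slot wss total within-cluster sum of squares of the retained solution.
#' @slot prognosis character of length 2 mapping cluster 1 and 2 to
#'   `"poor"`/`"good"`, or length 0 before [labelPrognosis()] is applied.
#' @export
setClass("ClusterAssignment",
         representation(cluster = "integer", wss = "numeric",
                        prognosis = "character"))

setValidity("ClusterAssignment", function(object) {
    msg <- NULL
    cl <- object@cluster
    if (is.null(names(cl)) || anyDuplicated(names(cl)))
        msg <- c(msg, "cluster vector must be uniquely named by sample id")
    if (!all(cl %in% 1:2))
        msg <- c(msg, "cluster labels must be 1 or 2")
    if (length(unique(cl)) != 2L)
        msg <- c(msg, "both clusters must be non-empty")
    if (length(object@wss) != 1L || object@wss < 0)
        msg <- c(msg, "wss must be a single non-negative number")
    if (length(object@prognosis) &&
        (length(object@prognosis) != 2L ||
         !setequal(object@prognosis, c("poor", "good"))))
        msg <- c(msg, "prognosis must label one cluster poor and one good")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ClusterAssignment named cluster labels (1 or 2)
#' @param x a `ClusterAssignment`
#' @export
clusterLabels <- function(x) x@cluster

#' @describeIn ClusterAssignment sizes of clusters 1 and 2
#' @export
clusterSizes <- function(x) as.integer(table(factor(x@cluster, levels = 1:2)))

#' @describeIn ClusterAssignment per-sample prognosis (`"poor"`/`"good"`),
#'   available after [labelPrognosis()]
#' @export
prognosisLabels <- function(x) {
    if (!length(x@prognosis))
        stop("prognosis labels not set; run labelPrognosis() first")
    stats::setNames(x@prognosis[x@cluster], names(x@cluster))
}

#' Random-signature permutation stability result
#'
#' @slot distances misclassification distances to the reference labeling, one
#'   per permuted signature, each in \[0, 0.5\].
#' @slot baseline per-permutation chance-agreement expected distances.
#' @slot tStatistic,pValue one-sample two-sided t test of
#'   `distances - baseline` against zero.
#' @slot nPerm number of random signatures drawn.
#' @export
setClass("StabilityResult",
         representation(distances = "numeric", baseline = "numeric",
                        tStatistic = "numeric", pValue = "numeric",
                        nPerm = "integer"))

setValidity("StabilityResult", function(object) {
    msg <- NULL
    if (length(object@distances) != object@nPerm)
        msg <- c(msg, "one distance per permutation is required")
    if (length(object@baseline) != object@nPerm)
        msg <- c(msg, "one baseline value per permutation is required")
    if (any(object@distances < 0 | object@distances > 0.5))
        msg <- c(msg, "distances must lie in [0, 0.5]")
    if (length(object@pValue) != 1L || object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn StabilityResult the permutation distances
#' @param x a `StabilityResult`
#' @export
stabilityDistances <- function(x) x@distances

#' @describeIn StabilityResult the t-test p-value
#' @export
stabilityP <- function(x) x@pValue

#' Kaplan-Meier product-limit curve
#'
#' @slot time distinct event times, ascending.
#' @slot nRisk number at risk just before each event time.
#' @slot nEvent events at each event time.
#' @slot survival product-limit estimate after each event time.
#' @slot finalRate estimate at the largest observed time (events or not).
#' @slot n,nEvents totals.
#' @export
setClass("KMCurve",
         representation(time = "numeric", nRisk = "numeric",
                        nEvent = "numeric", survival = "numeric",
                        finalRate = "numeric", n = "integer",
                        nEvents = "integer"))

setValidity("KMCurve", function(object) {
    msg <- NULL
    if (is.unsorted(object@time, strictly = TRUE) && length(object@time) > 1L)
        msg <- c(msg, "event times must be strictly increasing")
    if (any(object@survival < 0 | object@survival > 1))
        msg <- c(msg, "survival estimates must lie in [0, 1]")
    if (length(object@survival) > 1L &&
        any(diff(object@survival) > 1e-12))
        msg <- c(msg, "survival estimates must be non-increasing")
    if (length(object@nRisk) > 1L && any(diff(object@nRisk) > 0))
        msg <- c(msg, "at-risk counts must be non-increasing")
    if (is.null(msg)) TRUE else msg
})

#' Log-rank test result
#'
#' @slot chi2 chi-square statistic (1 df).
#' @slot p two-sided p-value.
#' @slot n1,n2 group sizes.
#' @export
setClass("LogRankResult",
         representation(chi2 = "numeric", p = "numeric",
                        n1 = "integer", n2 = "integer"))

#' Fitted Cox proportional-hazards model
#'
#' @slot coefficients data.frame with one row per covariate: `beta`, `se`,
#'   `hr`, `lower95`, `upper95`, `p`.
#' @slot loglik final log partial likelihood.
#' @slot converged logical convergence flag.
#' @slot iterations Newton iterations used.
#' @slot n,nEvents totals.
#' @slot ties tie-handling rule used (`"efron"` or `"breslow"`).
#' @export
setClass("CoxFit",
         representation(coefficients = "data.frame", loglik = "numeric",
                        converged = "logical", iterations = "integer",
                        n = "integer", nEvents = "integer", ties = "character"))

setValidity("CoxFit", function(object) {
    cf <- object@coefficients
    need <- c("beta", "se", "hr", "lower95", "upper95", "p")
    if (!all(need %in% names(cf)))
        return("coefficient table is missing columns")
    msg <- NULL
    if (any(cf$hr <= 0)) msg <- c(msg, "hazard ratios must be positive")
    if (any(cf$lower95 > cf$hr | cf$upper95 < cf$hr))
        msg <- c(msg, "the 95% CI must bracket the hazard ratio")
    if (any(cf$p < 0 | cf$p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CoxFit coefficient table (beta, se, hr, 95% CI, p)
#' @param x a `CoxFit`
#' @export
coxTable <- function(x) x@coefficients

## --- show methods -----------------------------------------------------------

setMethod("show", "ProbesetExperiment", function(object) {
    cat(sprintf("ProbesetExperiment: %d probesets x %d samples [%s scale]\n",
                nrow(object), ncol(object), exprScale(object)))
})

setMethod("show", "PairedDesign", function(object) {
    cat(sprintf("PairedDesign: %d cell lines (normoxic/hypoxic pairs)\n",
                nCellLines(object)))
})

setMethod("show", "GeneSignature", function(object) {
    cat(sprintf("GeneSignature '%s': %d probesets", object@name,
                length(object@probesets)))
    if (length(object@genes))
        cat(sprintf(", %d genes", length(object@genes)))
    cat("\n")
})

setMethod("show", "SelectionFrequencyTable", function(object) {
    cat(sprintf(
        "SelectionFrequencyTable: %d features over %d loops, LOO error %.1f%%\n",
        length(object@counts), object@L, 100 * object@looError))
})

setMethod("show", "ClusterAssignment", function(object) {
    sz <- clusterSizes(object)
    cat(sprintf("ClusterAssignment: clusters of %d and %d samples", sz[1], sz[2]))
    if (length(object@prognosis))
        cat(sprintf(" (cluster 1 = %s, cluster 2 = %s)",
                    object@prognosis[1], object@prognosis[2]))
    cat("\n")
})

setMethod("show", "StabilityResult", function(object) {
    cat(sprintf(
        "StabilityResult: %d permutations, mean distance %.3f, t = %.2f, p = %.3g\n",
        object@nPerm, mean(object@distances), object@tStatistic, object@pValue))
})

setMethod("show", "KMCurve", function(object) {
    cat(sprintf("KMCurve: %d subjects, %d events, final rate %.1f%%\n",
                object@n, object@nEvents, 100 * object@finalRate))
})

setMethod("show", "LogRankResult", function(object) {
    cat(sprintf("Log-rank: chi2 = %.3f (1 df), p = %.3g, groups %d/%d\n",
                object@chi2, object@p, object@n1, object@n2))
})

setMethod("show", "CoxFit", function(object) {
    cat(sprintf("CoxFit (%s ties): n = %d, events = %d, %s\n", object@ties,
                object@n, object@nEvents,
                if (object@converged) "converged" else "NOT converged"))
    print(round(object@coefficients, 4))
})
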