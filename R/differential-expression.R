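#' Per-line hypoxic/normoxic fold changes
#'
#' For every probeset and every cell line, the fold change is the linear
#' ratio hypoxic / normoxic; `mean_log2fc` is the mean over lines of the
#' log2 fold changes. The per-probeset two-sided one-sample t statistic of
#' the log2 ratios against 0 (equivalent to a paired t-test on the log2
#' values) is computed alongside; zero-variance probesets get `p = 1` and
#' are flagged in the `degenerate` column.
#'
#' @param expr linear-scale, strictly positive [ProbesetExperiment-class].
#' @param design a [PairedDesign-class].
#' @return list of class `FoldChangeResult`: `fc` (probesets x lines linear
#'   ratios), `table` (data.frame with `probeset`, `mean_log2fc`, `p`,
#'   `degenerate`), `nLines`.
#' @export
foldChanges <- function(expr, design) {
    if (exprScale(expr) != "linear")
        stop("foldChanges() expects linear-scale expression")
    validatePairing(expr, design)
    e <- designEntries(design)
    v <- exprValues(expr)
    num <- v[, e$hypoxic, drop = FALSE]
    den <- v[, e$normoxic, drop = FALSE]
    if (any(den == 0)) stop("domain error: zero normoxic expression value")
    fc <- num / den
    colnames(fc) <- e$cell_line
    lr <- log2(fc)
    tt <- pairedTTest(lr)
    res <- list(fc = fc,
                table = data.frame(probeset = rownames(v),
                                   mean_log2fc = rowMeans(lr),
                                   p = tt$p, degenerate = tt$degenerate,
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
                nLines = nrow(e))
    class(res) <- "FoldChangeResult"
    res
}

#' One-sample t-test of per-line log ratios against zero
#'
#' Row-wise over a probesets x lines matrix (or a single vector). Two-sided.
#' Rows with zero variance are degenerate: their p-value is set to 1 and
#' flagged rather than left undefined.
#'
#' @param logRatios numeric matrix (probesets x lines) or vector of log2
#'   ratios; at least 2 lines.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
pairedTTest <- function(logRatios) {
    if (is.vector(logRatios)) logRatios <- matrix(logRatios, nrow = 1L)
    n <- ncol(logRatios)
    if (n < 2L) stop("need at least 2 lines for a t-test")
    m <- rowMeans(logRatios)
    s <- sqrt(rowSums((logRatios - m)^2) / (n - 1L))
    degenerate <- s < .Machine$double.eps
    t <- ifelse(degenerate, 0, m / (s / sqrt(n)))
    p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(t), df = n - 1L))
    list(t = t, p = p, df = n - 1L, degenerate = degenerate)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (monotone, `>=` raw, `<= 1`).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
benjaminiHochberg <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("domain error: p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Differential-expression selection
#'
#' Keeps probesets modulated at least `fcThreshold`-fold as
#' `|mean_log2fc| >= log2(fcThreshold)` (or, with `fcRule = "all-lines"`, at
#' least that much in every individual line), then applies the
#' Benjamini-Hochberg correction to the t-test p-values of the kept set and
#' retains those with adjusted p below `alpha`.
#'
#' @param fcResult a `FoldChangeResult` from [foldChanges()].
#' @param fcThreshold minimum fold modulation (linear), `> 0`.
#' @param alpha FDR significance cutoff, `> 0`.
#' @param fcRule `"mean"` (default; threshold on the across-line mean log2
#'   fold change) or `"all-lines"` (threshold required in every line).
#' @param name name for the resulting signature.
#' @return a [GeneSignature-class] ordered by descending `|mean_log2fc|`.
#' @export
deSelect <- function(fcResult, fcThreshold = 2, alpha = 0.05,
                     fcRule = c("mean", "all-lines"),
                     name = "differential-expression") {
    fcRule <- match.arg(fcRule)
    if (fcThreshold <= 0 || alpha <= 0) stop("thresholds must be > 0")
    tab <- fcResult$table
    cut <- log2(fcThreshold)
    kept <- if (fcRule == "mean") abs(tab$mean_log2fc) >= cut
            else apply(abs(log2(fcResult$fc)) >= cut, 1L, all)
    adj <- rep(NA_real_, nrow(tab))
    adj[kept] <- benjaminiHochberg(tab$p[kept])
    pass <- kept & !is.na(adj) & adj < alpha
    tab$adj_p <- adj
    tab$pass <- pass
    sel <- tab[pass, , drop = FALSE]
    sel <- sel[order(-abs(sel$mean_log2fc), sel$probeset), , drop = FALSE]
    sig <- GeneSignature(name, sel$probeset)
    attr(sig, "table") <- tab
    sig
}

#' Export a fold-change / differential-expression table as TSV
#'
#' One row per probeset: the per-line fold changes, `mean_log2fc`, raw and
#' BH-adjusted p-values and the pass flag of a [deSelect()] run.
#'
#' @param fcResult a `FoldChangeResult`.
#' @param deSig the [GeneSignature-class] returned by [deSelect()] on it.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDeTable <- function(fcResult, deSig, path) {
    tab <- attr(deSig, "table")
    out <- cbind(probeset = tab$probeset,
                 as.data.frame(fcResult$fc, stringsAsFactors = FALSE),
                 tab[, c("mean_log2fc", "p", "adj_p", "pass")])
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
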