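#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of probeset ids
#' (GEO series-matrix orientation: probesets as rows, samples as columns).
#' Duplicate probeset ids, non-numeric cells and missing values are rejected;
#' nothing is imputed.
#'
#' @param path path to a TSV file.
#' @param scale scale the stored values live on, `"linear"` or `"log2"`.
#' @return A [ProbesetExperiment-class].
#' @export
readExpressionMatrix <- function(path, scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0L) stop("format error: empty file: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L || ncol(tab) < 2L)
        stop("format error: need a probeset id column and >= 1 sample column")
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("format error: duplicated probeset ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (anyNA(vals) || any(!nzchar(trimws(vals))))
        stop("format error: missing values are not accepted")
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("parse error: non-numeric value '%s' at row %d (probeset %s), column '%s'",
                     vals[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                     colnames(vals)[bad[1, 2]]))
    if (anyNA(num))
        stop("format error: missing values are not accepted")
    dimnames(num) <- list(ids, colnames(vals))
    ProbesetExperiment(num, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionMatrix()]: header row of sample ids, first
#' column (`probeset_id`) of probeset ids, full double precision.
#'
#' @param expr a [ProbesetExperiment-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeExpressionMatrix <- function(expr, path) {
    v <- exprValues(expr)
    df <- data.frame(probeset_id = rownames(v),
                     format(v, digits = 17, trim = TRUE, scientific = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Three-step array normalization chain
#'
#' Applies, in order: (1) per sample, rescaling so the sample mean equals
#' `targetMean` (MAS5-style global scaling, arithmetic mean); (2) per sample,
#' division by that sample's 50th percentile; (3) per probeset, division by
#' the probeset's median across samples. All steps act on the linear scale;
#' after step 3 every probeset has median exactly 1 across samples.
#'
#' With a single sample, step 3 is degenerate (it would flatten the array to
#' all ones); the step-2 output is returned with a warning.
#'
#' @param expr linear-scale [ProbesetExperiment-class], strictly positive.
#' @param targetMean target per-sample mean intensity for step 1.
#' @return A linear-scale [ProbesetExperiment-class].
#' @export
normalizeChain <- function(expr, targetMean = 500) {
    if (exprScale(expr) != "linear")
        stop("normalizeChain() expects a linear-scale matrix")
    v <- exprValues(expr)
    if (any(v <= 0))
        stop("domain error: normalization requires strictly positive values")
    v <- sweep(v, 2L, colMeans(v) / targetMean, "/")       # step 1
    v <- sweep(v, 2L, apply(v, 2L, stats::median), "/")    # step 2
    if (ncol(v) == 1L) {
        warning("single-sample matrix: per-probeset median step is degenerate; ",
                "returning the per-sample-normalized values")
        return(ProbesetExperiment(v, scale = "linear", colData = colData(expr)))
    }
    v <- sweep(v, 1L, apply(v, 1L, stats::median), "/")    # step 3
    ProbesetExperiment(v, scale = "linear", colData = colData(expr))
}

#' Elementwise log2 transform
#'
#' @param expr linear-scale [ProbesetExperiment-class].
#' @param pseudocount added before taking logs; all `values + pseudocount`
#'   must be positive.
#' @return A log2-scale [ProbesetExperiment-class].
#' @export
log2Transform <- function(expr, pseudocount = 0) {
    if (exprScale(expr) != "linear")
        stop("log2Transform() expects a linear-scale matrix")
    v <- exprValues(expr) + pseudocount
    if (any(v <= 0))
        stop("domain error: non-positive values; use a pseudocount")
    ProbesetExperiment(log2(v), scale = "log2",
                       colData = colData(expr))
}

#' Read a clinical table
#'
#' CSV with columns `id`, `time_years`, `event`, `mycn`, `inss`, `age_group`.
#' Categories are validated strictly: `mycn` in \{amplified, normal\}, `inss`
#' in \{1, 2, 3, 4, 4S\} (case-insensitive on 4S), `age_group` in
#' \{lt1, ge1\}; times must be finite and non-negative, events 0/1, ids
#' unique. Extra endpoint columns (e.g. `efs_time_years`, `efs_event`) are
#' carried through untouched.
#'
#' @param path CSV path.
#' @return a validated data.frame.
#' @export
readClinicalTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    validateClinicalTable(df)
}

#' Validate a clinical table already in memory
#'
#' @param df data.frame as described in [readClinicalTable()].
#' @return the validated (category-normalized) data.frame.
#' @export
validateClinicalTable <- function(df) {
    need <- c("id", "time_years", "event", "mycn", "inss", "age_group")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("clinical table is missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$id)) stop("patient ids must be unique")
    if (!is.numeric(df$time_years) || anyNA(df$time_years) ||
        any(!is.finite(df$time_years)) || any(df$time_years < 0))
        stop("time_years must be finite and >= 0")
    if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1")
    if (!all(df$mycn %in% c("amplified", "normal")))
        stop("mycn must be 'amplified' or 'normal'")
    df$inss <- toupper(as.character(df$inss))
    if (!all(df$inss %in% c("1", "2", "3", "4", "4S")))
        stop("inss must be one of 1, 2, 3, 4, 4S")
    if (!all(df$age_group %in% c("lt1", "ge1")))
        stop("age_group must be 'lt1' or 'ge1'")
    df
}

#' Read a probeset annotation table
#'
#' CSV with columns `probeset_id`, `gene_symbol`, `accession`; probeset ids
#' must be unique and gene symbols non-empty.
#'
#' @param path CSV path.
#' @return a data.frame usable by [mapProbesetsToGenes()].
#' @export
readAnnotationTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("probeset_id", "gene_symbol", "accession")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("annotation table is missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$probeset_id)) stop("probeset ids must be unique")
    if (any(!nzchar(trimws(df$gene_symbol)))) stop("gene symbols must be non-empty")
    df
}

#' Read / write plain-text signatures
#'
#' One probeset id per line; blank lines ignored, duplicates rejected.
#'
#' @param path file path.
#' @param name signature name (defaults to the file name).
#' @return [readSignature()] a [GeneSignature-class]; [writeSignature()]
#'   invisibly the path.
#' @export
readSignature <- function(path, name = basename(path)) {
    ids <- readLines(path)
    ids <- trimws(ids)
    ids <- ids[nzchar(ids)]
    GeneSignature(name, ids)
}

#' @rdname readSignature
#' @param sig a [GeneSignature-class] to write.
#' @export
writeSignature <- function(sig, path) {
    writeLines(sigProbesets(sig), path)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then member symbols.
#'
#' @param path GMT path.
#' @return named list of character vectors of gene symbols.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
        if (length(f) < 3L) stop("malformed GMT line: ", f[1])
        unique(f[-(1:2)])
    })
    names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
    sets
}
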