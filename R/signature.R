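#' Intersect two signatures
#'
#' Set intersection of the probeset lists, keeping the order of `A`. An
#' empty intersection is allowed (with a warning).
#'
#' @param A,B [GeneSignature-class] objects.
#' @param name name of the result.
#' @return a [GeneSignature-class], subset of both inputs.
#' @export
intersectSignatures <- function(A, B, name = paste(sigName(A), sigName(B),
                                                   sep = " & ")) {
    keep <- sigProbesets(A)[sigProbesets(A) %in% sigProbesets(B)]
    if (!length(keep)) warning("the two signatures share no probesets")
    GeneSignature(name, keep)
}

#' Attach gene symbols to a signature
#'
#' Maps the signature's probesets through an annotation table; distinct
#' probesets of the same gene collapse to one symbol. Unmapped probesets are
#' listed in a warning and excluded from the gene set (the probeset list is
#' untouched).
#'
#' @param sig a [GeneSignature-class].
#' @param annotation data.frame with `probeset_id` and `gene_symbol` columns
#'   (see [readAnnotationTable()]).
#' @return the signature with its `genes` slot filled.
#' @export
mapProbesetsToGenes <- function(sig, annotation) {
    idx <- match(sigProbesets(sig), annotation$probeset_id)
    unmapped <- sigProbesets(sig)[is.na(idx)]
    if (length(unmapped))
        warning("unmapped probesets excluded from the gene set: ",
                paste(unmapped, collapse = ", "))
    genes <- unique(trimws(annotation$gene_symbol[idx[!is.na(idx)]]))
    GeneSignature(sigName(sig), sigProbesets(sig), genes)
}

#' Count shared genes between two symbol sets
#'
#' Symbols are compared case-insensitively after whitespace stripping, so
#' lists assembled from different sources count correctly.
#'
#' @param genesA,genesB character vectors of gene symbols.
#' @return integer, `|A intersect B|`.
#' @export
overlapCount <- function(genesA, genesB) {
    a <- unique(toupper(trimws(genesA)))
    b <- unique(toupper(trimws(genesB)))
    length(intersect(a, b))
}
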