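#' Accessors for TrioMethExperiment and FilterLedger
#'
#' `trios()` returns the family structure (`DataFrame` with `family_id`,
#' `father`, `mother`, `child`); `methAssay()` and `covAssay()` return the
#' methylation-percent and coverage matrices; `ledgerTable()` returns a
#' `DataFrame` of the filter cascade (`stage`, `removed`, `remaining`).
#'
#' @param x A [TrioMethExperiment-class] (or [FilterLedger-class] for
#'   `ledgerTable`).
#' @param value Replacement trio table.
#' @return See the per-accessor description above.
#' @name accessors
#' @aliases trios methAssay covAssay ledgerTable trios<-
NULL

#' @rdname accessors
#' @export
setGeneric("trios", function(x) standardGeneric("trios"))

#' @rdname accessors
#' @export
setGeneric("trios<-", function(x, value) standardGeneric("trios<-"))

#' @rdname accessors
#' @export
setGeneric("methAssay", function(x) standardGeneric("methAssay"))

#' @rdname accessors
#' @export
setGeneric("covAssay", function(x) standardGeneric("covAssay"))

#' @rdname accessors
#' @export
setGeneric("ledgerTable", function(x) standardGeneric("ledgerTable"))

#' @rdname accessors
setMethod("trios", "TrioMethExperiment", function(x) x@trios)

#' @rdname accessors
setReplaceMethod("trios", "TrioMethExperiment", function(x, value) {
    x@trios <- as(as.data.frame(value, stringsAsFactors = FALSE), "DataFrame")
    validObject(x)
    x
})

#' @rdname accessors
setMethod("methAssay", "TrioMethExperiment",
          function(x) assay(x, "meth"))

#' @rdname accessors
setMethod("covAssay", "TrioMethExperiment",
          function(x) assay(x, "cov"))

#' @rdname accessors
setMethod("ledgerTable", "FilterLedger", function(x) {
    DataFrame(stage = x@stages, removed = x@removed, remaining = x@remaining)
})

setMethod("show", "TrioMethExperiment", function(object) {
    callNextMethod()
    tr <- trios(object)
    cat(sprintf("trios(%d): %s\n", nrow(tr),
                paste(head(tr$family_id, 6), collapse = " ")))
})

setMethod("show", "FilterLedger", function(object) {
    cat(sprintf("FilterLedger: %d sites in, %d stages\n",
                object@nInput, length(object@stages)))
    tab <- as.data.frame(ledgerTable(object))
    if (nrow(tab)) print(tab, row.names = FALSE)
})

setMethod("show", "GenomeLayout", function(object) {
    cat("GenomeLayout\n")
    cat(sprintf("  chromosomes: %s\n",
                paste(seqnames(object@seqinfo), collapse = ", ")))
    cat(sprintf("  CpGs: %d | islands: %d | genes: %d | SNPs: %d\n",
                length(object@cpgs), length(object@islands),
                length(object@genes), length(object@snps)))
    cat(sprintf("  chromatin tiles: %d | imprinted regions: %d\n",
                length(object@chromatin), length(object@imprinted)))
})
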