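#' TrioMethExperiment: trio WGBS methylation calls
#'
#' A \linkS4class{RangedSummarizedExperiment} holding per-CpG, per-sample
#' methylation percentages (assay `"meth"`, values in \[0, 100\] or `NA`) and
#' read coverage (assay `"cov"`, non-negative integers), with the trio
#' structure of the cohort in the `trios` slot. Rows are single-base ranges at
#' the C of each CpG dinucleotide (1-based); columns are samples.
#'
#' A methylation call is missing exactly when its coverage is zero: the
#' validity method enforces `is.na(meth) == (cov == 0)` cell by cell, along
#' with the \[0, 100\] range and the trio bookkeeping (three distinct samples
#' per family, every sample in exactly one trio, all samples present in the
#' assay columns).
#'
#' @slot trios `DataFrame` with columns `family_id`, `father`, `mother`,
#'   `child`; the last three reference `colnames` of the object.
#'
#' @seealso [TrioMethExperiment()] for the constructor, [trios()],
#'   [methAssay()], [covAssay()] for accessors.
#' @export
setClass("TrioMethExperiment",
    contains = "RangedSummarizedExperiment",
    slots = c(trios = "DataFrame"))

setValidity("TrioMethExperiment", function(object) {
    msg <- character()
    an <- assayNames(object)
    if (!all(c("meth", "cov") %in% an))
        return("assays must include 'meth' and 'cov'")
    meth <- assay(object, "meth")
    cov <- assay(object, "cov")
    if (any(!is.na(meth) & (meth < 0 | meth > 100)))
        msg <- c(msg, "'meth' values must lie in [0, 100] or be NA")
    if (any(is.na(cov)) || any(cov < 0))
        msg <- c(msg, "'cov' values must be non-negative and non-missing")
    if (any(is.na(meth) != (cov == 0)))
        msg <- c(msg, "'meth' must be NA exactly where 'cov' is 0")
    tr <- object@trios
    need <- c("family_id", "father", "mother", "child")
    if (!all(need %in% colnames(tr))) {
        msg <- c(msg, paste0("'trios' must have columns ",
                             paste(need, collapse = ", ")))
    } else if (nrow(tr) > 0L) {
        members <- c(tr$father, tr$mother, tr$child)
        if (anyDuplicated(members))
            msg <- c(msg, "every sample must belong to exactly one trio")
        for (i in seq_len(nrow(tr)))
            if (length(unique(c(tr$father[i], tr$mother[i], tr$child[i]))) != 3L)
                msg <- c(msg, sprintf(
                    "family '%s' must name three distinct samples",
                    tr$family_id[i]))
        missing <- setdiff(members, colnames(object))
        if (length(missing))
            msg <- c(msg, paste0("trio samples absent from assay columns: ",
                                 paste(missing, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TrioMethExperiment
#'
#' @param meth Numeric matrix, CpGs x samples, methylation percent in
#'   \[0, 100\] with `NA` where coverage is zero.
#' @param cov Integer matrix of the same shape: read coverage per cell.
#' @param rowRanges `GRanges` of single-base CpG positions (the C of the
#'   dinucleotide, 1-based), one per row of `meth`.
#' @param trios `data.frame` or `DataFrame` with columns `family_id`,
#'   `father`, `mother`, `child` mapping each family to sample identifiers
#'   (column names of `meth`).
#' @param colData Optional `DataFrame` of sample metadata; by default the
#'   family and role of each sample are derived from `trios`.
#'
#' @return A validated [TrioMethExperiment-class] object.
#' @examples
#' meth <- matrix(c(0, 100, 50, NA, 80, 20), nrow = 2,
#'                dimnames = list(c("cpg1", "cpg2"),
#'                                c("F1_father", "F1_mother", "F1_child")))
#' cov <- matrix(c(10L, 12L, 9L, 0L, 11L, 10L), nrow = 2,
#'               dimnames = dimnames(meth))
#' gr <- GenomicRanges::GRanges(c("chr1", "chr1"),
#'                              IRanges::IRanges(c(100, 500), width = 1))
#' trios <- data.frame(family_id = "F1", father = "F1_father",
#'                     mother = "F1_mother", child = "F1_child")
#' tme <- TrioMethExperiment(meth, cov, gr, trios)
#' @export
TrioMethExperiment <- function(meth, cov, rowRanges, trios, colData = NULL) {
    meth <- as.matrix(meth)
    cov <- as.matrix(cov)
    storage.mode(cov) <- "integer"
    trios <- as(as.data.frame(trios, stringsAsFactors = FALSE), "DataFrame")
    if (is.null(colnames(meth)))
        stop("'meth' must carry sample identifiers as column names")
    if (is.null(colData)) {
        role <- family <- setNames(rep(NA_character_, ncol(meth)),
                                   colnames(meth))
        for (i in seq_len(nrow(trios))) {
            family[c(trios$father[i], trios$mother[i], trios$child[i])] <-
                trios$family_id[i]
            role[trios$father[i]] <- "father"
            role[trios$mother[i]] <- "mother"
            role[trios$child[i]] <- "child"
        }
        colData <- DataFrame(family = family[colnames(meth)],
                             role = role[colnames(meth)],
                             row.names = colnames(meth))
    }
    names(rowRanges) <- rownames(meth)
    se <- SummarizedExperiment(
        assays = list(meth = meth, cov = cov),
        rowRanges = rowRanges, colData = colData)
    new("TrioMethExperiment", se, trios = trios)
}

#' FilterLedger: bookkeeping of a sequential filter cascade
#'
#' Ordered record of how many sites each pipeline stage removed and how many
#' remained, mirroring the filter-scheme arithmetic of trio methylome studies.
#' Each removal is attributed to the first failing stage, so
#' `remaining[i] = remaining[i - 1] - removed[i]` and `remaining` is
#' non-increasing; the validity method enforces this.
#'
#' @slot stages Character vector of stage names, in application order.
#' @slot removed Integer vector: sites removed at each stage.
#' @slot remaining Integer vector: sites surviving each stage.
#' @slot nInput Integer: number of sites entering the cascade.
#'
#' @seealso [FilterLedger()] for the constructor, [ledgerTable()].
#' @export
setClass("FilterLedger",
    slots = c(stages = "character", removed = "integer",
              remaining = "integer", nInput = "integer"))

setValidity("FilterLedger", function(object) {
    msg <- character()
    k <- length(object@stages)
    if (length(object@removed) != k || length(object@remaining) != k)
        return("'stages', 'removed' and 'remaining' must have equal length")
    if (anyDuplicated(object@stages))
        msg <- c(msg, "stage names must be unique")
    if (any(object@removed < 0))
        msg <- c(msg, "'removed' counts must be non-negative")
    prev <- c(object@nInput, object@remaining[-k])
    if (k > 0L && any(object@remaining != prev - object@removed))
        msg <- c(msg, "remaining[i] must equal remaining[i-1] - removed[i]")
    if (k > 0L && is.unsorted(rev(object@remaining)))
        msg <- c(msg, "'remaining' must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' Construct a FilterLedger from stage removal counts
#'
#' Given the number of sites entering a cascade and the count removed at each
#' stage, computes the running remainder. This is the bookkeeping used for the
#' filter-scheme arithmetic (e.g. Mendelian = filtered - non-Mendelian,
#' heritable = Mendelian - cis mQTL - trans mQTL).
#'
#' @param input Number of sites entering the cascade.
#' @param stages Character vector of stage names, in order.
#' @param removed Integer vector of per-stage removal counts.
#' @return A [FilterLedger-class] object.
#' @examples
#' led <- FilterLedger(8138969,
#'                     c("non_mendelian", "cis_mqtl", "trans_mqtl"),
#'                     c(6555252, 2724, 1577505))
#' ledgerTable(led)
#' @export
FilterLedger <- function(input, stages = character(), removed = integer()) {
    input <- as.integer(input)
    removed <- as.integer(removed)
    remaining <- input - cumsum(removed)
    new("FilterLedger", stages = as.character(stages), removed = removed,
        remaining = as.integer(remaining), nInput = input)
}

#' GenomeLayout: annotation tracks and sequence of a (synthetic) genome
#'
#' Container for the genomic context a trio methylome analysis needs: CpG
#' positions, CpG islands, gene models with exons, chromatin-state tiles,
#' imprinted regions, SNP positions, and the underlying sequence.
#'
#' @slot seqinfo `Seqinfo` with chromosome names and lengths.
#' @slot cpgs `GRanges`, single-base positions of the C of each CpG; mcols may
#'   carry a `class` column (truth labels for simulated data).
#' @slot islands `GRanges` of CpG islands.
#' @slot genes `GRanges` of gene bodies with strand and a `gene_id` column.
#' @slot exons `GRanges` of exons with a `gene_id` column.
#' @slot chromatin `GRanges` tiling with a `state` column (15-state-style
#'   segmentation labels).
#' @slot imprinted `GRanges` of imprinted regions.
#' @slot snps `GRanges` of single-base SNP positions with `snp_id` and founder
#'   allele frequency `af` columns.
#' @slot sequence `DNAStringSet`, one entry per chromosome.
#' @export
setClass("GenomeLayout",
    slots = c(seqinfo = "Seqinfo", cpgs = "GRanges", islands = "GRanges",
              genes = "GRanges", exons = "GRanges", chromatin = "GRanges",
              imprinted = "GRanges", snps = "GRanges",
              sequence = "DNAStringSet"))

setValidity("GenomeLayout", function(object) {
    msg <- character()
    lens <- seqlengths(object@seqinfo)
    for (nm in c("cpgs", "islands", "genes", "exons", "chromatin",
                 "imprinted", "snps")) {
        gr <- slot(object, nm)
        if (length(gr) == 0L) next
        chr <- as.character(seqnames(gr))
        if (!all(chr %in% names(lens))) {
            msg <- c(msg, sprintf("'%s' uses chromosomes absent from seqinfo", nm))
            next
        }
        if (any(start(gr) < 1L) || any(end(gr) > lens[chr]))
            msg <- c(msg, sprintf("'%s' intervals exceed chromosome bounds", nm))
    }
    if (length(object@cpgs)) {
        bychr <- split(start(object@cpgs), as.character(seqnames(object@cpgs)))
        if (any(vapply(bychr, function(p) is.unsorted(p, strictly = TRUE),
                       logical(1))))
            msg <- c(msg, "CpG positions must be strictly increasing per chromosome")
    }
    if (length(msg)) msg else TRUE
})
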