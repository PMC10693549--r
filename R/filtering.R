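# Pre-filter cascade on CpGs and the SNP-side Mendelian-consistency filter.

.asPositions <- function(x) {
    if (is(x, "SummarizedExperiment")) granges(rowRanges(x))
    else if (is(x, "GRanges")) granges(x)
    else stop("expected a GRanges or RangedSummarizedExperiment")
}

.isAutosome <- function(chr) {
    sub("^chr", "", chr) %in% as.character(1:22)
}

.checkChromNames <- function(chr) {
    known <- grepl("^(chr)?([0-9]+|X|Y|M|MT)$", chr)
    if (any(!known))
        stop("unknown chromosome names: ",
             paste(unique(chr[!known]), collapse = ", "))
}

.completeFamilies <- function(meth, trios) {
    cnt <- integer(nrow(meth))
    for (i in seq_len(nrow(trios))) {
        ok <- !is.na(meth[, trios$father[i]]) &
              !is.na(meth[, trios$mother[i]]) &
              !is.na(meth[, trios$child[i]])
        cnt <- cnt + ok
    }
    cnt
}

#' Apply the CpG pre-filter cascade
#'
#' Sequentially removes CpGs, attributing each removal to the first failing
#' stage: (1) `non_autosome` - sites off chr1-chr22; (2) `snp_overlap` - sites
#' where either base of the CpG dinucleotide (C at `pos`, G at `pos + 1`)
#' coincides with a known SNP position, since C-to-T SNPs on either strand
#' corrupt the bisulphite call; (3) `incomplete_families` - sites observed in
#' all three members of fewer than `min_complete_families` families;
#' (4) `imprinted_region` - sites inside supplied imprinted regions, where
#' parent-of-origin methylation is expected and confounded;
#' (5) `low_coverage` - sites whose total reads over all samples fall below
#' `min_mean_cov` x number of samples (strictly; 120 reads over 12 samples is
#' kept, 119 is removed).
#'
#' @param x A [TrioMethExperiment-class].
#' @param snps SNP positions: a `GRanges` (single-base) or a
#'   `RangedSummarizedExperiment` of genotypes. Empty to skip the stage.
#' @param imprinted `GRanges` of imprinted regions. Empty to skip.
#' @param thresholds A [methThresholds()] list.
#' @return A list with `filtered` (the surviving [TrioMethExperiment-class])
#'   and `ledger` (a [FilterLedger-class] with one row per stage).
#' @export
filterCpGs <- function(x, snps = GRanges(), imprinted = GRanges(),
                       thresholds = methThresholds()) {
    stopifnot(is(x, "TrioMethExperiment"))
    chr <- as.character(seqnames(rowRanges(x)))
    .checkChromNames(chr)
    snps <- if (length(snps)) .asPositions(snps) else GRanges()

    stages <- character()
    removed <- integer()
    cur <- x
    dropStage <- function(name, drop) {
        stages <<- c(stages, name)
        removed <<- c(removed, sum(drop))
        cur[!drop]
    }

    cur <- dropStage("non_autosome",
                     !.isAutosome(as.character(seqnames(rowRanges(cur)))))
    dinuc <- resize(granges(rowRanges(cur)), width = 2L, fix = "start",
                    ignore.strand = TRUE)
    cur <- dropStage("snp_overlap",
                     overlapsAny(dinuc, snps, ignore.strand = TRUE))
    cur <- dropStage("incomplete_families",
                     .completeFamilies(methAssay(cur), trios(cur)) <
                         thresholds$min_complete_families)
    cur <- dropStage("imprinted_region",
                     overlapsAny(granges(rowRanges(cur)), imprinted,
                                 ignore.strand = TRUE))
    cur <- dropStage("low_coverage",
                     rowSums(covAssay(cur)) <
                         thresholds$min_mean_cov * ncol(cur))

    list(filtered = cur,
         ledger = FilterLedger(nrow(x), stages, removed))
}

# dosage transmission lookup, indexed [father + 1, mother + 1, child + 1]
.dosageCompatArray <- local({
    a <- array(FALSE, dim = c(3, 3, 3))
    for (f in 0:2)
        for (m in 0:2) {
            kids <- unique(as.vector(outer(.dosageGametes[[f + 1L]],
                                           .dosageGametes[[m + 1L]], "+")))
            a[f + 1L, m + 1L, kids + 1L] <- TRUE
        }
    a
})

#' Filter SNPs on missingness and Mendelian consistency
#'
#' Removes SNPs with a missing rate above `maxMissing` across samples, then
#' SNPs where in any trio with complete data the child dosage is outside the
#' one-allele-per-parent transmission set of the parents (see
#' [dosageTransmissionSet()]).
#'
#' @param genotypes A `RangedSummarizedExperiment` with assay `"dosage"`
#'   (values in `{0, 1, 2, NA}`), or a plain dosage matrix (SNPs x samples).
#' @param trios `DataFrame`/`data.frame` with `family_id`, `father`, `mother`,
#'   `child` naming columns of the dosage matrix.
#' @param maxMissing Maximum tolerated missing rate per SNP (strict >;
#'   default 2 percent).
#' @return A list with `filtered` (same class as the input) and `ledger`
#'   (stages `high_missingness`, `mendelian_inconsistent`).
#' @export
filterSnpsMendelian <- function(genotypes, trios, maxMissing = 0.02) {
    dosage <- if (is(genotypes, "SummarizedExperiment"))
        assay(genotypes, "dosage") else as.matrix(genotypes)
    if (any(!is.na(dosage) & !dosage %in% 0:2))
        stop("dosages must be in {0, 1, 2} or NA")
    trios <- as.data.frame(trios, stringsAsFactors = FALSE)

    missRate <- rowMeans(is.na(dosage))
    drop1 <- missRate > maxMissing
    kept <- !drop1

    bad <- rep(FALSE, nrow(dosage))
    for (i in seq_len(nrow(trios))) {
        f <- dosage[, trios$father[i]]
        m <- dosage[, trios$mother[i]]
        k <- dosage[, trios$child[i]]
        complete <- !is.na(f) & !is.na(m) & !is.na(k)
        idx <- which(complete & kept)
        if (length(idx))
            bad[idx] <- bad[idx] |
                !.dosageCompatArray[cbind(f[idx] + 1L, m[idx] + 1L,
                                          k[idx] + 1L)]
    }
    drop2 <- kept & bad
    keep <- kept & !bad

    list(filtered = genotypes[keep, , drop = FALSE],
         ledger = FilterLedger(nrow(dosage),
                               c("high_missingness", "mendelian_inconsistent"),
                               c(sum(drop1), sum(drop2))))
}
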