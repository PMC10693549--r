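# Exhaustive CpG x SNP association scan (mQTL), cis/trans labelling, and
# selection of "heritable" CpGs (no SNP explains them at the Bonferroni
# threshold).

# zero-variance guards: centered sums of squares below these (scale-aware,
# per observation count) are treated as constant vectors
.varTol <- function(n, scale) 1e-10 * n * (scale + 1)^2

#' Bonferroni p-value threshold for an exhaustive mQTL scan
#'
#' `alpha / (nCpg * nSnp)`, the per-test threshold controlling the family-wise
#' error rate over all CpG x SNP pairs. With the study-scale counts of 1.58
#' million CpGs and 6.06 million SNPs at alpha 0.05 this is 5e-15 at one
#' significant figure.
#'
#' @param alpha Family-wise error rate.
#' @param nCpg,nSnp Numbers of CpGs and SNPs tested.
#' @return The per-test p-value threshold.
#' @examples
#' bonferroniThreshold(0.05, 1583717, 6056211)
#' @export
bonferroniThreshold <- function(alpha, nCpg, nSnp) {
    if (alpha <= 0 || nCpg <= 0 || nSnp <= 0)
        stop("'alpha', 'nCpg' and 'nSnp' must all be positive")
    alpha / (nCpg * nSnp)
}

#' Single CpG-SNP association test
#'
#' Ordinary least-squares regression of methylation percent on additive SNP
#' dosage over pairwise-complete observations: `t = slope / SE` with `n - 2`
#' degrees of freedom, two-sided p. Pairs with fewer than 3 complete
#' observations or zero variance in either vector are flagged untestable and
#' are never significant. A perfect fit yields `t = Inf` and `p = 0`, which
#' counts as significant.
#'
#' @param meth Numeric vector of methylation percentages (NA allowed).
#' @param dosage Numeric vector of dosages in `{0, 1, 2}` (NA allowed).
#' @return List with `slope` (percent per dosage unit), `t`, `p`, `n`
#'   (complete observations) and `testable`.
#' @examples
#' associationTest(c(0, 0, 50, 50, 100, 100), c(0, 0, 1, 1, 2, 2))
#' @export
associationTest <- function(meth, dosage) {
    if (length(meth) != length(dosage))
        stop("'meth' and 'dosage' must have equal length")
    ok <- !is.na(meth) & !is.na(dosage)
    y <- as.numeric(meth[ok])
    g <- as.numeric(dosage[ok])
    n <- length(y)
    untestable <- list(slope = NA_real_, t = NA_real_, p = NA_real_,
                       n = n, testable = FALSE)
    if (n < 3L) return(untestable)
    sgg <- sum((g - mean(g))^2)
    syy <- sum((y - mean(y))^2)
    if (sgg <= .varTol(n, 2) || syy <= .varTol(n, 100)) return(untestable)
    sgy <- sum((g - mean(g)) * (y - mean(y)))
    slope <- sgy / sgg
    rss <- max(0, syy - slope * sgy)
    se <- sqrt(rss / ((n - 2) * sgg))
    t <- if (se == 0) sign(slope) * Inf else slope / se
    list(slope = slope, t = t, p = 2 * pt(-abs(t), df = n - 2), n = n,
         testable = TRUE)
}

#' Exhaustive mQTL scan and heritable-CpG selection
#'
#' Tests every (CpG, SNP) pair by OLS of methylation on additive dosage,
#' computed blockwise with a matrix formulation of pairwise-complete sums
#' (equivalent to per-pair [associationTest()]). A CpG is explained if any
#' testable pair has `p < pThreshold`; the verdict is `cis_explained` if at
#' least one significant SNP lies within `cis_window` bp on the same
#' chromosome (cis takes precedence), `trans_explained` if only distal or
#' other-chromosome SNPs are significant, and `heritable` otherwise.
#'
#' @param x A [TrioMethExperiment-class] of Mendelian CpGs.
#' @param genotypes A `RangedSummarizedExperiment` with assay `"dosage"` over
#'   the same samples.
#' @param thresholds A [methThresholds()] list (`alpha`, `cis_window`).
#' @param pThreshold Explicit per-test threshold; by default
#'   [bonferroniThreshold()] on the scanned dimensions.
#' @param blockSize CpGs per computation block.
#' @return List with `verdict` (factor per CpG, levels `cis_explained`,
#'   `trans_explained`, `heritable`), `heritable` (CpG identifiers),
#'   `pairs` (`DataFrame` of significant pairs: `cpg`, `snp`, `slope`, `t`,
#'   `p`, `label`), `counts` (named vector `mendelian`, `cis_explained`,
#'   `trans_explained`, `heritable`), `pThreshold` and `ledger` (stages
#'   `cis_mqtl`, `trans_mqtl`).
#' @export
mqtlScan <- function(x, genotypes, thresholds = methThresholds(),
                     pThreshold = NULL, blockSize = 2000L) {
    stopifnot(is(x, "TrioMethExperiment"))
    M <- methAssay(x)
    D <- if (is(genotypes, "SummarizedExperiment"))
        assay(genotypes, "dosage") else as.matrix(genotypes)
    if (!setequal(colnames(M), colnames(D)))
        stop("methylation and genotype samples differ: ",
             paste(union(setdiff(colnames(M), colnames(D)),
                         setdiff(colnames(D), colnames(M))), collapse = ", "))
    D <- D[, colnames(M), drop = FALSE]
    if (is.null(pThreshold))
        pThreshold <- bonferroniThreshold(thresholds$alpha, nrow(M), nrow(D))

    cpgChr <- as.character(seqnames(rowRanges(x)))
    cpgPos <- start(rowRanges(x))
    snpGr <- .asPositions(genotypes)
    if (length(snpGr) != nrow(D))
        stop("genotype positions do not match the dosage matrix")
    snpChr <- as.character(seqnames(snpGr))
    snpPos <- start(snpGr)
    cpgIds <- rownames(M)
    if (is.null(cpgIds)) cpgIds <- paste0("cpg", seq_len(nrow(M)))
    snpIds <- rownames(D)
    if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(nrow(D)))

    # right-hand factors, shared across blocks
    Iy <- t(!is.na(D)) * 1
    Y0 <- D; Y0[is.na(Y0)] <- 0
    tY0 <- t(Y0); tY2 <- t(Y0^2)

    hasCis <- hasTrans <- rep(FALSE, nrow(M))
    pr <- list()
    for (from in seq(1L, max(nrow(M), 1L), by = blockSize)) {
        if (nrow(M) == 0L) break
        to <- min(from + blockSize - 1L, nrow(M))
        Xb <- M[from:to, , drop = FALSE]
        Ix <- (!is.na(Xb)) * 1
        X0 <- Xb; X0[is.na(X0)] <- 0
        n <- Ix %*% Iy
        Sx <- X0 %*% Iy                 # sum of meth over complete pairs
        Sy <- Ix %*% tY0                # sum of dosage
        Sxy <- X0 %*% tY0
        Sxx <- X0^2 %*% Iy
        Syy <- Ix %*% tY2
        cxy <- Sxy - Sx * Sy / n
        cgg <- Syy - Sy^2 / n           # dosage centered SS
        cmm <- Sxx - Sx^2 / n           # methylation centered SS
        testable <- n >= 3 & cgg > .varTol(n, 2) & cmm > .varTol(n, 100)
        slope <- cxy / cgg
        rss <- pmax(0, cmm - slope * cxy)
        se <- sqrt(rss / pmax(pmax(n - 2, 1) * cgg, .Machine$double.xmin))
        tstat <- ifelse(se == 0, sign(slope) * Inf, slope / se)
        p <- 2 * pt(-abs(tstat), df = pmax(n - 2, 1))
        p[!testable] <- NA_real_
        sig <- which(testable & p < pThreshold, arr.ind = TRUE)
        if (nrow(sig)) {
            ci <- from + sig[, 1L] - 1L
            sj <- sig[, 2L]
            cis <- cpgChr[ci] == snpChr[sj] &
                abs(cpgPos[ci] - snpPos[sj]) < thresholds$cis_window
            hasCis[unique(ci[cis])] <- TRUE
            hasTrans[unique(ci[!cis])] <- TRUE
            pr[[length(pr) + 1L]] <- DataFrame(
                cpg = cpgIds[ci], snp = snpIds[sj],
                slope = slope[sig], t = tstat[sig], p = p[sig],
                label = ifelse(cis, "cis", "trans"))
        }
    }
    pairs <- if (length(pr)) do.call(rbind, pr) else
        DataFrame(cpg = character(), snp = character(), slope = numeric(),
                  t = numeric(), p = numeric(), label = character())

    verdict <- ifelse(hasCis, "cis_explained",
                      ifelse(hasTrans, "trans_explained", "heritable"))
    verdict <- factor(verdict,
                      levels = c("cis_explained", "trans_explained",
                                 "heritable"))
    names(verdict) <- cpgIds
    counts <- c(mendelian = nrow(M),
                cis_explained = sum(verdict == "cis_explained"),
                trans_explained = sum(verdict == "trans_explained"),
                heritable = sum(verdict == "heritable"))
    list(verdict = verdict,
         heritable = cpgIds[verdict == "heritable"],
         pairs = pairs,
         counts = counts,
         pThreshold = pThreshold,
         ledger = FilterLedger(nrow(M), c("cis_mqtl", "trans_mqtl"),
                               c(counts[["cis_explained"]],
                                 counts[["trans_explained"]])))
}
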