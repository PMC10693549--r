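# Selection of parent-variable, trio-compatible ("Mendelian") CpGs.

#' Parental methylation variability per CpG
#'
#' `TRUE` for a CpG iff there exists a family in which both parents are
#' observed and the absolute mother-father methylation difference strictly
#' exceeds `delta` percentage points. Families with a missing parent cannot
#' satisfy the condition.
#'
#' @param x A [TrioMethExperiment-class].
#' @param delta Strict threshold in percentage points (default 20).
#' @return Logical vector, one element per CpG.
#' @export
parentalVariability <- function(x, delta = 20) {
    meth <- methAssay(x)
    tr <- trios(x)
    out <- rep(FALSE, nrow(meth))
    for (i in seq_len(nrow(tr))) {
        d <- abs(meth[, tr$mother[i]] - meth[, tr$father[i]])
        out <- out | (!is.na(d) & d > delta)
    }
    out
}

#' Select Mendelian CpGs
#'
#' Keeps CpGs that are parent-variable (see [parentalVariability()]) and whose
#' (father, mother, child) state triple is compatible with epiallele
#' transmission in every family where all three members are observed; one
#' incompatible complete family removes the site. States are computed from the
#' observed methylation percentages via [categorizeState()]. A family with a
#' missing member at a CpG neither passes nor fails compatibility there; the
#' upstream filter guarantees at least `min_complete_families` complete
#' families, and a CpG violating that contract is an error.
#'
#' @param x A filtered [TrioMethExperiment-class].
#' @param thresholds A [methThresholds()] list (`state_low`, `state_high`,
#'   `parental_delta`, `min_complete_families`).
#' @return A list with `mendelian` (the selected [TrioMethExperiment-class]),
#'   `keep` (logical over input CpGs), and `ledger` (single-stage
#'   [FilterLedger-class], stage `non_mendelian`).
#' @export
selectMendelian <- function(x, thresholds = methThresholds()) {
    stopifnot(is(x, "TrioMethExperiment"))
    meth <- methAssay(x)
    tr <- trios(x)
    states <- matrix(as.character(categorizeState(meth, thresholds)),
                     nrow = nrow(meth), dimnames = dimnames(meth))

    ncomplete <- .completeFamilies(meth, tr)
    short <- ncomplete < thresholds$min_complete_families
    if (any(short))
        stop(sum(short), " CpG(s) have fewer than ",
             thresholds$min_complete_families,
             " complete families; run filterCpGs() first (e.g. ",
             paste(head(rownames(meth)[short], 5), collapse = ", "), ")")

    compatible <- rep(TRUE, nrow(meth))
    for (i in seq_len(nrow(tr))) {
        f <- states[, tr$father[i]]
        m <- states[, tr$mother[i]]
        k <- states[, tr$child[i]]
        idx <- which(!is.na(f) & !is.na(m) & !is.na(k))
        if (length(idx))
            compatible[idx] <- compatible[idx] &
                .compatArray[cbind(f[idx], m[idx], k[idx])]
    }

    keep <- parentalVariability(x, thresholds$parental_delta) & compatible
    list(mendelian = x[keep],
         keep = keep,
         ledger = FilterLedger(nrow(meth), "non_mendelian", sum(!keep)))
}
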