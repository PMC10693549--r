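# Flanking-region methylation scenarios and flank GC content.

#' Flanking methylation profile of each CpG
#'
#' For every CpG in the set, counts the methylated (cross-sample mean
#' methylation in \[80, 100\]), unmethylated (\[0, 20\]) and total observed
#' CpGs among the other CpGs of the set within `flankWidth` bp upstream and
#' downstream (the index CpG is excluded; intermediates count in the total
#' only). Flank methylation is judged on the cross-sample mean, the scale on
#' which regional methylation analyses operate.
#'
#' @param x A [TrioMethExperiment-class].
#' @param flankWidth Width of each flanking window in bp (default 1000).
#' @param thresholds A [methThresholds()] list (`state_low`, `state_high`).
#' @return `DataFrame` with one row per CpG: `index_mean`, and per-side counts
#'   `up_meth`, `up_unmeth`, `up_total`, `down_meth`, `down_unmeth`,
#'   `down_total`.
#' @export
flankProfile <- function(x, flankWidth = 1000,
                         thresholds = methThresholds()) {
    stopifnot(is(x, "TrioMethExperiment"))
    pos <- granges(rowRanges(x))
    meanMeth <- rowMeans(methAssay(x), na.rm = TRUE)
    meanMeth[is.nan(meanMeth)] <- NA_real_
    n <- length(pos)

    sideCounts <- function(windows) {
        h <- findOverlaps(windows, pos, ignore.strand = TRUE)
        qh <- queryHits(h)
        m <- meanMeth[subjectHits(h)]
        obs <- !is.na(m)
        DataFrame(
            meth = tabulate(qh[obs & m >= thresholds$state_high], n),
            unmeth = tabulate(qh[obs & m <= thresholds$state_low], n),
            total = tabulate(qh[obs], n))
    }
    p <- start(pos)
    up <- GRanges(seqnames(pos),
                  IRanges(start = pmax(1, p - flankWidth),
                          end = pmax(p - 1, pmax(1, p - flankWidth) - 1)))
    down <- GRanges(seqnames(pos),
                    IRanges(start = p + 1, end = p + flankWidth))
    u <- sideCounts(up)
    d <- sideCounts(down)
    DataFrame(index_mean = meanMeth,
              up_meth = u$meth, up_unmeth = u$unmeth, up_total = u$total,
              down_meth = d$meth, down_unmeth = d$unmeth,
              down_total = d$total,
              row.names = rownames(x))
}

#' Classify CpGs into flanking-region scenarios
#'
#' A side is a methylated region if strictly more than `purity` of its
#' observed flanking CpGs are methylated, an unmethylated region if more than
#' `purity` are unmethylated; sides with fewer than `minFlank` observed CpGs
#' leave the site unclassified. Scenarios: `A` (both sides methylated, index
#' methylated - an MMM region), `B` (both unmethylated, index unmethylated -
#' UUU), `C` (both methylated, index unmethylated - MUM), `D` (both
#' unmethylated, index methylated - UMU), `E` (one methylated and one
#' unmethylated side, any index state - a transition CpG). Everything else -
#' mixed flanks, or an intermediate index with concordant flanks - is
#' `unclassified`. The index state uses the cross-sample mean with the same
#' 20/80 boundaries.
#'
#' @param profile A `DataFrame` from [flankProfile()].
#' @param purity Side purity threshold (strict >; default 0.8).
#' @param minFlank Minimum observed CpGs per side (default 3).
#' @param thresholds A [methThresholds()] list.
#' @return Factor with levels `A`-`E`, `unclassified`.
#' @export
classifyFlankScenario <- function(profile, purity = 0.8, minFlank = 3,
                                  thresholds = methThresholds()) {
    side <- function(m, u, tot) {
        out <- rep(NA_character_, length(tot))
        ok <- tot >= minFlank
        out[ok] <- "mixed"
        out[ok & m / tot > purity] <- "M"
        out[ok & u / tot > purity] <- "U"
        out
    }
    up <- side(profile$up_meth, profile$up_unmeth, profile$up_total)
    down <- side(profile$down_meth, profile$down_unmeth, profile$down_total)
    im <- profile$index_mean
    idx <- rep(NA_character_, length(im))
    idx[!is.na(im) & im >= thresholds$state_high] <- "M"
    idx[!is.na(im) & im <= thresholds$state_low] <- "U"
    idx[!is.na(im) & im > thresholds$state_low &
            im < thresholds$state_high] <- "I"

    out <- rep("unclassified", length(im))
    ok <- !is.na(up) & !is.na(down) & !is.na(idx)
    out[ok & up == "M" & down == "M" & idx == "M"] <- "A"
    out[ok & up == "U" & down == "U" & idx == "U"] <- "B"
    out[ok & up == "M" & down == "M" & idx == "U"] <- "C"
    out[ok & up == "U" & down == "U" & idx == "M"] <- "D"
    out[ok & ((up == "M" & down == "U") | (up == "U" & down == "M"))] <- "E"
    factor(out, levels = c("A", "B", "C", "D", "E", "unclassified"))
}

#' GC content of the flanking window of each position
#'
#' Fraction of G + C bases in the union of the two `flankWidth` bp flanks
#' (a `2 * flankWidth` window centred on the position, index base excluded).
#' Windows are truncated at chromosome ends and the denominator adjusted to
#' the bases actually covered.
#'
#' @param x Positions: `GRanges` or [TrioMethExperiment-class].
#' @param sequences `DNAStringSet` named by chromosome.
#' @param flankWidth Flank width in bp (default 1000).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
flankGC <- function(x, sequences, flankWidth = 1000) {
    q <- .asPositions(x)
    chr <- as.character(seqnames(q))
    missing <- setdiff(unique(chr), names(sequences))
    if (length(missing))
        stop("no sequence for chromosome(s): ",
             paste(missing, collapse = ", "))
    p <- start(q)
    L <- setNames(width(sequences), names(sequences))[chr]
    if (any(p < 1 | p > L))
        stop("position(s) outside the chromosome sequence")
    out <- numeric(length(q))
    for (cn in unique(chr)) {
        i <- which(chr == cn)
        s <- sequences[[cn]]
        for (j in i) {
            lo <- max(1L, p[j] - flankWidth)
            hi <- min(length(s), p[j] + flankWidth)
            gc <- 0L
            if (p[j] - 1L >= lo)
                gc <- gc + sum(letterFrequency(subseq(s, lo, p[j] - 1L),
                                               c("G", "C")))
            if (hi >= p[j] + 1L)
                gc <- gc + sum(letterFrequency(subseq(s, p[j] + 1L, hi),
                                               c("G", "C")))
            len <- (hi - lo + 1L) - 1L
            out[j] <- if (len > 0L) gc / len else NA_real_
        }
    }
    out
}
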