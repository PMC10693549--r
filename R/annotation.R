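# Genomic context of CpG sets: distance-to-nearest, CpG island bands,
# gene regions, chromatin-state aggregation.

#' Distance from positions to the nearest interval of a track
#'
#' Gap in bp to the closest interval on the same chromosome (0 for positions
#' inside or bordering an interval), following the `distanceToNearest`
#' convention of GenomicRanges. Positions on a chromosome with no intervals
#' get `NA`.
#'
#' @param x Positions: `GRanges` or [TrioMethExperiment-class].
#' @param track `GRanges` of intervals.
#' @return Numeric vector of distances, one per position.
#' @export
distanceToTrack <- function(x, track) {
    q <- .asPositions(x)
    d <- rep(NA_real_, length(q))
    if (length(track) == 0L || length(q) == 0L) return(d)
    # positions on chromosomes absent from the track legitimately get NA;
    # silence the seqlevel-merge notice that case triggers
    h <- suppressWarnings(distanceToNearest(q, track, ignore.strand = TRUE))
    d[queryHits(h)] <- mcols(h)$distance
    d
}

#' CpG island context from distance to the nearest island
#'
#' Classifies a distance into the standard bands: `island` at 0, `shore` in
#' (0, 2 kb), `shelf` in \[2 kb, 4 kb\] (both boundaries), `open_sea` beyond
#' 4 kb. Together the four classes partition \[0, Inf).
#'
#' @param distance Non-negative distances in bp (`NA` allowed).
#' @return Factor with levels `island`, `shore`, `shelf`, `open_sea`.
#' @examples
#' cpgIslandContext(c(0, 1500, 3000, 5000))
#' @export
cpgIslandContext <- function(distance) {
    d <- as.numeric(distance)
    if (any(!is.na(d) & d < 0))
        stop("distances must be non-negative")
    out <- rep(NA_character_, length(d))
    obs <- !is.na(d)
    out[obs & d == 0] <- "island"
    out[obs & d > 0 & d < 2000] <- "shore"
    out[obs & d >= 2000 & d <= 4000] <- "shelf"
    out[obs & d > 4000] <- "open_sea"
    factor(out, levels = c("island", "shore", "shelf", "open_sea"))
}

#' Gene context of positions
#'
#' Labels each position `promoter` (within 2 kb upstream of any transcription
#' start site, strand-aware), else `exon` (inside any exon), else `intron`
#' (inside a gene body), else `intergenic`. Precedence is
#' promoter > exon > intron. Genes without strand are an error, since the
#' promoter window direction depends on it.
#'
#' @param x Positions: `GRanges` or [TrioMethExperiment-class].
#' @param genes `GRanges` of gene bodies with strand.
#' @param exons `GRanges` of exons.
#' @param promoterWidth Upstream window in bp (default 2000).
#' @return Factor with levels `promoter`, `exon`, `intron`, `intergenic`.
#' @export
geneContext <- function(x, genes, exons = GRanges(), promoterWidth = 2000) {
    q <- .asPositions(x)
    out <- rep("intergenic", length(q))
    if (length(genes)) {
        if (any(as.character(strand(genes)) == "*"))
            stop("genes must carry strand (+ or -) to place promoters")
        hit <- function(subj) suppressWarnings(
            overlapsAny(q, subj, ignore.strand = TRUE))
        out[hit(genes)] <- "intron"
        if (length(exons)) out[hit(exons)] <- "exon"
        prom <- trim(promoters(genes, upstream = promoterWidth,
                               downstream = 0))
        out[hit(prom)] <- "promoter"
    }
    factor(out, levels = c("promoter", "exon", "intron", "intergenic"))
}

.chromatinAggregates <- c("Promoter", "Poised Promoter", "Enhancer",
                          "Insulator", "Transcription", "Polycomb repressed",
                          "Heterochromatin/low signal/Repetitive/CNV")

.chromatinMap <- c(
    active_promoter = "Promoter",
    weak_promoter = "Promoter",
    poised_promoter = "Poised Promoter",
    "inactive/poised_promoter" = "Poised Promoter",
    strong_enhancer = "Enhancer",
    weak_enhancer = "Enhancer",
    "weak/poised_enhancer" = "Enhancer",
    insulator = "Insulator",
    txn_transition = "Transcription",
    txn_elongation = "Transcription",
    weak_txn = "Transcription",
    transcriptional_transition = "Transcription",
    transcriptional_elongation = "Transcription",
    weak_transcribed = "Transcription",
    repressed = "Polycomb repressed",
    polycomb_repressed = "Polycomb repressed",
    "heterochrom/lo" = "Heterochromatin/low signal/Repetitive/CNV",
    "heterochromatin/low_signal" = "Heterochromatin/low signal/Repetitive/CNV",
    "repetitive/cnv" = "Heterochromatin/low signal/Repetitive/CNV",
    "repetitive/copy_number_variation" =
        "Heterochromatin/low signal/Repetitive/CNV")

#' Aggregate 15-state chromatin segmentation labels into 7 classes
#'
#' Maps ChromHMM-style labels (optionally prefixed with their state number,
#' e.g. `"2_Weak_Promoter"`) onto the seven aggregate classes: Promoter
#' (active and weak promoter), Poised Promoter, Enhancer (strong and
#' weak/poised), Insulator, Transcription (transition, elongation, weak
#' transcribed), Polycomb repressed, and Heterochromatin/low
#' signal/Repetitive/CNV. Unknown labels are an error.
#'
#' @param labels Character vector of raw segmentation labels.
#' @return Factor with the seven aggregate levels.
#' @examples
#' aggregateChromatinState(c("Weak_Promoter", "Insulator", "Repetitive/CNV"))
#' @export
aggregateChromatinState <- function(labels) {
    key <- tolower(gsub(" ", "_", sub("^[0-9]+_", "", as.character(labels))))
    out <- .chromatinMap[key]
    bad <- is.na(out) & !is.na(labels)
    if (any(bad))
        stop("unknown chromatin-state label(s): ",
             paste(unique(labels[bad]), collapse = ", "))
    factor(unname(out), levels = .chromatinAggregates)
}

#' Annotate a CpG set with genomic context
#'
#' One-stop annotation: distance to CpG islands and the derived
#' island/shore/shelf/open-sea band, gene context, aggregated chromatin state
#' of the overlapping tile, plus distance columns for any extra tracks
#' (e.g. transcription factor binding sites). Annotation is per-position,
#' order-independent and idempotent.
#'
#' @param x Positions: `GRanges` or [TrioMethExperiment-class].
#' @param islands,genes,exons,chromatin Annotation `GRanges` (chromatin with a
#'   `state` or `name` metadata column); `NULL` to skip.
#' @param extra Named list of additional `GRanges` tracks; each contributes a
#'   `dist_<name>` column.
#' @return `DataFrame` with one row per position.
#' @export
annotateCpGs <- function(x, islands = NULL, genes = NULL, exons = NULL,
                         chromatin = NULL, extra = list()) {
    q <- .asPositions(x)
    out <- new("DFrame", nrows = length(q))
    rownames(out) <- names(q)
    if (!is.null(islands)) {
        d <- distanceToTrack(q, islands)
        out$dist_island <- d
        out$island_context <- cpgIslandContext(d)
    }
    if (!is.null(genes))
        out$gene_context <- geneContext(q, genes,
                                        if (is.null(exons)) GRanges() else exons)
    if (!is.null(chromatin)) {
        lab <- mcols(chromatin)$state
        if (is.null(lab)) lab <- mcols(chromatin)$name
        if (is.null(lab)) stop("'chromatin' needs a 'state' or 'name' column")
        h <- suppressWarnings(findOverlaps(q, chromatin, select = "first",
                                           ignore.strand = TRUE))
        raw <- ifelse(is.na(h), NA_character_, as.character(lab)[h])
        out$chromatin_state <- aggregateChromatinState(raw)
    }
    for (nm in names(extra))
        out[[paste0("dist_", nm)]] <- distanceToTrack(q, extra[[nm]])
    out
}
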