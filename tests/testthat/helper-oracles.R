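# Independent oracles and fixture builders shared across tests.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
    library(Biostrings)
})

# Brute-force epiallele transmission: each state is an explicit pair of
# epialleles (1 = methylated); every gamete combination is enumerated.
oracleOffspringStates <- function(p1, p2) {
    pairs <- list(U = c(0L, 0L), I = c(1L, 0L), M = c(1L, 1L))
    lv <- c("U", "I", "M")
    out <- character(0)
    for (a in pairs[[p1]])
        for (b in pairs[[p2]])
            out <- c(out, lv[a + b + 1L])
    lv[lv %in% out]   # in U < I < M order
}

oracleTrioCompatible <- function(f, m, k) {
    k %in% oracleOffspringStates(f, m)
}

# Closed-form correlation-to-t association oracle: t = r * sqrt((n-2)/(1-r^2))
oracleAssoc <- function(meth, dosage) {
    ok <- !is.na(meth) & !is.na(dosage)
    y <- meth[ok]; g <- dosage[ok]; n <- length(y)
    r <- suppressWarnings(cor(y, g))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(slope = r * sd(y) / sd(g), t = t,
         p = 2 * pt(-abs(t), df = n - 2), n = n)
}

# Build a TrioMethExperiment from a methylation matrix whose column names
# follow the F<k>_<role> convention; coverage defaults to 10 (0 where NA).
tmeFromMeth <- function(meth, chrom = "chr1", pos = NULL, cov = NULL) {
    meth <- as.matrix(meth)
    n <- nrow(meth)
    if (is.null(rownames(meth)))
        rownames(meth) <- sprintf("c%03d", seq_len(n))
    if (is.null(pos)) pos <- seq_len(n) * 1000L
    if (length(chrom) == 1L) chrom <- rep(chrom, n)
    if (is.null(cov)) {
        cov <- matrix(10L, n, ncol(meth), dimnames = dimnames(meth))
        cov[is.na(meth)] <- 0L
    }
    fams <- unique(sub("_(father|mother|child)$", "", colnames(meth)))
    trios <- data.frame(family_id = fams,
                        father = paste0(fams, "_father"),
                        mother = paste0(fams, "_mother"),
                        child = paste0(fams, "_child"))
    TrioMethExperiment(meth, cov, GRanges(chrom, IRanges(pos, width = 1L)),
                       trios)
}

# Representative percentages for the three states.
statePct <- c(U = 10, I = 50, M = 90)

# Methylation matrix from per-family (father, mother, child) state triples:
# states is a list of length-3 character vectors, one per family.
methFromStates <- function(stateRows) {
    meth <- do.call(rbind, lapply(stateRows, function(states)
        unlist(lapply(states, function(tri) unname(statePct[tri])))))
    fams <- paste0("F", seq_along(stateRows[[1]]))
    colnames(meth) <- as.vector(vapply(fams, function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    meth
}

# Shared simulated fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())

defaultDataset <- function() {
    if (is.null(.fixtures$default))
        .fixtures$default <- simulateTrioDataset(simConfig())
    .fixtures$default
}

# High-coverage, low-noise conditions used for parameter-recovery checks.
hifiConfig <- function(seed = 7L,
                       class_counts = c(stable = 50, cis_mqtl = 50,
                                        trans_mqtl = 50,
                                        heritable_epiallele = 50,
                                        non_mendelian = 50, imprinted = 50))
    simConfig(class_counts = class_counts, mean_coverage = 150,
              noise_sd = 1, missing_rate = 0, seed = seed)

hifiReport <- function() {
    if (is.null(.fixtures$hifi))
        .fixtures$hifi <- runPipeline(simulateTrioDataset(hifiConfig()),
                                      stages = character())
    .fixtures$hifi
}
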