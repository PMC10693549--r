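# Build a TrioMethExperiment whose cross-sample mean methylation at given
# positions equals 'means' exactly (all samples identical).
tmeFromMeans <- function(means, pos) {
    fams <- paste0("F", 1:4)
    cols <- as.vector(vapply(fams, function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    meth <- matrix(rep(means, 12), ncol = 12,
                   dimnames = list(sprintf("p%03d", seq_along(means)), cols))
    tmeFromMeth(meth, pos = pos)
}

test_that("flank profiles count methylated/unmethylated neighbours per side", {
    # index at 5000 with three methylated CpGs on each side within 1 kb
    means <- c(90, 85, 95, 50, 90, 85, 95)
    pos <- c(4100L, 4400L, 4700L, 5000L, 5300L, 5600L, 5900L)
    prof <- flankProfile(tmeFromMeans(means, pos))
    i <- 4
    expect_equal(prof$up_meth[i], 3L)
    expect_equal(prof$up_unmeth[i], 0L)
    expect_equal(prof$up_total[i], 3L)
    expect_equal(prof$down_meth[i], 3L)
    expect_equal(prof$down_total[i], 3L)
    expect_equal(unname(prof$index_mean[i]), 50)

    # mixed flank: methylated + intermediate + unmethylated
    prof2 <- flankProfile(tmeFromMeans(c(90, 50, 10, 50),
                                       c(4100L, 4500L, 4900L, 5000L)))
    expect_equal(prof2$up_meth[4], 1L)
    expect_equal(prof2$up_unmeth[4], 1L)
    expect_equal(prof2$up_total[4], 3L)

    # isolated CpG: empty flanks
    prof3 <- flankProfile(tmeFromMeans(c(50, 50), c(5000L, 500000L)))
    expect_equal(prof3$up_total, c(0L, 0L))
    expect_equal(prof3$down_total, c(0L, 0L))
})

test_that("scenario classes match their definitions on designed flanks", {
    mkProfile <- function(upM, upU, upT, downM, downU, downT, mean)
        S4Vectors::DataFrame(index_mean = mean, up_meth = upM,
                             up_unmeth = upU, up_total = upT,
                             down_meth = downM, down_unmeth = downU,
                             down_total = downT)
    cls <- function(...) as.character(classifyFlankScenario(mkProfile(...)))
    expect_equal(cls(10, 0, 10, 10, 0, 10, 92), "A")
    expect_equal(cls(0, 10, 10, 0, 10, 10, 5), "B")
    expect_equal(cls(10, 0, 10, 9, 0, 10, 10), "C")
    expect_equal(cls(0, 9, 10, 0, 10, 10, 95), "D")
    expect_equal(cls(9, 1, 10, 0, 9, 10, 50), "E")
    expect_equal(cls(9, 1, 10, 0, 9, 10, 95), "E")   # E admits any index state
    expect_equal(cls(10, 0, 10, 10, 0, 10, 50), "unclassified")  # I index, MM
    expect_equal(cls(5, 5, 10, 10, 0, 10, 92), "unclassified")   # mixed side
    expect_equal(cls(10, 0, 10, 2, 0, 2, 92), "unclassified")    # thin side
    expect_equal(cls(8, 0, 10, 10, 0, 10, 92), "unclassified")   # 0.8 not > 0.8
})

test_that("scenario classes are mutually exclusive and exhaustive on a grid", {
    grid <- expand.grid(upM = 0:10, downM = 0:10, idx = c(5, 50, 95))
    prof <- S4Vectors::DataFrame(
        index_mean = grid$idx,
        up_meth = grid$upM, up_unmeth = 10L - grid$upM,
        up_total = 10L,
        down_meth = grid$downM, down_unmeth = 10L - grid$downM,
        down_total = 10L)
    got <- classifyFlankScenario(prof)
    expect_false(any(is.na(got)))
    # independent predicate check: each combination satisfies at most one
    side <- function(m) ifelse(m / 10 > 0.8, "M",
                               ifelse((10 - m) / 10 > 0.8, "U", "x"))
    up <- side(grid$upM); down <- side(grid$downM)
    idx <- ifelse(grid$idx >= 80, "M", ifelse(grid$idx <= 20, "U", "I"))
    pred <- cbind(A = up == "M" & down == "M" & idx == "M",
                  B = up == "U" & down == "U" & idx == "U",
                  C = up == "M" & down == "M" & idx == "U",
                  D = up == "U" & down == "U" & idx == "M",
                  E = (up == "M" & down == "U") | (up == "U" & down == "M"))
    expect_true(all(rowSums(pred) <= 1))
    want <- apply(pred, 1, function(r)
        if (any(r)) colnames(pred)[which(r)] else "unclassified")
    expect_equal(as.character(got), unname(want))
})

test_that("scenario proportions over a CpG set sum to one", {
    ds <- defaultDataset()
    scen <- classifyFlankScenario(flankProfile(ds$meth))
    expect_equal(sum(prop.table(table(scen))), 1)
})

test_that("transition CpGs concentrate at methylation-domain boundaries", {
    cfg <- simConfig(class_counts = c(stable = 600),
                     chrom_lengths = c(chr1 = 1e5),
                     islands_per_chrom = 8L, island_width = 2000L,
                     imprinted_per_chrom = 0L, genes_per_chrom = 2L,
                     stable_island_frac = 0.16, mean_coverage = 30,
                     noise_sd = 3, missing_rate = 0,
                     n_background_snps = 10L, seed = 11)
    ds <- simulateTrioDataset(cfg)
    scen <- classifyFlankScenario(flankProfile(ds$meth))
    expect_gt(sum(scen == "E"), 5)
    isl <- ds$layout@islands
    edges <- sort(c(start(isl), end(isl)))
    p <- start(rowRanges(ds$meth))
    dEdge <- vapply(p, function(x) min(abs(x - edges)), numeric(1))
    nearE <- mean(dEdge[scen == "E"] <= 1000)
    nearAll <- mean(dEdge <= 1000)
    expect_gt(nearE, nearAll)  # positive enrichment at boundaries
    expect_gt(nearE, 0.9)      # transition sites hug the island edges
})

test_that("flank GC content counts G+C over the truncated window", {
    seqs <- Biostrings::DNAStringSet(c(
        chr1 = paste0(strrep("A", 1000), "CG", strrep("G", 999)),
        chr2 = strrep("GC", 1500)))
    # index at 1001 (the C): upstream 1000 A's, downstream "G" + 999 G's
    gr <- GRanges(c("chr1", "chr2"), IRanges(c(1001L, 1500L), width = 1))
    gc <- flankGC(gr, seqs)
    expect_equal(gc[1], 1000 / 2000)  # downstream all G/C, upstream none
    expect_equal(gc[2], 1)            # all-GC window
    # all-AT window
    atSeq <- Biostrings::DNAStringSet(c(chr1 = strrep("AT", 1500)))
    expect_equal(flankGC(GRanges("chr1", IRanges(1500, 1500)), atSeq), 0)
    # truncation at the chromosome start renormalizes the denominator
    gcStart <- flankGC(GRanges("chr2", IRanges(100, 100)), seqs)
    expect_equal(gcStart, 1)
    expect_error(flankGC(GRanges("chr1", IRanges(5000, 5000)), atSeq),
                 "outside")
    expect_error(flankGC(GRanges("chrZ", IRanges(1, 1)), seqs), "chrZ")
})

test_that("a 60 percent GC flank is measured exactly", {
    # 2000-base window around the index: 1200 G/C and 800 A/T
    left <- paste0(strrep("G", 600), strrep("A", 400))
    right <- paste0(strrep("C", 600), strrep("T", 400))
    seqs <- Biostrings::DNAStringSet(c(chr1 = paste0(left, "A", right)))
    expect_equal(flankGC(GRanges("chr1", IRanges(1001, 1001)), seqs), 0.6)
})
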