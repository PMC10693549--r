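test_that("the generator is deterministic under a fixed seed", {
    cfg <- simConfig(class_counts = c(stable = 10, cis_mqtl = 5,
                                      heritable_epiallele = 5),
                     n_background_snps = 20L, seed = 42)
    a <- simulateTrioDataset(cfg)
    b <- simulateTrioDataset(cfg)
    expect_identical(methAssay(a$meth), methAssay(b$meth))
    expect_identical(covAssay(a$meth), covAssay(b$meth))
    expect_identical(assay(a$genotypes, "dosage"),
                     assay(b$genotypes, "dosage"))
    expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
    expect_identical(as.character(a$layout@sequence),
                     as.character(b$layout@sequence))
})

test_that("class counts and truth bookkeeping are exact", {
    cfg <- simConfig(class_counts = c(stable = 10, cis_mqtl = 5,
                                      trans_mqtl = 5,
                                      heritable_epiallele = 5,
                                      non_mendelian = 5, imprinted = 5),
                     n_background_snps = 30L, seed = 3)
    ds <- simulateTrioDataset(cfg)
    expect_equal(nrow(ds$truth), 35L)
    expect_equal(as.vector(table(ds$truth$class)[c(
        "stable", "cis_mqtl", "trans_mqtl", "heritable_epiallele",
        "non_mendelian", "imprinted")]),
        c(10L, 5L, 5L, 5L, 5L, 5L))
    # every CpG has exactly one class; drivers exist and satisfy the
    # cis/trans geometry
    expect_true(all(ds$truth$class %in% c("stable", "cis_mqtl", "trans_mqtl",
                                          "heritable_epiallele",
                                          "non_mendelian", "imprinted")))
    snps <- ds$layout@snps
    cpgs <- rowRanges(ds$meth)
    for (i in which(!is.na(ds$truth$driver_snp))) {
        drv <- snps[ds$truth$driver_snp[i]]
        cpg <- cpgs[ds$truth$cpg_id[i]]
        sameChr <- as.character(seqnames(drv)) == as.character(seqnames(cpg))
        d <- abs(start(drv) - start(cpg))
        if (ds$truth$class[i] == "cis_mqtl")
            expect_true(sameChr && d < 1e6)
        else
            expect_true(!sameChr || d >= 1e6)
    }
    expect_error(simConfig(n_families = 0), "at least one family")
    expect_error(simConfig(class_counts = c(bogus = 3)), "unknown CpG class")
})

test_that("noise-free high-coverage heritable CpGs are trio-compatible everywhere", {
    cfg <- simConfig(class_counts = c(heritable_epiallele = 40),
                     mean_coverage = 500, noise_sd = 0, missing_rate = 0,
                     n_background_snps = 10L, seed = 5)
    ds <- simulateTrioDataset(cfg)
    st <- matrix(as.character(categorizeState(methAssay(ds$meth))),
                 nrow = nrow(ds$meth), dimnames = dimnames(ds$meth))
    tr <- trios(ds$meth)
    for (i in seq_len(nrow(st)))
        for (f in seq_len(nrow(tr)))
            expect_true(st[i, tr$child[f]] %in% oracleOffspringStates(
                st[i, tr$father[f]], st[i, tr$mother[f]]))
})

test_that("binomial read sampling is unbiased around the true level", {
    # imprinted CpGs have true level 50 in every sample
    cfg <- simConfig(class_counts = c(imprinted = 30), noise_sd = 0,
                     missing_rate = 0, n_background_snps = 10L, seed = 9)
    ds <- simulateTrioDataset(cfg)
    m <- methAssay(ds$meth)
    expect_lt(abs(mean(m, na.rm = TRUE) - 50), 4)
})

test_that("heritable CpGs are not tied to any SNP and non-Mendelian CpGs stress the filter", {
    ds <- simulateTrioDataset(simConfig(
        class_counts = c(heritable_epiallele = 50, non_mendelian = 50),
        mean_coverage = 100, noise_sd = 1, missing_rate = 0,
        n_background_snps = 100L, seed = 13))
    her <- ds$truth$cpg_id[ds$truth$class == "heritable_epiallele"]
    r <- cor(t(methAssay(ds$meth)[her, ]),
             t(assay(ds$genotypes, "dosage")))
    expect_lt(max(abs(r), na.rm = TRUE), 0.97)
    # at least one non-Mendelian CpG violates compatibility in some family
    st <- matrix(as.character(categorizeState(methAssay(ds$meth))),
                 nrow = nrow(ds$meth), dimnames = dimnames(ds$meth))
    tr <- trios(ds$meth)
    nm <- ds$truth$cpg_id[ds$truth$class == "non_mendelian"]
    viol <- vapply(nm, function(id) {
        any(vapply(seq_len(nrow(tr)), function(f)
            !st[id, tr$child[f]] %in% oracleOffspringStates(
                st[id, tr$father[f]], st[id, tr$mother[f]]),
            logical(1)))
    }, logical(1))
    expect_gt(mean(viol), 0)
})

test_that("stable CpGs are hypomethylated in islands and methylated in open sea", {
    ds <- defaultDataset()
    stable <- ds$truth$cpg_id[ds$truth$class == "stable"]
    inIsl <- overlapsAny(rowRanges(ds$meth)[stable], ds$layout@islands)
    m <- rowMeans(methAssay(ds$meth)[stable, ], na.rm = TRUE)
    expect_lt(max(m[inIsl]), 30)
    expect_gt(min(m[!inIsl]), 70)
    # island sequence is GC-rich relative to background
    gc <- letterFrequency(ds$layout@sequence, "GC", as.prob = TRUE)
    expect_true(all(gc < 0.5))
    islSeq <- ds$layout@sequence[["chr1"]]
    isl <- ds$layout@islands[seqnames(ds$layout@islands) == "chr1"][1]
    gcIsl <- sum(letterFrequency(subseq(islSeq, start(isl), end(isl)),
                                 c("G", "C"))) / width(isl)
    expect_gt(gcIsl, 0.55)
})
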