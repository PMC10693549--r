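test_that("association test handles perfect fits and degenerate input", {
    meth <- c(0, 0, 0, 0, 50, 50, 50, 50, 100, 100, 100, 100)
    dose <- c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2)
    res <- associationTest(meth, dose)
    expect_equal(res$slope, 50)
    expect_true(is.infinite(res$t))
    expect_equal(res$p, 0)
    # constant methylation: untestable, never significant
    expect_false(associationTest(rep(50, 12), dose)$testable)
    expect_false(associationTest(rep(0.1, 12), dose)$testable)
    # constant dosage: untestable
    expect_false(associationTest(meth, rep(1, 12))$testable)
    # too few complete pairs
    expect_false(associationTest(c(1, 2, NA, NA), c(0, 1, 1, 2))$testable)
})

test_that("association test equals the closed-form r-to-t oracle", {
    set.seed(101)
    for (i in 1:20) {
        meth <- runif(12, 0, 100)
        dose <- sample(0:2, 12, replace = TRUE)
        if (length(unique(dose)) == 1L) next
        got <- associationTest(meth, dose)
        want <- oracleAssoc(meth, dose)
        expect_equal(got$slope, want$slope, tolerance = 1e-12)
        expect_equal(got$t, want$t, tolerance = 1e-12)
        expect_equal(got$p, want$p, tolerance = 1e-12)
    }
    # pairwise-complete observations with n recomputed
    meth <- c(runif(10, 0, 100), NA, 30)
    dose <- c(sample(0:2, 11, replace = TRUE), NA)
    got <- associationTest(meth, dose)
    expect_equal(got$n, 10L)
    expect_equal(got$p, oracleAssoc(meth, dose)$p, tolerance = 1e-12)
})

test_that("Bonferroni threshold is alpha over the test count", {
    expect_equal(bonferroniThreshold(0.05, 1, 1), 0.05)
    expect_equal(bonferroniThreshold(0.05, 10, 100), 5e-5)
    expect_equal(signif(bonferroniThreshold(0.05, 1583717, 6056211), 1),
                 5e-15)
    expect_error(bonferroniThreshold(0.05, 0, 10), "positive")
})

test_that("the blockwise scan equals a per-pair brute-force oracle loop", {
    set.seed(202)
    fams <- paste0("F", 1:4)
    cols <- as.vector(vapply(fams, function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    meth <- matrix(runif(20 * 12, 0, 100), 20,
                   dimnames = list(sprintf("c%02d", 1:20), cols))
    meth[3, 5] <- NA  # exercise pairwise-complete handling
    cov <- matrix(10L, 20, 12, dimnames = dimnames(meth))
    cov[is.na(meth)] <- 0L
    tme <- tmeFromMeth(meth, pos = seq_len(20) * 1000L, cov = cov)
    dose <- matrix(sample(0:2, 50 * 12, replace = TRUE), 50,
                   dimnames = list(sprintf("v%02d", 1:50), cols))
    geno <- SummarizedExperiment(
        assays = list(dosage = dose),
        rowRanges = GRanges("chr2", IRanges(seq_len(50) * 500L, width = 1)))
    colnames(geno) <- cols
    scan <- mqtlScan(tme, geno, pThreshold = 2, blockSize = 7L)
    expect_equal(nrow(scan$pairs), 20L * 50L)
    key <- paste(scan$pairs$cpg, scan$pairs$snp)
    for (i in seq_len(nrow(meth)))
        for (j in seq_len(nrow(dose))) {
            want <- oracleAssoc(meth[i, ], dose[j, ])
            k <- match(paste(rownames(meth)[i], rownames(dose)[j]), key)
            expect_equal(scan$pairs$p[k], want$p, tolerance = 1e-12)
            expect_equal(scan$pairs$slope[k], want$slope, tolerance = 1e-12)
            expect_equal(scan$pairs$t[k], want$t, tolerance = 1e-12)
        }
})

test_that("cis takes precedence and verdict counts partition the input", {
    set.seed(303)
    fams <- paste0("F", 1:4)
    cols <- as.vector(vapply(fams, function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    dose <- matrix(rep(c(0L, 1L, 2L), 4), nrow = 3, ncol = 12,
                   byrow = FALSE, dimnames = list(c("cisSnp", "transSnp",
                                                    "nullSnp"), cols))
    dose[1, ] <- rep(c(0L, 1L, 2L, 1L), 3)
    dose[2, ] <- dose[1, ]                     # identical driver in trans
    dose[3, ] <- 1L
    geno <- SummarizedExperiment(
        assays = list(dosage = dose),
        rowRanges = GRanges(c("chr1", "chr2", "chr2"),
                            IRanges(c(5000L, 5000L, 9000L), width = 1)))
    colnames(geno) <- cols
    meth <- rbind(50 * dose[1, ],              # driven: cis and trans both hit
                  runif(12, 40, 60))           # undriven
    rownames(meth) <- c("driven", "undriven")
    tme <- tmeFromMeth(meth, pos = c(2000L, 3000L))
    scan <- mqtlScan(tme, geno, pThreshold = 1e-8)
    expect_equal(as.character(scan$verdict[["driven"]]), "cis_explained")
    expect_equal(as.character(scan$verdict[["undriven"]]), "heritable")
    expect_equal(sum(scan$counts[c("cis_explained", "trans_explained",
                                   "heritable")]),
                 unname(scan$counts["mendelian"]))
    expect_equal(ledgerTable(scan$ledger)$remaining[2],
                 length(scan$heritable))
})

test_that("lowering the p threshold never decreases the heritable count", {
    ds <- hifiConfig(seed = 23, class_counts = c(cis_mqtl = 20,
                                                 heritable_epiallele = 20))
    sim <- simulateTrioDataset(ds)
    filt <- filterCpGs(sim$meth, snps = sim$layout@snps,
                       imprinted = sim$layout@imprinted)$filtered
    men <- selectMendelian(filt)$mendelian
    her <- vapply(c(1e-4, 1e-8, 1e-12, 1e-30),
                  function(thr) length(mqtlScan(men, sim$genotypes,
                                                pThreshold = thr)$heritable),
                  numeric(1))
    expect_false(is.unsorted(her))
})

test_that("sample mismatches between methylation and genotypes are an error", {
    ds <- defaultDataset()
    geno <- ds$genotypes
    colnames(geno) <- sub("F1_father", "intruder", colnames(geno))
    expect_error(mqtlScan(ds$meth, geno), "samples differ")
})
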