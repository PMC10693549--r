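test_that("the cascade attributes removals to the first failing stage", {
    # 6 CpGs, 4 trios; exactly two violate exactly one rule each
    meth <- matrix(50, nrow = 6, ncol = 12)
    colnames(meth) <- as.vector(vapply(paste0("F", 1:4), function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    rownames(meth) <- paste0("s", 1:6)
    cov <- matrix(10L, 6, 12, dimnames = dimnames(meth))
    cov[6, ] <- c(9L, rep(10L, 11))       # total 119 < 120
    chrom <- c("chrX", rep("chr1", 5))    # s1 off the autosomes
    tme <- tmeFromMeth(meth, chrom = chrom, cov = cov)
    res <- filterCpGs(tme)
    tab <- ledgerTable(res$ledger)
    expect_equal(tab$stage,
                 c("non_autosome", "snp_overlap", "incomplete_families",
                   "imprinted_region", "low_coverage"))
    expect_equal(tab$remaining, c(5L, 5L, 5L, 5L, 4L))
    expect_equal(rownames(res$filtered), paste0("s", 2:5))
})

test_that("the 10x mean coverage rule is a strict total-read floor", {
    meth <- matrix(50, nrow = 2, ncol = 12)
    colnames(meth) <- as.vector(vapply(paste0("F", 1:4), function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    cov <- matrix(10L, 2, 12, dimnames = dimnames(meth))
    cov[1, 1] <- 9L   # 119 total reads: removed
    # row 2 keeps exactly 120: kept
    res <- filterCpGs(tmeFromMeth(meth, cov = cov))
    expect_equal(ledgerTable(res$ledger)$removed,
                 c(0L, 0L, 0L, 0L, 1L))
    expect_equal(nrow(res$filtered), 1L)
})

test_that("SNPs on either base of the CpG dinucleotide remove the site", {
    meth <- matrix(50, nrow = 3, ncol = 12)
    colnames(meth) <- as.vector(vapply(paste0("F", 1:4), function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    tme <- tmeFromMeth(meth, pos = c(100L, 200L, 300L))
    snps <- GRanges("chr1", IRanges(c(100, 201), width = 1))  # C of s1, G of s2
    res <- filterCpGs(tme, snps = snps)
    expect_equal(ledgerTable(res$ledger)$removed[2], 2L)
    expect_equal(nrow(res$filtered), 1L)
})

test_that("missingness and imprinted stages apply their rules", {
    meth <- matrix(50, nrow = 3, ncol = 12)
    colnames(meth) <- as.vector(vapply(paste0("F", 1:4), function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    # s1: two incomplete families -> only 2 complete, below the floor of 3
    meth[1, c("F1_father", "F2_mother")] <- NA
    tme <- tmeFromMeth(meth, pos = c(100L, 5000L, 9000L))
    impr <- GRanges("chr1", IRanges(4000, 6000))
    res <- filterCpGs(tme, imprinted = impr)
    tab <- ledgerTable(res$ledger)
    expect_equal(tab$removed[tab$stage == "incomplete_families"], 1L)
    expect_equal(tab$removed[tab$stage == "imprinted_region"], 1L)
    expect_equal(nrow(res$filtered), 1L)
})

test_that("the ledger is invariant to input row order and counts always sum", {
    ds <- defaultDataset()
    x <- ds$meth
    res1 <- filterCpGs(x, snps = ds$layout@snps,
                       imprinted = ds$layout@imprinted)
    perm <- sample(nrow(x))
    res2 <- filterCpGs(x[perm], snps = ds$layout@snps,
                       imprinted = ds$layout@imprinted)
    expect_equal(ledgerTable(res1$ledger), ledgerTable(res2$ledger))
    tab <- ledgerTable(res1$ledger)
    expect_equal(nrow(x), tail(tab$remaining, 1) + sum(tab$removed))
    expect_setequal(rownames(res1$filtered), rownames(res2$filtered))
})

test_that("unknown chromosome names are an error listing the offenders", {
    meth <- matrix(50, nrow = 1, ncol = 12)
    colnames(meth) <- as.vector(vapply(paste0("F", 1:4), function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    expect_error(filterCpGs(tmeFromMeth(meth, chrom = "scaffold_7")),
                 "scaffold_7")
})

test_that("SNP Mendelian filter drops impossible transmissions and high missingness", {
    samples <- as.vector(vapply(paste0("F", 1:4), function(f)
        paste0(f, c("_father", "_mother", "_child")), character(3)))
    trios <- data.frame(family_id = paste0("F", 1:4),
                        father = paste0("F", 1:4, "_father"),
                        mother = paste0("F", 1:4, "_mother"),
                        child = paste0("F", 1:4, "_child"))
    d <- matrix(0L, nrow = 4, ncol = 12, dimnames = list(paste0("v", 1:4),
                                                         samples))
    d[2, ] <- c(0L, 0L, 1L, rep(0L, 9))        # parents (0,0), child 1: drop
    d[3, ] <- rep(c(0L, 2L, 1L), 4)            # forced heterozygotes: keep
    d[4, 1:3] <- c(1L, NA, 1L)                 # 1/12 missing > 2%: drop
    res <- filterSnpsMendelian(d, trios)
    tab <- ledgerTable(res$ledger)
    expect_equal(tab$removed[tab$stage == "high_missingness"], 1L)
    expect_equal(tab$removed[tab$stage == "mendelian_inconsistent"], 1L)
    expect_equal(rownames(res$filtered), c("v1", "v3"))
    expect_error(filterSnpsMendelian(matrix(3L, 1, 12,
                                            dimnames = list("v", samples)),
                                     trios),
                 "dosages")
})

test_that("a fully consistent complete panel loses nothing", {
    ds <- simulateTrioDataset(simConfig(class_counts = c(stable = 5),
                                        n_background_snps = 50L,
                                        missing_rate = 0, seed = 21))
    res <- filterSnpsMendelian(ds$genotypes, trios(ds$meth))
    expect_equal(sum(ledgerTable(res$ledger)$removed), 0L)
})
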