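# Seeded synthetic trio-methylome generator with a per-CpG truth set.

.cpgClasses <- c("stable", "cis_mqtl", "trans_mqtl", "heritable_epiallele",
                 "non_mendelian", "imprinted")

# ChromHMM-style 15-state vocabulary used for the synthetic segmentation
.chromatinVocab <- c("1_Active_Promoter", "2_Weak_Promoter",
                     "3_Poised_Promoter", "4_Strong_Enhancer",
                     "5_Strong_Enhancer", "6_Weak_Enhancer",
                     "7_Weak_Enhancer", "8_Insulator", "9_Txn_Transition",
                     "10_Txn_Elongation", "11_Weak_Txn", "12_Repressed",
                     "13_Heterochrom/lo", "14_Repetitive/CNV",
                     "15_Repetitive/CNV")

#' Configuration for the synthetic trio-methylome generator
#'
#' Defaults mirror the study design the pipeline targets: 4 trios (12
#' samples), Poisson read coverage with mean 12x, Gaussian noise of 5
#' percentage points on the true methylation level, 1 percent missing calls,
#' and a genome of two 2 Mb autosomes carrying CpG islands, genes, a
#' 15-state chromatin segmentation, imprinted regions, and a SNP panel.
#' CpG classes: `stable` (constant level: 0 inside CpG islands, 100 outside,
#' which also gives the methylome its island/open-sea boundary structure),
#' `cis_mqtl` / `trans_mqtl` (50 percentage points per dosage unit of a
#' driver SNP within 1 Mb / on another chromosome), `heritable_epiallele`
#' (founder epialleles drawn independently of all genotypes, child inherits
#' one per parent, 50 points per methylated epiallele), `non_mendelian`
#' (independent per-individual levels from \{0, 50, 100\}), and `imprinted`
#' (50 percent in everyone, placed inside imprinted regions).
#'
#' @param n_families Number of trios (>= 1).
#' @param class_counts Named integer vector of CpGs per class (any subset of
#'   the six class names; absent classes default to 0).
#' @param mean_coverage Mean read coverage lambda (> 0).
#' @param noise_sd SD of Gaussian noise on true methylation, percentage
#'   points.
#' @param missing_rate Per-cell probability of masking a call (coverage set
#'   to 0).
#' @param n_background_snps SNPs unrelated to any CpG, beyond the planted
#'   drivers.
#' @param chrom_lengths Named vector of chromosome lengths; at least two
#'   autosomes are needed when `trans_mqtl` CpGs are requested.
#' @param islands_per_chrom,island_width CpG island layout.
#' @param imprinted_per_chrom,imprinted_width Imprinted-region layout.
#' @param genes_per_chrom Gene models per chromosome (3 exons each).
#' @param chromatin_tile_width Width of chromatin-state tiles.
#' @param stable_island_frac Fraction of `stable` CpGs placed inside islands.
#' @param cov_dispersion Optional negative-binomial size parameter for
#'   overdispersed coverage; `NULL` (default) for Poisson.
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(n_families = 4L,
                      class_counts = c(stable = 100L, cis_mqtl = 50L,
                                       trans_mqtl = 50L,
                                       heritable_epiallele = 50L,
                                       non_mendelian = 50L, imprinted = 20L),
                      mean_coverage = 12,
                      noise_sd = 5,
                      missing_rate = 0.01,
                      n_background_snps = 200L,
                      chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                      islands_per_chrom = 8L,
                      island_width = 1000L,
                      imprinted_per_chrom = 2L,
                      imprinted_width = 20000L,
                      genes_per_chrom = 5L,
                      chromatin_tile_width = 100000L,
                      stable_island_frac = 0.3,
                      cov_dispersion = NULL,
                      seed = 1L) {
    if (n_families < 1L) stop("need at least one family")
    bad <- setdiff(names(class_counts), .cpgClasses)
    if (length(bad))
        stop("unknown CpG class(es): ", paste(bad, collapse = ", "))
    cc <- setNames(rep(0L, length(.cpgClasses)), .cpgClasses)
    cc[names(class_counts)] <- as.integer(class_counts)
    if (any(cc < 0)) stop("class counts must be non-negative")
    if (mean_coverage <= 0) stop("'mean_coverage' must be positive")
    if (noise_sd < 0) stop("'noise_sd' must be non-negative")
    if (missing_rate < 0 || missing_rate >= 1)
        stop("'missing_rate' must be in [0, 1)")
    if (is.null(names(chrom_lengths)))
        stop("'chrom_lengths' must be named")
    structure(list(n_families = as.integer(n_families), class_counts = cc,
                   mean_coverage = mean_coverage, noise_sd = noise_sd,
                   missing_rate = missing_rate,
                   n_background_snps = as.integer(n_background_snps),
                   chrom_lengths = chrom_lengths,
                   islands_per_chrom = as.integer(islands_per_chrom),
                   island_width = as.integer(island_width),
                   imprinted_per_chrom = as.integer(imprinted_per_chrom),
                   imprinted_width = as.integer(imprinted_width),
                   genes_per_chrom = as.integer(genes_per_chrom),
                   chromatin_tile_width = as.integer(chromatin_tile_width),
                   stable_island_frac = stable_island_frac,
                   cov_dispersion = cov_dispersion,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

.resample <- function(x, k) x[sample.int(length(x), k)]

.gridIntervals <- function(chrom, len, width, gap, n, what) {
    if (n == 0L) return(GRanges())
    slots <- seq(5000L, len - width - 5000L, by = width + gap)
    if (length(slots) < n)
        stop("chromosome ", chrom, " too short for ", n, " ", what)
    GRanges(chrom, IRanges(sort(.resample(slots, n)), width = width))
}

#' Simulate a trio methylome dataset with a truth set
#'
#' Generates a [GenomeLayout-class], a [TrioMethExperiment-class] of observed
#' methylation calls, a genotype `RangedSummarizedExperiment` (assay
#' `"dosage"`), and a per-CpG truth `DataFrame`. Founder genotypes are drawn
#' from per-SNP allele frequencies and children receive one allele per parent;
#' true methylation per class is described in [simConfig()]. Observed values
#' are binomial read draws: coverage `~ Poisson(mean_coverage)` (optionally
#' negative-binomial), observed percent `= 100 * Binomial(cov, true/100) /
#' cov`, missing when coverage is 0 or the call is masked. All randomness is
#' fixed by `config$seed`; the same config yields byte-identical output.
#'
#' @param config A [simConfig()] list.
#' @return A list of class `"TrioMethDataset"` with elements `layout`,
#'   `meth`, `genotypes`, `truth`, `config`.
#' @examples
#' ds <- simulateTrioDataset(simConfig(class_counts = c(stable = 10,
#'                                                      cis_mqtl = 5)))
#' ds$meth
#' @export
simulateTrioDataset <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    nf <- config$n_families
    fam <- paste0("F", seq_len(nf))
    fathers <- paste0(fam, "_father")
    mothers <- paste0(fam, "_mother")
    children <- paste0(fam, "_child")
    samples <- as.vector(rbind(fathers, mothers, children))
    nS <- length(samples)
    trios <- DataFrame(family_id = fam, father = fathers, mother = mothers,
                       child = children)

    chrlen <- config$chrom_lengths
    chroms <- names(chrlen)
    autos <- chroms[.isAutosome(chroms)]
    si <- Seqinfo(chroms, unname(chrlen))

    islands <- suppressWarnings(do.call(c, lapply(chroms, function(cn)
        .gridIntervals(cn, chrlen[[cn]], config$island_width, 9000L,
                       config$islands_per_chrom, "CpG islands"))))
    imprinted <- suppressWarnings(do.call(c, lapply(chroms, function(cn) {
        gr <- .gridIntervals(cn, chrlen[[cn]], config$imprinted_width, 5000L,
                             max(config$imprinted_per_chrom * 3L,
                                 config$imprinted_per_chrom), "imprinted regions")
        gr <- gr[!overlapsAny(gr, islands)]
        if (length(gr) < config$imprinted_per_chrom)
            stop("not enough island-free room for imprinted regions on ", cn)
        sort(.resample(gr, config$imprinted_per_chrom))
    })))

    geneLen <- 20000L
    genes <- suppressWarnings(do.call(c, lapply(chroms, function(cn) {
        gr <- .gridIntervals(cn, chrlen[[cn]], geneLen, 12000L,
                             config$genes_per_chrom, "genes")
        if (length(gr)) {
            strand(gr) <- .resample(rep(c("+", "-"), length(gr)), length(gr))
            gr$gene_id <- sprintf("g_%s_%02d", cn, seq_along(gr))
        }
        gr
    })))
    exons <- suppressWarnings(do.call(c, lapply(seq_along(genes), function(i) {
        g <- genes[i]
        gr <- GRanges(seqnames(g),
                      IRanges(start(g) + c(0L, 8000L, 16000L), width = 1000L),
                      strand = strand(g))
        gr$gene_id <- g$gene_id
        gr
    })))
    if (is.null(exons)) exons <- GRanges()

    chromatin <- suppressWarnings(do.call(c, lapply(chroms, function(cn) {
        st <- seq(1L, chrlen[[cn]], by = config$chromatin_tile_width)
        gr <- GRanges(cn, IRanges(st, end = pmin(st +
                          config$chromatin_tile_width - 1L, chrlen[[cn]])))
        gr$state <- sample(.chromatinVocab, length(gr), replace = TRUE)
        gr
    })))

    # ---- CpG placement -------------------------------------------------
    cc <- config$class_counts
    classes <- rep(names(cc), cc)
    nC <- length(classes)
    if (nC > 0L && length(autos) == 0L)
        stop("no autosomes in 'chrom_lengths'")
    if (cc[["trans_mqtl"]] > 0L && length(autos) < 2L)
        stop("trans mQTL CpGs need at least two autosomes")
    if (cc[["imprinted"]] > 0L && length(imprinted) == 0L)
        stop("imprinted CpGs need imprinted regions in the layout")

    used <- new.env(parent = emptyenv())
    for (cn in chroms) assign(cn, integer(), envir = used)
    placeAt <- function(cn, lo, hi) {
        u <- get(cn, envir = used)
        repeat {
            p <- lo + sample.int(hi - lo + 1L, 1L) - 1L
            if (!length(u) || all(abs(u - p) >= 2L)) {
                assign(cn, c(u, p), envir = used)
                return(p)
            }
        }
    }
    forbidden <- list(
        islands = split(ranges(islands), as.character(seqnames(islands))),
        imprinted = split(ranges(imprinted),
                          as.character(seqnames(imprinted))))
    inTrack <- function(track, cn, p) {
        ir <- forbidden[[track]][[cn]]
        if (is.null(ir) || length(ir) == 0L) return(FALSE)
        any(p >= start(ir) & p <= end(ir))
    }
    placeOutside <- function(cn, avoid) {
        repeat {
            p <- placeAt(cn, 2000L, chrlen[[cn]] - 2000L)
            if (!any(vapply(avoid, inTrack, logical(1), cn = cn, p = p)))
                return(p)
            assign(cn, setdiff(get(cn, envir = used), p), envir = used)
        }
    }

    cpgChrom <- character(nC)
    cpgPos <- integer(nC)
    for (i in seq_len(nC)) {
        cls <- classes[i]
        if (cls == "imprinted") {
            reg <- imprinted[sample.int(length(imprinted), 1L)]
            cn <- as.character(seqnames(reg))
            p <- placeAt(cn, start(reg) + 1L, end(reg) - 2L)
        } else if (cls == "stable" && length(islands) &&
                   runif(1) < config$stable_island_frac) {
            isl <- islands[sample.int(length(islands), 1L)]
            cn <- as.character(seqnames(isl))
            p <- placeAt(cn, start(isl), end(isl) - 1L)
        } else {
            cn <- if (length(autos) == 1L) autos else
                autos[sample.int(length(autos), 1L)]
            p <- placeOutside(cn, c("imprinted",
                                    if (cls == "stable") "islands"))
        }
        cpgChrom[i] <- cn
        cpgPos[i] <- p
    }
    ord <- order(factor(cpgChrom, levels = chroms), cpgPos)
    cpgChrom <- cpgChrom[ord]
    cpgPos <- cpgPos[ord]
    classes <- classes[ord]
    cpgIds <- sprintf("cpg_%05d", seq_len(nC))
    cpgGr <- GRanges(cpgChrom, IRanges(cpgPos, width = 1L), seqinfo = si)
    names(cpgGr) <- cpgIds
    cpgGr$class <- classes

    # ---- SNP panel (background + planted drivers) ----------------------
    cpgTaken <- split(c(cpgPos, cpgPos + 1L), rep(cpgChrom, 2L))
    snpTaken <- new.env(parent = emptyenv())
    for (cn in chroms) assign(cn, integer(), envir = snpTaken)
    freeSnpPos <- function(cn, cand) {
        taken <- c(cpgTaken[[cn]], get(cn, envir = snpTaken))
        repeat {
            p <- cand()
            if (!p %in% taken) {
                assign(cn, c(get(cn, envir = snpTaken), p),
                       envir = snpTaken)
                return(p)
            }
        }
    }
    snpChrom <- character(0); snpPos <- integer(0); snpAf <- numeric(0)
    snpKey <- character(0)
    addSnp <- function(cn, p, af, key) {
        snpChrom <<- c(snpChrom, cn); snpPos <<- c(snpPos, p)
        snpAf <<- c(snpAf, af); snpKey <<- c(snpKey, key)
    }
    for (j in seq_len(config$n_background_snps)) {
        cn <- if (length(autos) == 1L) autos else
            autos[sample.int(length(autos), 1L)]
        p <- freeSnpPos(cn, function() sample.int(chrlen[[cn]] - 2L, 1L) + 1L)
        addSnp(cn, p, runif(1, 0.2, 0.8), paste0("bg", j))
    }
    driverKey <- rep(NA_character_, nC)
    for (i in which(classes %in% c("cis_mqtl", "trans_mqtl"))) {
        if (classes[i] == "cis_mqtl") {
            cn <- cpgChrom[i]
            p <- freeSnpPos(cn, function() {
                off <- sample(1000:500000, 1L) * sample(c(-1L, 1L), 1L)
                min(max(cpgPos[i] + off, 1000L), chrlen[[cn]] - 1000L)
            })
        } else {
            cn <- .resample(setdiff(autos, cpgChrom[i]), 1L)
            p <- freeSnpPos(cn, function() sample.int(chrlen[[cn]] - 2L, 1L) + 1L)
        }
        driverKey[i] <- paste0("drv", i)
        addSnp(cn, p, runif(1, 0.3, 0.7), driverKey[i])
    }
    nSnp <- length(snpPos)
    sord <- order(factor(snpChrom, levels = chroms), snpPos)
    snpChrom <- snpChrom[sord]; snpPos <- snpPos[sord]
    snpAf <- snpAf[sord]; snpKey <- snpKey[sord]
    snpIds <- sprintf("snp_%05d", seq_len(nSnp))
    driverId <- setNames(snpIds, snpKey)[driverKey]
    snpGr <- GRanges(snpChrom, IRanges(snpPos, width = 1L), seqinfo = si)
    names(snpGr) <- snpIds
    snpGr$snp_id <- snpIds
    snpGr$af <- snpAf

    # ---- genotypes: founders from allele frequencies, Mendelian children
    alleles <- array(NA_integer_, dim = c(nSnp, nS, 2L),
                     dimnames = list(snpIds, samples, NULL))
    for (s in c(fathers, mothers)) {
        alleles[, s, 1L] <- rbinom(nSnp, 1L, snpAf)
        alleles[, s, 2L] <- rbinom(nSnp, 1L, snpAf)
    }
    for (i in seq_len(nf)) {
        pickF <- rbinom(nSnp, 1L, 0.5) + 1L
        pickM <- rbinom(nSnp, 1L, 0.5) + 1L
        fi <- match(fathers[i], samples)
        mi <- match(mothers[i], samples)
        alleles[, children[i], 1L] <-
            alleles[cbind(seq_len(nSnp), fi, pickF)]
        alleles[, children[i], 2L] <-
            alleles[cbind(seq_len(nSnp), mi, pickM)]
    }
    dosage <- matrix(as.integer(alleles[, , 1L] + alleles[, , 2L]),
                     nrow = nSnp, ncol = nS,
                     dimnames = list(snpIds, samples))

    # ---- true methylation per class ------------------------------------
    true <- matrix(0, nrow = nC, ncol = nS,
                   dimnames = list(cpgIds, samples))
    inIsland <- overlapsAny(cpgGr, islands, ignore.strand = TRUE)
    epiRecord <- rep(NA_character_, nC)
    for (i in seq_len(nC)) {
        true[i, ] <- switch(classes[i],
            stable = if (inIsland[i]) 0 else 100,
            imprinted = 50,
            cis_mqtl = ,
            trans_mqtl = 50 * dosage[driverId[i], ],
            non_mendelian = sample(c(0, 50, 100), nS, replace = TRUE),
            heritable_epiallele = {
                v <- numeric(nS)
                rec <- character(nf)
                for (f in seq_len(nf)) {
                    fe <- rbinom(2L, 1L, 0.5)
                    me <- rbinom(2L, 1L, 0.5)
                    ce <- c(fe[sample.int(2L, 1L)], me[sample.int(2L, 1L)])
                    v[samples == fathers[f]] <- 50 * sum(fe)
                    v[samples == mothers[f]] <- 50 * sum(me)
                    v[samples == children[f]] <- 50 * sum(ce)
                    code <- function(e) paste(c("u", "m")[e + 1L],
                                              collapse = "")
                    rec[f] <- sprintf("%s=%s/%s>%s", fam[f], code(fe),
                                      code(me), code(ce))
                }
                epiRecord[i] <- paste(rec, collapse = ";")
                v
            })
    }
    if (config$noise_sd > 0 && nC > 0L)
        true <- pmin(pmax(true + rnorm(nC * nS, 0, config$noise_sd), 0), 100)

    # ---- observed calls: binomial reads over Poisson/NB coverage -------
    cov <- if (is.null(config$cov_dispersion))
        rpois(nC * nS, config$mean_coverage)
    else
        rnbinom(nC * nS, mu = config$mean_coverage,
                size = config$cov_dispersion)
    if (config$missing_rate > 0 && nC > 0L)
        cov[runif(nC * nS) < config$missing_rate] <- 0L
    cov <- matrix(as.integer(cov), nrow = nC, ncol = nS,
                  dimnames = list(cpgIds, samples))
    k <- rbinom(length(cov), as.vector(cov), as.vector(true) / 100)
    meth <- matrix(ifelse(as.vector(cov) > 0, 100 * k / as.vector(cov),
                          NA_real_),
                   nrow = nC, ncol = nS, dimnames = list(cpgIds, samples))

    # ---- sequence: 40% GC background, >60% inside islands, CG at CpGs --
    seqs <- DNAStringSet(vapply(chroms, function(cn) {
        L <- chrlen[[cn]]
        base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                       prob = c(0.30, 0.20, 0.20, 0.30))
        isl <- islands[seqnames(islands) == cn]
        for (j in seq_along(isl)) {
            idx <- start(isl)[j]:end(isl)[j]
            base[idx] <- sample(c("A", "C", "G", "T"), length(idx),
                                replace = TRUE,
                                prob = c(0.185, 0.315, 0.315, 0.185))
        }
        p <- cpgPos[cpgChrom == cn]
        base[p] <- "C"
        base[p + 1L] <- "G"
        paste(base, collapse = "")
    }, character(1)))
    names(seqs) <- chroms

    layout <- new("GenomeLayout", seqinfo = si, cpgs = cpgGr,
                  islands = islands, genes = genes, exons = exons,
                  chromatin = chromatin, imprinted = imprinted,
                  snps = snpGr, sequence = seqs)
    validObject(layout)

    tme <- TrioMethExperiment(meth, cov, cpgGr, trios)
    geno <- SummarizedExperiment(assays = list(dosage = dosage),
                                 rowRanges = snpGr,
                                 colData = colData(tme))
    truth <- DataFrame(cpg_id = cpgIds, class = classes,
                       driver_snp = unname(driverId),
                       epialleles = epiRecord)

    structure(list(layout = layout, meth = tme, genotypes = geno,
                   truth = truth, config = config),
              class = "TrioMethDataset")
}
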