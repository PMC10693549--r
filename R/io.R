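# Serialization of trio methylome datasets: per-sample methylation tables,
# VCF genotypes, PED pedigree, BED tracks, FASTA sequence, truth TSV.

.writeTsv <- function(df, path, col.names = TRUE) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = col.names)
}

#' Write a simulated trio dataset to plain-text files
#'
#' Emits, under `dir`: one bedGraph-like methylation table per sample
#' (`<sample>.meth.tsv`: chrom, 1-based pos, methylation percent, coverage;
#' `NA` percent where coverage is 0), `genotypes.vcf` (VCF 4.2 with GT
#' genotypes and an `AF` INFO field), `pedigree.ped` (family, id, father,
#' mother, sex, phenotype), BED tracks `islands.bed`, `imprinted.bed`,
#' `chromatin.bed` (name column carries the raw state label), `genes.tsv`
#' (gene models with strand and comma-separated exon bounds, 1-based),
#' `genome.fa`, and `truth.tsv`. Methylation percentages are written with
#' full precision so a write/read round trip reproduces the matrices exactly.
#'
#' @param dataset A `"TrioMethDataset"` from [simulateTrioDataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTrioDataset <- function(dataset, dir) {
    stopifnot(inherits(dataset, "TrioMethDataset"))
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory: ", dir)
    x <- dataset$meth
    lay <- dataset$layout
    chr <- as.character(seqnames(rowRanges(x)))
    pos <- start(rowRanges(x))
    meth <- methAssay(x)
    cov <- covAssay(x)
    for (s in colnames(x)) {
        con <- file(file.path(dir, paste0(s, ".meth.tsv")), "w")
        writeLines("#chrom\tpos\tmeth\tcov", con)
        if (nrow(x))
            writeLines(sprintf("%s\t%d\t%s\t%d", chr, pos,
                               ifelse(is.na(meth[, s]), "NA",
                                      sprintf("%.17g", meth[, s])),
                               cov[, s]), con)
        close(con)
    }

    # VCF 4.2, GT-only, biallelic; REF taken from the sequence where known
    geno <- dataset$genotypes
    dos <- assay(geno, "dosage")
    sgr <- rowRanges(geno)
    schr <- as.character(seqnames(sgr))
    spos <- start(sgr)
    ref <- rep("A", length(sgr))
    if (length(lay@sequence)) {
        for (cn in intersect(unique(schr), names(lay@sequence))) {
            i <- which(schr == cn)
            ref[i] <- vapply(i, function(j) as.character(
                subseq(lay@sequence[[cn]], spos[j], spos[j])), character(1))
        }
    }
    alt <- ifelse(ref == "G", "A", "G")
    gtCode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
    gt[!is.na(dos)] <- gtCode[as.character(dos[!is.na(dos)])]
    af <- if (!is.null(sgr$af)) sgr$af else rep(NA_real_, length(sgr))
    con <- file(file.path(dir, "genotypes.vcf"), "w")
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s,length=%d>",
                         seqnames(lay@seqinfo),
                         seqlengths(lay@seqinfo)),
                 "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(dos)),
                       collapse = "\t")), con)
    if (nrow(dos))
        writeLines(paste(schr, spos, rownames(dos), ref, alt, ".", "PASS",
                         sprintf("AF=%.6g", af), "GT",
                         apply(gt, 1, paste, collapse = "\t"),
                         sep = "\t"), con)
    close(con)

    tr <- as.data.frame(trios(x))
    sex <- setNames(rep(0L, ncol(x)), colnames(x))
    sex[tr$father] <- 1L
    sex[tr$mother] <- 2L
    ped <- rbind(
        data.frame(family = tr$family_id, id = tr$father, father = "0",
                   mother = "0", sex = 1L, phenotype = 0L),
        data.frame(family = tr$family_id, id = tr$mother, father = "0",
                   mother = "0", sex = 2L, phenotype = 0L),
        data.frame(family = tr$family_id, id = tr$child, father = tr$father,
                   mother = tr$mother, sex = 0L, phenotype = 0L))
    ped <- ped[order(match(ped$id, colnames(x))), ]
    .writeTsv(ped, file.path(dir, "pedigree.ped"), col.names = FALSE)

    rtracklayer::export(lay@islands, file.path(dir, "islands.bed"),
                        format = "BED")
    rtracklayer::export(lay@imprinted, file.path(dir, "imprinted.bed"),
                        format = "BED")
    chromTrack <- lay@chromatin
    if (length(chromTrack)) names(chromTrack) <- chromTrack$state
    rtracklayer::export(chromTrack, file.path(dir, "chromatin.bed"),
                        format = "BED")

    g <- lay@genes
    ex <- lay@exons
    exs <- vapply(g$gene_id, function(id)
        paste(start(ex)[ex$gene_id == id], collapse = ","), character(1))
    exe <- vapply(g$gene_id, function(id)
        paste(end(ex)[ex$gene_id == id], collapse = ","), character(1))
    .writeTsv(data.frame(gene_id = if (length(g)) g$gene_id else character(0),
                         chrom = as.character(seqnames(g)),
                         strand = as.character(strand(g)),
                         start = start(g), end = end(g),
                         exon_starts = unname(exs), exon_ends = unname(exe)),
              file.path(dir, "genes.tsv"))

    writeXStringSet(lay@sequence, file.path(dir, "genome.fa"))
    .writeTsv(as.data.frame(dataset$truth), file.path(dir, "truth.tsv"))
    invisible(dir)
}

#' Read per-sample methylation tables
#'
#' Reads the bedGraph-like tables written by [writeTrioDataset()] (chrom,
#' 1-based position, methylation percent, coverage) into matrices.
#'
#' @param files Named character vector of file paths; names are sample
#'   identifiers.
#' @return List with `meth` and `cov` matrices (CpGs x samples) and
#'   `positions` (`GRanges`). Sites must agree across samples.
#' @export
readMethTables <- function(files) {
    if (is.null(names(files))) stop("'files' must be named by sample")
    tabs <- lapply(files, function(f) {
        if (length(readLines(f)) <= 1L)
            return(data.frame(chrom = character(0), pos = integer(0),
                              meth = numeric(0), cov = integer(0)))
        read.table(f, sep = "\t", comment.char = "",
                   col.names = c("chrom", "pos", "meth", "cov"),
                   colClasses = c("character", "integer", "numeric",
                                  "integer"),
                   skip = 1L)
    })
    key <- lapply(tabs, function(t) paste(t$chrom, t$pos))
    if (!all(vapply(key, identical, logical(1), y = key[[1]])))
        stop("methylation tables disagree on CpG sites")
    meth <- do.call(cbind, lapply(tabs, `[[`, "meth"))
    cov <- do.call(cbind, lapply(tabs, `[[`, "cov"))
    colnames(meth) <- colnames(cov) <- names(files)
    gr <- GRanges(tabs[[1]]$chrom, IRanges(tabs[[1]]$pos, width = 1L))
    ids <- sprintf("cpg_%05d", seq_along(gr))
    if (length(gr)) {
        rownames(meth) <- rownames(cov) <- ids
        names(gr) <- ids
    }
    list(meth = meth, cov = cov, positions = gr)
}

#' Read a PED pedigree into a trio table
#'
#' @param path PED file (family, id, father, mother, sex, phenotype).
#' @return List with `trios` (`DataFrame`: `family_id`, `father`, `mother`,
#'   `child`) and `samples` (ids in file order).
#' @export
readPedigree <- function(path) {
    ped <- read.table(path, sep = "\t", colClasses = "character",
                      col.names = c("family", "id", "father", "mother",
                                    "sex", "phenotype"))
    kids <- ped[ped$father != "0", ]
    list(trios = DataFrame(family_id = kids$family, father = kids$father,
                           mother = kids$mother, child = kids$id),
         samples = ped$id)
}

#' Read genotype dosages from a VCF
#'
#' Parses GT genotypes with [VariantAnnotation::readVcf()] and converts them
#' to additive dosages.
#'
#' @param path VCF file.
#' @return `RangedSummarizedExperiment` with assay `"dosage"`; row ranges
#'   carry `snp_id` and, when present, the `AF` INFO field as `af`.
#' @export
readGenotypeVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
    gt <- VariantAnnotation::geno(vcf)$GT
    code <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)
    dos <- matrix(code[gt], nrow = nrow(gt), dimnames = dimnames(gt))
    gr <- granges(SummarizedExperiment::rowRanges(vcf))
    mcols(gr) <- NULL
    gr$snp_id <- names(gr)
    af <- VariantAnnotation::info(vcf)$AF
    if (!is.null(af)) gr$af <- as.numeric(unlist(af))
    SummarizedExperiment(assays = list(dosage = dos), rowRanges = gr)
}

#' Read a written trio dataset back into memory
#'
#' Inverse of [writeTrioDataset()]: reconstructs the methylation experiment,
#' genotypes, truth table and annotation tracks from a directory. The
#' round trip reproduces the in-memory matrices exactly.
#'
#' @param dir Directory written by [writeTrioDataset()].
#' @return List with `meth` ([TrioMethExperiment-class]), `genotypes`,
#'   `truth`, and the annotation tracks (`islands`, `imprinted`, `chromatin`,
#'   `genes`, `exons`, `sequence`).
#' @export
readTrioDataset <- function(dir) {
    if (!dir.exists(dir)) stop("no such directory: ", dir)
    ped <- readPedigree(file.path(dir, "pedigree.ped"))
    files <- setNames(file.path(dir, paste0(ped$samples, ".meth.tsv")),
                      ped$samples)
    mt <- readMethTables(files)
    tme <- TrioMethExperiment(mt$meth, mt$cov, mt$positions, ped$trios)

    geno <- readGenotypeVcf(file.path(dir, "genotypes.vcf"))
    islands <- rtracklayer::import(file.path(dir, "islands.bed"),
                                   format = "BED")
    imprinted <- rtracklayer::import(file.path(dir, "imprinted.bed"),
                                     format = "BED")
    chromatin <- rtracklayer::import(file.path(dir, "chromatin.bed"),
                                     format = "BED")
    if (length(chromatin)) chromatin$state <- chromatin$name
    gtab <- read.table(file.path(dir, "genes.tsv"), sep = "\t",
                       header = TRUE, colClasses = c(
                           "character", "character", "character", "integer",
                           "integer", "character", "character"))
    genes <- GRanges(gtab$chrom, IRanges(gtab$start, gtab$end),
                     strand = gtab$strand, gene_id = gtab$gene_id)
    exons <- if (nrow(gtab)) suppressWarnings(do.call(c,
        lapply(seq_len(nrow(gtab)), function(i) {
            st <- as.integer(strsplit(gtab$exon_starts[i], ",")[[1]])
            en <- as.integer(strsplit(gtab$exon_ends[i], ",")[[1]])
            GRanges(gtab$chrom[i], IRanges(st, en),
                    strand = gtab$strand[i], gene_id = gtab$gene_id[i])
        }))) else GRanges()
    truth <- as(read.table(file.path(dir, "truth.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character"),
                "DataFrame")
    sequence <- readDNAStringSet(file.path(dir, "genome.fa"))
    names(sequence) <- sub(" .*", "", names(sequence))
    list(meth = tme, genotypes = geno, truth = truth, islands = islands,
         imprinted = imprinted, chromatin = chromatin, genes = genes,
         exons = exons, sequence = sequence)
}
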