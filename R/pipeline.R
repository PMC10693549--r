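# End-to-end orchestration: filter -> Mendelian selection -> mQTL scan ->
# annotation -> flanking scenarios -> clustering, with the combined ledger
# and (for simulated data) truth-set evaluation.

#' Run the trio methylation-inheritance pipeline
#'
#' Applies, in order: the CpG pre-filter cascade ([filterCpGs()]), the
#' SNP-side Mendelian filter ([filterSnpsMendelian()]), Mendelian CpG
#' selection ([selectMendelian()]), the exhaustive mQTL scan ([mqtlScan()]),
#' genomic annotation ([annotateCpGs()]), flanking-scenario classification
#' ([flankProfile()], [classifyFlankScenario()]) and subject clustering
#' ([clusterSubjects()]). The combined [FilterLedger-class] chains every
#' stage, so the final remainder is the heritable CpG count
#' (Mendelian - cis mQTL - trans mQTL). Deterministic given the dataset (or
#' simulation config, which carries its own seed).
#'
#' @param dataset A `"TrioMethDataset"` (from [simulateTrioDataset()] or
#'   assembled from [readTrioDataset()] output); alternatively `NULL` with
#'   `sim` supplied.
#' @param sim A [simConfig()] to simulate a dataset when `dataset` is `NULL`.
#' @param thresholds A [methThresholds()] list.
#' @param pThreshold Optional explicit mQTL p-value threshold (default:
#'   Bonferroni over the scanned grid).
#' @param snpTrack SNP positions for the CpG overlap filter; default: the
#'   dataset's full SNP panel. Pass `GRanges()` to disable the stage.
#' @param imprintedTrack Imprinted regions; default from the dataset layout.
#'   Pass `GRanges()` to disable.
#' @param stages Character subset of
#'   `c("annotate", "flanking", "clustering")` toggling the descriptive
#'   stages (the core filter/Mendelian/mQTL chain always runs).
#' @param outDir Optional directory; when given, result tables are written
#'   as TSV/BED/Newick files.
#' @return A list of class `"TrioMethReport"`: `ledger`, `filtered`,
#'   `mendelian`, `scan`, `heritable` (CpG ids), `status` (per input CpG),
#'   `annotation`, `scenarios`, `scenarioTable`, `clustering`, `snpLedger`,
#'   `evaluation` (when the dataset has a truth table), `timings`.
#' @export
runPipeline <- function(dataset = NULL, sim = NULL,
                        thresholds = methThresholds(), pThreshold = NULL,
                        snpTrack = NULL, imprintedTrack = NULL,
                        stages = c("annotate", "flanking", "clustering"),
                        outDir = NULL) {
    t0 <- proc.time()[["elapsed"]]
    if (is.null(dataset)) {
        if (is.null(sim)) stop("supply 'dataset' or 'sim'")
        dataset <- simulateTrioDataset(sim)
    }
    x <- dataset$meth
    lay <- dataset$layout
    if (is.null(snpTrack))
        snpTrack <- if (!is.null(lay)) lay@snps else GRanges()
    if (is.null(imprintedTrack))
        imprintedTrack <- if (!is.null(lay)) lay@imprinted else GRanges()

    timings <- c(setup = proc.time()[["elapsed"]] - t0)
    tick <- function(name) {
        timings[name] <<- proc.time()[["elapsed"]] - t0 - sum(timings)
    }

    gf <- filterSnpsMendelian(dataset$genotypes, trios(x))
    tick("snp_filter")
    fc <- filterCpGs(x, snps = snpTrack, imprinted = imprintedTrack,
                     thresholds = thresholds)
    tick("cpg_filter")
    sm <- selectMendelian(fc$filtered, thresholds)
    tick("mendelian")
    sc <- mqtlScan(sm$mendelian, gf$filtered, thresholds, pThreshold)
    tick("mqtl_scan")

    led <- FilterLedger(nrow(x),
                        c(fc$ledger@stages, sm$ledger@stages,
                          sc$ledger@stages),
                        c(fc$ledger@removed, sm$ledger@removed,
                          sc$ledger@removed))

    # per-CpG fate over the full input
    status <- setNames(rep("removed_prefilter", nrow(x)), rownames(x))
    status[rownames(fc$filtered)] <- "non_mendelian"
    status[rownames(sm$mendelian)] <- as.character(
        sc$verdict[rownames(sm$mendelian)])

    annotation <- NULL
    if ("annotate" %in% stages && !is.null(lay)) {
        annotation <- annotateCpGs(fc$filtered, islands = lay@islands,
                                   genes = lay@genes, exons = lay@exons,
                                   chromatin = lay@chromatin)
        annotation$group <- ifelse(
            rownames(fc$filtered) %in% sc$heritable, "heritable",
            ifelse(rownames(fc$filtered) %in% rownames(sm$mendelian),
                   "mendelian", "filtered"))
        tick("annotate")
    }

    scenarios <- scenarioTable <- NULL
    if ("flanking" %in% stages) {
        prof <- flankProfile(fc$filtered, thresholds$flank_width, thresholds)
        scen <- classifyFlankScenario(prof, thresholds$flank_purity,
                                      thresholds$min_flank_cpgs, thresholds)
        scenarios <- DataFrame(prof, scenario = scen)
        grp <- factor(ifelse(rownames(fc$filtered) %in% sc$heritable,
                             "heritable",
                             ifelse(rownames(fc$filtered) %in%
                                        rownames(sm$mendelian),
                                    "mendelian", "filtered")),
                      levels = c("filtered", "mendelian", "heritable"))
        scenarioTable <- table(scenario = scen, group = grp)
        tick("flanking")
    }

    clustering <- NULL
    if ("clustering" %in% stages && nrow(sm$mendelian) > 0L)
        clustering <- tryCatch(clusterSubjects(sm$mendelian),
                               error = function(e) NULL)
    tick("clustering")

    evaluation <- NULL
    if (!is.null(dataset$truth) && nrow(dataset$truth) > 0L)
        evaluation <- evaluateAgainstTruth(status, dataset$truth)

    report <- structure(list(
        ledger = led, filtered = fc$filtered, mendelian = sm$mendelian,
        scan = sc, heritable = sc$heritable, status = status,
        annotation = annotation, scenarios = scenarios,
        scenarioTable = scenarioTable, clustering = clustering,
        snpLedger = gf$ledger, evaluation = evaluation,
        timings = timings), class = "TrioMethReport")
    if (!is.null(outDir)) .writeReport(report, outDir)
    report
}

.writeReport <- function(report, outDir) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory: ", outDir)
    .writeTsv(as.data.frame(ledgerTable(report$ledger)),
              file.path(outDir, "ledger.tsv"))
    .writeTsv(as.data.frame(ledgerTable(report$snpLedger)),
              file.path(outDir, "snp_ledger.tsv"))
    her <- rowRanges(report$mendelian)[
        rownames(report$mendelian) %in% report$heritable]
    rtracklayer::export(her, file.path(outDir, "heritable.bed"),
                        format = "BED")
    rtracklayer::export(granges(rowRanges(report$mendelian)),
                        file.path(outDir, "mendelian.bed"), format = "BED")
    .writeTsv(data.frame(cpg = names(report$status),
                         status = unname(report$status)),
              file.path(outDir, "status.tsv"))
    .writeTsv(as.data.frame(report$scan$pairs),
              file.path(outDir, "mqtl_pairs.tsv"))
    if (!is.null(report$annotation))
        .writeTsv(cbind(cpg = rownames(report$filtered),
                        as.data.frame(report$annotation)),
                  file.path(outDir, "annotation.tsv"))
    if (!is.null(report$scenarios))
        .writeTsv(cbind(cpg = rownames(report$filtered),
                        as.data.frame(report$scenarios)),
                  file.path(outDir, "scenarios.tsv"))
    if (!is.null(report$clustering) && !is.null(report$clustering$newick))
        writeLines(report$clustering$newick,
                   file.path(outDir, "dendrogram.nwk"))
    if (!is.null(report$evaluation))
        .writeTsv(as.data.frame(report$evaluation$metrics),
                  file.path(outDir, "evaluation.tsv"))
    invisible(outDir)
}

#' Evaluate pipeline calls against the planted truth
#'
#' Cross-tabulates the per-CpG pipeline fate against the simulated class
#' labels and computes recovery metrics: sensitivity = planted
#' heritable-epiallele CpGs called heritable / planted; false discovery =
#' fraction of called-heritable CpGs planted as any other class; and the
#' fraction of planted mQTL CpGs not called heritable.
#'
#' @param status Named character vector of per-CpG fates (names = CpG ids,
#'   values in `removed_prefilter`, `non_mendelian`, `cis_explained`,
#'   `trans_explained`, `heritable`), e.g. `report$status`.
#' @param truth Truth `DataFrame` with `cpg_id` and `class`.
#' @return List with `metrics` (per class: `n`, `n_mendelian`,
#'   `n_heritable`), `table` (class x fate), `sensitivity`,
#'   `fdr`, `mqtl_removed_frac`.
#' @export
evaluateAgainstTruth <- function(status, truth) {
    if (inherits(status, "TrioMethReport")) status <- status$status
    missing <- setdiff(truth$cpg_id, names(status))
    if (length(missing))
        stop("truth CpGs absent from results: ",
             paste(head(missing, 5), collapse = ", "))
    fate <- factor(status[truth$cpg_id],
                   levels = c("removed_prefilter", "non_mendelian",
                              "cis_explained", "trans_explained",
                              "heritable"))
    cls <- factor(truth$class, levels = .cpgClasses)
    tab <- table(class = cls, fate = fate)
    mendelianFates <- c("cis_explained", "trans_explained", "heritable")
    metrics <- DataFrame(
        class = levels(cls),
        n = as.integer(table(cls)),
        n_mendelian = as.integer(rowSums(tab[, mendelianFates,
                                             drop = FALSE])),
        n_heritable = as.integer(tab[, "heritable"]))
    planted <- metrics$n[metrics$class == "heritable_epiallele"]
    recovered <- metrics$n_heritable[metrics$class == "heritable_epiallele"]
    sensitivity <- if (planted > 0) recovered / planted else NA_real_
    called <- sum(metrics$n_heritable)
    fdr <- if (called > 0) 1 - recovered / called else NA_real_
    mqtlN <- sum(metrics$n[metrics$class %in% c("cis_mqtl", "trans_mqtl")])
    mqtlHer <- sum(metrics$n_heritable[
        metrics$class %in% c("cis_mqtl", "trans_mqtl")])
    list(metrics = metrics, table = tab, sensitivity = sensitivity,
         fdr = fdr,
         mqtl_removed_frac = if (mqtlN > 0) 1 - mqtlHer / mqtlN else NA_real_)
}
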