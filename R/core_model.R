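#' Analysis thresholds for trio methylation inheritance
#'
#' Bundles every tunable cutoff of the pipeline with its conventional default:
#' state boundaries at 20/80 percent (a site is U at <= 20, M at >= 80, I in
#' between), a parental methylation difference of > 20 percentage points to
#' call a site parent-variable, a mean-coverage floor of 10x (total reads >=
#' 10 x number of samples), at least 3 families with complete trio data, a
#' 1 Mb cis window for mQTL labelling, family-wise alpha 0.05 for the
#' Bonferroni threshold, 1 kb flanking windows with > 80 percent purity and at
#' least 3 observed CpGs per side for scenario classification.
#'
#' @param state_low Percent at or below which a site is unmethylated (U).
#' @param state_high Percent at or above which a site is methylated (M).
#' @param parental_delta Strict parental difference, percentage points.
#' @param min_mean_cov Minimum mean read coverage per sample.
#' @param min_complete_families Minimum number of families with data for all
#'   three members.
#' @param cis_window Maximum CpG-SNP distance (bp) for a cis mQTL.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param flank_width Width (bp) of each flanking window.
#' @param flank_purity Fraction of flanking CpGs (strict >) that must share a
#'   state for a side to count as a methylated/unmethylated region.
#' @param min_flank_cpgs Minimum observed flanking CpGs per side.
#' @return A named list of class `"MethThresholds"`.
#' @examples
#' th <- methThresholds()
#' th$min_mean_cov * 12  # total-read floor for 12 samples
#' @export
methThresholds <- function(state_low = 20, state_high = 80,
                           parental_delta = 20, min_mean_cov = 10,
                           min_complete_families = 3, cis_window = 1e6,
                           alpha = 0.05, flank_width = 1000,
                           flank_purity = 0.8, min_flank_cpgs = 3) {
    if (!(state_low > 0 && state_low < state_high && state_high < 100))
        stop("need 0 < state_low < state_high < 100")
    if (parental_delta < 0 || min_mean_cov < 0 || min_complete_families < 0 ||
        cis_window <= 0 || flank_width <= 0 || min_flank_cpgs < 0)
        stop("thresholds must be non-negative (windows strictly positive)")
    if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
    if (flank_purity <= 0 || flank_purity >= 1)
        stop("'flank_purity' must be in (0, 1)")
    structure(list(state_low = state_low, state_high = state_high,
                   parental_delta = parental_delta,
                   min_mean_cov = min_mean_cov,
                   min_complete_families = min_complete_families,
                   cis_window = cis_window, alpha = alpha,
                   flank_width = flank_width, flank_purity = flank_purity,
                   min_flank_cpgs = min_flank_cpgs),
              class = "MethThresholds")
}

.stateLevels <- c("U", "I", "M")

#' Categorize methylation percentages into U / I / M states
#'
#' A site is unmethylated (U) at or below `state_low` percent, methylated (M)
#' at or above `state_high`, and intermediate (I) strictly in between; the
#' boundary values themselves belong to U and M. Missing input yields `NA`.
#'
#' @param meth Numeric vector of methylation percentages in \[0, 100\]
#'   (`NA` allowed).
#' @param thresholds A [methThresholds()] list.
#' @return Ordered factor with levels `U < I < M` (`NA` for missing input).
#' @examples
#' categorizeState(c(0, 20, 50, 80, 100, NA))
#' @export
categorizeState <- function(meth, thresholds = methThresholds()) {
    m <- as.numeric(meth)
    bad <- !is.na(m) & (m < 0 | m > 100)
    if (any(bad))
        stop("methylation percent outside [0, 100]: ",
             paste(head(unique(m[bad])), collapse = ", "))
    out <- rep(NA_character_, length(m))
    obs <- !is.na(m)
    out[obs & m <= thresholds$state_low] <- "U"
    out[obs & m > thresholds$state_low & m < thresholds$state_high] <- "I"
    out[obs & m >= thresholds$state_high] <- "M"
    factor(out, levels = .stateLevels, ordered = TRUE)
}

# Gametes of the diploid epiallele model: U = uu, I = mu, M = mm; each value
# is the number of methylated epialleles a gamete can carry.
.gametes <- list(U = 0L, I = c(0L, 1L), M = 1L)

.checkStates <- function(x, what) {
    x <- as.character(x)
    if (any(is.na(x)))
        stop(what, " state is missing; resolve missingness upstream")
    bad <- !x %in% .stateLevels
    if (any(bad))
        stop(what, " state must be one of U, I, M; got: ",
             paste(unique(x[bad]), collapse = ", "))
    x
}

#' Offspring methylation states reachable from two parental states
#'
#' Under the diploid epiallele model (M = mm, I = mu, U = uu) the child draws
#' one epiallele from each parent; the reachable child states are the distinct
#' sums of one gamete per parent. The function is symmetric in its arguments.
#'
#' @param parent1,parent2 Single states, each one of `"U"`, `"I"`, `"M"`
#'   (factors accepted). Missing states are an error.
#' @return Ordered factor of the reachable child states, sorted `U < I < M`.
#' @examples
#' punnettOffspringStates("M", "U")  # I only
#' punnettOffspringStates("I", "I")  # U, I, M
#' @export
punnettOffspringStates <- function(parent1, parent2) {
    if (length(parent1) != 1L || length(parent2) != 1L)
        stop("'parent1' and 'parent2' must be single states")
    p1 <- .checkStates(parent1, "parental")
    p2 <- .checkStates(parent2, "parental")
    counts <- unique(as.vector(outer(.gametes[[p1]], .gametes[[p2]], "+")))
    sort(factor(.stateLevels[counts + 1L], levels = .stateLevels,
                ordered = TRUE))
}

# 3 x 3 x 3 lookup: compat[father, mother, child], built from the
# transmission model above at install time.
.compatArray <- local({
    a <- array(FALSE, dim = c(3, 3, 3),
               dimnames = list(.stateLevels, .stateLevels, .stateLevels))
    for (f in .stateLevels)
        for (m in .stateLevels) {
            counts <- unique(as.vector(outer(.gametes[[f]], .gametes[[m]], "+")))
            a[f, m, .stateLevels[counts + 1L]] <- TRUE
        }
    a
})

#' Is a trio's state pattern compatible with epiallele transmission?
#'
#' `TRUE` iff the child state is reachable from the parental states under
#' one-epiallele-per-parent transmission (see [punnettOffspringStates()]).
#' Vectorized over triples; any missing state is an error, since missingness
#' must be handled by the upstream completeness filter.
#'
#' @param father,mother,child Vectors of states in `{U, I, M}` (equal length).
#' @return Logical vector.
#' @examples
#' trioCompatible("M", "U", "I")  # TRUE
#' trioCompatible("M", "U", "M")  # FALSE
#' @export
trioCompatible <- function(father, mother, child) {
    f <- .checkStates(father, "father")
    m <- .checkStates(mother, "mother")
    k <- .checkStates(child, "child")
    if (length(f) != length(m) || length(f) != length(k))
        stop("state vectors must have equal length")
    if (length(f) == 0L) return(logical(0))
    .compatArray[cbind(f, m, k)]
}

#' Full trio-compatibility truth table
#'
#' Enumerates all 27 ordered (father, mother, child) state triples with their
#' compatibility verdict under the epiallele transmission model. Exactly 15
#' triples are compatible.
#'
#' @return `DataFrame` with columns `father`, `mother`, `child`, `compatible`.
#' @examples
#' tab <- compatibilityTable()
#' sum(tab$compatible)  # 15
#' @export
compatibilityTable <- function() {
    g <- expand.grid(child = .stateLevels, mother = .stateLevels,
                     father = .stateLevels, stringsAsFactors = FALSE)
    g <- g[, c("father", "mother", "child")]
    DataFrame(father = g$father, mother = g$mother, child = g$child,
              compatible = trioCompatible(g$father, g$mother, g$child))
}

# Gamete model for SNP dosages: 0 -> ref/ref, 1 -> het, 2 -> alt/alt. Same
# algebra as the epiallele model under the mapping 0=U, 1=I, 2=M.
.dosageGametes <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)

#' Child dosages reachable from two parental dosages
#'
#' One-allele-per-parent transmission for biallelic SNP dosages: parents with
#' dosages 0 and 0 admit only 0, 0 and 2 force a heterozygote, etc. Identical
#' to [punnettOffspringStates()] under the mapping 0 = U, 1 = I, 2 = M.
#'
#' @param dosage1,dosage2 Single parental dosages in `{0, 1, 2}`.
#' @return Sorted integer vector of reachable child dosages.
#' @examples
#' dosageTransmissionSet(0, 2)  # 1
#' @export
dosageTransmissionSet <- function(dosage1, dosage2) {
    for (d in c(dosage1, dosage2))
        if (length(d) != 1L || is.na(d) || !d %in% 0:2)
            stop("dosages must be single values in {0, 1, 2}")
    sort(unique(as.vector(outer(.dosageGametes[[as.character(dosage1)]],
                                .dosageGametes[[as.character(dosage2)]],
                                "+"))))
}
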