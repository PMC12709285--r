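## Adaptation-mode bookkeeping: quartet enumeration, mode and
## selection-strength tallies per ploidy, and the 2x2 contingency tests
## (continuity-corrected chi-square, Fisher exact) used to compare them.
## Mode assignments come from composite-likelihood model fits performed
## upstream; this module consumes their per-case output table
## (gene, quartet, ploidy, best mode, maxSel bin, composite log-likelihood).

MODE_LEVELS <- c("neutral", "denovo", "standing", "migration")

#' Enumerate population quartets
#'
#' A quartet is an unordered pair of calcareous/siliceous contrasts of the
#' same ploidy whose lineages differ: the unit over which repeated
#' adaptation modes are inferred. Six lineage-distinct contrasts give 15
#' quartets, four give 6.
#'
#' @param contrasts data.frame with `pair_id`, `lineage`, `ploidy`.
#' @return data.frame: quartet_id, ploidy, pair1, pair2.
#' @export
enumerateQuartets <- function(contrasts) {
    out <- list()
    for (pl in sort(unique(contrasts$ploidy))) {
        sub <- contrasts[contrasts$ploidy == pl, , drop = FALSE]
        if (nrow(sub) < 2) {
            warning("fewer than two contrasts for ploidy ", pl)
            next
        }
        cmb <- utils::combn(nrow(sub), 2)
        for (j in seq_len(ncol(cmb))) {
            a <- cmb[1, j]; b <- cmb[2, j]
            if (sub$lineage[a] == sub$lineage[b]) next
            out[[length(out) + 1L]] <- data.frame(
                quartet_id = paste(sub$pair_id[a], sub$pair_id[b], sep = "~"),
                ploidy = pl, pair1 = sub$pair_id[a], pair2 = sub$pair_id[b])
        }
    }
    if (!length(out))
        return(data.frame(quartet_id = character(), ploidy = integer(),
                          pair1 = character(), pair2 = character()))
    do.call(rbind, out)
}

#' Read an adaptation-mode case table
#'
#' @param path TSV with columns gene_id, quartet_id, ploidy, mode, maxSel,
#'   and optionally mcl.
#' @return validated data.frame.
#' @export
readModeCases <- function(path) {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "quartet_id", "ploidy", "mode", "maxSel")
                  %in% names(x)))
    if (!all(x$mode %in% MODE_LEVELS))
        stop("unknown mode label in case table", call. = FALSE)
    if (!all(x$maxSel %in% .SEL_BINS))
        stop("maxSel outside the fixed bin set", call. = FALSE)
    x
}

#' Tally adaptation modes per ploidy
#'
#' Neutral cases are excluded; counts and fractions (over each ploidy's
#' non-neutral total) are reported for every non-neutral mode, including
#' zero-count ones.
#'
#' @param cases data.frame as from [readModeCases()].
#' @return data.frame: ploidy, mode, n, fraction.
#' @export
tallyModes <- function(cases) {
    cases <- cases[cases$mode != "neutral", , drop = FALSE]
    modes <- setdiff(MODE_LEVELS, "neutral")
    out <- list()
    for (pl in c(2L, 4L)) {
        sub <- cases[cases$ploidy == pl, , drop = FALSE]
        n <- vapply(modes, function(m) sum(sub$mode == m), 0L)
        out[[length(out) + 1L]] <- data.frame(
            ploidy = pl, mode = modes, n = n,
            fraction = if (nrow(sub) > 0) n / nrow(sub) else 0)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Continuity-corrected chi-square test for a 2x2 table
#'
#' Yates-corrected statistic
#' `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the corrected term
#' clamped at 0 when `|ad - bc| < N/2`; p-value from the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param tab 2x2 matrix of non-negative integer counts; all margins must be
#'   positive.
#' @return list: statistic, df, p.
#' @export
yatesChisq <- function(tab) {
    stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0),
              all(tab == round(tab)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("zero margin in table: ",
             paste(as.vector(tab), collapse = ","), call. = FALSE)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    N <- sum(tab)
    num <- max(abs(a * d - b * c) - N / 2, 0)
    stat <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
    list(statistic = stat, df = 1L,
         p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-tailed p sums the probabilities of all
#' tables with fixed margins whose probability does not exceed the observed
#' one.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @param two_tailed logical (default `TRUE`; otherwise upper tail).
#' @return p-value.
#' @export
fisherExact2x2 <- function(tab, two_tailed = TRUE) {
    stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("empty row or column in table", call. = FALSE)
    stats::fisher.test(tab, alternative =
        if (two_tailed) "two.sided" else "greater")$p.value
}

#' Selection-strength bins per ploidy with per-bin ploidy tests
#'
#' Proportion of cases per maxSel bin for each ploidy (bins absent from the
#' input are reported as 0, not dropped) and, per bin, a Fisher exact test
#' of ploidy x (bin vs rest). Neutral cases are excluded.
#'
#' @param cases data.frame as from [readModeCases()].
#' @return list: `proportions` (ploidy, maxSel, n, fraction), `tests`
#'   (maxSel, p; `NA` when a margin is empty).
#' @export
binSelectionStrength <- function(cases) {
    cases <- cases[cases$mode != "neutral", , drop = FALSE]
    props <- list()
    for (pl in c(2L, 4L)) {
        sub <- cases[cases$ploidy == pl, , drop = FALSE]
        n <- vapply(.SEL_BINS, function(b) sum(sub$maxSel == b), 0L)
        props[[length(props) + 1L]] <- data.frame(
            ploidy = pl, maxSel = .SEL_BINS, n = n,
            fraction = if (nrow(sub) > 0) n / nrow(sub) else 0)
    }
    props <- do.call(rbind, props)
    tests <- data.frame(maxSel = .SEL_BINS, p = NA_real_)
    for (i in seq_along(.SEL_BINS)) {
        b <- .SEL_BINS[i]
        tab <- rbind(
            c(sum(cases$ploidy == 2 & cases$maxSel == b),
              sum(cases$ploidy == 2 & cases$maxSel != b)),
            c(sum(cases$ploidy == 4 & cases$maxSel == b),
              sum(cases$ploidy == 4 & cases$maxSel != b)))
        if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
            tests$p[i] <- fisherExact2x2(tab)
    }
    list(proportions = props, tests = tests)
}
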