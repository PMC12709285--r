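## Order-statistics test of repeated differentiation across lineages.
## Each lineage contributes genome-wide empirical p-values (ranks of its
## windowed statistic); windows where several lineages are jointly extreme
## get small combined p-values. The combined statistic excludes the minimum
## order statistic so a single extreme lineage cannot drive significance,
## applies a Dunn-Sidak correction over the remaining configurations, and is
## calibrated against a Monte-Carlo null.

#' Empirical per-lineage p-values from windowed statistics
#'
#' `p = rank(-stat) / N` per lineage with average ranks for ties, giving
#' uniform marginals on `(0, 1]` by construction. Windows with a missing
#' statistic in any lineage are dropped (count in `attr(x, "n_dropped")`).
#'
#' @param stat_matrix numeric matrix, windows x lineages (one contrast per
#'   lineage).
#' @return matrix of empirical p-values with the same dimnames.
#' @export
empiricalPvalues <- function(stat_matrix) {
    stopifnot(is.matrix(stat_matrix), ncol(stat_matrix) >= 2)
    keep <- stats::complete.cases(stat_matrix)
    m <- stat_matrix[keep, , drop = FALSE]
    p <- apply(m, 2, function(x) rank(-x, ties.method = "average") / length(x))
    attr(p, "n_dropped") <- sum(!keep)
    attr(p, "kept") <- which(keep)
    p
}

#' Combined order-statistic p-value for one window
#'
#' For sorted ascending p-values `p_(1) <= ... <= p_(L)`, evaluates
#' `q_a = BetaCDF(p_(a); a, L - a + 1)` for `a = 2..L` (the minimum is
#' excluded) and combines as `1 - (1 - min_a q_a)^(L-1)` (Dunn-Sidak over
#' the L-1 configurations).
#'
#' @param p_sorted sorted ascending p-values, length `L` with `3 <= L <= 12`.
#' @return list: `p` (combined), `n_est` (the `a` attaining the minimum, the
#'   estimated number of repeatedly adapting lineages).
#' @export
orderStatPvalue <- function(p_sorted) {
    L <- length(p_sorted)
    stopifnot(L >= 3, L <= 12)
    if (is.unsorted(p_sorted))
        stop("p-values must be sorted ascending", call. = FALSE)
    a <- 2:L
    q <- stats::pbeta(p_sorted[a], a, L - a + 1)
    list(p = 1 - (1 - min(q))^(L - 1), n_est = a[which.min(q)])
}

## vectorized combined statistic over the rows of a p-value matrix
.combinedStat <- function(pmat) {
    L <- ncol(pmat)
    sorted <- t(apply(pmat, 1, sort))
    q <- matrix(NA_real_, nrow(pmat), L - 1)
    for (a in 2:L)
        q[, a - 1] <- stats::pbeta(sorted[, a], a, L - a + 1)
    minq <- do.call(pmin, as.data.frame(q))
    list(stat = 1 - (1 - minq)^(L - 1),
         n_est = (2:L)[apply(q, 1, which.min)])
}

#' Repeated-adaptation scan across lineages
#'
#' Combines each window's per-lineage empirical p-values with
#' [orderStatPvalue()], calibrates against `n_reps` Monte-Carlo draws of `L`
#' iid uniforms, and applies Benjamini-Hochberg FDR. `alpha_adapt` is the
#' fraction of null draws simulated as already adapted in one random lineage
#' (that lineage's p-value set to 0); because the combined statistic excludes
#' the minimum, this guards the calibration against single-lineage extremes.
#'
#' @param pmat matrix of per-lineage empirical p-values (windows x lineages),
#'   e.g. from [empiricalPvalues()].
#' @param n_reps Monte-Carlo repetitions (default 10000; < 1000 warns).
#' @param seed integer seed.
#' @param fdr_q FDR threshold (default 0.05).
#' @param alpha_adapt calibration-null adapted fraction (default 0.05).
#' @return data.frame: window, combined_p, calibrated_p, q, n_est,
#'   significant.
#' @export
repeatedAdaptationScan <- function(pmat, n_reps = 10000, seed = 1L,
                                   fdr_q = 0.05, alpha_adapt = 0.05) {
    stopifnot(is.matrix(pmat), all(pmat > 0 & pmat <= 1))
    if (n_reps < 1000)
        warning("fewer than 1000 repetitions: calibrated p-value resolution is coarse")
    L <- ncol(pmat)
    obs <- .combinedStat(pmat)
    set.seed(seed)
    null_p <- matrix(stats::runif(n_reps * L), n_reps, L)
    adapted <- stats::runif(n_reps) < alpha_adapt
    if (any(adapted)) {
        lane <- sample.int(L, sum(adapted), replace = TRUE)
        null_p[cbind(which(adapted), lane)] <- 0
    }
    null_stat <- sort(.combinedStat(null_p)$stat)
    calibrated <- (1 + findInterval(obs$stat, null_stat)) / (n_reps + 1)
    q <- stats::p.adjust(calibrated, method = "BH")
    data.frame(window = seq_len(nrow(pmat)), combined_p = obs$stat,
               calibrated_p = calibrated, q = q, n_est = obs$n_est,
               significant = q < fdr_q)
}
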