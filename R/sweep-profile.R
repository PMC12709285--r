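## Hard-sweep shape quantification from per-SNP Rho tracks: magnitude (raw
## peak above the genome-wide mean) and breadth (width of the smoothed curve
## above twice the local background). The smoother is local linear
## regression with the span selected by the bias-corrected AIC over a fixed
## candidate grid, so results are reproducible without a continuous
## optimizer.

#' Extract the per-SNP track around a gene
#'
#' SNPs within `flank` bp of the gene midpoint `floor((start + end) / 2)`.
#' Regions truncated by the scaffold edge are flagged; regions with fewer
#' than 20 SNPs are skipped (`NULL`).
#'
#' @param track data.frame with `scaffold`, `pos` and the statistic column
#'   (`rho`).
#' @param gene one-row data.frame or list with `scaffold`, `start`, `end`.
#' @param flank half-width of the curve region in bp (default 100000).
#' @return data.frame of region points (attributes `mid`, `truncated`), or
#'   `NULL` when under-populated.
#' @export
extractRegion <- function(track, gene, flank = 100000) {
    mid <- floor((gene$start + gene$end) / 2)
    on_sc <- track[track$scaffold == gene$scaffold, , drop = FALSE]
    if (nrow(on_sc) == 0) return(NULL)
    region <- on_sc[on_sc$pos >= mid - flank & on_sc$pos <= mid + flank, ,
                    drop = FALSE]
    if (nrow(region) < 20) return(NULL)
    attr(region, "mid") <- mid
    attr(region, "truncated") <- mid - flank < min(on_sc$pos) ||
        mid + flank > max(on_sc$pos)
    region
}

## bias-corrected AIC for a loess fit
.aicc <- function(fit) {
    n <- length(fit$residuals)
    tr <- fit$trace.hat
    denom <- 1 - (tr + 2) / n
    if (denom <= 0) return(Inf)
    log(sum(fit$residuals^2) / n) + (1 + tr / n) / denom
}

#' Fit a smoothed sweep curve on a 1-kbp grid
#'
#' Local linear regression of the statistic on position; the span is chosen
#' by minimizing the bias-corrected AIC,
#' `AICC = log(sigma2) + (1 + tr(L)/n) / (1 - (tr(L)+2)/n)`,
#' over the candidate grid 0.1-0.9 in steps of 0.05 (smallest span wins
#' ties). The curve is evaluated at 1-kbp spaced positions across the
#' region.
#'
#' @param region data.frame from [extractRegion()] with `pos` and `rho`.
#' @param stat name of the statistic column (default `"rho"`).
#' @param grid_bp curve evaluation spacing (default 1000).
#' @param spans candidate span grid.
#' @return data.frame `pos`, `fit` with attribute `span`.
#' @export
fitProfile <- function(region, stat = "rho", grid_bp = 1000,
                       spans = seq(0.1, 0.9, by = 0.05)) {
    stopifnot(nrow(region) >= 20)
    x <- region$pos; y <- region[[stat]]
    if (length(unique(x)) < 2)
        stop("degenerate region: all SNPs at one position", call. = FALSE)
    fits <- lapply(spans, function(s) suppressWarnings(
        try(stats::loess(y ~ x, span = s, degree = 1), silent = TRUE)))
    aicc <- vapply(fits, function(f)
        if (inherits(f, "try-error")) Inf else .aicc(f), 0)
    if (all(!is.finite(aicc)))
        stop("no loess fit succeeded on this region", call. = FALSE)
    best <- which.min(aicc)  # which.min takes the first (smallest span) on ties
    grid <- seq(min(x), max(x), by = grid_bp)
    out <- data.frame(pos = grid,
                      fit = stats::predict(fits[[best]], data.frame(x = grid)))
    attr(out, "span") <- spans[best]
    out
}

#' Sweep magnitude
#'
#' The highest raw per-SNP statistic within the region minus the genome-wide
#' mean. Raw points, not the fitted curve, define the peak; negative values
#' (region everywhere below the genome-wide mean) are legitimate and
#' flagged by the caller.
#'
#' @param region data.frame with the statistic column.
#' @param genomewide_mean genome-wide mean of the statistic.
#' @param stat statistic column name (default `"rho"`).
#' @return numeric magnitude.
#' @export
sweepMagnitude <- function(region, genomewide_mean, stat = "rho") {
    stopifnot(nrow(region) > 0)
    max(region[[stat]], na.rm = TRUE) - genomewide_mean
}

#' Sweep breadth
#'
#' Width in bp of the contiguous interval, containing the curve's maximum,
#' where the fitted curve exceeds twice the background level. Crossing
#' positions are linearly interpolated between grid points. Returns 0 with
#' flag `"below_threshold"` when the peak never exceeds the threshold, and
#' the full region length with flag `"never_crosses"` when the curve never
#' drops below it.
#'
#' @param curve data.frame `pos`, `fit` from [fitProfile()].
#' @param background_rho local background level (mean per-SNP statistic in
#'   the flanking regions beyond the curve region).
#' @return numeric breadth in bp, with a `flag` attribute
#'   (`"ok"`, `"below_threshold"`, `"never_crosses"`).
#' @export
sweepBreadth <- function(curve, background_rho) {
    thr <- 2 * background_rho
    f <- curve$fit; x <- curve$pos
    peak <- which.max(f)
    flag <- "ok"
    if (f[peak] <= thr) {
        out <- 0
        attr(out, "flag") <- "below_threshold"
        return(out)
    }
    cross_at <- function(i, j)  # linear interpolation between grid points
        x[i] + (thr - f[i]) * (x[j] - x[i]) / (f[j] - f[i])
    left <- peak
    while (left > 1 && f[left - 1] > thr) left <- left - 1
    lx <- if (left == 1) {flag <- "edge"; x[1]} else cross_at(left - 1, left)
    right <- peak
    while (right < length(f) && f[right + 1] > thr) right <- right + 1
    rx <- if (right == length(f)) {flag <- "edge"; x[length(f)]}
          else cross_at(right + 1, right)
    if (left == 1 && right == length(f)) flag <- "never_crosses"
    out <- rx - lx
    attr(out, "flag") <- flag
    out
}

#' Background differentiation in the flanks of a curve region
#'
#' Mean per-SNP statistic in the `bg_flank` bp on each side beyond the curve
#' region. Falls back to the genome-wide mean (flagged) when no flanking
#' SNPs exist.
#'
#' @param track per-SNP data.frame (`scaffold`, `pos`, statistic).
#' @param gene list/row with `scaffold`, `start`, `end`.
#' @param flank curve-region half width (default 100000).
#' @param bg_flank background flank width per side (default 200000).
#' @param genomewide_mean fallback value.
#' @param stat statistic column name.
#' @return numeric background with `flag` attribute (`"ok"`/`"fallback"`).
#' @export
backgroundRho <- function(track, gene, flank = 100000, bg_flank = 200000,
                          genomewide_mean = NA_real_, stat = "rho") {
    mid <- floor((gene$start + gene$end) / 2)
    on_sc <- track[track$scaffold == gene$scaffold, , drop = FALSE]
    sel <- (on_sc$pos >= mid - flank - bg_flank & on_sc$pos < mid - flank) |
           (on_sc$pos > mid + flank & on_sc$pos <= mid + flank + bg_flank)
    vals <- on_sc[[stat]][sel]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
        out <- genomewide_mean
        attr(out, "flag") <- "fallback"
        return(out)
    }
    out <- mean(vals)
    attr(out, "flag") <- "ok"
    out
}

#' Sweep profiles for a set of candidate genes in one population pair
#'
#' Runs region extraction, background estimation, curve fitting, magnitude
#' and breadth for each gene over the pair's per-SNP Rho track.
#'
#' @param track per-SNP data.frame with `scaffold`, `pos`, `rho` (e.g. the
#'   `snps` element of [differentiationScan()]).
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`.
#' @param pair_id label recorded in the output.
#' @param genomewide_mean genome-wide mean Rho for the pair.
#' @param flank,bg_flank region geometry in bp.
#' @return data.frame: gene_id, pair_id, n_snps, background, magnitude,
#'   breadth, span, flag.
#' @export
sweepProfiles <- function(track, genes, pair_id, genomewide_mean,
                          flank = 100000, bg_flank = 200000) {
    track <- track[!is.na(track$rho), , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        region <- extractRegion(track, g, flank)
        if (is.null(region)) next
        bg <- backgroundRho(track, g, flank, bg_flank, genomewide_mean)
        curve <- fitProfile(region)
        br <- sweepBreadth(curve, as.numeric(bg))
        out[[length(out) + 1L]] <- data.frame(
            gene_id = g$gene_id, pair_id = pair_id, n_snps = nrow(region),
            background = as.numeric(bg),
            magnitude = sweepMagnitude(region, genomewide_mean),
            breadth = as.numeric(br), span = attr(curve, "span"),
            flag = paste(attr(bg, "flag"), attr(br, "flag"), sep = "/"))
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
}
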