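## Ploidy-aware diversity and differentiation estimators. Windowed statistics
## are ratio-of-sums of per-SNP components, which avoids the upward bias of
## averaging per-SNP ratios; negative per-SNP variance components are kept in
## the sums and clamped to [0,1] only at reporting.

#' Downsample each population to a fixed number of individuals per site
#'
#' Uniform random choice without replacement among the non-missing samples of
#' each population at each site; sites where a population has fewer
#' non-missing individuals than requested are set fully missing for that
#' population. Populations with exactly `n_individuals` samples pass through
#' unchanged.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param n_individuals individuals retained per population per site
#'   (default 4).
#' @param seed integer seed.
#' @return A [GenotypeMatrix-class] with the discarded genotypes set `NA`.
#' @export
downsampleIndividuals <- function(gm, n_individuals = 4, seed = 1L) {
    set.seed(seed)
    d <- dosage(gm)
    pops <- populations(gm)
    for (p in unique(pops)) {
        cols <- which(pops == p)
        m <- length(cols)
        if (m == n_individuals) next
        sub <- d[, cols, drop = FALSE]
        nm <- !is.na(sub)
        cnt <- rowSums(nm)
        r <- matrix(stats::runif(nrow(sub) * m), nrow(sub))
        r[!nm] <- Inf
        ## row-wise rank without apply(); ties impossible a.s. among finite
        ## draws, and missing cells (Inf) are NA already so their rank is moot
        rk <- matrix(0L, nrow(sub), m)
        for (j in seq_len(m))
            rk[, j] <- 1L + as.integer(rowSums(r < r[, j]))
        sub[rk > n_individuals] <- NA_integer_
        sub[cnt < n_individuals, ] <- NA_integer_
        d[, cols] <- sub
    }
    SummarizedExperiment::assay(gm, "dosage") <- d
    new("GenotypeMatrix", gm)
}

#' Downsample allele counts to a fixed number of chromosomes per site
#'
#' Hypergeometric draw of `n_chromosomes` allele copies from each
#' population's sampled copies; equivalent to choosing chromosomes without
#' replacement from the pooled non-missing dosages. Sites with fewer copies
#' than requested become `NA` for that population. Populations holding
#' exactly `n_chromosomes` copies are returned exhaustively (deterministic
#' frequencies).
#'
#' @param aft an [AlleleFreqTable-class].
#' @param n_chromosomes chromosomes drawn per population per site
#'   (default 12).
#' @param seed integer seed.
#' @return An [AlleleFreqTable-class] with `chromosomesSampled` equal to
#'   `n_chromosomes` wherever defined.
#' @export
downsampleChromosomes <- function(aft, n_chromosomes = 12, seed = 1L) {
    set.seed(seed)
    f <- aft@freq; ch <- aft@chrom
    k <- round(f * ch)  # derived copies observed
    ok <- !is.na(f) & ch >= n_chromosomes
    draw <- matrix(NA_real_, nrow(f), ncol(f), dimnames = dimnames(f))
    draw[ok] <- stats::rhyper(sum(ok), k[ok], ch[ok] - k[ok], n_chromosomes)
    newch <- matrix(NA_integer_, nrow(f), ncol(f), dimnames = dimnames(f))
    newch[ok] <- as.integer(n_chromosomes)
    new("AlleleFreqTable", freq = draw / n_chromosomes, chrom = newch,
        sites = aft@sites, populations = aft@populations)
}

#' Per-site unbiased heterozygosity
#'
#' `2 k (n - k) / (n (n - 1))`: the probability that two chromosomes drawn
#' without replacement differ, i.e. the per-site component of pairwise
#' nucleotide diversity. Sites with `n < 2` return `NA`.
#'
#' @param k derived (or alternate) allele count per site.
#' @param n chromosomes sampled per site.
#' @return numeric vector of per-site heterozygosities.
#' @export
siteHeterozygosity <- function(k, n) {
    h <- 2 * k * (n - k) / (n * (n - 1))
    h[n < 2] <- NA_real_
    h
}

#' Tajima's D from segregating sites and mean pairwise differences
#'
#' Standard constants `a1..e2` from the chromosome count `n`; `D =
#' (pi_hat - S/a1) / sqrt(e1 S + e2 S (S-1))`. `S = 0` gives `NA`.
#'
#' @param S number of segregating sites in the window.
#' @param pi_sum sum over sites of pairwise-difference heterozygosity
#'   (mean pairwise differences, not per bp).
#' @param n chromosomes (use the downsampled chromosome count).
#' @return Tajima's D (numeric scalar, vectorized over `S`/`pi_sum`).
#' @export
tajimasD <- function(S, pi_sum, n) {
    stopifnot(n >= 4)
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    D <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
    D[S == 0] <- NA_real_
    D
}

#' Windowed within-population diversity scan
#'
#' For each population: downsample to `n_individuals` per site, then compute
#' per-window nucleotide diversity (per bp; monomorphic positions contribute
#' zero) and Tajima's D on the fixed downsampled chromosome count
#' (`n_individuals * ploidy`). Windows with fewer than `min_snps` SNPs are
#' dropped.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param window_size window size in bp (default 50000).
#' @param min_snps minimum SNPs per window (default 10).
#' @param n_individuals downsampling depth (default 4).
#' @param seed seed for the downsampling draw.
#' @return data.frame: population, scaffold, start, end, n_snps, pi,
#'   tajimas_d.
#' @export
diversityScan <- function(gm, window_size = 50000, min_snps = 10,
                          n_individuals = 4, seed = 1L) {
    gmd <- downsampleIndividuals(gm, n_individuals, seed)
    d <- dosage(gmd)
    pl <- samplePloidy(gmd)
    pops <- populations(gmd)
    rr <- SummarizedExperiment::rowRanges(gmd)
    sc <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    win <- (pos - 1) %/% window_size
    key <- paste(sc, win)
    out <- list()
    for (p in unique(pops)) {
        cols <- which(pops == p)
        n_chr <- n_individuals * pl[cols][1]
        sub <- d[, cols, drop = FALSE]
        nm_cnt <- rowSums(!is.na(sub))
        full <- nm_cnt == n_individuals
        k <- rowSums(sub, na.rm = TRUE)
        h <- siteHeterozygosity(k, n_chr)
        h[!full] <- NA_real_
        seg <- full & k > 0 & k < n_chr
        for (kk in unique(key)) {
            idx <- which(key == kk & full)
            if (length(idx) < min_snps) next
            S <- sum(seg[idx])
            psum <- sum(h[idx])
            out[[length(out) + 1L]] <- data.frame(
                population = p, scaffold = sc[idx[1]],
                start = win[idx[1]] * window_size + 1,
                end = (win[idx[1]] + 1) * window_size,
                n_snps = length(idx), pi = psum / window_size,
                tajimas_d = if (S > 0) tajimasD(S, psum, n_chr) else NA_real_)
        }
    }
    if (!length(out))
        return(data.frame(population = character(), scaffold = character(),
                          start = numeric(), end = numeric(),
                          n_snps = integer(), pi = numeric(),
                          tajimas_d = numeric()))
    do.call(rbind, out)
}

#' Weir-Cockerham F_ST components from allele counts
#'
#' Two-population estimator on allele counts (sample sizes are chromosome
#' counts; haplotype-level, no within-individual component). Returns the
#' per-SNP variance-component numerator and denominator; the windowed
#' estimate is the ratio of their sums.
#'
#' @param k1,n1 derived count and chromosomes in population 1 (vectors).
#' @param k2,n2 same for population 2.
#' @return data.frame `num`, `den`, `fst` (per-SNP ratio clamped to `[0,1]`
#'   for reporting; `num`/`den` retain raw values).
#' @export
wcFst <- function(k1, n1, k2, n2) {
    p1 <- k1 / n1; p2 <- k2 / n2
    nt <- n1 + n2
    pbar <- (k1 + k2) / nt
    nc <- nt - (n1^2 + n2^2) / nt
    msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2  # df = r - 1 = 1
    msg <- (k1 * (n1 - k1) / n1 + k2 * (n2 - k2) / n2) / (nt - 2)
    num <- msp - msg
    den <- msp + (nc - 1) * msg
    fst <- ifelse(den > 0, pmin(pmax(num / den, 0), 1), 0)
    data.frame(num = num, den = den, fst = fst)
}

## Gene-identity probabilities per site and population pair, excluding all
## within-individual copy comparisons; vectorized over sites.
.rhoIdentities <- function(d, cols1, cols2, pl1, pl2) {
    stat <- function(cols, m) {
        sub <- d[, cols, drop = FALSE]
        nm <- !is.na(sub)
        n_ind <- rowSums(nm)
        s1 <- rowSums(sub, na.rm = TRUE)
        s2 <- rowSums(sub^2, na.rm = TRUE)
        cs1 <- rowSums((m - sub), na.rm = TRUE)   # complement sums
        cs2 <- rowSums((m - sub)^2, na.rm = TRUE)
        ## sum over ordered pairs of distinct individuals of x_i x_j / m^2
        q2 <- ((s1^2 - s2) + (cs1^2 - cs2)) / (m^2 * n_ind * (n_ind - 1))
        list(n_ind = n_ind, p = s1 / (m * n_ind), q2 = q2)
    }
    A <- stat(cols1, pl1); B <- stat(cols2, pl2)
    ok <- A$n_ind >= 2 & B$n_ind >= 2
    q2 <- (A$q2 + B$q2) / 2
    q3 <- A$p * B$p + (1 - A$p) * (1 - B$p)
    out <- data.frame(q2 = q2, q3 = q3, num = q2 - q3, den = 1 - q3)
    out[!ok, ] <- NA_real_
    out
}

#' Rho: differentiation comparable across ploidy levels
#'
#' Gene-identity formulation of the F_ST analogue for mixed-ploidy data:
#' with `Q2` the probability that two allele copies drawn from *different*
#' individuals of the same population are identical and `Q3` the probability
#' for copies drawn from different populations,
#' `Rho = (Q2 - Q3) / (1 - Q3)`. Because no two copies are ever compared
#' within an individual, the statistic is unaffected by the within-individual
#' stratum (polysomic masking, inbreeding, double reduction) and is directly
#' comparable across ploidy levels. Individual-level dosages are therefore
#' required. Sites where either population has fewer than two genotyped
#' individuals are `NA`.
#'
#' @param d dosage matrix (sites x samples).
#' @param cols1,cols2 column indices of the two populations.
#' @param pl1,pl2 ploidy of each population.
#' @return data.frame with per-SNP identity probabilities `q2`, `q3`, the
#'   components `num` (`Q2 - Q3`) and `den` (`1 - Q3`) summed by windowed
#'   callers, and `rho` (per-SNP ratio clamped to `[0,1]` for reporting;
#'   negative numerators are preserved in `num`).
#' @export
rhoStat <- function(d, cols1, cols2, pl1, pl2) {
    comp <- .rhoIdentities(d, cols1, cols2, pl1, pl2)
    comp$rho <- ifelse(!is.na(comp$den) & comp$den > 0,
                       pmin(pmax(comp$num / comp$den, 0), 1), 0)
    comp$rho[is.na(comp$num)] <- NA_real_
    comp
}

#' Windowed differentiation scan for one population pair
#'
#' Computes per-SNP Weir-Cockerham F_ST (from allele counts) and Rho (from
#' dosages) for the pair, then aggregates both over a fixed non-overlapping
#' window grid anchored at position 1 as ratio-of-sums. Per-SNP values are
#' retained for sweep profiling.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param popA,popB population names (A conventionally calcareous).
#' @param window_size bp (default 1000).
#' @param min_snps minimum informative SNPs per window (default 10).
#' @return list with `windows` (scaffold, start, end, n_snps, fst, rho) and
#'   `snps` (scaffold, pos, fst_num, fst_den, rho_num, rho_den, fst, rho).
#' @export
differentiationScan <- function(gm, popA, popB, window_size = 1000,
                                min_snps = 10) {
    pops <- populations(gm)
    cols1 <- which(pops == popA); cols2 <- which(pops == popB)
    if (!length(cols1) || !length(cols2))
        stop("population not found in GenotypeMatrix", call. = FALSE)
    pl <- samplePloidy(gm)
    d <- dosage(gm)
    nm1 <- !is.na(d[, cols1, drop = FALSE]); nm2 <- !is.na(d[, cols2, drop = FALSE])
    n1 <- rowSums(nm1) * pl[cols1][1]; n2 <- rowSums(nm2) * pl[cols2][1]
    k1 <- rowSums(d[, cols1, drop = FALSE], na.rm = TRUE)
    k2 <- rowSums(d[, cols2, drop = FALSE], na.rm = TRUE)
    ok <- n1 > 0 & n2 > 0
    fst <- data.frame(num = NA_real_, den = NA_real_, fst = NA_real_)[rep(1, nrow(d)), ]
    fst[ok, ] <- wcFst(k1[ok], n1[ok], k2[ok], n2[ok])
    rho <- rhoStat(d, cols1, cols2, pl[cols1][1], pl[cols2][1])

    rr <- SummarizedExperiment::rowRanges(gm)
    sc <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    snps <- data.frame(scaffold = sc, pos = pos,
        fst_num = fst$num, fst_den = fst$den, fst = fst$fst,
        rho_num = rho$num, rho_den = rho$den, rho = rho$rho)
    win <- (pos - 1) %/% window_size
    informative <- ok & !is.na(rho$num)
    key <- paste(sc, win)
    agg <- snps[informative, ]
    keyi <- key[informative]
    sums <- rowsum(cbind(agg$fst_num, agg$fst_den, agg$rho_num, agg$rho_den,
                         rep(1, nrow(agg))), keyi)
    first <- agg[match(rownames(sums), keyi), c("scaffold", "pos")]
    windows <- data.frame(
        scaffold = first$scaffold,
        start = ((first$pos - 1) %/% window_size) * window_size + 1,
        end = ((first$pos - 1) %/% window_size + 1) * window_size,
        n_snps = sums[, 5],
        fst = pmin(pmax(ifelse(sums[, 2] > 0, sums[, 1] / sums[, 2], 0), 0), 1),
        rho = pmin(pmax(ifelse(sums[, 4] > 0, sums[, 3] / sums[, 4], 0), 0), 1))
    windows <- windows[windows$n_snps >= min_snps, ]
    windows <- windows[order(windows$scaffold, windows$start), ]
    rownames(windows) <- NULL
    list(windows = windows, snps = snps)
}
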