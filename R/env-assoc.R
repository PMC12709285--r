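## Latent-factor-corrected association between population allele frequencies
## and the soil PC1 gradient. The latent factors are principal components of
## the centered population-frequency matrix, entered as explicit covariates
## in a per-SNP linear regression — a transparent stand-in for latent factor
## mixed models, with equivalence asserted as calibration and power
## properties rather than coefficient identity.

#' Latent population-structure factors
#'
#' Top-`k` principal component scores of the centered (and per-SNP
#' mean-imputed) population frequency matrix. `k = 0` returns a zero-column
#' matrix (intercept-only correction downstream).
#'
#' @param freq numeric matrix, populations x SNPs (or an
#'   [AlleleFreqTable-class], which is transposed internally).
#' @param k number of factors; must satisfy `k < populations - 1`.
#' @return matrix, populations x k, orthogonal columns.
#' @export
latentFactors <- function(freq, k) {
    if (is(freq, "AlleleFreqTable")) freq <- t(freqs(freq))
    n_pop <- nrow(freq)
    if (k >= n_pop - 1)
        stop("k must be smaller than populations - 1", call. = FALSE)
    stopifnot(n_pop >= k + 2)
    if (k == 0)
        return(matrix(0, n_pop, 0, dimnames = list(rownames(freq), NULL)))
    freq <- .meanImputeCols(freq)
    keep <- apply(freq, 2, stats::var) > 0
    pc <- stats::prcomp(freq[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    ## degenerate components (data rank below k) would make the downstream
    ## design matrix singular; return only the informative ones
    informative <- which(pc$sdev > 1e-10 * pc$sdev[1])
    if (length(informative) < k)
        warning("frequency matrix supports only ", length(informative),
                " informative factors; k reduced")
    sc <- pc$x[, intersect(seq_len(k), informative), drop = FALSE]
    rownames(sc) <- rownames(freq)
    sc
}

.meanImputeCols <- function(m) {
    mi <- which(is.na(m), arr.ind = TRUE)
    if (nrow(mi)) {
        cm <- colMeans(m, na.rm = TRUE)
        m[mi] <- cm[mi[, 2]]
    }
    m
}

#' Per-SNP association of population allele frequencies with the soil gradient
#'
#' Fits `frequency ~ intercept + soil_pc1 + factors` per SNP over
#' populations, reporting the two-sided p-value of the soil coefficient and
#' its Benjamini-Hochberg q-value. Missing frequencies are mean-imputed per
#' SNP; SNPs with zero frequency variance are excluded (counted in
#' `attr(x, "n_constant")`).
#'
#' @param freq populations x SNPs matrix or [AlleleFreqTable-class].
#' @param soil_pc1 named numeric vector of soil PC1 scores per population;
#'   populations lacking a score are excluded from the regression.
#' @param k number of latent factors (default 4), or supply `factors`.
#' @param factors optional precomputed factor matrix (populations x k).
#' @param fdr_q significance threshold on q (default 0.1).
#' @return data.frame: snp, beta, p, q, significant. SNP column indices refer
#'   to columns of the input matrix.
#' @export
associationScan <- function(freq, soil_pc1, k = 4, factors = NULL,
                            fdr_q = 0.1) {
    if (is(freq, "AlleleFreqTable")) freq <- t(freqs(freq))
    pops <- rownames(freq)
    soil_pc1 <- soil_pc1[!is.na(soil_pc1)]
    use <- intersect(pops, names(soil_pc1))
    if (length(use) < 3)
        stop("too few populations with soil scores", call. = FALSE)
    freq <- freq[use, , drop = FALSE]
    soil <- soil_pc1[use]
    if (stats::sd(soil) == 0)
        stop("constant soil vector", call. = FALSE)
    if (is.null(factors)) factors <- latentFactors(freq, k)
    else factors <- factors[use, , drop = FALSE]
    Y <- .meanImputeCols(freq)
    const <- apply(Y, 2, stats::var) == 0
    X <- cbind(`(Intercept)` = 1, soil = soil, factors)
    n <- nrow(X); p_par <- ncol(X)
    if (n <= p_par) stop("more regressors than populations", call. = FALSE)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X))
        stop("design matrix is rank deficient (collinear factors or soil vector)",
             call. = FALSE)
    coefs <- qr.coef(qr_x, Y)
    res <- Y - X %*% coefs
    df <- n - p_par
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(qr.R(qr_x))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    tval <- coefs["soil", ] / se
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    pval[const] <- NA_real_
    out <- data.frame(snp = seq_len(ncol(Y)), beta = coefs["soil", ],
                      p = pval)
    out <- out[!is.na(out$p), ]
    out$q <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$q < fdr_q
    rownames(out) <- NULL
    attr(out, "n_constant") <- sum(const)
    attr(out, "k") <- ncol(factors)
    out
}

#' Genes supported by multiple significant association SNPs
#'
#' Genes containing at least `min_snps` significant SNPs within their
#' `[start, end]` span. A SNP inside two overlapping genes counts for both.
#'
#' @param sig_sites `GRanges` of significant SNP positions.
#' @param genes `GRanges` gene models with `gene_id`.
#' @param min_snps minimum significant SNPs per gene (default 3).
#' @return character vector of gene ids.
#' @export
assocCandidateGenes <- function(sig_sites, genes, min_snps = 3) {
    hits <- GenomicRanges::countOverlaps(genes, sig_sites)
    genes$gene_id[hits >= min_snps]
}
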