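## Reading mixed-ploidy VCFs and applying the site/gene filters used before
## any scan: per-cell depth masking, site-level missingness and MAF filters,
## the fixed-heterozygosity paralog mask, the excess-depth mask, and
## application of an ancestral-allele polarization key.

#' Read a mixed-ploidy VCF into a GenotypeMatrix
#'
#' GT strings of arity equal to the declared sample ploidy (`0/1`,
#' `0/0/0/1`, ...) are parsed to allele dosages. Any partially missing call
#' (`./.`, `./0/0/1`) is treated as fully missing. Multi-allelic records are
#' dropped and counted in the parse log
#' (`S4Vectors::metadata(x)$log`).
#'
#' @param path VCF 4.2 file (uncompressed or gzipped).
#' @param samples data.frame with `sample_id`, `population`, `ploidy`,
#'   `lineage` covering every sample in the VCF.
#' @return A [GenotypeMatrix-class].
#' @export
readMixedVcf <- function(path, samples) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (!is.matrix(fix)) fix <- t(as.matrix(fix))  # single-record VCF
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE) | is.na(fix[, "ALT"]) |
        nchar(fix[, "REF"]) != 1 | nchar(fix[, "ALT"]) != 1
    gt <- vcfR::extract.gt(v, element = "GT")
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
    keep <- !multi
    gt <- gt[keep, , drop = FALSE]; dp <- dp[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]

    vcf_samples <- colnames(gt)
    if (!all(vcf_samples %in% samples$sample_id))
        stop("sample metadata missing for: ",
             paste(setdiff(vcf_samples, samples$sample_id), collapse = ", "),
             call. = FALSE)
    samples <- samples[match(vcf_samples, samples$sample_id), , drop = FALSE]

    dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
    for (j in seq_len(ncol(gt))) {
        g <- gt[, j]
        miss <- is.na(g) | grepl(".", g, fixed = TRUE)
        ok <- which(!miss)
        if (length(ok)) {
            arity <- nchar(g[ok]) - nchar(gsub("[/|]", "", g[ok])) + 1L
            bad <- arity != samples$ploidy[j]
            if (any(bad)) {
                b <- ok[which(bad)[1]]
                stop(sprintf(
                    "GT arity does not match ploidy %d for sample %s at %s:%s (GT '%s')",
                    samples$ploidy[j], vcf_samples[j], fix[b, "CHROM"],
                    fix[b, "POS"], g[b]), call. = FALSE)
            }
            dos[ok, j] <- nchar(g[ok]) - nchar(gsub("1", "", g[ok], fixed = TRUE))
        }
    }
    dp[is.na(dp)] <- 0
    sites <- GenomicRanges::GRanges(fix[, "CHROM"],
        IRanges::IRanges(as.integer(fix[, "POS"]), width = 1L),
        ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
        ancestral = "unknown")
    gm <- GenotypeMatrix(dos, dp, sites, samples)
    S4Vectors::metadata(gm)$log <- list(n_multiallelic_dropped = sum(multi),
                                        n_sites = length(sites))
    gm
}

#' Depth, missingness and MAF site filters
#'
#' Applies, in this fixed order: (i) genotype cells with depth below
#' `min_depth` are set missing; (ii) sites whose missing fraction exceeds
#' `max_missing` are removed; (iii) sites with minor-allele frequency (over
#' all samples, allele-copy weighted) below `maf` are removed. The filter log
#' is stored in `S4Vectors::metadata(x)$filter_log`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param min_depth minimum per-genotype depth (default 8).
#' @param max_missing maximum fraction of missing genotypes per site
#'   (default 0.5).
#' @param maf minimum minor-allele frequency (default 0, i.e. no MAF filter).
#' @return The filtered [GenotypeMatrix-class].
#' @export
filterSites <- function(gm, min_depth = 8, max_missing = 0.5, maf = 0) {
    stopifnot(min_depth >= 0, max_missing >= 0, max_missing <= 1,
              maf >= 0, maf <= 0.5)
    d <- dosage(gm)
    dp <- readDepth(gm)
    n0 <- nrow(gm)
    low <- dp < min_depth & !is.na(d)
    d[low] <- NA_integer_
    miss_frac <- rowMeans(is.na(d))
    keep_miss <- miss_frac <= max_missing
    pl <- samplePloidy(gm)
    nm <- !is.na(d)
    chrom <- nm %*% pl
    derived <- rowSums(d * 1L, na.rm = TRUE)
    f <- ifelse(chrom > 0, derived / chrom, NA)
    mafv <- pmin(f, 1 - f)
    keep_maf <- !is.na(mafv) & mafv >= maf
    keep <- keep_miss & keep_maf
    out <- gm[keep, ]
    SummarizedExperiment::assay(out, "dosage") <- d[keep, , drop = FALSE]
    out <- new("GenotypeMatrix", out)
    S4Vectors::metadata(out)$filter_log <- list(
        n_input = n0, n_cells_depth_masked = sum(low),
        n_removed_missing = sum(!keep_miss),
        n_removed_maf = sum(keep_miss & !keep_maf), n_output = sum(keep))
    out
}

#' Mask genes with excess fixed heterozygosity (putative paralogs)
#'
#' A SNP is "fixed heterozygous" in a population when every non-missing
#' sample carries dosage `ploidy/2` (diploid `0/1`, tetraploid `0/0/1/1`).
#' Genes accumulating at least `min_fixed_het` such SNPs in at least
#' `min_pops` populations are flagged as collapsed paralogs and all their
#' sites masked.
#'
#' @param gm a [GenotypeMatrix-class]; all ploidies must be even.
#' @param genes `GRanges` of gene models with a `gene_id` column.
#' @param min_fixed_het,min_pops thresholds (defaults 5 SNPs, 2 populations).
#' @return Logical site mask (`TRUE` = masked), with the masked gene ids in
#'   `attr(x, "masked_genes")`.
#' @export
maskParalogGenes <- function(gm, genes, min_fixed_het = 5, min_pops = 2) {
    pl <- samplePloidy(gm)
    if (any(pl %% 2 != 0))
        stop("fixed heterozygosity undefined for odd ploidy", call. = FALSE)
    d <- dosage(gm)
    pops <- populations(gm)
    upop <- unique(pops)
    fh <- vapply(upop, function(p) {
        cols <- which(pops == p)
        half <- pl[cols][1] / 2
        sub <- d[, cols, drop = FALSE]
        nm <- !is.na(sub)
        het <- sub == half & nm
        rowSums(nm) > 0 & rowSums(het) == rowSums(nm)
    }, logical(nrow(gm)))
    ov <- GenomicRanges::findOverlaps(SummarizedExperiment::rowRanges(gm), genes)
    mask <- logical(nrow(gm))
    masked_genes <- character()
    for (gi in unique(S4Vectors::subjectHits(ov))) {
        sidx <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == gi]
        counts <- colSums(fh[sidx, , drop = FALSE])
        if (sum(counts >= min_fixed_het) >= min_pops) {
            mask[sidx] <- TRUE
            masked_genes <- c(masked_genes, genes$gene_id[gi])
        }
    }
    attr(mask, "masked_genes") <- masked_genes
    mask
}

#' Mask sites with excess depth of coverage
#'
#' Depth statistics are computed per sample over all sites; a site is masked
#' when at least `min_individuals` samples show depth exceeding their own
#' mean + `sd_multiplier` standard deviations. A sample with zero depth
#' variance never flags a site (exceedance is strict).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param sd_multiplier multiplier of the per-sample depth SD (default 2).
#' @param min_individuals minimum number of exceeding samples (default 20).
#' @return Logical site mask (`TRUE` = masked).
#' @export
maskExcessDepth <- function(gm, sd_multiplier = 2, min_individuals = 20) {
    dp <- readDepth(gm)
    mu <- colMeans(dp)
    sdv <- apply(dp, 2, stats::sd)
    thr <- mu + sd_multiplier * sdv
    exceed <- sweep(dp, 2, thr, `>`)
    rowSums(exceed) >= min_individuals
}

#' Polarize dosages to the derived allele using an ancestral-probability key
#'
#' Sites where the key gives probability `>= threshold` that the reference
#' allele is ancestral keep their dosages (derived = alt); sites where the
#' probability that the *alternate* allele is ancestral is `>= threshold`
#' have dosages flipped to `ploidy - dosage`; all other covered sites, and
#' sites absent from the key, are marked `unknown` and are excluded from
#' polarization-dependent statistics downstream while being retained here.
#'
#' @param gm an unpolarized [GenotypeMatrix-class].
#' @param key data.frame with `scaffold`, `pos`, `p_ref_ancestral` in `[0,1]`.
#' @param threshold ancestral-call probability threshold (default 0.7).
#' @return The polarized [GenotypeMatrix-class].
#' @export
polarizeGenotypes <- function(gm, key, threshold = 0.7) {
    stopifnot(all(c("scaffold", "pos", "p_ref_ancestral") %in% names(key)))
    if (any(!is.finite(key$p_ref_ancestral) | key$p_ref_ancestral < 0 |
            key$p_ref_ancestral > 1))
        stop("ancestral probabilities outside [0,1]", call. = FALSE)
    rr <- SummarizedExperiment::rowRanges(gm)
    id_gm <- paste(as.character(GenomicRanges::seqnames(rr)),
                   GenomicRanges::start(rr))
    id_key <- paste(key$scaffold, key$pos)
    m <- match(id_gm, id_key)
    p <- key$p_ref_ancestral[m]
    anc <- rep("unknown", nrow(gm))
    anc[!is.na(p) & p >= threshold] <- "ref"
    anc[!is.na(p) & (1 - p) >= threshold] <- "alt"
    d <- dosage(gm)
    flip <- which(anc == "alt")
    if (length(flip)) {
        pl <- samplePloidy(gm)
        d[flip, ] <- rep(pl, each = length(flip)) - d[flip, , drop = FALSE]
    }
    S4Vectors::mcols(SummarizedExperiment::rowRanges(gm))$ancestral <- anc
    SummarizedExperiment::assay(gm, "dosage") <- d
    new("GenotypeMatrix", gm)
}

#' Population derived-allele frequencies
#'
#' Frequency is the summed dosage over the summed ploidy of non-missing
#' samples per population; when every sample of a population is missing the
#' frequency is `NA` (absence, not zero).
#'
#' @param gm a [GenotypeMatrix-class].
#' @return An [AlleleFreqTable-class].
#' @examples
#' # two diploids with dosages {1,1} -> 0.5; one tetraploid dosage 3 -> 0.75
#' @export
populationFrequencies <- function(gm) {
    d <- dosage(gm)
    pl <- samplePloidy(gm)
    pops <- populations(gm)
    upop <- unique(pops)
    nm <- !is.na(d)
    freq <- chrom <- matrix(NA_real_, nrow(gm), length(upop),
                            dimnames = list(NULL, upop))
    for (p in upop) {
        cols <- which(pops == p)
        ch <- nm[, cols, drop = FALSE] %*% pl[cols]
        der <- rowSums(d[, cols, drop = FALSE], na.rm = TRUE)
        freq[, p] <- ifelse(ch > 0, der / ch, NA_real_)
        chrom[, p] <- ch
    }
    storage.mode(chrom) <- "integer"
    new("AlleleFreqTable", freq = freq, chrom = chrom,
        sites = GenomicRanges::granges(SummarizedExperiment::rowRanges(gm)),
        populations = upop)
}
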