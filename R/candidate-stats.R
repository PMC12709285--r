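## Fixation counting, allele-frequency-spectrum summaries and relative
## differentiation of candidate genes, the quantities compared between
## ploidies. Fixation is strict: a SNP counts only when one population's
## frequency is exactly 0 and the other's exactly 1 on the chromosome set in
## use (full data or a standardized 12-chromosome subsample).

#' Count fixed differences in the windows overlapping a gene
#'
#' SNPs inside the 1-kbp windows overlapping `[start, end]` of the gene
#' where one population has derived-allele frequency exactly 0 and the other
#' exactly 1. Frequencies near but not at the boundary (e.g. 0.96) never
#' count.
#'
#' @param freqA,freqB per-SNP frequencies of the two populations.
#' @param sites `GRanges` of the SNP positions (parallel to the frequency
#'   vectors).
#' @param gene list/row with `scaffold`, `start`, `end`.
#' @param window_size window grid size (default 1000).
#' @return integer count; attribute `no_windows` is `TRUE` when no window
#'   overlaps the gene.
#' @export
fixedSnpCount <- function(freqA, freqB, sites, gene, window_size = 1000) {
    first_win <- (gene$start - 1) %/% window_size
    last_win <- (gene$end - 1) %/% window_size
    lo <- first_win * window_size + 1
    hi <- (last_win + 1) * window_size
    sel <- as.character(GenomicRanges::seqnames(sites)) == gene$scaffold &
        GenomicRanges::start(sites) >= lo & GenomicRanges::start(sites) <= hi
    out <- sum((freqA[sel] == 0 & freqB[sel] == 1) |
               (freqA[sel] == 1 & freqB[sel] == 0), na.rm = TRUE)
    attr(out, "no_windows") <- !any(sel)
    out
}

#' Average fixation per gene over its qualifying pairs
#'
#' A population pair enters a gene's mean only when the gene was a
#' significant outlier in that specific pair. Also reports the ploidy-level
#' mean of gene means and the fraction of genes with at least one fixed SNP.
#'
#' @param counts data.frame with `gene_id`, `pair_id`, `n_fixed`.
#' @param outlier_map data.frame with `gene_id`, `pair_id` listing the pairs
#'   in which each gene is an outlier.
#' @return list: `per_gene` (gene_id, mean_fixed, n_pairs),
#'   `mean_over_genes`, `fraction_with_fixed`.
#' @export
averageFixation <- function(counts, outlier_map) {
    key <- paste(counts$gene_id, counts$pair_id)
    okey <- paste(outlier_map$gene_id, outlier_map$pair_id)
    qual <- counts[key %in% okey, , drop = FALSE]
    if (nrow(qual) == 0)
        return(list(per_gene = data.frame(gene_id = character(),
                                          mean_fixed = numeric(),
                                          n_pairs = integer()),
                    mean_over_genes = NA_real_,
                    fraction_with_fixed = NA_real_))
    per_gene <- do.call(rbind, lapply(split(qual, qual$gene_id), function(x)
        data.frame(gene_id = x$gene_id[1], mean_fixed = mean(x$n_fixed),
                   n_pairs = nrow(x))))
    rownames(per_gene) <- NULL
    list(per_gene = per_gene,
         mean_over_genes = mean(per_gene$mean_fixed),
         fraction_with_fixed = mean(tapply(qual$n_fixed, qual$gene_id,
                                           function(x) any(x > 0))))
}

#' Average allele frequency of candidate SNPs by soil class
#'
#' For every SNP within a candidate gene (plus `flank` bp), the mean
#' frequency across the qualifying populations of each soil class. For
#' display the pair of means is oriented so that the siliceous class carries
#' the higher value (`oriented_*` columns); the raw means are kept.
#'
#' @param aft an [AlleleFreqTable-class].
#' @param gene list/row with `scaffold`, `start`, `end`, `gene_id`.
#' @param pops_cal,pops_sil qualifying population names per soil class.
#' @param flank bp added on each side of the gene (default 2000).
#' @return data.frame: gene_id, pos, mean_cal, mean_sil, oriented_cal,
#'   oriented_sil, flipped.
#' @export
afDistribution <- function(aft, gene, pops_cal, pops_sil, flank = 2000) {
    sites <- aft@sites
    sel <- which(as.character(GenomicRanges::seqnames(sites)) == gene$scaffold &
        GenomicRanges::start(sites) >= gene$start - flank &
        GenomicRanges::start(sites) <= gene$end + flank)
    if (!length(sel)) return(NULL)
    f <- aft@freq
    mc <- rowMeans(f[sel, pops_cal, drop = FALSE], na.rm = TRUE)
    ms <- rowMeans(f[sel, pops_sil, drop = FALSE], na.rm = TRUE)
    flip <- !is.na(mc) & !is.na(ms) & mc > ms
    data.frame(gene_id = gene$gene_id, pos = GenomicRanges::start(sites)[sel],
               mean_cal = mc, mean_sil = ms,
               oriented_cal = ifelse(flip, 1 - mc, mc),
               oriented_sil = ifelse(flip, 1 - ms, ms),
               flipped = flip)
}

#' Relative differentiation of a candidate gene
#'
#' Mean Rho of the windows overlapping the gene divided by the genome-wide
#' Rho, per pair, averaged over the qualifying pairs (those in which the
#' gene is an outlier).
#'
#' @param gene_window_rho named numeric vector: pair id -> mean candidate
#'   window Rho for this gene.
#' @param genomewide_rho named numeric vector: pair id -> genome-wide Rho.
#' @param qualifying_pairs character vector of pair ids to average over.
#' @return numeric ratio (NA when no qualifying pair has data).
#' @export
relativeGeneDifferentiation <- function(gene_window_rho, genomewide_rho,
                                        qualifying_pairs) {
    use <- intersect(qualifying_pairs,
                     intersect(names(gene_window_rho), names(genomewide_rho)))
    if (!length(use)) return(NA_real_)
    if (any(genomewide_rho[use] <= 0))
        stop("genome-wide Rho must be positive", call. = FALSE)
    mean(gene_window_rho[use] / genomewide_rho[use])
}
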