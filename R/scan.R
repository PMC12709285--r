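## Window construction, outlier calling, gene annotation, lineage-aware
## parallelism and the two set-level tests (hypergeometric overlap and the
## recombination-rate permutation test).

#' Build a fixed non-overlapping window grid over SNP positions
#'
#' Windows are anchored at position 1 of each scaffold (`[1, w]`,
#' `[w+1, 2w]`, ...); windows containing fewer than `min_snps` SNPs are
#' discarded and counted in `attr(x, "n_discarded")`.
#'
#' @param sites `GRanges` of SNP positions (sorted).
#' @param window_size bp (default 1000).
#' @param min_snps minimum SNPs per retained window (default 10).
#' @return `GRanges` of retained windows with an `n_snps` metadata column.
#' @export
buildWindows <- function(sites, window_size = 1000, min_snps = 10) {
    sc <- as.character(GenomicRanges::seqnames(sites))
    win <- (GenomicRanges::start(sites) - 1) %/% window_size
    key <- paste(sc, win)
    tab <- table(key)
    first <- match(names(tab), key)
    gr <- GenomicRanges::GRanges(sc[first],
        IRanges::IRanges(win[first] * window_size + 1,
                         (win[first] + 1) * window_size),
        n_snps = as.integer(tab))
    gr <- GenomicRanges::sort(gr)
    keep <- gr$n_snps >= min_snps
    out <- gr[keep]
    attr(out, "n_discarded") <- sum(!keep)
    out
}

#' Top-quantile outlier windows
#'
#' Returns the top `ceiling(quantile * N)` windows by the statistic; windows
#' tied with the cutoff value are all included (tie count in
#' `attr(x, "n_ties_added")`).
#'
#' @param stat numeric vector of windowed statistics.
#' @param quantile upper tail fraction (default 0.01).
#' @return Integer indices of the outlier windows.
#' @export
outlierWindows <- function(stat, quantile = 0.01) {
    n <- sum(!is.na(stat))
    if (n < 100)
        stop("fewer than 100 windows; the outlier quantile is unstable",
             call. = FALSE)
    if (length(unique(stat[!is.na(stat)])) == 1)
        stop("all window statistics identical; no outliers definable",
             call. = FALSE)
    k <- ceiling(quantile * n)
    cutoff <- sort(stat, decreasing = TRUE)[k]
    idx <- which(!is.na(stat) & stat >= cutoff)
    attr(idx, "n_ties_added") <- as.integer(length(idx) - k)
    idx
}

#' Annotate outlier windows (or SNPs) to genes
#'
#' A gene is hit when any query range overlaps its `[start, end]` span by at
#' least 1 bp. Queries on scaffolds absent from the annotation trigger a
#' warning with the unmatched count.
#'
#' @param query `GRanges` of outlier windows or SNPs.
#' @param genes `GRanges` of gene models with a `gene_id` column.
#' @return Character vector of hit gene ids.
#' @export
annotateGenes <- function(query, genes) {
    unmatched <- !(as.character(GenomicRanges::seqnames(query)) %in%
                   GenomeInfoDb::seqlevels(genes))
    if (any(unmatched))
        warning(sum(unmatched), " query ranges on scaffolds absent from the annotation")
    ov <- suppressWarnings(GenomicRanges::findOverlaps(query, genes))
    unique(genes$gene_id[S4Vectors::subjectHits(ov)])
}

#' Lineage-aware parallel candidate genes
#'
#' A gene is a parallel candidate when it is an outlier in at least
#' `min_pairs` population pairs and its supporting pairs span at least two
#' distinct lineages — repeated emergence in independent lineages, not a
#' single lineage's drift.
#'
#' @param per_pair named list (pair id -> character vector of outlier gene
#'   ids).
#' @param pair_lineage named character vector mapping pair id to lineage.
#' @param min_pairs minimum supporting pairs (default 2).
#' @return data.frame: gene_id, n_pairs, pairs, lineages.
#' @export
parallelCandidates <- function(per_pair, pair_lineage, min_pairs = 2) {
    stopifnot(length(per_pair) >= 2, all(names(per_pair) %in% names(pair_lineage)))
    if (length(unique(pair_lineage[names(per_pair)])) < 2) {
        warning("all pairs belong to one lineage; no parallel candidates definable")
        return(data.frame(gene_id = character(), n_pairs = integer(),
                          pairs = character(), lineages = character()))
    }
    long <- data.frame(
        gene_id = unlist(per_pair, use.names = FALSE),
        pair = rep(names(per_pair), lengths(per_pair)))
    long$lineage <- pair_lineage[long$pair]
    out <- lapply(split(long, long$gene_id), function(x) {
        if (nrow(x) >= min_pairs && length(unique(x$lineage)) >= 2)
            data.frame(gene_id = x$gene_id[1], n_pairs = nrow(x),
                       pairs = paste(sort(x$pair), collapse = ","),
                       lineages = paste(sort(unique(x$lineage)), collapse = ","))
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(gene_id = character(), n_pairs = integer(),
                          pairs = character(), lineages = character())
    rownames(out) <- NULL
    out
}

#' Intersect the F_ST scan with the supporting methods
#'
#' Top candidates are the parallel F_ST candidates confirmed by at least one
#' of the repeated-adaptation scan or the environmental association scan:
#' `fst \%in\% (repeatability U association)`, with per-gene provenance.
#'
#' @param fst_parallel gene ids from [parallelCandidates()].
#' @param repeatability_genes gene ids from the repeated-adaptation scan.
#' @param assoc_genes gene ids from the association scan.
#' @return data.frame: gene_id, methods (comma-separated provenance).
#' @export
topCandidates <- function(fst_parallel, repeatability_genes, assoc_genes) {
    keep <- fst_parallel[fst_parallel %in% union(repeatability_genes, assoc_genes)]
    methods <- vapply(keep, function(g) paste(c("fst_scan",
        if (g %in% repeatability_genes) "repeatability",
        if (g %in% assoc_genes) "env_assoc"), collapse = ","), "")
    data.frame(gene_id = keep, methods = unname(methods))
}

#' Hypergeometric test of gene-set overlap
#'
#' Upper-tail probability `P(X >= overlap)` of drawing the observed overlap
#' when two sets of the given sizes are sampled independently from a
#' universe of `universe_size` genes (Fisher's exact test, one-sided).
#'
#' @param n_a,n_b set sizes.
#' @param overlap observed overlap.
#' @param universe_size number of genes in the comparison universe. The
#'   appropriate universe is analysis-dependent; a sensible default is the
#'   count of annotated genes overlapping at least one analyzable window.
#' @return p-value.
#' @export
overlapTest <- function(n_a, n_b, overlap, universe_size) {
    stopifnot(overlap <= min(n_a, n_b), n_a <= universe_size,
              n_b <= universe_size)
    if (universe_size < n_a + n_b - overlap)
        stop("universe smaller than the union of the two sets", call. = FALSE)
    stats::phyper(overlap - 1, n_a, universe_size - n_a, n_b,
                  lower.tail = FALSE)
}

#' Permutation test of candidate-gene recombination rates
#'
#' One-sided test of whether candidate genes sit in regions of elevated
#' recombination: the observed mean rate over candidates is compared with
#' means of `n_perm` equally sized random gene draws (without replacement);
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param candidate_genes character vector of candidate gene ids.
#' @param rates named numeric vector, gene id -> recombination rate.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return list: p, observed, n_used, coverage.
#' @export
recombinationPermutationTest <- function(candidate_genes, rates,
                                         n_perm = 10000, seed = 1L) {
    if (length(candidate_genes) == 0)
        stop("empty candidate set", call. = FALSE)
    have <- candidate_genes %in% names(rates)
    coverage <- mean(have)
    if (coverage < 0.9)
        warning(sprintf("recombination rate available for only %.0f%% of candidates",
                        100 * coverage))
    obs_rates <- rates[candidate_genes[have]]
    k <- length(obs_rates)
    if (k == 0) stop("no candidate has a recombination rate", call. = FALSE)
    observed <- mean(obs_rates)
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) mean(sample(rates, k)), 0)
    list(p = (1 + sum(null >= observed)) / (n_perm + 1),
         observed = observed, n_used = k, coverage = coverage)
}
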