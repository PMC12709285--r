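#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' GenotypeMatrix: mixed-ploidy genotype dosages with site metadata
#'
#' A `RangedSummarizedExperiment` holding per-site, per-sample derived- (or
#' alternate-) allele dosages for a mixed-ploidy resequencing study. Rows are
#' biallelic SNPs (a [GenomicRanges::GRanges] with `ref`, `alt` and
#' `ancestral` metadata columns), columns are samples with `population`,
#' `ploidy` (2 or 4) and `lineage` assignments. Assays are `dosage` (integer
#' in `[0, ploidy]`, `NA` when missing) and `depth` (sequencing depth).
#'
#' The `ancestral` column is one of `"ref"`, `"alt"` or `"unknown"`; after
#' [polarizeGenotypes()] dosages count derived alleles wherever the ancestral
#' state is known.
#'
#' @slot ... inherited from `RangedSummarizedExperiment`.
#' @seealso [GenotypeMatrix()] for the constructor, [readMixedVcf()].
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

.validGenotypeMatrix <- function(object) {
    msg <- NULL
    if (!all(c("dosage", "depth") %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assays 'dosage' and 'depth' are required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("sample_id", "population", "ploidy", "lineage") %in% colnames(cd)))
        msg <- c(msg, "colData needs sample_id, population, ploidy, lineage")
    else {
        if (anyDuplicated(cd$sample_id))
            msg <- c(msg, "sample_ids must be unique")
        if (!all(cd$ploidy %in% c(2L, 4L)))
            msg <- c(msg, "ploidy must be 2 or 4")
        pl <- tapply(cd$ploidy, cd$population, function(x) length(unique(x)))
        if (any(pl > 1))
            msg <- c(msg, "each population must have a single ploidy")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (!all(c("ref", "alt", "ancestral") %in% colnames(S4Vectors::mcols(rr))))
        msg <- c(msg, "rowRanges need ref, alt, ancestral metadata columns")
    if (is.null(msg) && ncol(object) > 0 && nrow(object) > 0) {
        d <- SummarizedExperiment::assay(object, "dosage")
        pmax_ok <- sweep(d, 2, cd$ploidy, `<=`) | is.na(d)
        if (!all(pmax_ok))
            msg <- c(msg, "dosage exceeds sample ploidy")
        if (any(d < 0, na.rm = TRUE))
            msg <- c(msg, "negative dosages")
        if (GenomicRanges::isDisjoint(rr)) {
            o <- order(GenomicRanges::seqnames(rr), GenomicRanges::start(rr))
            if (!identical(o, seq_along(rr)))
                msg <- c(msg, "sites must be sorted by scaffold then position")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' AlleleFreqTable: population-level derived-allele frequencies
#'
#' Per-site, per-population derived-allele frequencies together with the
#' number of chromosomes (allele copies) actually sampled, i.e. the summed
#' ploidy of non-missing genotypes. Frequencies are `NA`, never 0, when all
#' samples of a population are missing at a site.
#'
#' @slot freq numeric matrix, sites x populations, values in `[0, 1]` or `NA`.
#' @slot chrom integer matrix, same shape, chromosomes sampled.
#' @slot sites `GRanges` of the sites (same order as rows).
#' @slot populations character vector naming the columns.
#' @export
setClass("AlleleFreqTable",
    representation(freq = "matrix", chrom = "matrix", sites = "GRanges",
                   populations = "character"))

setValidity("AlleleFreqTable", function(object) {
    msg <- NULL
    if (!identical(dim(object@freq), dim(object@chrom)))
        msg <- c(msg, "freq and chrom dimensions differ")
    if (length(object@sites) != nrow(object@freq))
        msg <- c(msg, "sites length != freq rows")
    if (length(object@populations) != ncol(object@freq))
        msg <- c(msg, "populations length != freq cols")
    f <- object@freq
    if (any(f < 0 | f > 1, na.rm = TRUE))
        msg <- c(msg, "frequencies outside [0,1]")
    if (is.null(msg)) TRUE else msg
})

#' SimConfig: parameters of the synthetic mixed-ploidy study
#'
#' Frozen description of the simulated study design: hierarchically structured
#' diploid and autotetraploid lineages, each containing calcareous/siliceous
#' population pairs, with sweeps of stated strength planted inside annotated
#' genes. Allele frequencies follow a Balding-Nichols hierarchy
#' (ancestral Beta frequency, lineage drift `F_lineage`, population drift
#' `F_pop`); at swept loci the siliceous population of each affected pair is
#' pushed toward the derived allele by an amount increasing in the selection
#' coefficient `s`, capped at `tetraploid_freq_cap` in tetraploids.
#'
#' @slot n_lineages_per_ploidy integer, lineages per ploidy level.
#' @slot pops_per_lineage integer (even), populations per lineage, arranged in
#'   calcareous/siliceous pairs.
#' @slot inds_per_pop integer, individuals sequenced per population.
#' @slot n_scaffolds,scaffold_len integer, genome layout in bp.
#' @slot snp_density numeric, SNPs per bp.
#' @slot F_lineage,F_pop numeric drift parameters in (0, 1).
#' @slot sweep_loci data.frame with columns `gene_index`, `s`, `mode`
#'   (`denovo`/`standing`/`migration`), `ploidy` (2, 4 or 0 for both).
#' @slot sweep_half_width numeric, bp over which the planted frequency
#'   elevation decays to zero beyond the gene edges.
#' @slot tetraploid_freq_cap numeric in (0, 1], maximum pushed derived
#'   frequency in tetraploids (dominance-like fixation cap).
#' @slot missing_rate numeric, fraction of genotype calls set missing.
#' @slot mean_depth numeric, mean simulated sequencing depth.
#' @slot seed integer master seed.
#' @seealso [SimConfig()], [simulateDataset()].
#' @export
setClass("SimConfig",
    representation(
        n_lineages_per_ploidy = "integer",
        pops_per_lineage = "integer",
        inds_per_pop = "integer",
        n_scaffolds = "integer",
        scaffold_len = "integer",
        snp_density = "numeric",
        F_lineage = "numeric",
        F_pop = "numeric",
        sweep_loci = "data.frame",
        sweep_half_width = "numeric",
        tetraploid_freq_cap = "numeric",
        missing_rate = "numeric",
        mean_depth = "numeric",
        seed = "integer"))

#' SyntheticBundle: a complete synthetic study with known ground truth
#'
#' Everything the scan pipeline consumes, generated in one deterministic draw:
#' genotypes ([GenotypeMatrix]), gene models, soil chemistry, per-gene
#' recombination rates, a protein-interaction edge list with ID mapping,
#' adaptation-mode case assignments, and a truth table of the planted sweeps.
#'
#' @slot geno [GenotypeMatrix] of all samples, both ploidies.
#' @slot genes `GRanges` of gene models (`gene_id` metadata column).
#' @slot soil data.frame of soil chemistry per population.
#' @slot recomb data.frame `gene_id`, `rate` (recombination rate per gene).
#' @slot edges data.frame `protein1`, `protein2`, `combined_score`.
#' @slot idmap data.frame `gene_id`, `protein_id`.
#' @slot truth data.frame, one row per planted sweep.
#' @slot modes data.frame of adaptation-mode cases (gene x quartet).
#' @slot config the [SimConfig] that produced the bundle.
#' @export
setClass("SyntheticBundle",
    representation(geno = "GenotypeMatrix", genes = "GRanges",
                   soil = "data.frame", recomb = "data.frame",
                   edges = "data.frame", idmap = "data.frame",
                   truth = "data.frame", modes = "data.frame",
                   config = "SimConfig"))

setValidity("SyntheticBundle", function(object) {
    msg <- NULL
    if (nrow(object@truth) != nrow(object@config@sweep_loci))
        msg <- c(msg, "truth table rows != planted sweep count")
    if (nrow(object@truth) > 0) {
        hit <- GenomicRanges::countOverlaps(
            GenomicRanges::GRanges(object@truth$scaffold,
                IRanges::IRanges(object@truth$gene_start, object@truth$gene_end)),
            object@genes)
        if (any(hit == 0))
            msg <- c(msg, "a planted sweep lies outside all annotated genes")
    }
    if (is.null(msg)) TRUE else msg
})
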