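#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix, sites x samples, allele dosages in
#'   `[0, ploidy]`, `NA` for missing calls.
#' @param depth integer matrix of sequencing depths, same shape (defaults to
#'   a constant high depth when not supplied).
#' @param sites `GRanges` of width-1 SNP positions (1-based, as in VCF) with
#'   metadata columns `ref`, `alt` and optionally `ancestral`.
#' @param samples data.frame with columns `sample_id`, `population`, `ploidy`
#'   (2 or 4), `lineage`, and optionally `soil_pc1`.
#' @return A [GenotypeMatrix-class] object, sites sorted by scaffold and
#'   position.
#' @examples
#' sites <- GenomicRanges::GRanges("sc1", IRanges::IRanges(c(10, 40), width = 1),
#'                                 ref = "A", alt = "T")
#' smp <- data.frame(sample_id = c("d1", "t1"), population = c("P1", "P2"),
#'                   ploidy = c(2L, 4L), lineage = c("L1", "L2"))
#' gm <- GenotypeMatrix(matrix(c(1L, 3L, 0L, 4L), 2), sites = sites, samples = smp)
#' dosage(gm)
#' @export
GenotypeMatrix <- function(dosage, depth = NULL, sites, samples) {
    stopifnot(is.matrix(dosage), length(sites) == nrow(dosage),
              nrow(samples) == ncol(dosage))
    if (is.null(depth))
        depth <- matrix(30L, nrow(dosage), ncol(dosage))
    if (is.null(S4Vectors::mcols(sites)$ancestral))
        S4Vectors::mcols(sites)$ancestral <- "unknown"
    o <- order(as.factor(GenomicRanges::seqnames(sites)),
               GenomicRanges::start(sites))
    storage.mode(dosage) <- "integer"
    storage.mode(depth) <- "integer"
    dosage <- dosage[o, , drop = FALSE]
    depth <- depth[o, , drop = FALSE]
    sites <- sites[o]
    rownames(dosage) <- rownames(depth) <- NULL
    colnames(dosage) <- colnames(depth) <- samples$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage, depth = depth),
        rowRanges = sites,
        colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
    new("GenotypeMatrix", se)
}

#' Accessors for GenotypeMatrix
#'
#' `dosage()` and `readDepth()` return the assay matrices; `samplePloidy()`,
#' `populations()` and `sampleTable()` expose the per-sample metadata;
#' `ancestralAllele()` returns the per-site ancestral state
#' (`"ref"`, `"alt"` or `"unknown"`).
#'
#' @param x a [GenotypeMatrix-class].
#' @name GenotypeMatrix-accessors
#' @aliases dosage readDepth samplePloidy populations sampleTable ancestralAllele
NULL

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("dosage", "GenotypeMatrix", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("readDepth", "GenotypeMatrix", function(x)
    SummarizedExperiment::assay(x, "depth"))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("samplePloidy", "GenotypeMatrix", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$ploidy,
                    SummarizedExperiment::colData(x)$sample_id))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("populations", "GenotypeMatrix", function(x)
    stats::setNames(as.character(SummarizedExperiment::colData(x)$population),
                    SummarizedExperiment::colData(x)$sample_id))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("sampleTable", "GenotypeMatrix", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname GenotypeMatrix-accessors
#' @export
setMethod("ancestralAllele", "GenotypeMatrix", function(x)
    S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$ancestral)

setMethod("show", "GenotypeMatrix", function(object) {
    cd <- SummarizedExperiment::colData(object)
    d <- SummarizedExperiment::assay(object, "dosage")
    cat("GenotypeMatrix:", nrow(object), "biallelic SNPs x",
        ncol(object), "samples\n")
    cat("  populations:", length(unique(cd$population)),
        " | ploidy:", paste(sort(unique(cd$ploidy)), collapse = "/"),
        " | lineages:", length(unique(cd$lineage)), "\n")
    cat(sprintf("  missing genotypes: %.2f%% | polarized sites: %d/%d\n",
        100 * mean(is.na(d)),
        sum(ancestralAllele(object) != "unknown"), nrow(object)))
})

#' @rdname AlleleFreqTable-accessors
#' @param x an [AlleleFreqTable-class].
#' @name AlleleFreqTable-accessors
#' @export
setMethod("freqs", "AlleleFreqTable", function(x) x@freq)

#' @rdname AlleleFreqTable-accessors
#' @export
setMethod("chromosomesSampled", "AlleleFreqTable", function(x) x@chrom)

setMethod("show", "AlleleFreqTable", function(object) {
    cat("AlleleFreqTable:", nrow(object@freq), "sites x",
        length(object@populations), "populations\n")
})

setMethod("show", "SimConfig", function(object) {
    n_pop <- 2L * object@n_lineages_per_ploidy * object@pops_per_lineage
    cat("SimConfig:", object@n_lineages_per_ploidy, "lineages/ploidy,",
        object@pops_per_lineage, "pops/lineage (", n_pop, "pops ),",
        object@inds_per_pop, "inds/pop\n")
    cat("  genome:", object@n_scaffolds, "x", object@scaffold_len,
        "bp, SNP density", object@snp_density, "\n")
    cat("  F_lineage", object@F_lineage, "F_pop", object@F_pop,
        "| sweeps:", nrow(object@sweep_loci),
        "| 4x cap", object@tetraploid_freq_cap, "| seed", object@seed, "\n")
})

setMethod("show", "SyntheticBundle", function(object) {
    cat("SyntheticBundle with", nrow(object@geno), "SNPs,",
        ncol(object@geno), "samples,", length(object@genes), "genes,",
        nrow(object@truth), "planted sweeps\n")
})
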