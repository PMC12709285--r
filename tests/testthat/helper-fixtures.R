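## Shared fixtures, generated in code once per test run.

GR <- function(scaffold, pos)
    GenomicRanges::GRanges(scaffold, IRanges::IRanges(pos, width = 1L),
                           ref = "A", alt = "T")

geneGR <- function(scaffold, start, end, id)
    GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end),
                           gene_id = id)

## small mixed-ploidy genotype matrix: 2 diploid + 2 tetraploid populations,
## 3 individuals each, deterministic dosages
tinyGm <- function(dosage = NULL, depth = NULL, n_sites = 6) {
    smp <- data.frame(
        sample_id = paste0(rep(c("p1", "p2", "p3", "p4"), each = 3), "_i", 1:3),
        population = rep(c("p1", "p2", "p3", "p4"), each = 3),
        ploidy = rep(c(2L, 2L, 4L, 4L), each = 3),
        lineage = rep(c("L1", "L2", "L1", "L2"), each = 3))
    if (is.null(dosage)) {
        set.seed(11)
        dosage <- matrix(0L, n_sites, 12)
        for (j in 1:12)
            dosage[, j] <- rbinom(n_sites, smp$ploidy[j], 0.4)
    }
    sites <- GR("sc01", seq(100, by = 200, length.out = nrow(dosage)))
    GenotypeMatrix(dosage, depth, sites, smp)
}

## bundle cache: the small fixture study (two lineages/ploidy, two scaffolds)
.fixture_env <- new.env()
fixtureBundle <- function() {
    if (is.null(.fixture_env$bundle))
        .fixture_env$bundle <- makeFixtures(7L)
    .fixture_env$bundle
}

## default-condition bundle cache (used by acceptance-level checks)
defaultBundle <- function() {
    if (is.null(.fixture_env$default))
        .fixture_env$default <- simulateDataset(SimConfig())
    .fixture_env$default
}
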