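test_that("config validation rejects out-of-range values with the parameter name", {
    expect_error(SimConfig(F_pop = 1.2), "F_pop")
    expect_error(SimConfig(missing_rate = -0.1), "missing_rate")
    expect_error(SimConfig(tetraploid_freq_cap = 0), "tetraploid_freq_cap")
    expect_error(SimConfig(snp_density = NaN), "snp_density")
    expect_error(SimConfig(pops_per_lineage = 3), "pops_per_lineage")
    expect_error(SimConfig(scaffold_len = 5000), "scaffold_len")
})

test_that("identical config and seed give byte-identical bundles", {
    cfg <- SimConfig(n_lineages_per_ploidy = 2L, n_scaffolds = 1L,
                     scaffold_len = 60000L, inds_per_pop = 3L, seed = 99L)
    b1 <- simulateDataset(cfg)
    b2 <- simulateDataset(cfg)
    expect_identical(dosage(b1@geno), dosage(b2@geno))
    expect_identical(b1@soil, b2@soil)
    expect_identical(b1@edges, b2@edges)
    d1 <- file.path(tempdir(), "bnd1"); d2 <- file.path(tempdir(), "bnd2")
    writeBundle(b1, d1, overwrite = TRUE)
    writeBundle(b2, d2, overwrite = TRUE)
    expect_identical(readLines(file.path(d1, "genotypes.vcf")),
                     readLines(file.path(d2, "genotypes.vcf")))
})

test_that("without drift below the lineage level, window F_ST is centred at zero", {
    cfg <- SimConfig(n_lineages_per_ploidy = 1L, n_scaffolds = 1L,
                     scaffold_len = 530000L, F_pop = 0,
                     sweep_loci = data.frame(), missing_rate = 0, seed = 5L)
    ## single lineage per ploidy: no quartets exist, which warns by design
    bnd <- suppressWarnings(simulateDataset(cfg))
    sc <- differentiationScan(bnd@geno, "dip_L1_cal1", "dip_L1_sil1")
    expect_gte(nrow(sc$windows), 500)
    ## unclamped per-window ratio-of-sums, Monte-Carlo mean against zero
    s <- sc$snps[!is.na(sc$snps$fst_num), ]
    win <- paste(s$scaffold, (s$pos - 1) %/% 1000)
    wfst <- rowsum(s$fst_num, win)[, 1] / rowsum(s$fst_den, win)[, 1]
    se <- sd(wfst) / sqrt(length(wfst))
    expect_lt(abs(mean(wfst)), 3 * se)
})

test_that("the tetraploid frequency cap suppresses fixed differences that diploids reach", {
    cfg <- SimConfig(n_lineages_per_ploidy = 2L, n_scaffolds = 1L,
                     scaffold_len = 120000L, inds_per_pop = 6L,
                     sweep_loci = data.frame(gene_index = 5L, s = 0.5,
                                             mode = "standing", ploidy = 0L),
                     sweep_half_width = 15000, tetraploid_freq_cap = 0.85,
                     seed = 21L)
    bnd <- simulateDataset(cfg)
    aft <- populationFrequencies(bnd@geno)
    gene <- list(scaffold = bnd@truth$scaffold[1],
                 start = bnd@truth$gene_start[1], end = bnd@truth$gene_end[1])
    n_dip <- fixedSnpCount(freqs(aft)[, "dip_L1_cal1"],
                           freqs(aft)[, "dip_L1_sil1"], aft@sites, gene)
    n_tet <- fixedSnpCount(freqs(aft)[, "tet_L1_cal1"],
                           freqs(aft)[, "tet_L1_sil1"], aft@sites, gene)
    expect_gte(n_dip, 1)
    expect_identical(as.integer(n_tet), 0L)
})

test_that("written bundles follow the exchange formats", {
    bnd <- fixtureBundle()
    dir <- file.path(tempdir(), "bundle_fmt")
    manifest <- writeBundle(bnd, dir, overwrite = TRUE)
    ## refusal on existing non-empty directory
    expect_error(writeBundle(bnd, dir), "non-empty")
    vcf <- readLines(file.path(dir, "genotypes.vcf"))
    expect_identical(vcf[1], "##fileformat=VCFv4.2")
    body <- vcf[!startsWith(vcf, "#")]
    smp <- sampleTable(bnd@geno)
    tet_col <- 9L + which(smp$ploidy == 4L)[1]
    dos_tet <- dosage(bnd@geno)[, which(smp$ploidy == 4L)[1]]
    i2 <- which(dos_tet == 2L)[1]
    gt <- sub(":.*", "", strsplit(body[i2], "\t")[[1]][tet_col])
    expect_identical(gt, "0/0/1/1")  # four alleles, two alternate
    ## GFF3 gene count equals the gene models
    gff <- readLines(file.path(dir, "genes.gff3"))
    expect_identical(sum(grepl("\tgene\t", gff)), length(bnd@genes))
    ## manifest lists every file with a checksum
    expect_true(all(vapply(manifest, function(m)
        nchar(m$md5) == 32 && file.exists(file.path(dir, m$path)), TRUE)))
})

test_that("write / read round-trip reproduces the dosage matrix", {
    bnd <- fixtureBundle()
    dir <- file.path(tempdir(), "bundle_rt")
    writeBundle(bnd, dir, overwrite = TRUE)
    gm2 <- readMixedVcf(file.path(dir, "genotypes.vcf"),
                        sampleTable(bnd@geno))
    expect_identical(unname(dosage(gm2)), unname(dosage(bnd@geno)))
    expect_identical(GenomicRanges::start(SummarizedExperiment::rowRanges(gm2)),
                     GenomicRanges::start(SummarizedExperiment::rowRanges(bnd@geno)))
    ## full bundle directory read-back drives the same pipeline input
    bnd2 <- readBundleDir(dir)
    expect_identical(unname(dosage(bnd2@geno)), unname(dosage(bnd@geno)))
    expect_identical(bnd2@truth$gene_id, bnd@truth$gene_id)
})

test_that("planted sweeps lie inside annotated genes and the truth table is complete", {
    bnd <- fixtureBundle()
    expect_identical(nrow(bnd@truth), nrow(bnd@config@sweep_loci))
    hits <- GenomicRanges::countOverlaps(
        GenomicRanges::GRanges(bnd@truth$scaffold,
            IRanges::IRanges(bnd@truth$gene_start, bnd@truth$gene_end)),
        bnd@genes)
    expect_true(all(hits >= 1))
})
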