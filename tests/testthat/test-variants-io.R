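## hand-written VCF fragments for GT parsing edge cases
writeTestVcf <- function(rows, samples) {
    path <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples), collapse = "\t"),
        rows), path)
    path
}

test_that("mixed-ploidy GT strings parse to dosages, partial calls are missing", {
    smp <- data.frame(sample_id = c("d1", "t1"), population = c("P1", "P2"),
                      ploidy = c(2L, 4L), lineage = c("L1", "L2"))
    path <- writeTestVcf(c(
        "sc1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:20\t0/0/0/1:22",
        "sc1\t200\t.\tG\tC\t.\tPASS\t.\tGT:DP\t./.:9\t./0/0/1:15",
        "sc1\t300\t.\tA\tC,G\t.\tPASS\t.\tGT:DP\t0/1:12\t0/0/1/1:12",
        "sc1\t400\t.\tT\tA\t.\tPASS\t.\tGT:DP\t1/1:30\t1/1/1/1:31"),
        c("d1", "t1"))
    gm <- readMixedVcf(path, smp)
    expect_identical(nrow(gm), 3L)  # multi-allelic record dropped
    expect_identical(S4Vectors::metadata(gm)$log$n_multiallelic_dropped, 1L)
    d <- dosage(gm)
    expect_identical(d[1, ], c(d1 = 1L, t1 = 1L))  # 0/0/0/1 -> 1
    expect_true(all(is.na(d[2, ])))                # ./. and ./0/0/1 missing
    expect_identical(d[3, ], c(d1 = 2L, t1 = 4L))
})

test_that("GT arity mismatching the declared ploidy is a per-record error", {
    smp <- data.frame(sample_id = "s1", population = "P1", ploidy = 4L,
                      lineage = "L1")
    path <- writeTestVcf("sc1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:20", "s1")
    expect_error(readMixedVcf(path, smp), "s1.*sc1:100")
    path2 <- writeTestVcf("sc1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:20", "sX")
    expect_error(readMixedVcf(path2, smp), "sX")  # missing metadata is fatal
})

test_that("site filters apply depth, missingness and MAF rules in order", {
    set.seed(3)
    n <- 20
    dos <- sapply(rep(c(2L, 2L, 4L, 4L), each = 3), function(pl)
        rbinom(n, pl, 0.4))
    depth <- matrix(30L, n, 12)
    depth[1, 1] <- 7L                       # low-depth cell -> missing
    dos[2, 1:7] <- NA                       # 7/12 missing > 0.5 -> site out
    gm <- tinyGm(dos, depth)
    out <- filterSites(gm, min_depth = 8, max_missing = 0.5)
    log <- S4Vectors::metadata(out)$filter_log
    expect_identical(log$n_cells_depth_masked, 1L)
    expect_true(log$n_removed_missing >= 1)
    kept_pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(out))
    expect_false(300 %in% kept_pos)         # site 2 sits at pos 300
    expect_true(is.na(dosage(out)[1, 1]))   # depth-7 cell masked

    ## brute-force enumeration oracle for the surviving site count
    surv <- 0L
    for (i in seq_len(n)) {
        d <- dos[i, ]
        d[depth[i, ] < 8] <- NA
        miss <- mean(is.na(d))
        ch <- sum(c(2, 2, 4, 4)[(0:11) %/% 3 + 1][!is.na(d)])
        f <- sum(d, na.rm = TRUE) / ch
        if (miss <= 0.5 && !is.nan(f) && min(f, 1 - f) >= 0.05) surv <- surv + 1L
    }
    out2 <- filterSites(gm, min_depth = 8, max_missing = 0.5, maf = 0.05)
    expect_identical(nrow(out2), surv)
})

test_that("fixed-heterozygosity paralog masking follows the 5-SNPs-2-pops rule", {
    n <- 8
    dos <- matrix(0L, n, 12)
    dos[, 7:12] <- 1L
    ## sites 1-5 fixed heterozygous in both diploid pops; tetraploids dosage 2
    dos[1:5, 1:6] <- 1L
    dos[1:5, 7:12] <- 2L
    gm <- tinyGm(dos)
    genes <- geneGR("sc01", c(50, 1150), c(1100, 1700), c("gA", "gB"))
    mask <- maskParalogGenes(gm, genes)  # sites at 100,300,...  gA covers 1-5
    expect_true(all(mask[1:5]))
    expect_identical(attr(mask, "masked_genes"), "gA")
    ## four qualifying SNPs only -> not masked
    dos4 <- dos; dos4[5, ] <- 0L
    mask4 <- maskParalogGenes(tinyGm(dos4), genes)
    expect_false(any(mask4))
    ## tetraploid all-dosage-2 SNPs alone also qualify (ploidy/2 = 2)
    dos_t <- matrix(0L, n, 12); dos_t[1:5, 7:12] <- 2L
    mask_t <- maskParalogGenes(tinyGm(dos_t), genes)
    expect_true(all(mask_t[1:5]))
})

test_that("excess-depth masking matches a brute-force recomputation", {
    gm0 <- tinyGm(n_sites = 50)
    set.seed(8)
    depth <- matrix(rpois(50 * 12, 25), 50, 12)
    depth[7, ] <- 120L  # spike site
    gm <- tinyGm(dosage(gm0), depth)
    mask <- maskExcessDepth(gm, sd_multiplier = 2, min_individuals = 10)
    oracle <- logical(50)
    for (i in 1:50) {
        ex <- 0L
        for (j in 1:12)
            if (depth[i, j] > mean(depth[, j]) + 2 * sd(depth[, j])) ex <- ex + 1L
        oracle[i] <- ex >= 10
    }
    expect_identical(mask, oracle)
    expect_true(mask[7])
    ## uniform depth: SD = 0, exceedance is strict, nothing masked
    gm_u <- tinyGm(dosage(gm0), matrix(30L, 50, 12))
    expect_false(any(maskExcessDepth(gm_u, min_individuals = 1)))
})

test_that("polarization applies the 0.7 threshold and flips dosages for alt-ancestral sites", {
    gm <- tinyGm()
    rr <- SummarizedExperiment::rowRanges(gm)
    key <- data.frame(scaffold = "sc01",
                      pos = GenomicRanges::start(rr)[1:4],
                      p_ref_ancestral = c(0.9, 0.69, 0.2, 0.3))
    out <- polarizeGenotypes(gm, key)
    anc <- ancestralAllele(out)
    expect_identical(anc[1:4], c("ref", "unknown", "alt", "alt"))
    expect_identical(anc[5:6], c("unknown", "unknown"))  # not in key
    d0 <- dosage(gm); d1 <- dosage(out)
    expect_identical(d1[1, ], d0[1, ])                         # unchanged
    pl <- samplePloidy(gm)
    expect_identical(d1[3, ], pl - d0[3, ])                    # complement
    ## involution: flipping the flipped rows again restores the original
    d2 <- rep(pl, each = 2) - d1[3:4, ]
    expect_identical(d2, d0[3:4, ])
    expect_error(polarizeGenotypes(gm, transform(key, p_ref_ancestral = 1.4)),
                 "\\[0,1\\]")
})

test_that("population frequencies distinguish absence from zero", {
    dos <- matrix(NA_integer_, 3, 12)
    dos[1, ] <- c(1L, 1L, 0L, 1L, 1L, 0L, rep(2L, 6))
    dos[2, 7:9] <- 3L
    gm <- tinyGm(dos)
    aft <- populationFrequencies(gm)
    f <- freqs(aft)
    expect_equal(unname(f[1, "p1"]), 2 / 6)  # dosages 1,1,0 over 6 chromosomes
    expect_equal(unname(f[2, "p3"]), 0.75)   # one tetraploid pattern: 3/4 each
    expect_true(all(is.na(f[3, ])))          # all missing -> NA, not 0
    expect_identical(unname(chromosomesSampled(aft)[2, "p3"]), 12L)
    expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
})
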