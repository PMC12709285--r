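test_that("the window grid is anchored at position 1 and enforces the SNP minimum", {
    w10 <- buildWindows(GR("sc01", 1:10), 1000, 10)
    expect_identical(length(w10), 1L)
    expect_identical(GenomicRanges::start(w10), 1L)
    expect_identical(GenomicRanges::end(w10), 1000L)
    w9 <- buildWindows(GR("sc01", 1:9), 1000, 10)
    expect_identical(length(w9), 0L)
    expect_identical(attr(w9, "n_discarded"), 1L)
    ## positions 1000 and 1001 fall in adjacent grid windows
    wb <- buildWindows(GR("sc01", c(1000, 1001)), 1000, 1)
    expect_identical(GenomicRanges::start(wb), c(1L, 1001L))
})

test_that("outlier calling uses the ceiling rule and includes cutoff ties", {
    expect_length(outlierWindows(seq_len(1000) / 1000), 10)
    expect_length(outlierWindows(seq_len(250)), 3)       # ceiling(2.5) = 3
    ## ties at the cutoff all included
    x <- c(rep(1, 5), seq(0, 0.9, length.out = 495))
    idx <- outlierWindows(x, 0.01)
    expect_identical(sort(idx[1:5]), 1:5)
    expect_identical(attr(idx, "n_ties_added"), 0L)
    xt <- c(rep(1, 7), seq(0, 0.9, length.out = 493))
    expect_length(outlierWindows(xt, 0.01), 7)           # 5 needed, 7 tied
    expect_error(outlierWindows(rep(1, 500)), "identical")
    expect_error(outlierWindows(1:50), "100")
})

test_that("gene annotation matches a quadratic interval-intersection oracle", {
    genes <- geneGR("sc01", c(999, 1001), c(1500, 1500), c("gA", "gB"))
    win <- GenomicRanges::GRanges("sc01", IRanges::IRanges(1, 1000))
    expect_identical(annotateGenes(win, genes), "gA")  # 2-bp overlap, gB misses
    set.seed(4)
    qs <- GenomicRanges::GRanges("sc01",
        IRanges::IRanges(sample(5000, 40), width = sample(500, 40)))
    gs <- geneGR("sc01", st <- sample(5000, 25), st + sample(800, 25),
                 paste0("g", 1:25))
    oracle <- character()
    for (i in seq_along(gs)) for (j in seq_along(qs)) {
        if (GenomicRanges::start(qs)[j] <= GenomicRanges::end(gs)[i] &&
            GenomicRanges::end(qs)[j] >= GenomicRanges::start(gs)[i])
            oracle <- c(oracle, gs$gene_id[i])
    }
    expect_setequal(annotateGenes(qs, gs), unique(oracle))
    expect_warning(annotateGenes(GenomicRanges::GRanges("scX",
        IRanges::IRanges(1, 10)), gs), "absent")
})

test_that("parallel candidates require support from distinct lineages", {
    per_pair <- list(pA = c("g1", "g2", "g3"), pB = c("g1", "g3"),
                     pC = c("g2", "g3"))
    lin <- c(pA = "L1", pB = "L2", pC = "L1")
    out <- parallelCandidates(per_pair, lin)
    ## g1: {L1, L2} kept; g2: {L1, L1} dropped; g3: {L1, L2, L1} kept
    expect_setequal(out$gene_id, c("g1", "g3"))
    expect_identical(out$n_pairs[out$gene_id == "g3"], 3L)
    expect_warning(parallelCandidates(list(a = "g1", b = "g1"),
                                      c(a = "L1", b = "L1")), "one lineage")
})

test_that("top candidates are the F_ST set confirmed by another method", {
    out <- topCandidates(c("g1", "g2", "g3"), c("g2", "g9"), c("g3", "g8"))
    expect_setequal(out$gene_id, c("g2", "g3"))
    expect_identical(out$methods[out$gene_id == "g2"], "fst_scan,repeatability")
    ## fst-only and non-fst genes are excluded; output is always a subset
    expect_false("g1" %in% out$gene_id)
    expect_false(any(c("g8", "g9") %in% out$gene_id))
})

test_that("the overlap test equals the exact hypergeometric tail sum", {
    expect_equal(overlapTest(10, 10, 0, 100), 1)
    oracle <- sum(dhyper(5:10, 10, 90, 10))
    expect_equal(overlapTest(10, 10, 5, 100), oracle)
    ## overlap at its maximum with a tiny universe: single pmf term
    expect_equal(overlapTest(3, 5, 3, 6), dhyper(3, 3, 3, 5))
    expect_error(overlapTest(8, 8, 0, 10), "universe")
})

test_that("the recombination permutation test hits its analytic extremes", {
    rates <- setNames(rlnorm(200), paste0("g", 1:200))
    all_p <- recombinationPermutationTest(names(rates), rates, n_perm = 200,
                                          seed = 1)
    expect_equal(all_p$p, 1)
    topk <- names(sort(rates, decreasing = TRUE))[1:5]
    top_p <- recombinationPermutationTest(topk, rates, n_perm = 1000, seed = 1)
    expect_equal(top_p$p, 1 / 1001)
    expect_gte(top_p$p, 1 / (1000 + 1))          # permutation floor
    expect_error(recombinationPermutationTest(character(), rates), "empty")
    expect_warning(
        recombinationPermutationTest(c("g1", "nope", "alsono"), rates,
                                     n_perm = 50, seed = 1),
        "only")
})
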