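mkContrasts <- function(n, ploidy, lineages = NULL) {
    data.frame(pair_id = paste0("pl", ploidy, "_p", seq_len(n)),
               lineage = if (is.null(lineages)) paste0("L", seq_len(n))
                         else lineages,
               ploidy = ploidy)
}

test_that("quartet enumeration gives choose(n, 2) for lineage-distinct contrasts", {
    q6 <- enumerateQuartets(mkContrasts(6, 2L))
    expect_identical(nrow(q6), 15L)
    q4 <- enumerateQuartets(mkContrasts(4, 4L))
    expect_identical(nrow(q4), 6L)
    both <- enumerateQuartets(rbind(mkContrasts(6, 2L), mkContrasts(4, 4L)))
    expect_identical(nrow(both), 21L)
    expect_warning(q1 <- enumerateQuartets(mkContrasts(1, 2L)), "fewer")
    expect_identical(nrow(q1), 0L)
    ## same-lineage pairs are skipped
    qs <- enumerateQuartets(mkContrasts(3, 2L, c("L1", "L1", "L2")))
    expect_identical(nrow(qs), 2L)
})

test_that("mode tallies exclude neutral cases and keep zero-count modes", {
    cases <- data.frame(
        gene_id = "g", quartet_id = "q", ploidy = rep(c(2L, 4L), c(6, 4)),
        mode = c("standing", "standing", "denovo", "migration", "neutral",
                 "standing", "standing", "migration", "neutral", "neutral"),
        maxSel = 0.001)
    t <- tallyModes(cases)
    expect_equal(t$n[t$ploidy == 2 & t$mode == "standing"], 3L)
    expect_equal(t$fraction[t$ploidy == 2 & t$mode == "standing"], 3 / 5)
    expect_equal(t$n[t$ploidy == 4 & t$mode == "denovo"], 0L)
    expect_equal(sum(t$fraction[t$ploidy == 2]), 1)
    ## empty input: zero counts, no division error
    t0 <- tallyModes(cases[cases$mode == "neutral", ])
    expect_true(all(t0$n == 0) && all(t0$fraction == 0))
})

test_that("the continuity-corrected chi-square matches stats::chisq.test", {
    set.seed(17)
    for (i in 1:20) {
        tab <- matrix(rpois(4, 20) + 1, 2)
        got <- yatesChisq(tab)
        ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
        expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
        expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    }
    expect_equal(yatesChisq(matrix(10, 2, 2))$statistic, 0)
    ## correction clamps at zero rather than going negative
    expect_equal(yatesChisq(matrix(c(10, 9, 9, 10), 2))$statistic, 0)
    expect_error(yatesChisq(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("Fisher's exact two-tailed p equals full enumeration over fixed margins", {
    expect_equal(fisherExact2x2(matrix(5, 2, 2)), 1)
    tab <- matrix(c(1, 9, 9, 1), 2)
    rs <- rowSums(tab); cs <- colSums(tab)
    probs <- vapply(0:min(rs[1], cs[1]), function(a) {
        b <- rs[1] - a; c <- cs[1] - a; d <- rs[2] - c
        if (any(c(b, c, d) < 0)) return(NA_real_)
        exp(lchoose(cs[1], a) + lchoose(cs[2], b) - lchoose(sum(tab), rs[1]))
    }, 0)
    probs <- probs[!is.na(probs)]
    obs <- exp(lchoose(cs[1], tab[1, 1]) + lchoose(cs[2], tab[1, 2]) -
               lchoose(sum(tab), rs[1]))
    oracle <- sum(probs[probs <= obs * (1 + 1e-7)])
    expect_equal(fisherExact2x2(tab), oracle, tolerance = 1e-9)
    expect_error(fisherExact2x2(matrix(c(0, 5, 0, 5), 2)), "empty")
})

test_that("selection-strength bins are schema-stable with per-bin tests", {
    cases <- data.frame(gene_id = "g", quartet_id = "q",
                        ploidy = rep(c(2L, 4L), c(10, 8)),
                        mode = "standing",
                        maxSel = c(rep(0.5, 6), rep(0.001, 4),
                                   rep(0.001, 8)))
    out <- binSelectionStrength(cases)
    expect_identical(nrow(out$proportions), 10L)  # 5 bins x 2 ploidies
    p2 <- out$proportions[out$proportions$ploidy == 2, ]
    expect_equal(p2$fraction[p2$maxSel == 0.5], 0.6)
    expect_equal(p2$fraction[p2$maxSel == 0.0001], 0)
    one <- binSelectionStrength(transform(cases, maxSel = 0.01))
    po <- one$proportions
    expect_true(all(po$fraction[po$maxSel == 0.01] == 1))
    ## per-bin Fisher test present where both margins are populated
    expect_false(is.na(out$tests$p[out$tests$maxSel == 0.5]))
})

test_that("mode case tables round-trip through the TSV exchange format", {
    bnd <- fixtureBundle()
    path <- file.path(tempdir(), "modes.tsv")
    write.table(bnd@modes, path, sep = "\t", quote = FALSE, row.names = FALSE)
    back <- readModeCases(path)
    expect_identical(back$mode, bnd@modes$mode)
    bad <- transform(bnd@modes, maxSel = 0.3)
    write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readModeCases(path), "bin")
})
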