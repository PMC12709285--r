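## End-to-end orchestration: soil gradient -> filters -> frequencies ->
## diversity and differentiation scans -> outlier/parallel/association
## candidates -> method intersection -> sweep profiles -> fixation, mode and
## network comparisons. Stages communicate through the returned list only;
## every tunable is echoed into the manifest.

.defaultParams <- function() list(
    min_depth = 8, max_missing = 0.5,
    window_size = 1000, min_snps = 10,
    diversity_window = 50000, diversity_min_snps = 10, n_individuals = 4,
    outlier_quantile = 0.01, min_pairs = 2,
    picmin_reps = 10000, picmin_fdr = 0.05, alpha_adapt = 0.05,
    assoc_maf = 0.05, assoc_max_missing = 0.1, assoc_k = 2, assoc_fdr = 0.1,
    assoc_min_snps = 3,
    sweep_flank = 100000, sweep_bg_flank = 200000,
    n_chromosomes = 12, af_flank = 2000,
    n_perm = 10000, seed = 1L)

#' Run the full mixed-ploidy scan pipeline on a bundle
#'
#' Executes every stage in dependency order on a [SyntheticBundle-class]
#' (or a directory produced by [writeBundle()]): soil PCA, site filters and
#' masks, population frequencies, diversity scan, per-pair differentiation
#' scans, top-1\% outlier calling, lineage-aware parallel candidates, the
#' repeated-adaptation scan, the soil association scan, method intersection,
#' sweep profiling, fixation/relative-differentiation/allele-frequency
#' summaries, adaptation-mode tallies with contingency tests, and the
#' protein-interaction degree test. Deterministic for a fixed bundle and
#' `params$seed`.
#'
#' @param bundle a [SyntheticBundle-class] or a bundle directory path.
#' @param params named list overriding entries of the default parameter set;
#'   unknown names are rejected.
#' @return A list with one element per stage plus a `manifest` echoing
#'   parameters, seeds and per-stage row counts.
#' @export
runPipeline <- function(bundle, params = list()) {
    defaults <- .defaultParams()
    unknown <- setdiff(names(params), names(defaults))
    if (length(unknown))
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    prm <- utils::modifyList(defaults, params)
    if (is.character(bundle)) bundle <- readBundleDir(bundle)
    stopifnot(is(bundle, "SyntheticBundle"))
    res <- list()

    ## --- soil gradient -------------------------------------------------
    soil <- imputeSoil(bundle@soil)
    pca <- soilPCA(soil)
    soil_pc1 <- stats::setNames(pca$scores$pc1, pca$scores$population)
    res$soil <- list(pca = pca, pc1 = soil_pc1)

    ## --- filters and masks ---------------------------------------------
    gm <- filterSites(bundle@geno, min_depth = prm$min_depth,
                      max_missing = prm$max_missing)
    mask <- maskParalogGenes(gm, bundle@genes) | maskExcessDepth(gm)
    gm <- new("GenotypeMatrix", gm[!mask, ])
    res$filters <- list(log = S4Vectors::metadata(gm)$filter_log,
                        n_masked = sum(mask), n_sites = nrow(gm))

    smp <- sampleTable(gm)
    layout <- unique(smp[, c("population", "ploidy", "lineage", "pair_id",
                             "soil_class")])
    aft <- populationFrequencies(gm)
    res$frequencies <- aft

    ## --- within-population diversity -----------------------------------
    div <- diversityScan(gm, window_size = prm$diversity_window,
                         min_snps = prm$diversity_min_snps,
                         n_individuals = prm$n_individuals, seed = prm$seed)
    div$ploidy <- layout$ploidy[match(div$population, layout$population)]
    res$diversity <- list(
        windows = div,
        pop_means = if (nrow(div)) stats::aggregate(
            cbind(pi, tajimas_d) ~ population + ploidy, div,
            function(x) mean(x, na.rm = TRUE), na.action = stats::na.pass))

    ## --- per-pair differentiation scans ---------------------------------
    pairs <- unique(layout[, c("pair_id", "ploidy", "lineage")])
    scans <- list()
    for (i in seq_len(nrow(pairs))) {
        pp <- layout[layout$pair_id == pairs$pair_id[i], ]
        popA <- pp$population[pp$soil_class == "calcareous"]
        popB <- pp$population[pp$soil_class == "siliceous"]
        sc <- differentiationScan(gm, popA, popB, prm$window_size, prm$min_snps)
        ok <- !is.na(sc$snps$rho_num)
        sc$genomewide_rho <- sum(sc$snps$rho_num[ok]) /
            sum(sc$snps$rho_den[ok])
        okf <- !is.na(sc$snps$fst_num)
        sc$genomewide_fst <- sum(sc$snps$fst_num[okf]) /
            sum(sc$snps$fst_den[okf])
        scans[[pairs$pair_id[i]]] <- sc
    }
    res$scans <- scans

    ## --- F_ST outliers and parallel candidates --------------------------
    per_pair_genes <- lapply(scans, function(sc) {
        idx <- outlierWindows(sc$windows$fst, prm$outlier_quantile)
        w <- sc$windows[idx, ]
        annotateGenes(GenomicRanges::GRanges(w$scaffold,
            IRanges::IRanges(w$start, w$end)), bundle@genes)
    })
    pair_lineage <- stats::setNames(pairs$lineage, pairs$pair_id)
    parallel <- list()
    for (pl in c(2L, 4L)) {
        ids <- pairs$pair_id[pairs$ploidy == pl]
        parallel[[as.character(pl)]] <-
            parallelCandidates(per_pair_genes[ids], pair_lineage, prm$min_pairs)
    }
    res$outliers <- list(per_pair = per_pair_genes, parallel = parallel)

    ## --- repeated-adaptation scan (one contrast per lineage) -----------
    repeat_genes <- list()
    repeat_scans <- list()
    for (pl in c(2L, 4L)) {
        sub <- pairs[pairs$ploidy == pl, ]
        ## one contrast per lineage: the pair with the lowest genome-wide Rho
        chosen <- vapply(split(sub, sub$lineage), function(x)
            x$pair_id[which.min(vapply(x$pair_id, function(id)
                scans[[id]]$genomewide_rho, 0))], "")
        wtabs <- lapply(chosen, function(id) {
            w <- scans[[id]]$windows
            stats::setNames(w$fst, paste(w$scaffold, w$start))
        })
        shared <- Reduce(intersect, lapply(wtabs, names))
        if (length(shared) < 100 || length(chosen) < 3) next
        m <- vapply(wtabs, function(x) x[shared], numeric(length(shared)))
        pm <- empiricalPvalues(m)
        ras <- repeatedAdaptationScan(pm, n_reps = prm$picmin_reps,
                                      seed = prm$seed, fdr_q = prm$picmin_fdr,
                                      alpha_adapt = prm$alpha_adapt)
        sig <- shared[ras$significant]
        parts <- strsplit(sig, " ")
        gr <- GenomicRanges::GRanges(vapply(parts, `[`, "", 1),
            IRanges::IRanges(as.numeric(vapply(parts, `[`, "", 2)),
                             width = prm$window_size))
        repeat_genes[[as.character(pl)]] <- annotateGenes(gr, bundle@genes)
        repeat_scans[[as.character(pl)]] <- ras
    }
    res$repeatability <- list(genes = repeat_genes, scans = repeat_scans)

    ## --- environmental association --------------------------------------
    assoc_genes <- list()
    assoc_res <- list()
    for (pl in c(2L, 4L)) {
        cols <- smp$ploidy == pl
        gmp <- new("GenotypeMatrix", gm[, cols])
        gmp <- filterSites(gmp, min_depth = prm$min_depth,
                           max_missing = prm$assoc_max_missing,
                           maf = prm$assoc_maf)
        afp <- populationFrequencies(gmp)
        ## cap the latent-factor count so the regression keeps >= 2 residual df
        k_eff <- max(0L, min(prm$assoc_k, length(afp@populations) - 4L))
        a <- associationScan(afp, soil_pc1, k = k_eff, fdr_q = prm$assoc_fdr)
        sig_sites <- afp@sites[a$snp[a$significant]]
        assoc_genes[[as.character(pl)]] <-
            assocCandidateGenes(sig_sites, bundle@genes, prm$assoc_min_snps)
        assoc_res[[as.character(pl)]] <- a
    }
    res$association <- list(genes = assoc_genes, scans = assoc_res)

    ## --- method intersection and set tests ------------------------------
    top <- list()
    for (pl in c("2", "4"))
        top[[pl]] <- topCandidates(parallel[[pl]]$gene_id,
                                   if (is.null(repeat_genes[[pl]])) character()
                                   else repeat_genes[[pl]],
                                   assoc_genes[[pl]])
    all_windows <- buildWindows(SummarizedExperiment::rowRanges(gm),
                                prm$window_size, prm$min_snps)
    universe <- length(annotateGenes(all_windows, bundle@genes))
    shared_genes <- intersect(top[["2"]]$gene_id, top[["4"]]$gene_id)
    overlap_p <- if (nrow(top[["2"]]) && nrow(top[["4"]]))
        overlapTest(nrow(top[["2"]]), nrow(top[["4"]]),
                    length(shared_genes), universe) else NA_real_
    rates <- stats::setNames(bundle@recomb$rate, bundle@recomb$gene_id)
    cand_union <- union(parallel[["2"]]$gene_id, parallel[["4"]]$gene_id)
    recomb_test <- if (length(cand_union))
        recombinationPermutationTest(cand_union, rates, prm$n_perm, prm$seed)
        else NULL
    res$candidates <- list(top = top, shared = shared_genes,
                           universe = universe, overlap_p = overlap_p,
                           recomb_test = recomb_test)

    ## --- sweep profiles, fixation, relative differentiation -------------
    gene_df <- data.frame(gene_id = bundle@genes$gene_id,
        scaffold = as.character(GenomicRanges::seqnames(bundle@genes)),
        start = GenomicRanges::start(bundle@genes),
        end = GenomicRanges::end(bundle@genes))
    aft12 <- downsampleChromosomes(aft, prm$n_chromosomes, prm$seed)
    profiles <- list(); fixation <- list(); reldiff <- list(); afdist <- list()
    for (pl in c("2", "4")) {
        genes_pl <- top[[pl]]$gene_id
        if (!length(genes_pl)) next
        prof <- list(); fx <- list(); rd <- c(); ad <- list()
        for (g in genes_pl) {
            qual <- names(per_pair_genes)[vapply(per_pair_genes,
                function(x) g %in% x, TRUE)]
            qual <- intersect(qual, pairs$pair_id[pairs$ploidy == as.integer(pl)])
            grow <- gene_df[gene_df$gene_id == g, ]
            gwr <- c(); gw_rho <- c()
            for (id in qual) {
                sc <- scans[[id]]
                prof[[length(prof) + 1L]] <- sweepProfiles(sc$snps, grow, id,
                    sc$genomewide_rho, prm$sweep_flank, prm$sweep_bg_flank)
                pp <- layout[layout$pair_id == id, ]
                popA <- pp$population[pp$soil_class == "calcareous"]
                popB <- pp$population[pp$soil_class == "siliceous"]
                n_fixed <- fixedSnpCount(aft@freq[, popA], aft@freq[, popB],
                                         aft@sites, grow, prm$window_size)
                n_fixed12 <- fixedSnpCount(aft12@freq[, popA], aft12@freq[, popB],
                                           aft12@sites, grow, prm$window_size)
                fx[[length(fx) + 1L]] <- data.frame(gene_id = g, pair_id = id,
                    ploidy = as.integer(pl), n_fixed = as.integer(n_fixed),
                    n_fixed_12chrom = as.integer(n_fixed12))
                ## mean rho of the gene's windows in this pair
                w <- sc$windows
                inw <- w$scaffold == grow$scaffold & w$end >= grow$start &
                    w$start <= grow$end
                if (any(inw)) {
                    gwr <- c(gwr, stats::setNames(mean(w$rho[inw]), id))
                    gw_rho <- c(gw_rho, stats::setNames(sc$genomewide_rho, id))
                }
                pops_cal <- pp$population[pp$soil_class == "calcareous"]
                pops_sil <- pp$population[pp$soil_class == "siliceous"]
                ad[[length(ad) + 1L]] <- afDistribution(aft, grow, pops_cal,
                                                        pops_sil, prm$af_flank)
            }
            if (length(gwr))
                rd <- c(rd, stats::setNames(
                    relativeGeneDifferentiation(gwr, gw_rho, qual), g))
        }
        profiles[[pl]] <- do.call(rbind, prof)
        fixation[[pl]] <- do.call(rbind, fx)
        reldiff[[pl]] <- rd
        afdist[[pl]] <- do.call(rbind, ad)
    }
    outlier_map <- do.call(rbind, lapply(names(per_pair_genes), function(id)
        if (length(per_pair_genes[[id]]))
            data.frame(gene_id = per_pair_genes[[id]], pair_id = id)))
    fix_summary <- lapply(fixation, function(fx)
        if (!is.null(fx)) averageFixation(fx, outlier_map))
    res$sweeps <- list(profiles = profiles, fixation = fixation,
                       fixation_summary = fix_summary,
                       relative_differentiation = reldiff,
                       af_distribution = afdist)

    ## --- adaptation modes ------------------------------------------------
    tall <- tallyModes(bundle@modes)
    mode_tests <- list()
    for (m in c("standing", "denovo", "migration")) {
        tab <- matrix(c(tall$n[tall$ploidy == 2 & tall$mode == m],
                        sum(tall$n[tall$ploidy == 2 & tall$mode != m]),
                        tall$n[tall$ploidy == 4 & tall$mode == m],
                        sum(tall$n[tall$ploidy == 4 & tall$mode != m])),
                      2, byrow = TRUE)
        mode_tests[[m]] <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
            yatesChisq(tab) else NULL
    }
    res$modes <- list(tally = tall, tests = mode_tests,
                      bins = binSelectionStrength(bundle@modes))

    ## --- protein-interaction degrees -------------------------------------
    degs <- loadEdges(bundle@edges)
    net <- list()
    for (pl in c("2", "4")) {
        if (!nrow(top[[pl]])) next
        mp <- mapCandidateIds(top[[pl]]$gene_id, bundle@idmap, degs)
        if (length(mp$degrees))
            net[[pl]] <- c(degreePermutationTest(mp$degrees, degs$degree,
                                                 prm$n_perm, prm$seed),
                           list(unmapped = mp$unmapped))
    }
    res$network <- net

    res$manifest <- list(
        params = prm,
        n_sites_input = nrow(bundle@geno), n_sites_analyzed = nrow(gm),
        n_samples = ncol(gm), n_pairs = nrow(pairs),
        n_windows = vapply(scans, function(s) nrow(s$windows), 0),
        n_parallel = vapply(parallel, nrow, 0),
        n_top = vapply(top, nrow, 0))
    res
}

#' Read a bundle directory written by writeBundle back into a bundle
#'
#' @param directory path containing `genotypes.vcf`, `samples.tsv`,
#'   `genes.gff3` and the auxiliary TSVs.
#' @return A [SyntheticBundle-class] (config slot holds a placeholder
#'   reconstructed from the sample table dimensions).
#' @export
readBundleDir <- function(directory) {
    need <- c("genotypes.vcf", "samples.tsv", "genes.gff3", "soil.tsv",
              "recombination.tsv", "edges.tsv", "idmap.tsv", "truth.tsv",
              "mode_cases.tsv")
    missing <- need[!file.exists(file.path(directory, need))]
    if (length(missing))
        stop("bundle directory lacks: ", paste(missing, collapse = ", "),
             call. = FALSE)
    tsv <- function(f) utils::read.table(file.path(directory, f),
        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    samples <- tsv("samples.tsv")
    gm <- readMixedVcf(file.path(directory, "genotypes.vcf"), samples)
    gff <- utils::read.table(file.path(directory, "genes.gff3"), sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    genes <- GenomicRanges::GRanges(gff$V1, IRanges::IRanges(gff$V4, gff$V5),
        strand = gff$V7,
        gene_id = sub(".*Name=([^;]+).*", "\\1", gff$V9))
    truth <- tsv("truth.tsv")
    cfg <- SimConfig(sweep_loci = if (nrow(truth)) data.frame(
        gene_index = match(truth$gene_id, genes$gene_id), s = truth$s,
        mode = truth$mode, ploidy = truth$ploidy) else data.frame())
    new("SyntheticBundle", geno = gm, genes = genes, soil = tsv("soil.tsv"),
        recomb = tsv("recombination.tsv"), edges = tsv("edges.tsv"),
        idmap = tsv("idmap.tsv"), truth = truth, modes = tsv("mode_cases.tsv"),
        config = cfg)
}

#' Generate a small deterministic fixture bundle
#'
#' A reduced synthetic study (two lineages per ploidy, two scaffolds,
#' ~4,800 SNPs, well under 2 MB on disk) regenerated bit-identically from
#' the seed; used by the unit tests and usable as a quick demo input.
#'
#' @param seed integer seed (default 7).
#' @param directory optional path; when given the bundle is also written
#'   there via [writeBundle()].
#' @return The [SyntheticBundle-class], invisibly when written.
#' @export
makeFixtures <- function(seed = 7L, directory = NULL) {
    cfg <- SimConfig(n_lineages_per_ploidy = 2L, pops_per_lineage = 2L,
                     inds_per_pop = 4L, n_scaffolds = 2L,
                     scaffold_len = 120000L, snp_density = 0.02,
                     sweep_half_width = 15000, seed = as.integer(seed))
    bundle <- simulateDataset(cfg)
    if (!is.null(directory)) {
        writeBundle(bundle, directory, overwrite = TRUE)
        return(invisible(bundle))
    }
    bundle
}
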