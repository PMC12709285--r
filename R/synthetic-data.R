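## Synthetic mixed-ploidy study generator.
##
## Allele frequencies follow a Balding-Nichols hierarchy: an ancestral
## frequency per SNP, a lineage-level draw with drift F_lineage, and a
## population-level draw with drift F_pop. Linkage is absent except inside
## planted sweeps, where a deterministic flat-topped triangular kernel (weight
## 1 across the gene body, linear decay to 0 at `sweep_half_width` beyond the
## gene edges) elevates the derived-allele frequency in the siliceous member
## of each affected pair and depresses it in the calcareous member.

.SEL_BINS <- c(0.0001, 0.001, 0.01, 0.05, 0.5)

#' Create a synthetic-study configuration
#'
#' Defaults describe the frozen study conditions used throughout the test
#' suite: four lineages per ploidy each contributing one calcareous/siliceous
#' population pair, six individuals per population sequenced at 25x mean
#' depth, a 4 x 500-kbp genome at 0.02 SNPs/bp, and four planted sweeps (two
#' at the strongest selection bin). `F_lineage`/`F_pop` are chosen so that
#' neutral pairwise differentiation between the members of a pair falls in
#' the 0.1-0.2 range typical of conspecific population contrasts.
#'
#' @param n_lineages_per_ploidy,pops_per_lineage,inds_per_pop study design.
#' @param n_scaffolds,scaffold_len,snp_density genome layout.
#' @param F_lineage,F_pop Balding-Nichols drift parameters in (0, 1).
#' @param sweep_loci data.frame (`gene_index`, `s`, `mode`, `ploidy`); `NULL`
#'   for the default four sweeps, `data.frame()` for none. `ploidy` 0 plants
#'   the sweep in both ploidies; `gene_index` indexes the deterministic gene
#'   layout (genes every 12 kbp per scaffold, see [simulateDataset()]).
#' @param sweep_half_width bp of linear kernel decay beyond the gene edges.
#' @param tetraploid_freq_cap maximum pushed derived frequency in tetraploids;
#'   when < 1 the swept region of a tetraploid population always retains at
#'   least one ancestral chromosome (dominance-like fixation cap).
#' @param missing_rate,mean_depth genotype-level nuisance parameters.
#' @param seed master seed; identical config + seed gives byte-identical
#'   bundles.
#' @return A validated [SimConfig-class] object.
#' @export
SimConfig <- function(n_lineages_per_ploidy = 4L, pops_per_lineage = 2L,
                      inds_per_pop = 6L, n_scaffolds = 4L,
                      scaffold_len = 500000L, snp_density = 0.02,
                      F_lineage = 0.15, F_pop = 0.08, sweep_loci = NULL,
                      sweep_half_width = 25000, tetraploid_freq_cap = 0.85,
                      missing_rate = 0.05, mean_depth = 25, seed = 42L) {
    num1 <- function(x, nm) {
        if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
            stop("invalid value for '", nm, "'", call. = FALSE)
        x
    }
    frac <- function(x, nm) {
        x <- num1(x, nm)
        if (x < 0 || x > 1) stop("'", nm, "' must lie in [0,1]", call. = FALSE)
        x
    }
    n_lineages_per_ploidy <- as.integer(num1(n_lineages_per_ploidy, "n_lineages_per_ploidy"))
    pops_per_lineage <- as.integer(num1(pops_per_lineage, "pops_per_lineage"))
    if (pops_per_lineage < 2L || pops_per_lineage %% 2L != 0L)
        stop("'pops_per_lineage' must be an even integer >= 2", call. = FALSE)
    inds_per_pop <- as.integer(num1(inds_per_pop, "inds_per_pop"))
    n_scaffolds <- as.integer(num1(n_scaffolds, "n_scaffolds"))
    scaffold_len <- as.integer(num1(scaffold_len, "scaffold_len"))
    if (scaffold_len < 10000L)
        stop("'scaffold_len' must be at least 10x the 1-kbp window size", call. = FALSE)
    snp_density <- num1(snp_density, "snp_density")
    if (snp_density <= 0 || snp_density > 1)
        stop("'snp_density' must lie in (0,1]", call. = FALSE)
    F_lineage <- frac(F_lineage, "F_lineage")
    F_pop <- frac(F_pop, "F_pop")
    if (F_lineage >= 1 || F_pop >= 1)
        stop("drift parameters must be < 1", call. = FALSE)
    sweep_half_width <- num1(sweep_half_width, "sweep_half_width")
    tetraploid_freq_cap <- frac(tetraploid_freq_cap, "tetraploid_freq_cap")
    if (tetraploid_freq_cap <= 0)
        stop("'tetraploid_freq_cap' must lie in (0,1]", call. = FALSE)
    missing_rate <- frac(missing_rate, "missing_rate")
    mean_depth <- num1(mean_depth, "mean_depth")
    seed <- as.integer(num1(seed, "seed"))

    if (is.null(sweep_loci)) {
        genes_per_scaffold <- length(.geneStarts(scaffold_len))
        center <- which.min(abs(.geneStarts(scaffold_len) + 1500 - scaffold_len / 2))
        idx <- function(sc) (sc - 1L) * genes_per_scaffold + center
        sweep_loci <- data.frame(
            gene_index = vapply(seq_len(min(4L, n_scaffolds)), idx, 1L),
            s = c(0.5, 0.5, 0.01, 0.05)[seq_len(min(4L, n_scaffolds))],
            mode = c("standing", "denovo", "migration", "standing")[seq_len(min(4L, n_scaffolds))],
            ploidy = c(0L, 2L, 4L, 0L)[seq_len(min(4L, n_scaffolds))])
    }
    if (nrow(sweep_loci) > 0) {
        stopifnot(all(c("gene_index", "s", "mode", "ploidy") %in% names(sweep_loci)))
        if (!all(sweep_loci$mode %in% c("denovo", "standing", "migration")))
            stop("invalid value for 'sweep_loci$mode'", call. = FALSE)
        if (!all(sweep_loci$ploidy %in% c(0L, 2L, 4L)))
            stop("invalid value for 'sweep_loci$ploidy'", call. = FALSE)
        if (any(!is.finite(sweep_loci$s) | sweep_loci$s < 0))
            stop("invalid value for 'sweep_loci$s'", call. = FALSE)
    }
    new("SimConfig", n_lineages_per_ploidy = n_lineages_per_ploidy,
        pops_per_lineage = pops_per_lineage, inds_per_pop = inds_per_pop,
        n_scaffolds = n_scaffolds, scaffold_len = scaffold_len,
        snp_density = snp_density, F_lineage = F_lineage, F_pop = F_pop,
        sweep_loci = sweep_loci, sweep_half_width = sweep_half_width,
        tetraploid_freq_cap = tetraploid_freq_cap, missing_rate = missing_rate,
        mean_depth = mean_depth, seed = seed)
}

## deterministic gene layout: one gene every 12 kbp, 3 kbp long
.geneStarts <- function(scaffold_len)
    seq(5000L, scaffold_len - 8000L, by = 12000L)

.geneModels <- function(config) {
    st <- .geneStarts(config@scaffold_len)
    gr <- GenomicRanges::GRanges(
        rep(sprintf("sc%02d", seq_len(config@n_scaffolds)), each = length(st)),
        IRanges::IRanges(rep(st, config@n_scaffolds), width = 3000L),
        strand = "+")
    S4Vectors::mcols(gr)$gene_id <- sprintf("gene%04d", seq_along(gr))
    gr
}

## Balding-Nichols draw around p with drift F (elementwise)
.bnDraw <- function(p, F) {
    if (F < 1e-12) return(p)
    out <- numeric(length(p))
    fixed <- p <= 0 | p >= 1
    out[fixed] <- p[fixed]
    i <- !fixed
    scale <- (1 - F) / F
    out[i] <- stats::rbeta(sum(i), p[i] * scale, (1 - p[i]) * scale)
    pmin(pmax(out, 0), 1)
}

## flat-topped triangular kernel: 1 inside [start,end], linear decay outside
.sweepKernel <- function(pos, start, end, half_width) {
    d <- pmax(0, pmax(start - pos, pos - end))
    pmax(0, 1 - d / half_width)
}

## pushed target frequency as a saturating function of s
.pushTarget <- function(s) s / (s + 0.005)

#' Simulate a complete synthetic mixed-ploidy study
#'
#' Draws genotypes for all populations of both ploidies under the
#' Balding-Nichols hierarchy described in the package vignette, plants the
#' configured sweeps, and assembles gene models, soil chemistry, per-gene
#' recombination rates, a protein-interaction edge list with gene-to-protein
#' mapping, a truth table and an adaptation-mode case fixture.
#'
#' At swept loci the siliceous population of each affected pair has its
#' derived frequency pushed toward `min(s/(s+0.005), cap)` (cap 1 in diploids,
#' `tetraploid_freq_cap` in tetraploids) weighted by the sweep kernel, while
#' the calcareous member is depressed toward 0. Modes differ in how the push
#' is shared across pairs: `standing` applies one shared elevation, `denovo`
#' jitters it independently per pair, `migration` copies the first pair's
#' pushed frequencies to all other affected pairs. When the tetraploid cap is
#' < 1 a swept tetraploid population never fixes the derived allele: if all
#' non-missing chromosomes carry it, one chromosome is reverted.
#'
#' @param config a [SimConfig-class] from [SimConfig()].
#' @return A [SyntheticBundle-class]; identical `config` (including seed)
#'   yields an identical bundle.
#' @examples
#' cfg <- SimConfig(n_scaffolds = 1L, scaffold_len = 60000L, inds_per_pop = 3L,
#'                  sweep_loci = data.frame(), seed = 7L)
#' bnd <- simulateDataset(cfg)
#' bnd
#' @export
simulateDataset <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)

    genes <- .geneModels(config)
    scafs <- sprintf("sc%02d", seq_len(config@n_scaffolds))
    n_per_sc <- round(config@snp_density * config@scaffold_len)
    pos_list <- lapply(scafs, function(s)
        sort(sample.int(config@scaffold_len, n_per_sc)))
    sites <- GenomicRanges::GRanges(rep(scafs, each = n_per_sc),
        IRanges::IRanges(unlist(pos_list), width = 1L))
    n_snp <- length(sites)
    S4Vectors::mcols(sites)$ref <- rep_len(c("A", "C", "G", "T"), n_snp)
    S4Vectors::mcols(sites)$alt <- rep_len(c("G", "T", "A", "C"), n_snp)
    S4Vectors::mcols(sites)$ancestral <- "ref"

    ## sample layout
    layout <- do.call(rbind, lapply(c(2L, 4L), function(pl) {
        pre <- if (pl == 2L) "dip" else "tet"
        do.call(rbind, lapply(seq_len(config@n_lineages_per_ploidy), function(j) {
            do.call(rbind, lapply(seq_len(config@pops_per_lineage / 2L), function(k) {
                data.frame(
                    population = sprintf("%s_L%d_%s%d", pre, j, c("cal", "sil"), k),
                    ploidy = pl, lineage = sprintf("%s_L%d", pre, j),
                    pair_id = sprintf("%s_L%d_pair%d", pre, j, k),
                    soil_class = c("calcareous", "siliceous"))
            }))
        }))
    }))
    n_pop <- nrow(layout)
    samples <- data.frame(
        sample_id = paste0(rep(layout$population, each = config@inds_per_pop),
                           "_i", seq_len(config@inds_per_pop)),
        population = rep(layout$population, each = config@inds_per_pop),
        ploidy = rep(layout$ploidy, each = config@inds_per_pop),
        lineage = rep(layout$lineage, each = config@inds_per_pop),
        pair_id = rep(layout$pair_id, each = config@inds_per_pop),
        soil_class = rep(layout$soil_class, each = config@inds_per_pop))

    ## hierarchical frequencies; tetraploid lineages drift less (larger
    ## effective size), mirroring the lower neutral pairwise differentiation
    ## and higher diversity of autotetraploid populations
    tet_drift <- 0.65
    p0 <- stats::rbeta(n_snp, 0.8, 0.8)
    lineages <- unique(layout$lineage)
    lin_ploidy <- layout$ploidy[match(lineages, layout$lineage)]
    lin_freq <- vapply(seq_along(lineages), function(l)
        .bnDraw(p0, config@F_lineage *
                    if (lin_ploidy[l] == 4L) tet_drift else 1),
        numeric(n_snp))
    colnames(lin_freq) <- lineages
    pop_freq <- vapply(seq_len(n_pop), function(g)
        .bnDraw(lin_freq[, layout$lineage[g]],
                config@F_pop * if (layout$ploidy[g] == 4L) tet_drift else 1),
        numeric(n_snp))
    colnames(pop_freq) <- layout$population

    ## plant sweeps
    sw <- config@sweep_loci
    truth <- data.frame(gene_id = character(), scaffold = character(),
                        gene_start = integer(), gene_end = integer(),
                        s = numeric(), mode = character(), ploidy = integer(),
                        target_dip = numeric(), target_tet = numeric())
    cap_sites <- vector("list", n_pop)  # per-pop site indices under the 4x cap
    if (nrow(sw) > 0) {
        for (r in seq_len(nrow(sw))) {
            g <- genes[sw$gene_index[r]]
            sc <- as.character(GenomicRanges::seqnames(g))
            gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
            on_sc <- which(as.character(GenomicRanges::seqnames(sites)) == sc)
            w <- .sweepKernel(GenomicRanges::start(sites)[on_sc], gs, ge,
                              config@sweep_half_width)
            idx <- on_sc[w > 0]
            w <- w[w > 0]
            ploidies <- if (sw$ploidy[r] == 0L) c(2L, 4L) else sw$ploidy[r]
            for (pl in ploidies) {
                cap <- if (pl == 4L) config@tetraploid_freq_cap else 1
                tgt <- min(.pushTarget(sw$s[r]), cap)
                aff <- which(layout$ploidy == pl)
                sil <- aff[layout$soil_class[aff] == "siliceous"]
                cal <- aff[layout$soil_class[aff] == "calcareous"]
                first_sil_freq <- NULL
                for (gp in sil) {
                    w_eff <- w
                    if (sw$mode[r] == "denovo")
                        w_eff <- w * stats::runif(1, 0.85, 1)
                    p <- pop_freq[idx, gp]
                    if (sw$mode[r] == "migration" && !is.null(first_sil_freq)) {
                        pop_freq[idx, gp] <- first_sil_freq
                    } else {
                        pop_freq[idx, gp] <- p + pmax(0, tgt - p) * w_eff
                        if (is.null(first_sil_freq))
                            first_sil_freq <- pop_freq[idx, gp]
                    }
                    if (pl == 4L && cap < 1)
                        cap_sites[[gp]] <- union(cap_sites[[gp]], idx)
                }
                for (gp in cal)
                    pop_freq[idx, gp] <- pop_freq[idx, gp] * (1 - w)
            }
            truth <- rbind(truth, data.frame(
                gene_id = g$gene_id, scaffold = sc, gene_start = gs,
                gene_end = ge, s = sw$s[r], mode = sw$mode[r],
                ploidy = sw$ploidy[r],
                target_dip = min(.pushTarget(sw$s[r]), 1),
                target_tet = min(.pushTarget(sw$s[r]), config@tetraploid_freq_cap)))
        }
    }

    ## genotype dosages, depth, missingness
    n_samp <- nrow(samples)
    dos <- matrix(NA_integer_, n_snp, n_samp)
    for (g in seq_len(n_pop)) {
        cols <- which(samples$population == layout$population[g])
        pl <- layout$ploidy[g]
        dos[, cols] <- stats::rbinom(n_snp * length(cols), pl, pop_freq[, g])
    }
    depth <- matrix(stats::rpois(n_snp * n_samp, config@mean_depth), n_snp)
    if (config@missing_rate > 0)
        dos[stats::runif(n_snp * n_samp) < config@missing_rate] <- NA_integer_
    ## enforce the tetraploid fixation cap on the realized sample
    for (g in seq_len(n_pop)) {
        if (is.null(cap_sites[[g]])) next
        cols <- which(samples$population == layout$population[g])
        pl <- layout$ploidy[g]
        for (s_i in cap_sites[[g]]) {
            x <- dos[s_i, cols]
            nm <- which(!is.na(x))
            if (length(nm) > 0 && all(x[nm] == pl))
                dos[s_i, cols[nm[1]]] <- pl - 1L
        }
    }

    gm <- GenotypeMatrix(dos, depth, sites, samples)

    ## soil chemistry: two clusters separated along pH/Ca/CEC
    cls <- layout$soil_class
    n_cal <- sum(cls == "calcareous")
    rn <- function(m_cal, m_sil, sd) {
        x <- numeric(n_pop)
        x[cls == "calcareous"] <- stats::rnorm(n_cal, m_cal, sd)
        x[cls == "siliceous"] <- stats::rnorm(n_pop - n_cal, m_sil, sd)
        x
    }
    soil <- data.frame(population = layout$population,
        pH_H2O = pmin(pmax(rn(7.8, 4.8, 0.3), 0), 14),
        pH_KCl = pmin(pmax(rn(7.1, 4.1, 0.3), 0), 14),
        bioavailable_Ca = pmax(rn(250, 40, 25), 0),
        Ca = pmax(rn(300, 50, 35), 0), Mg = pmax(rn(60, 30, 10), 0),
        K = pmax(rn(15, 25, 4), 0), Na = pmax(rn(5, 4, 1.5), 0),
        CEC = pmax(rn(250, 80, 30), 0))
    ## two populations lack the lab-measured totals (to exercise imputation)
    soil[c(1L, n_pop), c("Ca", "Mg", "K", "Na", "CEC")] <- NA_real_

    recomb <- data.frame(gene_id = genes$gene_id,
                         rate = stats::rlnorm(length(genes), 0, 0.5))

    ## protein-interaction edge list; swept genes are made hub-like
    prot <- sprintf("PROT%04d", seq_along(genes))
    idmap <- data.frame(gene_id = genes$gene_id, protein_id = prot)
    unmapped <- c(5L, 10L)
    idmap <- idmap[-unmapped[unmapped <= nrow(idmap)], ]
    n_edges <- 8L * length(genes)
    wts <- rep(1, length(genes))
    if (nrow(truth) > 0)
        wts[match(truth$gene_id, genes$gene_id)] <- 10
    wts[sample.int(length(genes), min(10L, length(genes)))] <- 10
    e1 <- sample.int(length(genes), n_edges, replace = TRUE, prob = wts)
    e2 <- sample.int(length(genes), n_edges, replace = TRUE)
    keep <- e1 != e2
    edges <- unique(data.frame(protein1 = prot[pmin(e1, e2)[keep]],
                               protein2 = prot[pmax(e1, e2)[keep]]))
    edges$combined_score <- sample(150:999, nrow(edges), replace = TRUE)
    rownames(edges) <- NULL

    ## adaptation-mode case fixture: planted sweeps expanded over quartets
    contrasts <- unique(layout[, c("pair_id", "lineage", "ploidy")])
    quart <- enumerateQuartets(contrasts)
    modes <- data.frame(gene_id = character(), quartet_id = character(),
                        ploidy = integer(), mode = character(),
                        maxSel = numeric(), mcl = numeric())
    if (nrow(truth) > 0 && nrow(quart) > 0) {
        for (r in seq_len(nrow(truth))) {
            ploidies <- if (truth$ploidy[r] == 0L) c(2L, 4L) else truth$ploidy[r]
            q <- quart[quart$ploidy %in% ploidies, ]
            if (nrow(q) == 0) next
            bin <- .SEL_BINS[which.min(abs(log(.SEL_BINS) - log(truth$s[r])))]
            modes <- rbind(modes, data.frame(
                gene_id = truth$gene_id[r], quartet_id = q$quartet_id,
                ploidy = q$ploidy, mode = truth$mode[r], maxSel = bin,
                mcl = round(stats::runif(nrow(q), -500, -100), 2)))
        }
    }
    neutral_genes <- setdiff(genes$gene_id, truth$gene_id)[1:2]
    for (pl in c(2L, 4L)) {
        q <- quart[quart$ploidy == pl, ]
        if (nrow(q) == 0) next
        modes <- rbind(modes, data.frame(
            gene_id = neutral_genes, quartet_id = q$quartet_id[1],
            ploidy = pl, mode = "neutral", maxSel = 0.0001,
            mcl = round(stats::runif(2, -500, -100), 2)))
    }
    rownames(modes) <- NULL

    new("SyntheticBundle", geno = gm, genes = genes, soil = soil,
        recomb = recomb, edges = edges, idmap = idmap, truth = truth,
        modes = modes, config = config)
}

#' Write a synthetic bundle to standard file formats
#'
#' Emits a VCF 4.2 with ploidy-correct GT strings, a GFF3 of the gene models,
#' tab-separated tables (samples, soil, recombination rates, edge list, ID
#' mapping, truth, mode cases), and a JSON manifest listing every file with
#' its md5 checksum.
#'
#' @param bundle a [SyntheticBundle-class].
#' @param directory output directory; refused when it exists non-empty unless
#'   `overwrite = TRUE`.
#' @param overwrite logical.
#' @return Invisibly, the manifest as a named list of
#'   `list(path, md5)` entries (also written to `manifest.json`).
#' @export
writeBundle <- function(bundle, directory, overwrite = FALSE) {
    stopifnot(is(bundle, "SyntheticBundle"))
    if (dir.exists(directory) && length(dir(directory)) > 0 && !overwrite)
        stop("directory '", directory, "' is non-empty; use overwrite = TRUE",
             call. = FALSE)
    dir.create(directory, showWarnings = FALSE, recursive = TRUE)

    gm <- bundle@geno
    smp <- sampleTable(gm)
    vcf_path <- file.path(directory, "genotypes.vcf")
    .writeVcf(gm, vcf_path)

    gff_path <- file.path(directory, "genes.gff3")
    g <- bundle@genes
    gff <- c("##gff-version 3",
        sprintf("%s\tPloidyScan\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s",
            as.character(GenomicRanges::seqnames(g)), GenomicRanges::start(g),
            GenomicRanges::end(g), as.character(GenomicRanges::strand(g)),
            g$gene_id, g$gene_id))
    writeLines(gff, gff_path)

    tsv <- function(df, name) {
        p <- file.path(directory, name)
        utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
    }
    paths <- c(vcf = vcf_path, genes = gff_path,
        samples = tsv(smp, "samples.tsv"), soil = tsv(bundle@soil, "soil.tsv"),
        recomb = tsv(bundle@recomb, "recombination.tsv"),
        edges = tsv(bundle@edges, "edges.tsv"),
        idmap = tsv(bundle@idmap, "idmap.tsv"),
        truth = tsv(bundle@truth, "truth.tsv"),
        modes = tsv(bundle@modes, "mode_cases.tsv"))
    manifest <- lapply(stats::setNames(paths, names(paths)), function(p)
        list(path = basename(p), md5 = unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}

## VCF 4.2 writer for mixed-ploidy dosage data
.writeVcf <- function(gm, path) {
    smp <- sampleTable(gm)
    d <- dosage(gm); dp <- readDepth(gm)
    rr <- SummarizedExperiment::rowRanges(gm)
    gt_lookup <- list(
        `2` = c(vapply(0:2, function(k)
            paste(c(rep("0", 2 - k), rep("1", k)), collapse = "/"), ""),
            "./."),
        `4` = c(vapply(0:4, function(k)
            paste(c(rep("0", 4 - k), rep("1", k)), collapse = "/"), ""),
            "./././."))
    cols <- lapply(seq_len(ncol(d)), function(j) {
        pl <- smp$ploidy[j]
        lk <- gt_lookup[[as.character(pl)]]
        x <- d[, j]
        x[is.na(x)] <- pl + 1L
        paste0(lk[x + 1L], ":", dp[, j])
    })
    sl <- tapply(GenomicRanges::end(rr),
                 as.character(GenomicRanges::seqnames(rr)), max)
    hdr <- c("##fileformat=VCFv4.2", "##source=PloidyScan",
        sprintf("##contig=<ID=%s,length=%d>", names(sl), sl),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                "FORMAT", smp$sample_id), collapse = "\t"))
    body <- do.call(paste, c(list(
        as.character(GenomicRanges::seqnames(rr)), GenomicRanges::start(rr),
        ".", rr$ref, rr$alt, ".", "PASS", ".", "GT:DP"), cols, sep = "\t"))
    writeLines(c(hdr, body), path)
    invisible(path)
}
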