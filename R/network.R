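## Protein-interaction degree statistics: undirected deduplicated degrees
## from a STRING-format edge list, candidate-gene mapping, and the one-sided
## mean-degree permutation test. Degree (count of distinct interaction
## partners) is the connectivity statistic; the combined-score threshold is
## exposed but defaults to 0 (no subsetting).

#' Node degrees from a STRING-format edge list
#'
#' Edges are undirected and deduplicated (`A-B` and `B-A` count once);
#' self-loops are dropped and counted; rows with a combined score below
#' `score_threshold` are excluded. Malformed rows (missing ends) are logged.
#'
#' @param edges data.frame or TSV path with columns `protein1`, `protein2`,
#'   `combined_score` (score optional when `score_threshold = 0`).
#' @param score_threshold minimum combined score (default 0).
#' @return data.frame `protein_id`, `degree`, with attributes
#'   `n_self_loops`, `n_malformed`.
#' @export
loadEdges <- function(edges, score_threshold = 0) {
    if (is.character(edges))
        edges <- utils::read.table(edges, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
    stopifnot(all(c("protein1", "protein2") %in% names(edges)))
    bad <- is.na(edges$protein1) | is.na(edges$protein2) |
        edges$protein1 == "" | edges$protein2 == ""
    n_malformed <- sum(bad)
    edges <- edges[!bad, , drop = FALSE]
    if (score_threshold > 0) {
        stopifnot("combined_score" %in% names(edges))
        edges <- edges[edges$combined_score >= score_threshold, , drop = FALSE]
    }
    self <- edges$protein1 == edges$protein2
    n_self <- sum(self)
    edges <- edges[!self, , drop = FALSE]
    if (nrow(edges) == 0)
        warning("no edges retained at this score threshold")
    und <- unique(data.frame(a = pmin(edges$protein1, edges$protein2),
                             b = pmax(edges$protein1, edges$protein2)))
    deg <- table(c(und$a, und$b))
    out <- data.frame(protein_id = names(deg), degree = as.integer(deg))
    rownames(out) <- NULL
    attr(out, "n_self_loops") <- n_self
    attr(out, "n_malformed") <- n_malformed
    out
}

#' Map candidate genes to protein degrees
#'
#' Genes without a protein mapping, or whose protein is absent from the
#' degree table, are reported and excluded. Duplicate mapping rows keep the
#' first entry with a warning.
#'
#' @param candidate_genes character vector of gene ids.
#' @param idmap data.frame `gene_id`, `protein_id`.
#' @param degrees data.frame from [loadEdges()].
#' @return list: `degrees` (named numeric, gene id -> degree), `unmapped`
#'   (gene ids excluded).
#' @export
mapCandidateIds <- function(candidate_genes, idmap, degrees) {
    if (anyDuplicated(idmap$gene_id)) {
        warning("duplicate mapping rows; keeping the first per gene")
        idmap <- idmap[!duplicated(idmap$gene_id), , drop = FALSE]
    }
    prot <- idmap$protein_id[match(candidate_genes, idmap$gene_id)]
    deg <- degrees$degree[match(prot, degrees$protein_id)]
    ok <- !is.na(deg)
    list(degrees = stats::setNames(deg[ok], candidate_genes[ok]),
         unmapped = candidate_genes[!ok])
}

#' One-sided permutation test of candidate mean degree
#'
#' Tests whether candidate genes are more connected than average: the
#' observed mean candidate degree is compared with means of `n_perm`
#' same-size draws without replacement from all node degrees;
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param candidate_degrees numeric vector of candidate node degrees.
#' @param all_degrees numeric vector of all node degrees in the network.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return list: p, observed, null_mean.
#' @export
degreePermutationTest <- function(candidate_degrees, all_degrees,
                                  n_perm = 10000, seed = 1L) {
    stopifnot(length(candidate_degrees) > 0,
              length(all_degrees) >= length(candidate_degrees))
    observed <- mean(candidate_degrees)
    k <- length(candidate_degrees)
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) mean(sample(all_degrees, k)), 0)
    list(p = (1 + sum(null >= observed)) / (n_perm + 1),
         observed = observed, null_mean = mean(null))
}
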