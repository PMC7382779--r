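#' Mask deleted genes in their cognate strains
#'
#' Sets the deleted gene's own ratio (and, at the phosphosite level, the
#' ratios of sites on the deleted protein) to missing in its cognate strain,
#' so that the deletion itself cannot create false correlations.
#'
#' @param rm A [ratio_matrix()] (replicate-resolved or merged).
#' @param deletion_map Named character vector, strain -> deleted gene.
#' @param site_to_protein Optional site -> protein map (phosphosite level).
#' @return The masked [ratio_matrix()], with attribute `n_masked` counting
#'   the (molecule, strain) entries set to missing.
#' @export
mask_deleted <- function(rm, deletion_map, site_to_protein = NULL) {
  stopifnot(inherits(rm, "ratio_matrix"))
  if (!all(unique(rm$samples$strain) %in% names(deletion_map)))
    stop("deletion_map must cover every strain in the matrix")
  vals <- rm$values
  gene_of_row <- if (!is.null(site_to_protein))
    unname(site_to_protein[rownames(vals)]) else rownames(vals)
  n_masked <- 0L
  for (s in unique(rm$samples$strain)) {
    rows <- which(!is.na(gene_of_row) & gene_of_row == deletion_map[[s]])
    if (!length(rows)) next
    cols <- which(rm$samples$strain == s)
    n_masked <- n_masked + length(rows)
    vals[rows, cols] <- NA_real_
  }
  out <- rm
  out$values <- vals
  attr(out, "n_masked") <- n_masked
  out
}

#' Select paired responsive features for a strain pair
#'
#' Retains molecules measured in both strains with `|log2 ratio| >= fc_floor`
#' in at least one of the two strains (requiring both would bias the pair
#' toward shared responders), and returns the paired vectors.
#'
#' @param merged Merged strain-level [ratio_matrix()].
#' @param strain_a,strain_b Strain column names.
#' @param fc_floor Log2 responsiveness floor (0.38 protein, 0.5 phosphosite).
#' @return List with `x`, `y` (paired values) and `n`.
#' @export
select_pair_features <- function(merged, strain_a, strain_b, fc_floor) {
  x <- merged$values[, strain_a]
  y <- merged$values[, strain_b]
  keep <- !is.na(x) & !is.na(y) & (abs(x) >= fc_floor | abs(y) >= fc_floor)
  list(x = unname(x[keep]), y = unname(y[keep]), n = sum(keep))
}

pearson_edge <- function(x, y) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = 0, n = n, p = NA_real_, degenerate = TRUE))
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, n = n, p = p, degenerate = FALSE)
}

#' Pearson correlation edge for one strain pair
#'
#' Pearson r with a two-sided p-value from the t transform on n - 2 degrees
#' of freedom. Zero variance in either vector yields r = 0 (degenerate).
#'
#' @param pairs Output of [select_pair_features()].
#' @param node_a,node_b Node labels for the edge record.
#' @return One-row data frame: `node_a`, `node_b`, `r`, `n`, `p`, `sign`.
#' @export
gene_pair_correlation <- function(pairs, node_a = "a", node_b = "b") {
  e <- pearson_edge(pairs$x, pairs$y)
  data.frame(node_a = node_a, node_b = node_b, r = e$r, n = e$n, p = e$p,
             sign = ifelse(e$r >= 0, "pos", "neg"), stringsAsFactors = FALSE)
}

#' Deletion-strain correlation network
#'
#' Evaluates every strain pair on the deletion-masked, merged matrix:
#' responsive molecules are selected with [select_pair_features()], pairs
#' with fewer than `min_n` molecules or `|r| < r_min` are recorded as 0 in
#' the correlation matrix, and Benjamini-Hochberg adjustment is applied
#' across all evaluated pairs of the level. Surviving edges satisfy
#' `|r| >= r_min`; their adjusted p-values are reported (the study observed
#' a maximum adjusted p of 0.003 at this r cutoff).
#'
#' @param merged Merged strain-level [ratio_matrix()].
#' @param deletion_map Strain -> deleted gene map (for masking).
#' @param fc_floor Responsiveness floor (log2).
#' @param r_min Absolute correlation cutoff (default 0.6).
#' @param min_n Minimum paired molecules per strain pair (default 25).
#' @param site_to_protein Site -> protein map for phosphosite-level masking.
#' @return List with `edges` (node_a, node_b, r, n, p, p_adj, sign),
#'   `matrix` (symmetric strain x strain correlation matrix, unit diagonal,
#'   0 for low/insufficient pairs), `order` (strains in average-linkage
#'   dendrogram order of the matrix), and `n_pairs_tested`.
#' @export
build_gene_network <- function(merged, deletion_map = NULL, fc_floor = 0.38,
                               r_min = 0.6, min_n = 25,
                               site_to_protein = NULL) {
  stopifnot(inherits(merged, "ratio_matrix"))
  if (!is.null(deletion_map))
    merged <- mask_deleted(merged, deletion_map, site_to_protein)
  strains <- colnames(merged$values)
  ns <- length(strains)
  cmat <- diag(1, ns)
  dimnames(cmat) <- list(strains, strains)
  recs <- list(); k <- 0L
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      pr <- select_pair_features(merged, strains[i], strains[j], fc_floor)
      if (pr$n < min_n) next
      e <- pearson_edge(pr$x, pr$y)
      if (e$degenerate) next
      k <- k + 1L
      recs[[k]] <- data.frame(node_a = strains[i], node_b = strains[j],
                              r = e$r, n = e$n, p = e$p, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    edges <- data.frame(node_a = character(), node_b = character(), r = numeric(),
                        n = integer(), p = numeric(), p_adj = numeric(),
                        sign = character(), stringsAsFactors = FALSE)
    return(list(edges = edges, matrix = cmat, order = strains, n_pairs_tested = 0L))
  }
  tested <- do.call(rbind, recs)
  tested$p_adj <- stats::p.adjust(tested$p, method = "BH")
  pass <- abs(tested$r) >= r_min
  edges <- tested[pass, , drop = FALSE]
  edges$sign <- ifelse(edges$r >= 0, "pos", "neg")
  rownames(edges) <- NULL
  if (nrow(edges)) {
    cmat[cbind(edges$node_a, edges$node_b)] <- edges$r
    cmat[cbind(edges$node_b, edges$node_a)] <- edges$r
  }
  ord <- if (ns >= 3L) {
    hc <- stats::hclust(stats::as.dist(1 - cmat), method = "average")
    strains[hc$order]
  } else strains
  list(edges = edges, matrix = cmat, order = ord, n_pairs_tested = k)
}
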