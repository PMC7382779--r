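#' Molecule-level covariance network
#'
#' Evaluates every molecule pair with shared measurements in at least
#' `min_shared_fraction` of the strains, computing Pearson r across strains
#' and a two-sided p-value from the t transform. P-values are Bonferroni
#' corrected by the number of evaluated pairs; edges satisfy `|r| >= r_min`
#' and adjusted p `<= p_adj_max`. Pairs are reported once, in lexicographic
#' node order.
#'
#' @param merged Merged, deletion-masked [ratio_matrix()].
#' @param min_shared_fraction Minimum fraction of strains with paired
#'   measurements (default 0.5).
#' @param r_min Absolute correlation cutoff (default 0.7).
#' @param p_adj_max Bonferroni-adjusted p cutoff (default 0.001).
#' @return List with `edges` (node_a, node_b, r, n, p, p_adj, sign) and
#'   `n_pairs_tested` (the Bonferroni family size).
#' @export
molecule_pair_correlations <- function(merged, min_shared_fraction = 0.5,
                                       r_min = 0.7, p_adj_max = 0.001) {
  stopifnot(inherits(merged, "ratio_matrix"))
  X <- t(merged$values)                       # strains x molecules
  ns <- nrow(X)
  min_n <- max(3L, ceiling(min_shared_fraction * ns))
  if (anyNA(X)) {
    R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
    N <- crossprod(!is.na(X))
  } else {
    sds <- apply(X, 2L, stats::sd)
    R <- suppressWarnings(stats::cor(X))
    R[sds == 0, ] <- NA; R[, sds == 0] <- NA
    N <- matrix(ns, ncol(X), ncol(X))
  }
  ut <- upper.tri(R)
  tested <- ut & N >= min_n & !is.na(R)
  m <- sum(tested)
  idx <- which(tested, arr.ind = TRUE)
  r <- R[tested]; n <- N[tested]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p_adj <- pmin(p * m, 1)
  pass <- abs(r) >= r_min & p_adj <= p_adj_max
  mols <- colnames(R)
  a <- mols[idx[pass, 1L]]; b <- mols[idx[pass, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(node_a = a, node_b = b, r = r[pass], n = n[pass],
                      p = p[pass], p_adj = p_adj[pass],
                      sign = ifelse(r[pass] >= 0, "pos", "neg"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, n_pairs_tested = m)
}

#' Permutation estimate of the covariance network false-positive rate
#'
#' Each permutation independently shuffles the strain order of every
#' molecule's profile, preserving each molecule's marginal distribution while
#' destroying cross-molecule structure, then rebuilds the network with the
#' same thresholds. The rate is the mean permuted edge count as a percentage
#' of the observed edge count.
#'
#' @param merged Merged, deletion-masked [ratio_matrix()].
#' @param n_perm Number of permutations (default 1000).
#' @param min_shared_fraction,r_min,p_adj_max Thresholds as in
#'   [molecule_pair_correlations()].
#' @param seed Seed for the permutation stream.
#' @return List with `rate_pct` (NA-flagged when no observed edges),
#'   `observed_edges`, `mean_permuted_edges`, `permuted_counts`, and
#'   `undefined` (TRUE when the observed network is empty).
#' @export
permutation_false_positive_rate <- function(merged, n_perm = 1000,
                                            min_shared_fraction = 0.5,
                                            r_min = 0.7, p_adj_max = 0.001,
                                            seed = 1L) {
  obs <- molecule_pair_correlations(merged, min_shared_fraction, r_min, p_adj_max)
  n_obs <- nrow(obs$edges)
  set.seed(seed)
  vals <- merged$values
  nc <- ncol(vals)
  counts <- integer(n_perm)
  perm <- merged
  for (b in seq_len(n_perm)) {
    pv <- vals
    for (i in seq_len(nrow(pv))) pv[i, ] <- pv[i, sample.int(nc)]
    perm$values <- pv
    counts[b] <- nrow(molecule_pair_correlations(perm, min_shared_fraction,
                                                 r_min, p_adj_max)$edges)
  }
  list(rate_pct = if (n_obs > 0) 100 * mean(counts) / n_obs else NA_real_,
       observed_edges = n_obs, mean_permuted_edges = mean(counts),
       permuted_counts = counts, undefined = n_obs == 0)
}

#' Attribute covariance edges to known relationship classes
#'
#' For each annotation database, computes the fraction of edges whose
#' endpoint genes share a term (or form a known interaction pair). Classes
#' are non-exclusive: an edge counts toward every class it matches. Also
#' reports the fraction explained by any class, the unexplained fraction,
#' and, when `site_to_protein` is given (phosphosite networks), the fraction
#' of edges between sites on the same protein.
#'
#' @param edges Edge data frame from [molecule_pair_correlations()].
#' @param databases List of [annotation_db()].
#' @param site_to_protein Optional site -> protein map; endpoint genes are
#'   then the cognate proteins.
#' @return List with `fractions` (data frame: class, n_explained, fraction)
#'   and `per_edge` (logical edges x classes matrix).
#' @export
attribute_edges <- function(edges, databases, site_to_protein = NULL) {
  ga <- edges$node_a; gb <- edges$node_b
  same_protein <- NULL
  if (!is.null(site_to_protein)) {
    ga <- unname(site_to_protein[edges$node_a])
    gb <- unname(site_to_protein[edges$node_b])
    same_protein <- !is.na(ga) & !is.na(gb) & ga == gb
  }
  per_edge <- matrix(FALSE, nrow(edges), length(databases),
                     dimnames = list(NULL, vapply(databases, `[[`, "", "name")))
  for (d in seq_along(databases)) {
    db <- databases[[d]]
    if (db$kind == "interaction") {
      key <- paste(pmin(ga, gb), pmax(ga, gb), sep = "\r")
      per_edge[, d] <- key %in% paste(db$pairs$a, db$pairs$b, sep = "\r")
    } else {
      terms_of <- function(g) {
        hits <- vapply(db$sets, function(s) g %in% s, logical(1L))
        names(db$sets)[hits]
      }
      genes <- unique(c(ga, gb))
      tl <- lapply(stats::setNames(genes, genes), terms_of)
      per_edge[, d] <- mapply(function(x, y) length(intersect(tl[[x]], tl[[y]])) > 0L,
                              ga, gb, USE.NAMES = FALSE)
    }
  }
  n <- max(1L, nrow(edges))
  fractions <- data.frame(class = colnames(per_edge),
                          n_explained = colSums(per_edge),
                          fraction = colSums(per_edge) / n,
                          stringsAsFactors = FALSE)
  any_known <- if (ncol(per_edge)) rowSums(per_edge) > 0L else logical(nrow(edges))
  fractions <- rbind(fractions,
                     data.frame(class = "any_known", n_explained = sum(any_known),
                                fraction = sum(any_known) / n),
                     data.frame(class = "unexplained", n_explained = sum(!any_known),
                                fraction = sum(!any_known) / n))
  if (!is.null(same_protein))
    fractions <- rbind(fractions,
                       data.frame(class = "same_protein",
                                  n_explained = sum(same_protein),
                                  fraction = sum(same_protein) / n))
  rownames(fractions) <- NULL
  list(fractions = fractions, per_edge = per_edge)
}

#' First-shell neighbor subnetwork of a node
#'
#' Returns the node's direct neighbors under a sign filter, the induced
#' edges among the node and its neighbors, and (when a ratio matrix is
#' given) the neighbors' strain profiles for heatmap export.
#'
#' @param node Node ID (must be present in the network's node set).
#' @param edges Edge data frame with `node_a`, `node_b`, `sign`.
#' @param merged Optional merged [ratio_matrix()] for the profile table.
#' @param sign_filter `"both"`, `"pos"`, or `"neg"`.
#' @return List with `neighbors`, `edges` (induced), and `profiles`
#'   (molecules x strains matrix, or NULL).
#' @export
neighbor_subnetwork <- function(node, edges, merged = NULL,
                                sign_filter = c("both", "pos", "neg")) {
  sign_filter <- match.arg(sign_filter)
  nodes <- unique(c(edges$node_a, edges$node_b))
  if (!node %in% nodes) stop("node '", node, "' is not in the network")
  e <- edges
  if (sign_filter != "both") e <- e[e$sign == sign_filter, , drop = FALSE]
  touch <- e$node_a == node | e$node_b == node
  neighbors <- sort(unique(c(e$node_a[touch], e$node_b[touch])))
  neighbors <- setdiff(neighbors, node)
  members <- c(node, neighbors)
  induced <- e[e$node_a %in% members & e$node_b %in% members, , drop = FALSE]
  rownames(induced) <- NULL
  profiles <- NULL
  if (!is.null(merged)) {
    rows <- intersect(members, rownames(merged$values))
    profiles <- merged$values[rows, , drop = FALSE]
  }
  list(neighbors = neighbors, edges = induced, profiles = profiles)
}
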