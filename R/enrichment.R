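#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated members in a query of
#' size `n` drawn without replacement from a background of size `N`
#' containing `K` annotated members.
#'
#' @param k Observed overlap.
#' @param K Annotated members in the background (term size).
#' @param n Query size.
#' @param N Background size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n)))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the output is order-preserving with respect to the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Regulator enrichment of a pathway's kinases/phosphatases
#'
#' For each molecule, tests whether the set of deletion strains in which it
#' is called regulated over-represents a given pathway's regulators, against
#' the background of all regulators showing any effect at the level under
#' study. With `consistency = TRUE`, molecules whose call direction differs
#' across their pathway-strain calls are removed after testing.
#'
#' @param calls Call data frame from [call_regulated_events()].
#' @param pathway_regulators Character vector of pathway strains (must be a
#'   subset of the background).
#' @param active_background Character vector of background strains (all
#'   regulators with any effect at this level).
#' @param consistency Drop molecules with direction conflicts across their
#'   pathway-strain calls (default TRUE).
#' @param alpha BH-adjusted significance cutoff (default 0.01).
#' @return Data frame with one row per molecule passing `p_adj <= alpha`:
#'   `molecule`, `k`, `K`, `n`, `N`, `p`, `p_adj`, `direction`. Attribute
#'   `all_tested` carries the full pre-filter table.
#' @export
regulator_enrichment <- function(calls, pathway_regulators, active_background,
                                 consistency = TRUE, alpha = 0.01) {
  if (!length(active_background)) stop("empty background strain set")
  if (!all(pathway_regulators %in% active_background))
    stop("pathway regulators must be a subset of the background")
  calls <- calls[calls$strain %in% active_background, , drop = FALSE]
  N <- length(unique(active_background))
  K <- length(unique(pathway_regulators))
  by_mol <- split(calls, calls$molecule)
  res <- do.call(rbind, lapply(names(by_mol), function(mol) {
    d <- by_mol[[mol]]
    regs <- unique(d$strain)
    k <- sum(regs %in% pathway_regulators)
    pw <- d[d$strain %in% pathway_regulators, , drop = FALSE]
    dirs <- unique(pw$direction)
    data.frame(molecule = mol, k = k, K = K, n = length(regs), N = N,
               p = hypergeometric_tail(k, K, length(regs), N),
               direction = if (length(dirs) == 1L) dirs else
                 if (length(dirs) > 1L) "inconsistent" else NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(molecule = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  res <- res[order(res$molecule), , drop = FALSE]     # deterministic BH ties
  res$p_adj <- bh_adjust(res$p)
  out <- res[res$p_adj <= alpha, , drop = FALSE]
  if (consistency) out <- out[is.na(out$direction) |
                                out$direction != "inconsistent", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_tested") <- res
  out
}

term_universe <- function(db, background) {
  sets <- lapply(db$sets, intersect, background)
  sets[lengths(sets) > 0L]
}

#' Effector enrichment per strain and direction
#'
#' Tests each deletion strain's upregulated and downregulated effector
#' proteins separately against each term of each database. Phosphosites
#' collapse to their cognate protein, and multiple regulated sites on one
#' protein count once. The background is the union of all perturbed proteins
#' across the regulation network; term universes are restricted to that
#' background. BH adjustment spans all strains, directions and terms within
#' one database.
#'
#' @param calls Call data frame from [call_regulated_events()].
#' @param databases List of term-type [annotation_db()].
#' @param site_to_protein Optional site -> protein map (phospho calls).
#' @param alpha BH cutoff (default 0.01).
#' @return Data frame of results passing `p_adj <= alpha`: `database`,
#'   `strain`, `direction`, `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#'   Attribute `all_tested` carries every computed test.
#' @export
effector_enrichment <- function(calls, databases, site_to_protein = NULL,
                                alpha = 0.01) {
  prot <- if (!is.null(site_to_protein)) unname(site_to_protein[calls$molecule])
          else calls$molecule
  calls <- data.frame(strain = calls$strain, protein = prot,
                      direction = calls$direction, stringsAsFactors = FALSE)
  calls <- unique(calls[!is.na(calls$protein), , drop = FALSE])
  background <- unique(calls$protein)
  N <- length(background)
  all_rows <- list()
  for (db in databases) {
    sets <- term_universe(db, background)
    if (!length(sets) || !N) next
    rows <- list(); k0 <- 0L
    for (s in unique(calls$strain)) {
      for (dir in c("up", "down")) {
        q <- unique(calls$protein[calls$strain == s & calls$direction == dir])
        if (!length(q)) next
        for (tm in names(sets)) {
          k0 <- k0 + 1L
          k <- length(intersect(q, sets[[tm]]))
          rows[[k0]] <- data.frame(database = db$name, strain = s,
                                   direction = dir, term = tm, k = k,
                                   K = length(sets[[tm]]), n = length(q), N = N,
                                   p = hypergeometric_tail(k, length(sets[[tm]]),
                                                           length(q), N),
                                   stringsAsFactors = FALSE)
        }
      }
    }
    if (!k0) next
    res <- do.call(rbind, rows)
    res <- res[order(res$strain, res$direction, res$term), , drop = FALSE]
    res$p_adj <- bh_adjust(res$p)
    all_rows[[db$name]] <- res
  }
  if (!length(all_rows))
    return(data.frame(database = character(), strain = character(),
                      direction = character(), term = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      p = numeric(), p_adj = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, all_rows)
  rownames(res) <- NULL
  out <- res[res$p_adj <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_tested") <- res
  out
}

#' Neighbor enrichment in a covariance network
#'
#' For each protein of the covariance network, tests its positively
#' correlated neighbors against each term of each database. The background
#' is every positively connected protein except the surveyed one; term
#' universes are restricted to the connected set. BH adjustment spans all
#' nodes and terms within one database.
#'
#' @param edges Covariance edge data frame (with `sign` column).
#' @param databases List of term-type [annotation_db()].
#' @param node Optional single node: results are computed network-wide (so
#'   the BH family is unchanged) and then restricted to this node.
#' @param alpha BH cutoff (default 0.01).
#' @return Data frame of results passing `p_adj <= alpha`: `database`,
#'   `node`, `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`. Attribute
#'   `all_tested` carries every computed test.
#' @export
neighbor_enrichment <- function(edges, databases, node = NULL, alpha = 0.01) {
  pos <- edges[edges$sign == "pos", , drop = FALSE]
  connected <- sort(unique(c(pos$node_a, pos$node_b)))
  nbr <- function(v) sort(unique(c(pos$node_b[pos$node_a == v],
                                   pos$node_a[pos$node_b == v])))
  all_rows <- list()
  for (db in databases) {
    rows <- list(); k0 <- 0L
    for (v in connected) {
      q <- nbr(v)
      if (!length(q)) next
      background <- setdiff(connected, v)
      sets <- term_universe(db, background)
      N <- length(background)
      for (tm in names(sets)) {
        k0 <- k0 + 1L
        k <- length(intersect(q, sets[[tm]]))
        rows[[k0]] <- data.frame(database = db$name, node = v, term = tm,
                                 k = k, K = length(sets[[tm]]),
                                 n = length(q), N = N,
                                 p = hypergeometric_tail(k, length(sets[[tm]]),
                                                         length(q), N),
                                 stringsAsFactors = FALSE)
      }
    }
    if (!k0) next
    res <- do.call(rbind, rows)
    res <- res[order(res$node, res$term), , drop = FALSE]
    res$p_adj <- bh_adjust(res$p)
    all_rows[[db$name]] <- res
  }
  if (!length(all_rows))
    return(data.frame(database = character(), node = character(),
                      term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, all_rows)
  rownames(res) <- NULL
  out <- res[res$p_adj <= alpha, , drop = FALSE]
  if (!is.null(node)) {
    if (!node %in% connected) stop("node '", node,
                                   "' has no positive neighbors in the network")
    out <- out[out$node == node, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "all_tested") <- res
  out
}
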