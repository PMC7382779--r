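#' Correct reporter intensities for isotopic label impurities
#'
#' Reporter channels of isobaric labels bleed into neighbouring channels
#' according to the manufacturer's impurity specification. With `M[i, j]` the
#' fraction of channel `j`'s signal detected in channel `i`, the observed
#' vector per molecule is `obs = M %*% true`; this solves the linear system
#' per molecule. Only rows observed in every channel are corrected (this
#' package's missingness is plex-structured, so partial rows do not arise
#' from simulation); negative solutions are clamped to 0 and counted.
#'
#' @param table A [plex_table()].
#' @param impurity_matrix Square channels x channels matrix of fractions;
#'   columns must sum to at most 1.
#' @return The corrected [plex_table()], with attribute `n_clamped`.
#' @export
correct_isotopic_impurities <- function(table, impurity_matrix) {
  stopifnot(inherits(table, "plex_table"))
  k <- ncol(table$intensities)
  if (!is.matrix(impurity_matrix) || nrow(impurity_matrix) != k ||
      ncol(impurity_matrix) != k)
    stop("impurity matrix must be ", k, " x ", k, " to match the channels")
  if (any(colSums(impurity_matrix) > 1 + 1e-9))
    stop("impurity matrix columns must sum to <= 1")
  inv <- tryCatch(solve(impurity_matrix),
                  error = function(e) stop("impurity matrix is singular", call. = FALSE))
  X <- table$intensities
  full <- which(rowSums(is.na(X)) == 0L)
  corrected <- X
  if (length(full)) corrected[full, ] <- X[full, , drop = FALSE] %*% t(inv)
  n_clamped <- sum(corrected < 0, na.rm = TRUE)
  if (n_clamped > 0) {
    message(n_clamped, " negative corrected intensities clamped to 0")
    corrected[!is.na(corrected) & corrected < 0] <- 0
  }
  out <- table
  out$intensities <- corrected
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Filter peptides on summed signal-to-noise and isolation specificity
#'
#' Retains peptides whose summed signal-to-noise across all channels reaches
#' `snr_sum_min` and whose MS1 isolation specificity reaches `isolation_min`;
#' both thresholds are inclusive.
#'
#' @param table A peptide-level [plex_table()].
#' @param noise Named per-channel noise estimates.
#' @param specificity Named per-peptide isolation specificity values.
#' @param snr_sum_min Summed signal-to-noise threshold (default 200).
#' @param isolation_min Isolation specificity threshold (default 0.5).
#' @return The filtered [plex_table()].
#' @export
filter_peptides <- function(table, noise, specificity,
                            snr_sum_min = 200, isolation_min = 0.5) {
  stopifnot(inherits(table, "plex_table"))
  if (table$level != "peptide") stop("filter_peptides expects a peptide-level table")
  if (is.null(noise) || !all(colnames(table$intensities) %in% names(noise)))
    stop("input error: per-channel noise estimates missing")
  mols <- rownames(table$intensities)
  if (is.null(specificity) || !all(mols %in% names(specificity)))
    stop("input error: per-peptide isolation specificity missing")
  snr <- rowSums(sweep(table$intensities, 2L,
                       noise[colnames(table$intensities)], `/`), na.rm = TRUE)
  keep <- snr >= snr_sum_min & specificity[mols] >= isolation_min
  out <- table
  out$intensities <- table$intensities[keep, , drop = FALSE]
  out
}

#' Sum unique peptides into protein quantifications
#'
#' Only peptides mapping to exactly one protein contribute; shared peptides
#' are discarded entirely. A protein's channel value is the sum of its
#' peptides' intensities, missing when no peptide contributes a value.
#'
#' @param table A peptide-level [plex_table()].
#' @param peptide_to_protein Data frame with columns `peptide`, `protein`
#'   (one row per mapping; peptides occurring with several proteins are
#'   treated as shared), or a named character vector.
#' @return A protein-level [plex_table()].
#' @export
rollup_peptides_to_protein <- function(table, peptide_to_protein) {
  stopifnot(inherits(table, "plex_table"))
  if (is.character(peptide_to_protein))
    peptide_to_protein <- data.frame(peptide = names(peptide_to_protein),
                                     protein = unname(peptide_to_protein),
                                     stringsAsFactors = FALSE)
  map <- unique(peptide_to_protein[, c("peptide", "protein")])
  shared <- unique(map$peptide[duplicated(map$peptide)])
  map <- map[!map$peptide %in% shared, , drop = FALSE]
  map <- map[map$peptide %in% rownames(table$intensities), , drop = FALSE]
  prots <- sort(unique(map$protein))
  X <- table$intensities[map$peptide, , drop = FALSE]
  g <- factor(map$protein, levels = prots)
  sum_keep_na <- function(col) {
    s <- tapply(col, g, function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
    as.numeric(s)
  }
  out_mat <- vapply(seq_len(ncol(X)), function(j) sum_keep_na(X[, j]),
                    numeric(length(prots)))
  if (is.null(dim(out_mat))) out_mat <- matrix(out_mat, nrow = length(prots))
  dimnames(out_mat) <- list(prots, colnames(X))
  plex_table(table$plex_id, "protein", table$channels, out_mat)
}

#' Equalize per-channel protein loading within a plex
#'
#' Scales each channel so that the summed protein quantity (over molecules
#' observed in every channel of the plex) is equal across channels, i.e.
#' equals the cross-channel mean of the raw sums. The per-channel factors are
#' returned for reuse on the plex's phosphosite table.
#'
#' @param table A protein-level [plex_table()].
#' @return List with `table` (scaled) and `factors` (named per-channel).
#' @export
equalize_loading <- function(table) {
  stopifnot(inherits(table, "plex_table"))
  if (table$level != "protein") stop("equalize_loading expects a protein-level table")
  X <- table$intensities
  full <- rowSums(is.na(X)) == 0L
  if (!any(full)) stop("no molecule observed in all channels; cannot equalize loading")
  sums <- colSums(X[full, , drop = FALSE])
  if (any(sums == 0)) stop("channel '", colnames(X)[sums == 0][1L],
                           "' has zero total intensity")
  factors <- mean(sums) / sums
  out <- table
  out$intensities <- sweep(X, 2L, factors, `*`)
  list(table = out, factors = factors)
}

#' Apply protein-derived loading factors to a phosphosite table
#'
#' The phosphopeptide enrichment input is the same labeled digest as the
#' protein analysis, so channel loading variance is corrected with the
#' factors estimated from the protein table of the same plex.
#'
#' @param phospho_table A phosphosite-level [plex_table()].
#' @param factors Named per-channel factors from [equalize_loading()].
#' @return The scaled [plex_table()].
#' @export
apply_loading_to_phospho <- function(phospho_table, factors) {
  stopifnot(inherits(phospho_table, "plex_table"))
  chans <- colnames(phospho_table$intensities)
  if (!setequal(chans, names(factors)))
    stop("channel mismatch between phosphosite table and loading factors")
  out <- phospho_table
  out$intensities <- sweep(phospho_table$intensities, 2L, factors[chans], `*`)
  out
}

#' Log2 ratios to the wild-type bridge channel
#'
#' Log2-transforms intensities and subtracts the bridge (wild-type) channel's
#' value per molecule, yielding one ratio column per sample channel. Zero
#' intensities become missing (counted); a molecule missing in the bridge has
#' all its ratios missing in that plex.
#'
#' @param table A [plex_table()].
#' @return List with `plex_id`, `level`, `samples` (strain/replicate data
#'   frame), and `ratios` (molecules x sample channels log2 matrix).
#' @export
bridge_log2_ratios <- function(table) {
  stopifnot(inherits(table, "plex_table"))
  X <- table$intensities
  n_zero <- sum(X == 0, na.rm = TRUE)
  if (n_zero > 0) {
    message(n_zero, " zero intensities treated as missing before log transform")
    X[!is.na(X) & X == 0] <- NA_real_
  }
  L <- log2(X)
  bi <- which(table$channels$is_bridge)
  ratios <- L[, -bi, drop = FALSE] - L[, bi]
  ratios[is.na(L[, bi]), ] <- NA_real_
  list(plex_id = table$plex_id, level = table$level,
       samples = data.frame(strain = table$channels$strain[-bi],
                            replicate = table$channels$replicate[-bi],
                            stringsAsFactors = FALSE),
       ratios = ratios)
}

trimmed_mean <- function(v, trim = 0.05) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (!n) return(NA_real_)
  k <- floor(trim * n)
  if (n - 2L * k < 1L) k <- 0L
  v <- sort(v)
  mean(v[(k + 1L):(n - k)])
}

#' Center each sample column at its trimmed mean
#'
#' Within a plex, each sample column of log2 ratios is shifted so that its
#' trimmed mean (default 5% per tail) is 0. This absorbs measurement error in
#' the bridge sample and per-channel offsets that survive loading
#' equalization.
#'
#' @param ratio_block Output of [bridge_log2_ratios()] (or a bare matrix).
#' @param trim_fraction Fraction trimmed from each tail (default 0.05).
#' @return Same structure as the input, centered.
#' @export
center_trimmed_mean <- function(ratio_block, trim_fraction = 0.05) {
  mat <- if (is.list(ratio_block)) ratio_block$ratios else ratio_block
  centers <- apply(mat, 2L, trimmed_mean, trim = trim_fraction)
  centers[is.na(centers)] <- 0
  mat <- sweep(mat, 2L, centers, `-`)
  if (is.list(ratio_block)) { ratio_block$ratios <- mat; ratio_block }
  else mat
}

#' Join per-plex ratio columns into the complete dataset
#'
#' Plexes are joined by molecule identification: the joined matrix has the
#' union of molecules in its rows and one column per (strain, replicate),
#' missing where a molecule was absent from the source plex.
#'
#' @param blocks List of [bridge_log2_ratios()] outputs (centered).
#' @param level Level recorded on the joined matrix (default from blocks).
#' @return A [ratio_matrix()].
#' @export
join_plexes <- function(blocks, level = NULL) {
  stopifnot(length(blocks) >= 1L)
  if (is.null(level)) level <- blocks[[1L]]$level
  samples <- do.call(rbind, lapply(blocks, `[[`, "samples"))
  key <- paste(samples$strain, samples$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("design error: duplicate (strain, replicate) column '",
         samples$strain[duplicated(key)][1L], "'")
  mols <- sort(unique(unlist(lapply(blocks, function(b) rownames(b$ratios)))))
  out <- matrix(NA_real_, length(mols), nrow(samples),
                dimnames = list(mols, NULL))
  j0 <- 0L
  for (b in blocks) {
    jj <- j0 + seq_len(ncol(b$ratios))
    out[match(rownames(b$ratios), mols), jj] <- b$ratios
    j0 <- j0 + ncol(b$ratios)
  }
  ratio_matrix(level, out, samples)
}

#' Normalize phosphosite ratios by cognate protein ratios
#'
#' Subtracts the cognate protein's log2 ratio from each phosphosite's log2
#' ratio per (strain, replicate), so the remainder reflects phosphorylation
#' stoichiometry change. Entries without a cognate protein ratio (or sites
#' whose protein was not quantified) keep the unnormalized value and are
#' flagged; the fraction of normalizable entries is recorded as attribute
#' `normalized_fraction`.
#'
#' @param phospho A phosphosite-level [ratio_matrix()].
#' @param protein A protein-level [ratio_matrix()] on the same sample grid.
#' @param site_to_protein Named character vector, site ID -> protein ID.
#' @return A [ratio_matrix()] with the `normalized` flag matrix set.
#' @export
normalize_phospho_by_protein <- function(phospho, protein, site_to_protein) {
  stopifnot(inherits(phospho, "ratio_matrix"), inherits(protein, "ratio_matrix"))
  pk <- paste(phospho$samples$strain, phospho$samples$replicate, sep = "\r")
  qk <- paste(protein$samples$strain, protein$samples$replicate, sep = "\r")
  col_of <- match(pk, qk)
  if (anyNA(col_of)) stop("phosphosite and protein matrices must share the sample grid")
  sites <- rownames(phospho$values)
  cognate <- site_to_protein[sites]
  row_of <- match(cognate, rownames(protein$values))
  vals <- phospho$values
  flags <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  have_prot <- which(!is.na(row_of))
  if (length(have_prot)) {
    P <- protein$values[row_of[have_prot], col_of, drop = FALSE]
    ok <- !is.na(P) & !is.na(vals[have_prot, , drop = FALSE])
    sub <- vals[have_prot, , drop = FALSE]
    sub[ok] <- sub[ok] - P[ok]
    vals[have_prot, ] <- sub
    flags[have_prot, ] <- ok
  }
  frac <- sum(flags) / max(1L, sum(!is.na(phospho$values)))
  out <- ratio_matrix(phospho$level, vals, phospho$samples, normalized = flags)
  attr(out, "normalized_fraction") <- frac
  out
}

#' Keep molecules quantified in at least a fraction of strains
#'
#' A molecule counts as quantified in a strain when any of its replicates is
#' non-missing; it is retained when quantified in at least
#' `ceiling(min_fraction * n_strains)` strains.
#'
#' @param rm A [ratio_matrix()].
#' @param min_fraction Minimum fraction of strains (default 0.5).
#' @return The filtered [ratio_matrix()].
#' @export
filter_min_coverage <- function(rm, min_fraction = 0.5) {
  stopifnot(inherits(rm, "ratio_matrix"))
  strains <- unique(rm$samples$strain)
  if (!nrow(rm$values)) return(rm)
  present <- !is.na(rm$values)
  by_strain <- vapply(strains, function(s)
    rowSums(present[, rm$samples$strain == s, drop = FALSE]) > 0L,
    logical(nrow(rm$values)))
  if (is.null(dim(by_strain))) by_strain <- matrix(by_strain, nrow = nrow(rm$values))
  n_quant <- rowSums(by_strain)
  keep <- n_quant >= ceiling(min_fraction * length(strains))
  out <- rm
  out$values <- rm$values[keep, , drop = FALSE]
  if (!is.null(rm$normalized)) out$normalized <- rm$normalized[keep, , drop = FALSE]
  out
}

#' Hierarchical clustering of samples on correlation distance
#'
#' Average-linkage clustering of sample columns on pairwise-complete Pearson
#' correlation distance (1 - r). Columns sharing fewer than 3 observations
#' with every other column are excluded with a warning.
#'
#' @param rm A [ratio_matrix()].
#' @return List with `hclust` (the merge tree) and `order` (leaf labels in
#'   dendrogram order).
#' @export
cluster_samples <- function(rm) {
  stopifnot(inherits(rm, "ratio_matrix"))
  X <- rm$values
  if (ncol(X) < 2L) stop("need at least 2 sample columns to cluster")
  obs <- !is.na(X)
  shared <- crossprod(obs)
  diag(shared) <- 0L
  bad <- apply(shared, 2L, max) < 3L
  if (any(bad)) {
    warning("excluding ", sum(bad), " column(s) with < 3 shared observations: ",
            paste(colnames(X)[bad], collapse = ", "))
    X <- X[, !bad, drop = FALSE]
  }
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(hclust = hc, order = colnames(X)[hc$order])
}

#' Run the full ratio-building chain on simulated (or read) plex tables
#'
#' Convenience wrapper for the per-plex chain: loading equalization on the
#' protein table, reuse of the factors on the phosphosite table, bridge log2
#' ratios, trimmed-mean centering, joining across plexes, and protein
#' normalization of phosphosites.
#'
#' @param sim Output of [simulate_reporter_data()], or a list with `protein`
#'   and `phospho` lists of [plex_table()] keyed by plex.
#' @param site_to_protein Named site -> protein map (defaults to the
#'   simulation truth when present).
#' @param trim_fraction Trim fraction for column centering.
#' @return List of [ratio_matrix()]: `protein`, `phospho_raw`, `phospho_norm`.
#' @export
build_ratio_matrices <- function(sim, site_to_protein = NULL, trim_fraction = 0.05) {
  if (is.null(site_to_protein) && !is.null(sim$truth))
    site_to_protein <- sim$truth$site_to_protein
  prot_blocks <- list(); phos_blocks <- list()
  for (px in names(sim$protein)) {
    eq <- equalize_loading(sim$protein[[px]])
    prot_blocks[[px]] <- center_trimmed_mean(bridge_log2_ratios(eq$table),
                                             trim_fraction)
    if (!is.null(sim$phospho[[px]])) {
      ph <- apply_loading_to_phospho(sim$phospho[[px]], eq$factors)
      phos_blocks[[px]] <- center_trimmed_mean(bridge_log2_ratios(ph),
                                               trim_fraction)
    }
  }
  protein <- join_plexes(prot_blocks, "protein")
  out <- list(protein = protein)
  if (length(phos_blocks)) {
    phospho_raw <- join_plexes(phos_blocks, "phosphosite")
    out$phospho_raw <- phospho_raw
    if (!is.null(site_to_protein))
      out$phospho_norm <- normalize_phospho_by_protein(phospho_raw, protein,
                                                       site_to_protein)
  }
  out
}
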