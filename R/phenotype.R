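#' Merge biological replicates into strain-level profiles
#'
#' The merged value is the arithmetic mean of the available replicates;
#' replicate support (number of contributing replicates) is recorded.
#'
#' @param rm A replicate-resolved [ratio_matrix()].
#' @return A strain-level [ratio_matrix()] (`replicate = NA`) with field
#'   `reps`, the molecules x strains matrix of contributing replicate counts.
#' @export
merge_replicates <- function(rm) {
  stopifnot(inherits(rm, "ratio_matrix"))
  strains <- unique(rm$samples$strain)
  vals <- matrix(NA_real_, nrow(rm$values), length(strains),
                 dimnames = list(rownames(rm$values), strains))
  reps <- matrix(0L, nrow(rm$values), length(strains),
                 dimnames = dimnames(vals))
  for (s in strains) {
    sub <- rm$values[, rm$samples$strain == s, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[n == 0L] <- NA_real_
    vals[, s] <- m
    reps[, s] <- n
  }
  out <- ratio_matrix(rm$level, vals,
                      data.frame(strain = strains, replicate = NA_integer_,
                                 stringsAsFactors = FALSE))
  out$reps <- reps
  out
}

#' Trimmed standard deviation of one profile
#'
#' SD computed after removing the highest and lowest `floor(trim * n)` values
#' (default 5% per tail). Ties at the trim boundary are broken by value order
#' (then input order), making the result deterministic.
#'
#' @param values Numeric vector (missing values dropped).
#' @param trim Fraction trimmed per tail.
#' @return The trimmed SD, or `NA` when fewer than 3 values remain in total.
#' @export
trimmed_sd <- function(values, trim = 0.05) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 3L) return(NA_real_)
  k <- floor(trim * n)
  if (k > 0L) {
    v <- sort(v)
    v <- v[(k + 1L):(n - k)]
  }
  stats::sd(v)
}

#' Per-molecule trimmed-SD statistics and call thresholds
#'
#' Computes the trimmed SD of each molecule's merged strain profile and the
#' derived per-replicate (3 SD) and single-replicate (6 SD) thresholds.
#' Molecules with fewer than 3 merged values are excluded with a warning.
#'
#' @param merged A merged [ratio_matrix()] from [merge_replicates()].
#' @param trim Fraction trimmed per tail (default 0.05).
#' @return Data frame with columns `molecule`, `sd`, `n_used`, `thr3`, `thr6`.
#' @export
compute_trimmed_stats <- function(merged, trim = 0.05) {
  n_obs <- rowSums(!is.na(merged$values))
  sds <- apply(merged$values, 1L, trimmed_sd, trim = trim)
  drop <- n_obs < 3L
  if (any(drop))
    warning(sum(drop), " molecule(s) with < 3 strain values excluded from SD stats")
  keep <- which(!drop)
  n_used <- n_obs[keep] - 2L * floor(trim * n_obs[keep])
  data.frame(molecule = rownames(merged$values)[keep],
             sd = unname(sds[keep]), n_used = unname(n_used),
             thr3 = unname(3 * sds[keep]), thr6 = unname(6 * sds[keep]),
             stringsAsFactors = FALSE)
}

#' Call regulated events per deletion strain
#'
#' A molecule is called regulated in a strain when its replicate evidence
#' clears the molecule's trimmed-SD threshold and the merged ratio clears the
#' fold-change floor:
#' * two (or more) replicates present: every replicate satisfies
#'   `|ratio| >= 3 * SD` and all replicates agree in sign;
#' * a single replicate present: `|ratio| >= 6 * SD`;
#' * in all cases `|merged ratio| >= fc_floor` (log2 0.38 for proteins,
#'   0.5 for phosphosites, i.e. minimum fold changes of 1.3 and 1.4).
#'
#' The deleted gene's own product (and, at the phosphosite level, sites on
#' it) is excluded from its cognate strain's effector calls; such events are
#' returned separately as deletion confirmations.
#'
#' @param rm Replicate-resolved [ratio_matrix()].
#' @param stats Data frame from [compute_trimmed_stats()] (computed from the
#'   merged matrix if omitted).
#' @param fc_floor Log2 fold-change floor on the merged ratio.
#' @param sd_mult_both,sd_mult_single SD multipliers (defaults 3 and 6).
#' @param deletion_map Optional named strain -> deleted gene map.
#' @param site_to_protein Optional site -> protein map (phosphosite level).
#' @param level Label recorded on the calls (defaults to `rm$level`).
#' @return Data frame of calls with columns `strain`, `molecule`, `level`,
#'   `direction`, `ratio` (merged), `support` (`"both"`/`"single"`);
#'   attribute `deletion_confirmations` holds the masked self-calls.
#' @export
call_regulated_events <- function(rm, stats = NULL, fc_floor = 0.38,
                                  sd_mult_both = 3, sd_mult_single = 6,
                                  deletion_map = NULL, site_to_protein = NULL,
                                  level = NULL) {
  stopifnot(inherits(rm, "ratio_matrix"))
  if (is.null(level)) level <- rm$level
  merged <- merge_replicates(rm)
  if (is.null(stats)) stats <- suppressWarnings(compute_trimmed_stats(merged))
  idx <- match(stats$molecule, rownames(rm$values))
  sd_of <- stats$sd
  strains <- unique(rm$samples$strain)
  out <- vector("list", length(strains))
  for (si in seq_along(strains)) {
    s <- strains[si]
    sub <- rm$values[idx, rm$samples$strain == s, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- merged$values[idx, s]
    absmin <- suppressWarnings(apply(abs(sub), 1L, min, na.rm = TRUE))
    sgn_ok <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      length(v) > 0L && (all(v > 0) || all(v < 0))
    })
    pass <- !is.na(m) & abs(m) >= fc_floor & sd_of > 0 &
      ((n >= 2L & sgn_ok & absmin >= sd_mult_both * sd_of) |
         (n == 1L & absmin >= sd_mult_single * sd_of))
    if (!any(pass)) next
    out[[si]] <- data.frame(
      strain = s, molecule = stats$molecule[pass], level = level,
      direction = ifelse(m[pass] > 0, "up", "down"),
      ratio = m[pass], support = ifelse(n[pass] >= 2L, "both", "single"),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls))
    calls <- data.frame(strain = character(), molecule = character(),
                        level = character(), direction = character(),
                        ratio = numeric(), support = character(),
                        stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  confirmations <- calls[0L, ]
  if (!is.null(deletion_map)) {
    gene_of <- if (!is.null(site_to_protein)) {
      unname(site_to_protein[calls$molecule])
    } else calls$molecule
    self <- !is.na(gene_of) & gene_of == unname(deletion_map[calls$strain])
    confirmations <- calls[self, , drop = FALSE]
    calls <- calls[!self, , drop = FALSE]
    rownames(calls) <- rownames(confirmations) <- NULL
  }
  attr(calls, "deletion_confirmations") <- confirmations
  calls
}

#' Attribute phosphorylation events to protein abundance vs stoichiometry
#'
#' Compares the regulation calls made on raw (unnormalized) phosphosite
#' ratios with those made on protein-normalized ratios over the same site
#' universe:
#' * `protein_driven` - called raw-only: the change disappears once the
#'   cognate protein's abundance change is accounted for;
#' * `phospho_driven` - called on both: a genuine stoichiometry change;
#' * `newly_captured` - called normalized-only: a stoichiometry change that
#'   protein abundance masked before normalization.
#'
#' @param raw_calls Calls on the unnormalized phosphosite matrix.
#' @param normalized_calls Calls on the protein-normalized matrix.
#' @return Data frame of `(strain, molecule, attribution)` events; attribute
#'   `summary` holds the overall and per-strain class fractions.
#' @export
attribute_phospho_events <- function(raw_calls, normalized_calls) {
  key <- function(d) paste(d$strain, d$molecule, sep = "\r")
  rk <- key(raw_calls); nk <- key(normalized_calls)
  all_ev <- rbind(raw_calls[, c("strain", "molecule")],
                  normalized_calls[!nk %in% rk, c("strain", "molecule")])
  ak <- paste(all_ev$strain, all_ev$molecule, sep = "\r")
  attribution <- ifelse(ak %in% rk & ak %in% nk, "phospho_driven",
                        ifelse(ak %in% rk, "protein_driven", "newly_captured"))
  events <- cbind(all_ev, attribution = attribution, stringsAsFactors = FALSE)
  rownames(events) <- NULL
  frac <- function(x) {
    tb <- table(factor(x, levels = c("protein_driven", "phospho_driven",
                                     "newly_captured")))
    as.list(tb / max(1L, length(x)))
  }
  per_strain <- lapply(split(events$attribution, events$strain), frac)
  attr(events, "summary") <- list(overall = frac(events$attribution),
                                  n_events = nrow(events),
                                  per_strain = per_strain)
  events
}

#' Per-strain impact factors
#'
#' The impact factor of a deletion strain is the percentage of quantified
#' molecules called regulated in that strain.
#'
#' @param calls Call data frame from [call_regulated_events()].
#' @param merged Merged [ratio_matrix()] defining what was quantified.
#' @return Data frame with `strain`, `n_called`, `n_quantified`, `impact_pct`.
#' @export
impact_factor <- function(calls, merged) {
  stopifnot(inherits(merged, "ratio_matrix"))
  strains <- unique(merged$samples$strain)
  n_quant <- colSums(!is.na(merged$values))
  n_called <- table(factor(calls$strain, levels = strains))
  data.frame(strain = strains,
             n_called = as.integer(n_called[strains]),
             n_quantified = as.integer(n_quant[match(strains, colnames(merged$values))]),
             impact_pct = 100 * as.integer(n_called[strains]) /
               pmax(1L, as.integer(n_quant[match(strains, colnames(merged$values))])),
             stringsAsFactors = FALSE)
}

#' Bipartite regulator -> effector regulation network
#'
#' Nodes are deletion strains (regulators) and regulated molecules
#' (effectors); each call becomes one directed edge carrying its direction
#' and level.
#'
#' @param calls Call data frame from [call_regulated_events()].
#' @return List with `edges` (regulator, effector, direction, level) and
#'   `summary` (regulator, effector, up- and down-edge counts).
#' @export
build_regulation_network <- function(calls) {
  edges <- data.frame(regulator = calls$strain, effector = calls$molecule,
                      direction = calls$direction, level = calls$level,
                      stringsAsFactors = FALSE)
  list(edges = edges,
       summary = list(n_regulators = length(unique(edges$regulator)),
                      n_effectors = length(unique(edges$effector)),
                      n_up = sum(edges$direction == "up"),
                      n_down = sum(edges$direction == "down"),
                      n_edges = nrow(edges)))
}

#' Recovery of planted effects by the calling pipeline
#'
#' Compares a call set against the generator's planted truth. The target set
#' is every (molecule, strain) entry whose planted log2 effect reaches
#' `min_abs_effect`; members of planted co-regulation modules are excluded
#' from both sides, since their continuous shared effects are the covariance
#' network's recovery surface, not the event caller's.
#'
#' @param calls Call data frame from [call_regulated_events()].
#' @param truth A [build_truth()] object.
#' @param level `"protein"`, `"phospho_raw"` (total site signal) or
#'   `"phospho_norm"` (stoichiometry signal only).
#' @param min_abs_effect Minimum planted |log2 effect| counted as a target.
#' @return List with `sensitivity`, `precision`, `n_targets`, `n_calls`.
#' @export
recovery_metrics <- function(calls, truth, level = c("protein", "phospho_raw",
                                                     "phospho_norm"),
                             min_abs_effect = 0.6) {
  level <- match.arg(level)
  if (level == "protein") {
    E <- truth$protein_effects
    module_members <- unique(unlist(truth$modules[grepl("^PMOD", names(truth$modules))]))
  } else {
    E <- truth$phospho_effects
    if (level == "phospho_raw")
      E <- E + truth$protein_effects[truth$site_to_protein, , drop = FALSE]
    rownames(E) <- truth$phosphosites
    smod <- unique(unlist(truth$modules[grepl("^SMOD", names(truth$modules))]))
    pmod <- unique(unlist(truth$modules[grepl("^PMOD", names(truth$modules))]))
    module_members <- c(smod, truth$phosphosites[truth$site_to_protein %in% pmod])
  }
  keep <- !rownames(E) %in% module_members
  E <- E[keep, , drop = FALSE]
  tgt <- which(abs(E) >= min_abs_effect, arr.ind = TRUE)
  target_keys <- paste(rownames(E)[tgt[, 1L]], colnames(E)[tgt[, 2L]], sep = "\r")
  calls <- calls[!calls$molecule %in% module_members, , drop = FALSE]
  call_keys <- paste(calls$molecule, calls$strain, sep = "\r")
  nonzero <- which(E != 0, arr.ind = TRUE)
  nonzero_keys <- paste(rownames(E)[nonzero[, 1L]], colnames(E)[nonzero[, 2L]],
                        sep = "\r")
  list(sensitivity = if (length(target_keys)) mean(target_keys %in% call_keys)
                     else NA_real_,
       precision = if (length(call_keys)) mean(call_keys %in% nonzero_keys)
                   else NA_real_,
       n_targets = length(target_keys), n_calls = length(call_keys))
}
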