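#' Configuration for the synthetic deletion-strain experiment
#'
#' Describes a panel of single-deletion strains profiled in biological
#' replicate on isobaric plexes, each plex carrying one wild-type bridge
#' channel. Defaults mirror the study design this package targets: 110
#' strains, 14 random assignment groups run in duplicate (28 11-plexes), 16
#' growth batches, log2-scale measurement noise of 0.1 and planted effect
#' sizes of |log2| 0.6 and 1.0.
#'
#' Regulator strains receive planted protein and phosphosite targets. Of the
#' phosphosite targets, `prot_driven_fraction` change only through their
#' cognate protein's abundance (phosphorylation stoichiometry unchanged),
#' `compensated_fraction` change stoichiometry in exact opposition to a
#' protein change (invisible before protein normalization), and the rest are
#' pure stoichiometry changes. Co-regulated modules add a shared, continuous
#' per-strain effect to their members, creating covariance structure across
#' the panel.
#'
#' @param n_strains Number of deletion strains.
#' @param n_proteins,n_phosphosites Numbers of quantifiable molecules.
#' @param n_regulators Number of strains with planted downstream targets.
#' @param targets_per_regulator Planted protein targets per regulator.
#' @param phospho_targets_per_regulator Planted phosphosite targets per regulator.
#' @param prot_driven_fraction Fraction of phosphosite targets whose change is
#'   purely protein-abundance driven.
#' @param compensated_fraction Fraction of phosphosite targets whose
#'   stoichiometry change exactly cancels a protein change.
#' @param regulator_overlap Fraction of each later regulator's protein targets
#'   shared (with identical effects) with the first regulator, emulating
#'   regulators acting in one pathway (0 = independent target sets).
#' @param n_modules Number of co-regulated modules planted per level.
#' @param module_size Members per module.
#' @param module_sd SD (log2) of the shared per-strain module effect.
#' @param plex_size Channels per plex (default 11).
#' @param n_assignment_groups Number of random strain-assignment groups.
#' @param n_batches Number of growth batches (metadata only).
#' @param replicate_count Biological replicates per strain.
#' @param noise_sd Log2-scale SD of multiplicative measurement noise.
#' @param loading_cv Coefficient of variation of per-channel loading factors.
#' @param effect_grid Planted log2 effect sizes (sampled uniformly, signed as given).
#' @param missing_rate_plex Probability a molecule is absent from an entire plex.
#' @param suppression_log2 Log2 suppression applied to the deleted gene's own
#'   product in its cognate strain (near-background, not zero).
#' @param seed Integer seed controlling all randomness of the generator.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 110L, n_proteins = 2000L, n_phosphosites = 3000L,
                       n_regulators = 10L, targets_per_regulator = 20L,
                       phospho_targets_per_regulator = 20L,
                       prot_driven_fraction = 0.6, compensated_fraction = 0.1,
                       regulator_overlap = 0,
                       n_modules = 3L, module_size = 20L, module_sd = 0.5,
                       plex_size = 11L, n_assignment_groups = 14L, n_batches = 16L,
                       replicate_count = 2L, noise_sd = 0.1, loading_cv = 0.1,
                       effect_grid = c(-1, -0.6, 0.6, 1),
                       missing_rate_plex = 0.05, suppression_log2 = -5,
                       seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains), n_proteins = as.integer(n_proteins),
              n_phosphosites = as.integer(n_phosphosites),
              n_regulators = as.integer(n_regulators),
              targets_per_regulator = as.integer(targets_per_regulator),
              phospho_targets_per_regulator = as.integer(phospho_targets_per_regulator),
              prot_driven_fraction = prot_driven_fraction,
              compensated_fraction = compensated_fraction,
              regulator_overlap = regulator_overlap,
              n_modules = as.integer(n_modules), module_size = as.integer(module_size),
              module_sd = module_sd, plex_size = as.integer(plex_size),
              n_assignment_groups = as.integer(n_assignment_groups),
              n_batches = as.integer(n_batches),
              replicate_count = as.integer(replicate_count),
              noise_sd = noise_sd, loading_cv = loading_cv,
              effect_grid = effect_grid, missing_rate_plex = missing_rate_plex,
              suppression_log2 = suppression_log2, seed = as.integer(seed))
  chk <- function(ok, field, why)
    if (!isTRUE(ok)) stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  chk(cfg$plex_size >= 3L, "plex_size", "must be >= 3")
  chk(cfg$replicate_count >= 1L, "replicate_count", "must be >= 1")
  chk(cfg$n_strains >= 1L, "n_strains", "must be >= 1")
  chk(cfg$n_strains <= cfg$n_proteins, "n_proteins",
      "each strain deletes a distinct gene; need n_proteins >= n_strains")
  chk(cfg$missing_rate_plex >= 0 && cfg$missing_rate_plex <= 1,
      "missing_rate_plex", "must lie in [0, 1]")
  chk(cfg$prot_driven_fraction >= 0 && cfg$prot_driven_fraction <= 1,
      "prot_driven_fraction", "must lie in [0, 1]")
  chk(cfg$compensated_fraction >= 0 &&
        cfg$prot_driven_fraction + cfg$compensated_fraction <= 1,
      "compensated_fraction", "fractions must be in [0, 1] and sum to <= 1")
  chk(cfg$regulator_overlap >= 0 && cfg$regulator_overlap <= 1,
      "regulator_overlap", "must lie in [0, 1]")
  chk(all(is.finite(cfg$effect_grid)), "effect_grid", "effect sizes must be finite")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(cfg$loading_cv >= 0, "loading_cv", "must be >= 0")
  chk(cfg$n_regulators <= cfg$n_strains, "n_regulators", "cannot exceed n_strains")
  class(cfg) <- "sim_config"
  cfg
}

#' Plant the ground-truth regulatory structure
#'
#' Builds the deletion map (strain -> deleted gene), the site-to-protein map,
#' the planted regulator -> target effect matrices at both levels, the
#' attribution class of every phosphosite target, and the co-regulated
#' modules with their shared per-strain profiles. Module effects are folded
#' into the effect matrices, so `protein_effects` / `phospho_effects` hold
#' the complete planted log2 signal per (molecule, strain).
#'
#' @param config A [sim_config()].
#' @return An object of class `ground_truth` with fields `strains`,
#'   `proteins`, `phosphosites`, `deletion_map`, `site_to_protein`,
#'   `protein_effects`, `phospho_effects` (molecules x strains matrices),
#'   `phospho_attribution` (data frame), `regulator_targets` (data frame of
#'   the discrete planted targets), `modules` (named list of member sets)
#'   and `module_profiles` (modules x strains matrix of shared effects).
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  proteins <- sprintf("PROT%04d", seq_len(config$n_proteins))
  genes_deleted <- proteins[seq_len(config$n_strains)]
  strains <- paste0("d", genes_deleted)
  deletion_map <- stats::setNames(genes_deleted, strains)

  prot_idx <- sample.int(config$n_proteins, config$n_phosphosites, replace = TRUE)
  within_rank <- stats::ave(seq_along(prot_idx), prot_idx, FUN = seq_along)
  pos <- within_rank * 10L + sample.int(10L, config$n_phosphosites, replace = TRUE) - 1L
  res <- sample(c("S", "T", "Y"), config$n_phosphosites, replace = TRUE,
                prob = c(0.6, 0.3, 0.1))
  phosphosites <- paste0(proteins[prot_idx], "_p", res, pos)
  site_to_protein <- stats::setNames(proteins[prot_idx], phosphosites)

  E_prot <- matrix(0, config$n_proteins, config$n_strains,
                   dimnames = list(proteins, strains))
  E_site <- matrix(0, config$n_phosphosites, config$n_strains,
                   dimnames = list(phosphosites, strains))
  attribution <- NULL
  target_rows <- list()

  regulators <- strains[seq_len(config$n_regulators)]
  anchor_tg <- character(); anchor_eff <- numeric()
  for (rg in regulators) {
    candidates <- setdiff(proteins, deletion_map[[rg]])
    if (config$targets_per_regulator > 0L) {
      n_shared <- if (rg == regulators[1L]) 0L else
        min(round(config$regulator_overlap * config$targets_per_regulator),
            length(anchor_tg))
      shared <- if (n_shared > 0L) {
        ok <- anchor_tg != deletion_map[[rg]]
        utils::head(which(ok), n_shared)
      } else integer()
      tg_shared <- anchor_tg[shared]
      fresh <- sample(setdiff(candidates, tg_shared),
                      config$targets_per_regulator - length(tg_shared))
      eff_fresh <- sample(config$effect_grid, length(fresh), replace = TRUE)
      tg <- c(tg_shared, fresh)
      eff <- c(anchor_eff[shared], eff_fresh)
      E_prot[cbind(tg, rg)] <- eff
      target_rows[[length(target_rows) + 1L]] <-
        data.frame(strain = rg, molecule = tg, level = "protein",
                   effect = eff, stringsAsFactors = FALSE)
      if (rg == regulators[1L]) { anchor_tg <- tg; anchor_eff <- eff }
    }
    if (config$phospho_targets_per_regulator > 0L) {
      # plant on sites whose cognate proteins are distinct and otherwise
      # unperturbed in this strain, so each site's attribution class is clean
      ok <- site_to_protein != deletion_map[[rg]] &
        E_prot[site_to_protein, rg] == 0
      cand <- sample(phosphosites[ok])
      cand <- cand[!duplicated(site_to_protein[cand])]
      if (length(cand) < config$phospho_targets_per_regulator)
        stop("invalid sim_config field 'phospho_targets_per_regulator': ",
             "not enough sites on distinct unperturbed proteins", call. = FALSE)
      st <- cand[seq_len(config$phospho_targets_per_regulator)]
      n_pd <- round(config$prot_driven_fraction * length(st))
      n_cp <- round(config$compensated_fraction * length(st))
      cls <- rep("phospho_driven", length(st))
      if (n_pd > 0L) cls[seq_len(n_pd)] <- "protein_driven"
      if (n_cp > 0L) cls[n_pd + seq_len(n_cp)] <- "compensated"
      eff <- sample(config$effect_grid, length(st), replace = TRUE)
      for (i in seq_along(st)) {
        pr <- site_to_protein[[st[i]]]
        if (cls[i] == "protein_driven") {
          E_prot[pr, rg] <- eff[i]          # site moves only through its protein
        } else if (cls[i] == "compensated") {
          E_prot[pr, rg] <- eff[i]          # stoichiometry cancels the protein change
          E_site[st[i], rg] <- -eff[i]
        } else {
          E_site[st[i], rg] <- eff[i]
        }
      }
      attribution <- rbind(attribution,
                           data.frame(strain = rg, phosphosite = st, class = cls,
                                      effect = eff, stringsAsFactors = FALSE))
      target_rows[[length(target_rows) + 1L]] <-
        data.frame(strain = rg, molecule = st, level = "phospho",
                   effect = eff, stringsAsFactors = FALSE)
    }
  }

  modules <- list()
  module_profiles <- NULL
  if (config$n_modules > 0L && config$module_size > 0L) {
    unplanted_p <- setdiff(proteins[rowSums(E_prot != 0) == 0], genes_deleted)
    unplanted_s <- phosphosites[rowSums(E_site != 0) == 0]
    module_profiles <- matrix(stats::rnorm(2L * config$n_modules * config$n_strains,
                                           0, config$module_sd),
                              2L * config$n_modules, config$n_strains,
                              dimnames = list(NULL, strains))
    nm <- character(2L * config$n_modules)
    for (m in seq_len(config$n_modules)) {
      mem <- sample(unplanted_p, config$module_size)
      unplanted_p <- setdiff(unplanted_p, mem)
      modules[[sprintf("PMOD%02d", m)]] <- mem
      nm[m] <- sprintf("PMOD%02d", m)
      E_prot[mem, ] <- E_prot[mem, ] +
        matrix(module_profiles[m, ], config$module_size, config$n_strains, byrow = TRUE)
    }
    for (m in seq_len(config$n_modules)) {
      mem <- sample(unplanted_s, config$module_size)
      unplanted_s <- setdiff(unplanted_s, mem)
      modules[[sprintf("SMOD%02d", m)]] <- mem
      nm[config$n_modules + m] <- sprintf("SMOD%02d", m)
      E_site[mem, ] <- E_site[mem, ] +
        matrix(module_profiles[config$n_modules + m, ],
               config$module_size, config$n_strains, byrow = TRUE)
    }
    rownames(module_profiles) <- nm
  }

  structure(list(strains = strains, proteins = proteins, phosphosites = phosphosites,
                 deletion_map = deletion_map, site_to_protein = site_to_protein,
                 protein_effects = E_prot, phospho_effects = E_site,
                 phospho_attribution = attribution,
                 regulator_targets = if (length(target_rows))
                   do.call(rbind, target_rows) else NULL,
                 modules = modules, module_profiles = module_profiles,
                 config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> %d strains, %d proteins, %d phosphosites; ",
                     "%d nonzero protein effects, %d nonzero phospho effects, %d modules\n"),
              length(x$strains), length(x$proteins), length(x$phosphosites),
              sum(x$protein_effects != 0), sum(x$phospho_effects != 0),
              length(x$modules)))
  invisible(x)
}

#' Construct the multiplexed plex design
#'
#' Randomly assigns strains to assignment groups, then runs every group once
#' per biological replicate, so replicate plexes mirror group membership.
#' Each plex carries the group's strains plus one wild-type bridge channel.
#' With the default configuration (110 strains, 14 groups, duplicates) this
#' yields 28 11-plexes.
#'
#' @param config A [sim_config()].
#' @return A data frame of class `plex_design` with columns `plex`, `channel`,
#'   `strain` (`"WT"` for the bridge), `replicate`, `is_bridge`, `batch`.
#' @export
build_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  capacity <- config$n_assignment_groups * (config$plex_size - 1L)
  if (config$n_strains > capacity)
    stop("design error: ", config$n_strains, " strains exceed capacity ",
         capacity, " (", config$n_assignment_groups, " groups x ",
         config$plex_size - 1L, " sample channels)")
  set.seed(config$seed + 1L)
  strains <- build_truth_strain_names(config)
  grp <- sort(rep_len(seq_len(config$n_assignment_groups), config$n_strains))
  grp <- grp[order(sample.int(config$n_strains))]  # random group membership
  batches <- matrix(sample.int(config$n_batches, config$n_strains * config$replicate_count,
                               replace = TRUE),
                    config$n_strains, config$replicate_count)
  rows <- vector("list", config$n_assignment_groups * config$replicate_count)
  k <- 0L
  for (r in seq_len(config$replicate_count)) {
    for (g in seq_len(config$n_assignment_groups)) {
      members <- strains[grp == g]
      if (!length(members)) next
      k <- k + 1L
      plex_id <- sprintf("plex%02d", (r - 1L) * config$n_assignment_groups + g)
      ch <- channel_names(config$plex_size)[seq_len(length(members) + 1L)]
      rows[[k]] <- data.frame(
        plex = plex_id, channel = ch,
        strain = c("WT", members), replicate = r,
        is_bridge = c(TRUE, rep(FALSE, length(members))),
        batch = c(NA_integer_, batches[match(members, strains), r]),
        stringsAsFactors = FALSE)
    }
  }
  design <- do.call(rbind, rows[seq_len(k)])
  rownames(design) <- NULL
  class(design) <- c("plex_design", "data.frame")
  design
}

build_truth_strain_names <- function(config) {
  paste0("d", sprintf("PROT%04d", seq_len(config$n_strains)))
}

channel_names <- function(plex_size) {
  if (plex_size == 11L)
    c("126", "127N", "127C", "128N", "128C", "129N", "129C",
      "130N", "130C", "131N", "131C")
  else sprintf("ch%02d", seq_len(plex_size))
}

#' Simulate reporter intensities for every plex
#'
#' Generates protein-level and phosphosite-level reporter intensity tables
#' for each plex of the design. Each intensity is
#' `baseline * 2^effect * loading * 2^noise`: baselines are log-uniform over
#' three orders of magnitude, effects come from the planted truth (the
#' phosphosite signal compounds the cognate protein's effect and the
#' stoichiometry effect), per-channel loading factors are log-normal with the
#' configured CV (shared between the protein and phosphosite tables of a
#' plex, as both derive from the same labeled sample), and noise is
#' multiplicative log-normal. The deleted gene's own product (and its
#' phosphosites) is suppressed to near-background in its cognate strain.
#' Missingness is plex-structured: a molecule drops out of an entire plex.
#'
#' @param truth A [build_truth()] result.
#' @param design A [build_design()] result.
#' @param config The shared [sim_config()].
#' @param dir Optional directory; when given, per-plex tables, the design and
#'   the truth tables are written as plain-text files.
#' @return List with `protein` and `phospho` (lists of [plex_table()] keyed by
#'   plex ID), plus `design`, `truth`, and `loading_factors`.
#' @export
simulate_reporter_data <- function(truth, design, config, dir = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "plex_design"))
  if (!all(setdiff(design$strain, "WT") %in% truth$strains))
    stop("design and truth do not share the same strain universe")
  set.seed(config$seed + 2L)
  base_p <- stats::setNames(10^stats::runif(config$n_proteins, 3, 6), truth$proteins)
  base_s <- stats::setNames(10^stats::runif(config$n_phosphosites, 3, 6), truth$phosphosites)

  # phosphosite total signal = protein abundance effect + stoichiometry effect
  E_site_total <- truth$protein_effects[truth$site_to_protein, , drop = FALSE] +
    truth$phospho_effects
  rownames(E_site_total) <- truth$phosphosites

  supp_p <- matrix(0, config$n_proteins, config$n_strains,
                   dimnames = dimnames(truth$protein_effects))
  supp_p[cbind(match(truth$deletion_map, truth$proteins), seq_len(config$n_strains))] <-
    config$suppression_log2
  supp_s <- supp_p[truth$site_to_protein, , drop = FALSE]
  rownames(supp_s) <- truth$phosphosites

  plex_ids <- unique(design$plex)
  sdlog <- if (config$loading_cv > 0) sqrt(log(1 + config$loading_cv^2)) else 0
  prot_tables <- phos_tables <- stats::setNames(vector("list", length(plex_ids)), plex_ids)
  loadings <- stats::setNames(vector("list", length(plex_ids)), plex_ids)

  one_level <- function(pd, base, eff, supp, level, load) {
    mols <- names(base)
    present <- if (config$missing_rate_plex > 0)
      stats::runif(length(mols)) >= config$missing_rate_plex else rep(TRUE, length(mols))
    mols <- mols[present]
    log2sig <- matrix(0, length(mols), nrow(pd))      # bridge column: effect 0
    smp <- !pd$is_bridge
    log2sig[, smp] <- eff[mols, pd$strain[smp], drop = FALSE] +
      supp[mols, pd$strain[smp], drop = FALSE]
    noise <- matrix(0, length(mols), nrow(pd))
    if (config$noise_sd > 0) {
      # noise is attached to the sample channels; residual bridge measurement
      # error is what the per-column trimmed-mean centering absorbs downstream
      noise[, smp] <- stats::rnorm(length(mols) * sum(smp), 0, config$noise_sd)
    }
    int <- base[mols] * 2^(log2sig + noise)
    int <- sweep(int, 2L, load, `*`)
    rownames(int) <- mols
    plex_table(pd$plex[1L], level,
               data.frame(channel = pd$channel, strain = pd$strain,
                          replicate = pd$replicate, is_bridge = pd$is_bridge,
                          stringsAsFactors = FALSE),
               int)
  }

  for (px in plex_ids) {
    pd <- design[design$plex == px, , drop = FALSE]
    load <- if (sdlog > 0) exp(stats::rnorm(nrow(pd), 0, sdlog)) else rep(1, nrow(pd))
    loadings[[px]] <- stats::setNames(load, pd$channel)
    prot_tables[[px]] <- one_level(pd, base_p, truth$protein_effects, supp_p,
                                   "protein", load)
    phos_tables[[px]] <- one_level(pd, base_s, E_site_total, supp_s,
                                   "phosphosite", load)
  }

  out <- list(protein = prot_tables, phospho = phos_tables,
              design = design, truth = truth, loading_factors = loadings)
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (px in names(sim$protein)) {
    write_intensity_table(sim$protein[[px]], file.path(dir, paste0(px, "_protein.tsv")))
    write_intensity_table(sim$phospho[[px]], file.path(dir, paste0(px, "_phospho.tsv")))
  }
  write_design(sim$design, file.path(dir, "design.yaml"))
  tr <- sim$truth
  eff <- function(E) {
    idx <- which(E != 0, arr.ind = TRUE)
    data.frame(molecule = rownames(E)[idx[, 1L]], strain = colnames(E)[idx[, 2L]],
               log2_effect = E[idx], stringsAsFactors = FALSE)
  }
  utils::write.table(eff(tr$protein_effects), file.path(dir, "truth_protein_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(eff(tr$phospho_effects), file.path(dir, "truth_phospho_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(strain = names(tr$deletion_map),
                                deleted_gene = unname(tr$deletion_map)),
                     file.path(dir, "truth_deletions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
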