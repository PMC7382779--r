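#' Default pipeline run configuration
#'
#' All thresholds of the analysis live here (never hard-coded in stage
#' code); the defaults are the study's: 3/6 SD replicate cutoffs, log2
#' fold-change floors 0.38 (protein) and 0.5 (phosphosite), |r| cutoffs 0.6
#' (strain pairs, >= 25 shared responsive molecules) and 0.7 (molecule pairs,
#' Bonferroni-adjusted p <= 0.001, >= 50% shared strains), 50% strain
#' coverage, 5% trimming per tail, 1000 permutations, and BH enrichment at 1%.
#'
#' @return Nested named list: `seed`, `simulate` (arguments forwarded to
#'   [sim_config()]), `thresholds`, `stages`.
#' @export
kd_default_config <- function() {
  list(
    seed = 1L,
    simulate = list(),
    thresholds = list(
      trim = 0.05,
      min_coverage = 0.5,
      sd_mult_both = 3, sd_mult_single = 6,
      fc_floor_protein = 0.38, fc_floor_phospho = 0.5,
      gene_r_min = 0.6, gene_min_n = 25,
      cov_r_min = 0.7, cov_p_adj_max = 0.001, min_shared_fraction = 0.5,
      n_perm = 1000,
      enrich_alpha = 0.01),
    stages = c("simulate", "normalize", "call", "gene_corr", "covariance",
               "enrichment")
  )
}

merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config error: unknown key", if (length(unknown) > 1) "s", " ",
         paste0("'", path, unknown, "'", collapse = ", "), call. = FALSE)
  out <- defaults
  for (nm in names(user)) {
    out[[nm]] <- if (is.list(defaults[[nm]]) && nm != "simulate")
      merge_config(user[[nm]], defaults[[nm]], paste0(path, nm, "/"))
    else user[[nm]]
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> normalize -> call -> gene-corr -> covariance ->
#' enrichment on a synthetic panel, writing every stage's outputs and a
#' machine-readable run manifest (package version, seed, thresholds, stage
#' counts) to `out_dir`. Reruns with the same config produce identical
#' outputs. For the enrichment stage, the planted co-regulation modules of
#' the ground truth double as a synthetic annotation database.
#'
#' @param config A nested list (see [kd_default_config()]) or the path to a
#'   YAML file holding one; unknown keys raise a config error before any
#'   computation.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage's in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(config, kd_default_config())
  th <- config$thresholds
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  say <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ...,
                           "\n", file = logf, append = TRUE)
  res <- list(config = config)
  counts <- list()

  # --- simulate -------------------------------------------------------------
  scfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
  truth <- build_truth(scfg)
  design <- build_design(scfg)
  sim <- simulate_reporter_data(truth, design, scfg,
                                dir = file.path(out_dir, "simulated"))
  say("simulate:", length(sim$protein), "plexes")
  counts$n_plexes <- length(sim$protein)
  counts$n_strains <- scfg$n_strains
  res$sim <- sim
  if (!"normalize" %in% config$stages)
    return(invisible(finish_run(res, counts, out_dir, config)))

  # --- normalize ------------------------------------------------------------
  mats <- build_ratio_matrices(sim, trim_fraction = th$trim)
  mats$protein <- filter_min_coverage(mats$protein, th$min_coverage)
  mats$phospho_raw <- filter_min_coverage(mats$phospho_raw, th$min_coverage)
  mats$phospho_norm <- filter_min_coverage(mats$phospho_norm, th$min_coverage)
  write_ratio_matrix(mats$protein, file.path(out_dir, "ratios_protein.tsv"))
  write_ratio_matrix(mats$phospho_raw, file.path(out_dir, "ratios_phospho_raw.tsv"))
  write_ratio_matrix(mats$phospho_norm, file.path(out_dir, "ratios_phospho_norm.tsv"))
  say("normalize:", nrow(mats$protein$values), "proteins,",
      nrow(mats$phospho_norm$values), "phosphosites after coverage filter")
  counts$n_proteins_kept <- nrow(mats$protein$values)
  counts$n_phosphosites_kept <- nrow(mats$phospho_norm$values)
  res$matrices <- mats
  if (!"call" %in% config$stages)
    return(invisible(finish_run(res, counts, out_dir, config)))

  # --- call -----------------------------------------------------------------
  dm <- truth$deletion_map; s2p <- truth$site_to_protein
  calls_prot <- call_regulated_events(mats$protein, fc_floor = th$fc_floor_protein,
                                      sd_mult_both = th$sd_mult_both,
                                      sd_mult_single = th$sd_mult_single,
                                      deletion_map = dm)
  calls_raw <- call_regulated_events(mats$phospho_raw, fc_floor = th$fc_floor_phospho,
                                     sd_mult_both = th$sd_mult_both,
                                     sd_mult_single = th$sd_mult_single,
                                     deletion_map = dm, site_to_protein = s2p,
                                     level = "phospho_raw")
  calls_norm <- call_regulated_events(mats$phospho_norm, fc_floor = th$fc_floor_phospho,
                                      sd_mult_both = th$sd_mult_both,
                                      sd_mult_single = th$sd_mult_single,
                                      deletion_map = dm, site_to_protein = s2p,
                                      level = "phospho_normalized")
  attribution <- attribute_phospho_events(calls_raw, calls_norm)
  merged_prot <- merge_replicates(mats$protein)
  merged_norm <- merge_replicates(mats$phospho_norm)
  impact <- rbind(cbind(level = "protein", impact_factor(calls_prot, merged_prot)),
                  cbind(level = "phospho", impact_factor(calls_norm, merged_norm)))
  net_prot <- build_regulation_network(calls_prot)
  utils::write.table(calls_prot, file.path(out_dir, "calls_protein.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls_norm, file.path(out_dir, "calls_phospho.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(attribution, file.path(out_dir, "attribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(impact, file.path(out_dir, "impact_factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(net_prot$edges, file.path(out_dir, "regulation_protein.sif"), "sif")
  say("call:", nrow(calls_prot), "protein calls,", nrow(calls_norm),
      "phospho calls (normalized)")
  counts$n_protein_calls <- nrow(calls_prot)
  counts$n_phospho_calls <- nrow(calls_norm)
  res$calls <- list(protein = calls_prot, phospho_raw = calls_raw,
                    phospho_norm = calls_norm, attribution = attribution,
                    impact = impact, network = net_prot)
  res$merged <- list(protein = merged_prot, phospho_norm = merged_norm)
  if (!"gene_corr" %in% config$stages)
    return(invisible(finish_run(res, counts, out_dir, config)))

  # --- gene-gene correlation ------------------------------------------------
  gnet_prot <- build_gene_network(merged_prot, dm, th$fc_floor_protein,
                                  th$gene_r_min, th$gene_min_n)
  gnet_phos <- build_gene_network(merged_norm, dm, th$fc_floor_phospho,
                                  th$gene_r_min, th$gene_min_n,
                                  site_to_protein = s2p)
  write_network(gnet_prot$edges, file.path(out_dir, "gene_network_protein.tsv"))
  write_network(gnet_phos$edges, file.path(out_dir, "gene_network_phospho.tsv"))
  utils::write.table(gnet_prot$matrix[gnet_prot$order, gnet_prot$order],
                     file.path(out_dir, "gene_corr_matrix_protein.tsv"),
                     sep = "\t", quote = FALSE)
  say("gene_corr:", nrow(gnet_prot$edges), "protein edges,",
      nrow(gnet_phos$edges), "phospho edges")
  counts$n_gene_edges_protein <- nrow(gnet_prot$edges)
  counts$n_gene_edges_phospho <- nrow(gnet_phos$edges)
  res$gene_networks <- list(protein = gnet_prot, phospho = gnet_phos)
  if (!"covariance" %in% config$stages)
    return(invisible(finish_run(res, counts, out_dir, config)))

  # --- covariance -----------------------------------------------------------
  masked_prot <- mask_deleted(merged_prot, dm)
  masked_phos <- mask_deleted(merged_norm, dm, s2p)
  cov_prot <- molecule_pair_correlations(masked_prot, th$min_shared_fraction,
                                         th$cov_r_min, th$cov_p_adj_max)
  cov_phos <- molecule_pair_correlations(masked_phos, th$min_shared_fraction,
                                         th$cov_r_min, th$cov_p_adj_max)
  fpr <- permutation_false_positive_rate(masked_prot, n_perm = th$n_perm,
                                         min_shared_fraction = th$min_shared_fraction,
                                         r_min = th$cov_r_min,
                                         p_adj_max = th$cov_p_adj_max,
                                         seed = config$seed)
  write_network(cov_prot$edges, file.path(out_dir, "covariance_protein.tsv"))
  write_network(cov_phos$edges, file.path(out_dir, "covariance_phospho.tsv"))
  say("covariance:", nrow(cov_prot$edges), "protein edges,",
      nrow(cov_phos$edges), "phospho edges; permutation FPR",
      signif(fpr$rate_pct, 3), "%")
  counts$n_cov_edges_protein <- nrow(cov_prot$edges)
  counts$n_cov_edges_phospho <- nrow(cov_phos$edges)
  counts$permutation_fpr_pct <- fpr$rate_pct
  res$covariance <- list(protein = cov_prot, phospho = cov_phos, fpr = fpr)
  if (!"enrichment" %in% config$stages)
    return(invisible(finish_run(res, counts, out_dir, config)))

  # --- enrichment (synthetic module annotation) -------------------------------
  pm <- truth$modules[grepl("^PMOD", names(truth$modules))]
  if (length(pm)) {
    db <- annotation_db("synthetic_modules", "pathway", sets = pm)
    eff <- effector_enrichment(calls_prot, list(db), alpha = th$enrich_alpha)
    nbe <- neighbor_enrichment(cov_prot$edges, list(db), alpha = th$enrich_alpha)
    utils::write.table(eff, file.path(out_dir, "enrichment_effectors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nbe, file.path(out_dir, "enrichment_neighbors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("enrichment:", nrow(eff), "effector results,", nrow(nbe),
        "neighbor results")
    counts$n_effector_enrichments <- nrow(eff)
    res$enrichment <- list(effectors = eff, neighbors = nbe)
  }
  invisible(finish_run(res, counts, out_dir, config))
}

finish_run <- function(res, counts, out_dir, config) {
  manifest <- list(package = "kinodelta",
                   version = as.character(utils::packageVersion("kinodelta")),
                   seed = config$seed,
                   thresholds = config$thresholds,
                   stages = config$stages,
                   counts = counts)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$manifest <- manifest
  res
}
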