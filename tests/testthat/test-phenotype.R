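mk_ratio <- function(values, strains, reps) {
  ratio_matrix("protein", values,
               data.frame(strain = strains, replicate = reps,
                          stringsAsFactors = FALSE))
}

test_that("replicate merging averages available values and records support", {
  v <- matrix(c(0.4, 0.6,   # both present
                0.4, NA,    # single
                NA, NA),    # none
              3, 2, byrow = TRUE, dimnames = list(paste0("m", 1:3), NULL))
  rm <- mk_ratio(v, c("dA", "dA"), 1:2)
  mg <- merge_replicates(rm)
  expect_equal(unname(mg$values[, "dA"]), c(0.5, 0.4, NA))
  expect_equal(unname(mg$reps[, "dA"]), c(2L, 1L, 0L))
})

test_that("trimmed SD is robust, homogeneous, and zero on constants", {
  expect_equal(trimmed_sd(rep(2.5, 30)), 0)
  expect_true(is.na(trimmed_sd(c(1, 2))))
  set.seed(4)
  x <- stats::rnorm(20)
  spiked <- x; spiked[7] <- 50
  # one spike among 20: floor(0.05*20) = 1 trimmed per tail; within 20% of the
  # clean SD of the remaining values
  expect_lt(abs(trimmed_sd(spiked) - stats::sd(x[-7])) / stats::sd(x[-7]), 0.2)
  # homogeneity: scaling values scales the SD
  expect_equal(trimmed_sd(3 * x), 3 * trimmed_sd(x), tolerance = 1e-12)
  expect_equal(trimmed_sd(-2 * x), 2 * trimmed_sd(x), tolerance = 1e-12)
})

test_that("regulation calls follow the replicate SD and fold-change rules", {
  # 40 strains: 38 null columns with small jitter define the trimmed SD
  set.seed(5)
  n_str <- 40
  strains <- paste0("d", seq_len(n_str))
  v <- matrix(stats::rnorm(2 * 2 * n_str, 0, 0.1), 2, 2 * n_str,
              dimnames = list(c("mA", "mB"), NULL))
  rm <- mk_ratio(v, rep(strains, each = 2), rep(1:2, n_str))
  stats0 <- compute_trimmed_stats(merge_replicates(rm))
  sdA <- stats0$sd[stats0$molecule == "mA"]
  # both replicates above 3 SD, same sign, merged above the floor -> call up
  rm$values["mA", 1:2] <- c(3.5, 3.2) * sdA + 0.45
  calls <- call_regulated_events(rm, stats = stats0, fc_floor = 0.38)
  hit <- calls[calls$molecule == "mA" & calls$strain == "d1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$direction, "up")
  expect_equal(hit$support, "both")
  # opposite-sign excursions are irreproducibility, not regulation
  rm2 <- rm
  rm2$values["mA", 1:2] <- c(3.5, -3.5) * max(sdA, 0.2)
  calls2 <- call_regulated_events(rm2, stats = stats0, fc_floor = 0.38)
  expect_false(any(calls2$molecule == "mA" & calls2$strain == "d1"))
  # a single replicate needs 6 SD: probe with an extreme value to pin the
  # trimmed SD (the probe itself is trimmed out), then test around 6 SD
  rm3 <- rm
  rm3$values["mA", 1:2] <- c(1, NA)
  st3 <- compute_trimmed_stats(merge_replicates(rm3))
  thr6 <- 6 * st3$sd[st3$molecule == "mA"]
  rm3$values["mA", 1] <- max(0.9 * thr6, 0.38)
  st3b <- compute_trimmed_stats(merge_replicates(rm3))
  calls3 <- call_regulated_events(rm3, stats = st3b, fc_floor = 0.38)
  expect_false(any(calls3$molecule == "mA" & calls3$strain == "d1"))
  rm3$values["mA", 1] <- max(1.1 * thr6, 0.38)
  st3c <- compute_trimmed_stats(merge_replicates(rm3))
  calls4 <- call_regulated_events(rm3, stats = st3c, fc_floor = 0.38)
  hit4 <- calls4[calls4$molecule == "mA" & calls4$strain == "d1", ]
  expect_equal(nrow(hit4), 1)
  expect_equal(hit4$support, "single")
})

test_that("merged ratios below the fold-change floor are never called", {
  strains <- paste0("d", 1:30)
  set.seed(6)
  v <- matrix(stats::rnorm(2 * 60, 0, 0.02), 2, 60,
              dimnames = list(c("mA", "mB"), NULL))
  v["mA", 1:2] <- c(0.3, 0.3)   # far above 3 SD but merged 0.3 < 0.38
  rm <- mk_ratio(v, rep(strains, each = 2), rep(1:2, 30))
  calls <- call_regulated_events(rm, fc_floor = 0.38)
  expect_false(any(calls$molecule == "mA" & calls$strain == "d1"))
  calls_low <- call_regulated_events(rm, fc_floor = 0.25)
  expect_true(any(calls_low$molecule == "mA" & calls_low$strain == "d1"))
})

test_that("raising thresholds never adds calls (monotonicity)", {
  mats <- build_ratio_matrices(run_sim(tiny_cfg(noise_sd = 0.1)))
  rm <- filter_min_coverage(mats$protein)
  key <- function(d) paste(d$strain, d$molecule)
  base <- call_regulated_events(rm, fc_floor = 0.38)
  higher_floor <- call_regulated_events(rm, fc_floor = 0.6)
  expect_true(all(key(higher_floor) %in% key(base)))
  stricter_sd <- call_regulated_events(rm, fc_floor = 0.38,
                                       sd_mult_both = 5, sd_mult_single = 10)
  expect_true(all(key(stricter_sd) %in% key(base)))
})

test_that("the deleted gene's own product is logged, not called", {
  sim <- run_sim(tiny_cfg(noise_sd = 0.05))
  rm <- filter_min_coverage(build_ratio_matrices(sim)$protein)
  calls <- call_regulated_events(rm, deletion_map = sim$truth$deletion_map)
  conf <- attr(calls, "deletion_confirmations")
  # suppressed products are caught as strong down events in their own strain
  expect_gt(nrow(conf), 0)
  expect_true(all(conf$direction == "down"))
  expect_true(all(conf$molecule == unname(sim$truth$deletion_map[conf$strain])))
  # and never appear as effector calls
  expect_false(any(paste(calls$strain, calls$molecule) %in%
                     paste(names(sim$truth$deletion_map),
                           unname(sim$truth$deletion_map))))
})

test_that("attribution classes partition raw and normalized call sets", {
  raw <- data.frame(strain = c("d1", "d1", "d2"),
                    molecule = c("s1", "s2", "s3"),
                    stringsAsFactors = FALSE)
  nrm <- data.frame(strain = c("d1", "d2", "d2"),
                    molecule = c("s2", "s3", "s4"),
                    stringsAsFactors = FALSE)
  ev <- attribute_phospho_events(raw, nrm)
  cls <- stats::setNames(ev$attribution, paste(ev$strain, ev$molecule))
  expect_equal(unname(cls["d1 s1"]), "protein_driven")
  expect_equal(unname(cls["d1 s2"]), "phospho_driven")
  expect_equal(unname(cls["d2 s3"]), "phospho_driven")
  expect_equal(unname(cls["d2 s4"]), "newly_captured")
  sm <- attr(ev, "summary")
  expect_equal(sm$n_events, 4)
  expect_equal(sm$overall$protein_driven, 0.25)
})

test_that("noiseless attribution is error-free for every planted class", {
  # enough strains that the 5% trim drops the planted entries from each
  # profile, keeping per-molecule SDs (and hence call thresholds) small
  cfg <- noiseless_cfg(n_strains = 40L, n_proteins = 300L,
                       n_phosphosites = 400L, n_regulators = 3L,
                       phospho_targets_per_regulator = 10L,
                       targets_per_regulator = 0L,
                       n_assignment_groups = 5L, seed = 19)
  sim <- run_sim(cfg)
  mats <- build_ratio_matrices(sim)
  mkc <- function(m) call_regulated_events(
    filter_min_coverage(m), fc_floor = 0.5,
    deletion_map = sim$truth$deletion_map,
    site_to_protein = sim$truth$site_to_protein)
  ev <- attribute_phospho_events(mkc(mats$phospho_raw), mkc(mats$phospho_norm))
  cls <- stats::setNames(ev$attribution, paste(ev$strain, ev$molecule))
  att <- sim$truth$phospho_attribution
  att <- att[abs(att$effect) >= 0.5, ]
  expected <- c(protein_driven = "protein_driven",
                phospho_driven = "phospho_driven",
                compensated = "newly_captured")
  for (i in seq_len(nrow(att))) {
    got <- cls[paste(att$strain[i], att$phosphosite[i])]
    # sites on another regulator's targeted protein can legitimately pick up
    # additional protein-driven signal; restrict to cleanly planted cases
    if (!is.na(got))
      expect_equal(unname(got), unname(expected[att$class[i]]),
                   info = paste(att$strain[i], att$phosphosite[i], att$class[i]))
  }
  expect_gt(sum(!is.na(cls[paste(att$strain, att$phosphosite)])),
            0.9 * nrow(att))
})

test_that("impact factor is calls over quantified, per strain", {
  v <- matrix(stats::rnorm(500 * 2, 0, 0.05), 500, 2,
              dimnames = list(paste0("m", 1:500), NULL))
  merged <- ratio_matrix("protein", v,
                         data.frame(strain = c("dA", "dB"),
                                    replicate = NA_integer_))
  calls <- data.frame(strain = rep("dA", 5), molecule = paste0("m", 1:5))
  imp <- impact_factor(calls, merged)
  expect_equal(imp$impact_pct[imp$strain == "dA"], 1.0)
  expect_equal(imp$impact_pct[imp$strain == "dB"], 0)
})

test_that("regulation network conserves calls as edges", {
  calls <- data.frame(strain = c("d1", "d1", "d2"),
                      molecule = c("P1", "P2", "P1"),
                      direction = c("up", "down", "up"),
                      level = "protein", stringsAsFactors = FALSE)
  net <- build_regulation_network(calls)
  expect_equal(net$summary$n_edges, 3)
  expect_equal(net$summary$n_regulators, 2)
  expect_equal(net$summary$n_effectors, 2)
  expect_equal(net$summary$n_up, 2)
  expect_equal(net$summary$n_down, 1)
  empty <- build_regulation_network(calls[0, ])
  expect_equal(empty$summary$n_edges, 0)
})

test_that("planted effects are recalled with high sensitivity and precision", {
  cfg <- tiny_cfg(n_strains = 24L, n_proteins = 600, n_regulators = 4L,
                  noise_sd = 0.1, effect_grid = c(-1, -0.6, 0.6, 1),
                  n_assignment_groups = 4L, seed = 23)
  sim <- run_sim(cfg)
  rm <- filter_min_coverage(build_ratio_matrices(sim)$protein)
  calls <- call_regulated_events(rm, fc_floor = 0.38,
                                 deletion_map = sim$truth$deletion_map)
  met <- recovery_metrics(calls, sim$truth, "protein", min_abs_effect = 0.6)
  expect_gte(met$sensitivity, 0.9)
  expect_gte(met$precision, 0.9)
})
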