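mk_table <- function(mat, strains = NULL, level = "protein", plex = "plex01") {
  k <- ncol(mat)
  if (is.null(strains)) strains <- c("WT", paste0("d", LETTERS[seq_len(k - 1)]))
  plex_table(plex, level,
             data.frame(channel = paste0("ch", seq_len(k)), strain = strains,
                        replicate = 1L, is_bridge = strains == "WT",
                        stringsAsFactors = FALSE),
             mat)
}

test_that("isotopic impurity correction solves the mixing system", {
  m <- matrix(c(100, 200, 300, 80, 160, 240), 3, 2,
              dimnames = list(paste0("P", 1:3), NULL))
  tb <- mk_table(m)
  # identity matrix leaves the table unchanged
  out <- correct_isotopic_impurities(tb, diag(2))
  expect_equal(out$intensities, tb$intensities, ignore_attr = TRUE)
  # 10% spill from channel 1 into channel 2: observed (90, 110) -> (100, 100)
  M <- rbind(c(0.9, 0), c(0.1, 1))
  tb2 <- mk_table(matrix(c(90, 110), 1, 2, dimnames = list("P1", NULL)))
  out2 <- correct_isotopic_impurities(tb2, M)
  expect_equal(unname(out2$intensities[1, ]), c(100, 100), tolerance = 1e-12)
  # inverse consistency: re-mixing the solution recovers the observation
  remixed <- M %*% t(out2$intensities)
  expect_equal(as.numeric(remixed), c(90, 110), tolerance = 1e-12)
  # contract errors
  expect_error(correct_isotopic_impurities(tb2, rbind(c(1.2, 0), c(0.1, 1))),
               "sum")
  expect_error(correct_isotopic_impurities(tb2, matrix(0.5, 2, 2)), "singular")
})

test_that("peptide filter applies inclusive S/N and specificity thresholds", {
  # 5 peptides with hand-set values: 3 pass
  int <- matrix(c(1000, 999.5, 2000, 5000, 1500), 5, 1,
                dimnames = list(paste0("pep", 1:5), NULL))
  tb <- plex_table("p1", "peptide",
                   data.frame(channel = "ch1", strain = "WT", replicate = 1L,
                              is_bridge = TRUE), int)
  noise <- c(ch1 = 5)  # S/N sums: 200, 199.9, 400, 1000, 300
  spec <- c(pep1 = 0.5, pep2 = 0.9, pep3 = 0.49, pep4 = 0.8, pep5 = 0.6)
  out <- filter_peptides(tb, noise, spec)
  expect_setequal(rownames(out$intensities), c("pep1", "pep4", "pep5"))
  # boundary: S/N exactly 200 and specificity exactly 0.5 retained (pep1);
  # 199.9 removed (pep2 fails S/N); 0.49 removed (pep3 fails specificity)
  expect_error(filter_peptides(tb, NULL, spec), "noise")
  expect_error(filter_peptides(tb, noise, NULL), "specificity")
})

test_that("protein rollup sums unique peptides and drops shared ones", {
  int <- matrix(c(10, 5, 7, 3,
                  20, 5, 9, 4), 4, 2,
                dimnames = list(paste0("pep", 1:4), NULL))
  tb <- mk_table(int, level = "peptide")
  map <- data.frame(peptide = c("pep1", "pep2", "pep3", "pep3", "pep4"),
                    protein = c("P1", "P1", "P1", "P2", "P2"))
  out <- rollup_peptides_to_protein(tb, map)
  # pep3 maps to two proteins -> excluded from both
  expect_equal(unname(out$intensities["P1", ]), c(15, 25))
  expect_equal(unname(out$intensities["P2", ]), c(3, 4))
  # random toy set equals a brute-force group-by sum
  set.seed(8)
  int2 <- matrix(stats::runif(40, 1, 100), 10, 4,
                 dimnames = list(paste0("q", 1:10), NULL))
  tb2 <- mk_table(int2, strains = c("WT", "dA", "dB", "dC"), level = "peptide")
  map2 <- data.frame(peptide = paste0("q", 1:10),
                     protein = sample(c("X", "Y", "Z"), 10, replace = TRUE))
  out2 <- rollup_peptides_to_protein(tb2, map2)
  oracle <- rowsum(int2[map2$peptide, ], map2$protein)
  expect_equal(unclass(out2$intensities), unclass(oracle[rownames(out2$intensities), ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("loading equalization matches hand arithmetic and is scale invariant", {
  m <- matrix(c(40, 60, 120, 180), 2, 2, dimnames = list(c("P1", "P2"), NULL))
  tb <- mk_table(m)  # column sums 100 and 300
  eq <- equalize_loading(tb)
  expect_equal(unname(eq$factors), c(2.0, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(colSums(eq$table$intensities)), c(200, 200), tolerance = 1e-9)
  # already-equal columns give unit factors
  eq2 <- equalize_loading(mk_table(matrix(c(50, 50, 60, 40), 2, 2,
                                          dimnames = list(c("P1", "P2"), NULL))))
  expect_equal(unname(eq2$factors), c(1, 1))
  # global scaling leaves downstream ratios unchanged
  tb7 <- mk_table(7 * m)
  r1 <- bridge_log2_ratios(equalize_loading(tb)$table)
  r7 <- bridge_log2_ratios(equalize_loading(tb7)$table)
  expect_equal(r1$ratios, r7$ratios, tolerance = 1e-12)
  expect_error(equalize_loading(mk_table(matrix(c(0, 0, 1, 2), 2, 2,
                                                dimnames = list(c("P1", "P2"), NULL)))),
               "zero total")
})

test_that("protein-derived factors transfer to the phosphosite table", {
  ph <- mk_table(matrix(c(10, 20, 30, 40), 2, 2,
                        dimnames = list(c("S1", "S2"), NULL)),
                 level = "phosphosite")
  f <- c(ch1 = 2, ch2 = 1)
  out <- apply_loading_to_phospho(ph, f)
  expect_equal(unname(out$intensities[, 1]), c(20, 40))
  expect_equal(unname(out$intensities[, 2]), c(30, 40))
  # unit factors leave the table unchanged
  out1 <- apply_loading_to_phospho(ph, c(ch1 = 1, ch2 = 1))
  expect_equal(out1$intensities, ph$intensities)
  expect_error(apply_loading_to_phospho(ph, c(chX = 1, chY = 1)), "mismatch")
})

test_that("bridge ratios are log2 differences against the wild-type channel", {
  m <- matrix(c(100, 100, 100,   # bridge
                100, 200, 50,
                400, 100, 25), 3, 3,
              dimnames = list(paste0("P", 1:3), NULL))
  tb <- mk_table(m)
  rb <- bridge_log2_ratios(tb)
  expect_equal(unname(rb$ratios[, 1]), c(0, 1, -1), tolerance = 1e-12)
  expect_equal(unname(rb$ratios[, 2]), c(2, 0, log2(25 / 100)), tolerance = 1e-12)
  # zeros become missing, molecule missing in bridge blanks the row
  m2 <- m; m2[1, 2] <- 0; m2[2, 1] <- NA
  expect_message(rb2 <- bridge_log2_ratios(mk_table(m2)), "zero")
  expect_true(is.na(rb2$ratios[1, 1]))
  expect_true(all(is.na(rb2$ratios[2, ])))
})

test_that("trimmed-mean centering zeroes each column's trimmed mean", {
  set.seed(11)
  x <- c(stats::rnorm(19), 100)  # one wild outlier among 20 values
  mat <- matrix(x, 20, 1, dimnames = list(paste0("m", 1:20), NULL))
  out <- center_trimmed_mean(mat)
  # the outlier is excluded from the centering mean: recompute by hand
  k <- floor(0.05 * 20)
  hand <- mean(sort(x)[(k + 1):(20 - k)])
  expect_equal(out[, 1], mat[, 1] - hand, tolerance = 1e-12)
  # post-centering trimmed mean is 0
  v <- sort(out[, 1])
  expect_lt(abs(mean(v[(k + 1):(20 - k)])), 1e-9)
  # constant column collapses to zero
  expect_true(all(center_trimmed_mean(matrix(3.5, 25, 1)) == 0))
  # symmetric already-centered column unchanged
  sym <- matrix(seq(-1, 1, length.out = 21), 21, 1)
  expect_equal(center_trimmed_mean(sym), sym, tolerance = 1e-12)
})

test_that("plex joining unions molecules and rejects duplicate columns", {
  b1 <- list(plex_id = "p1", level = "protein",
             samples = data.frame(strain = "dA", replicate = 1L),
             ratios = matrix(1, 2, 1, dimnames = list(c("P1", "P2"), NULL)))
  b2 <- list(plex_id = "p2", level = "protein",
             samples = data.frame(strain = "dB", replicate = 1L),
             ratios = matrix(2, 2, 1, dimnames = list(c("P3", "P4"), NULL)))
  j <- join_plexes(list(b1, b2))
  expect_equal(dim(j$values), c(4, 2))
  expect_true(all(is.na(j$values[c("P3", "P4"), 1])))
  expect_true(all(is.na(j$values[c("P1", "P2"), 2])))
  # full overlap gives a dense matrix; counts follow set arithmetic
  b3 <- b2; b3$ratios <- matrix(3, 2, 1, dimnames = list(c("P1", "P2"), NULL))
  j2 <- join_plexes(list(b1, b3))
  expect_false(anyNA(j2$values))
  b4 <- b2; b4$ratios <- matrix(4, 2, 1, dimnames = list(c("P2", "P5"), NULL))
  j3 <- join_plexes(list(b1, b4))
  expect_equal(nrow(j3$values), length(union(c("P1", "P2"), c("P2", "P5"))))
  # duplicate (strain, replicate) columns are a design error
  expect_error(join_plexes(list(b1, b1)), "design error")
})

test_that("protein normalization subtracts cognate ratios and flags the rest", {
  samples <- data.frame(strain = c("dA", "dB"), replicate = 1L)
  prot <- ratio_matrix("protein",
                       matrix(c(-1.2, 1, 0, 0), 2, 2, byrow = TRUE,
                              dimnames = list(c("P1", "P2"), NULL)), samples)
  phos <- ratio_matrix("phosphosite",
                       matrix(c(-1.2, 0, 0, 0, 2, 2), 3, 2, byrow = TRUE,
                              dimnames = list(c("P1_pS10", "P1_pT20", "Q9_pS5"),
                                              NULL)), samples)
  s2p <- c(P1_pS10 = "P1", P1_pT20 = "P1", Q9_pS5 = "Q9")
  out <- normalize_phospho_by_protein(phos, prot, s2p)
  # raw -1.2 with protein -1.2 -> 0 (purely protein-driven pattern)
  expect_equal(unname(out$values["P1_pS10", 1]), 0)
  # raw 0 with protein +1 -> -1 (change unmasked by normalization)
  expect_equal(unname(out$values["P1_pT20", 2]), -1)
  # site without protein quantification passes through, flagged FALSE
  expect_equal(unname(out$values["Q9_pS5", ]), c(2, 2))
  expect_false(any(out$normalized["Q9_pS5", ]))
  expect_equal(attr(out, "normalized_fraction"), 4 / 6)
  # protein ratios of 0 leave values unchanged
  prot0 <- ratio_matrix("protein",
                        matrix(0, 2, 2, dimnames = list(c("P1", "Q9"), NULL)),
                        samples)
  out0 <- normalize_phospho_by_protein(phos, prot0, s2p)
  expect_equal(out0$values, phos$values)
  # involution partner: adding the protein matrix back restores the input
  restored <- out$values
  restored[out$normalized] <- restored[out$normalized] +
    prot$values[match(s2p[rownames(out$values)], rownames(prot$values)), ][out$normalized]
  expect_equal(restored, phos$values, tolerance = 1e-12)
})

test_that("coverage filter uses the ceiling of the strain fraction", {
  n_strains <- 110
  samples <- data.frame(strain = paste0("d", seq_len(n_strains)),
                        replicate = NA_integer_)
  v <- matrix(NA_real_, 3, n_strains,
              dimnames = list(c("all", "m54", "m55"), NULL))
  v["all", ] <- 1
  v["m54", 1:54] <- 1
  v["m55", 1:55] <- 1
  rm <- ratio_matrix("protein", v, samples)
  out <- filter_min_coverage(rm, 0.5)
  expect_setequal(rownames(out$values), c("all", "m55"))
  # empty matrix stays empty
  empty <- ratio_matrix("protein", v[0, , drop = FALSE], samples)
  expect_equal(nrow(filter_min_coverage(empty)$values), 0)
})

test_that("sample clustering pairs duplicated columns first", {
  set.seed(3)
  base <- stats::rnorm(60)
  v <- cbind(base, base, stats::rnorm(60), stats::rnorm(60))
  rownames(v) <- paste0("m", 1:60)
  rm <- ratio_matrix("protein", v,
                     data.frame(strain = c("dA", "dA", "dB", "dC"),
                                replicate = c(1L, 2L, 1L, 1L)))
  cl <- cluster_samples(rm)
  first_merge <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first_merge], c("dA::R1", "dA::R2"))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  # two columns produce a single merge
  rm2 <- ratio_matrix("protein", v[, 1:2],
                      data.frame(strain = "dA", replicate = 1:2))
  expect_equal(nrow(cluster_samples(rm2)$hclust$merge), 1)
})

test_that("replicates of every strain are mutual nearest neighbors on clean data", {
  cfg <- tiny_cfg(noise_sd = 0.01, missing_rate_plex = 0)
  mats <- build_ratio_matrices(run_sim(cfg))
  r <- stats::cor(mats$protein$values, use = "pairwise.complete.obs")
  d <- 1 - r; diag(d) <- Inf
  lab <- mats$protein$samples$strain
  for (j in seq_len(ncol(d))) {
    expect_equal(lab[which.min(d[, j])], lab[j])
  }
})

test_that("the full noiseless chain recovers planted effects exactly", {
  # planted entries per strain stay below the 5% trim tail at both levels, so
  # the trimmed column means see only the constant loading offset
  cfg <- noiseless_cfg(loading_cv = 0.15, n_phosphosites = 500L,
                       phospho_targets_per_regulator = 5L, seed = 77)
  sim <- run_sim(cfg)
  mats <- build_ratio_matrices(sim)
  merged <- merge_replicates(mats$protein)
  E <- sim$truth$protein_effects
  strains <- colnames(merged$values)
  for (st in strains) {
    mols <- rownames(merged$values)
    mols <- mols[mols != sim$truth$deletion_map[[st]]]
    got <- merged$values[mols, st]
    expect_equal(got, E[mols, st], tolerance = 1e-9)
  }
  # deletion suppression passes through exactly as well
  for (st in strains[1:3]) {
    expect_equal(unname(merged$values[sim$truth$deletion_map[[st]], st]),
                 cfg$suppression_log2, tolerance = 1e-9)
  }
  # compositionality: raw phospho ratio of a protein-driven site equals the
  # protein effect; the protein-normalized ratio is 0
  att <- sim$truth$phospho_attribution
  pd <- att[att$class == "protein_driven", ][1, ]
  raw <- merge_replicates(mats$phospho_raw)
  nrm <- merge_replicates(mats$phospho_norm)
  expect_equal(unname(raw$values[pd$phosphosite, pd$strain]), pd$effect,
               tolerance = 1e-9)
  expect_equal(unname(nrm$values[pd$phosphosite, pd$strain]), 0,
               tolerance = 1e-9)
})

test_that("equalized column sums agree to relative 1e-9 on simulated data", {
  sim <- run_sim(tiny_cfg(missing_rate_plex = 0))
  for (px in names(sim$protein)[1:2]) {
    eq <- equalize_loading(sim$protein[[px]])
    s <- colSums(eq$table$intensities)
    expect_lt(diff(range(s)) / mean(s), 1e-9)
  }
})
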