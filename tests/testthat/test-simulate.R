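# Synthetic-data generators: determinism, config validation, planted-truth
# behaviour of the cohort, expression and gene-set simulators.

test_that("generators are bit-identical under a fixed seed", {
  cfg <- morph_sim_config(3, 3, n_regions = 6, seed = 101)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$subjects[[1]]$features, c2$subjects[[1]]$features)
  expect_identical(c1$metadata, c2$metadata)

  ecfg <- expression_sim_config(n_genes = 20, n_regions = 8, n_donors = 3,
                                n_signal_pos = 2, seed = 5)
  tm <- sin(seq_len(8))
  e1 <- simulate_expression(ecfg, tm)
  e2 <- simulate_expression(ecfg, tm)
  expect_identical(e1$tables[[2]]$intensities, e2$tables[[2]]$intensities)

  gcfg <- geneset_sim_config(500, 40, 30, 2, seed = 9)
  expect_identical(simulate_genesets(gcfg), simulate_genesets(gcfg))
})

test_that("generator streams do not disturb the caller's RNG", {
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(simulate_genesets(geneset_sim_config(100, 10, 10)))
  expect_identical(rnorm(3), before)
})

test_that("invalid configurations are rejected", {
  expect_error(morph_sim_config(2, 2, n_regions = 2), "n_regions")
  expect_error(morph_sim_config(2, 2, n_features = 1), "n_features")
  expect_error(morph_sim_config(2, 2, noise_sd = 0), "noise_sd")
  expect_error(morph_sim_config(2, 2, effect_map = c(0, 0)), "effect_map")
  expect_error(expression_sim_config(10, n_signal_pos = 6, n_signal_neg = 6),
               "exceed")
  expect_error(expression_sim_config(10, alignment_strength = 1.2),
               "alignment_strength")
  expect_error(simulate_expression(expression_sim_config(5, n_regions = 8),
                                   rep(1, 3)), "length")
  expect_error(geneset_sim_config(100, 200, 10), "set_size")
  expect_error(geneset_sim_config(100, 10, 10, planted_odds_ratio = -1),
               "positive")
})

test_that("null cohorts give calibrated regional type-I error", {
  # effect-free cohorts; per-replicate rejection fractions are the MC units
  cfg0 <- morph_sim_config(20, 20, n_regions = 16, seed = 1)
  fracs <- vapply(1:25, function(r) {
    cfg <- morph_sim_config(20, 20, n_regions = 16, seed = 1000 + r)
    coh <- simulate_cohort(cfg)
    map <- fit_region_models(ms_pipeline(coh$subjects)$regional, coh$metadata)
    mean(map$p < 0.05)
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.05), 3 * max(se, 0.01))
})

test_that("a single large planted shift ranks first by |t| downstream", {
  eff <- rep(0, 16); eff[5] <- 0.06
  cfg <- morph_sim_config(80, 80, n_regions = 16, effect_map = eff, seed = 1)
  del <- calibrate_effect_deltas(cfg)
  hits <- vapply(1:15, function(r) {
    cfg_r <- morph_sim_config(80, 80, n_regions = 16, effect_map = eff,
                              seed = 3000 + r)
    coh <- simulate_cohort(cfg_r, deltas = del)
    map <- fit_region_models(ms_pipeline(coh$subjects)$regional, coh$metadata)
    which.max(abs(map$t_stat)) == 5
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("noiseless aligned expression correlates perfectly with the target", {
  tm <- sin(seq(0, 2 * pi, length.out = 10))
  cfg <- expression_sim_config(n_genes = 8, n_regions = 10, n_donors = 3,
                               n_signal_pos = 2, n_signal_neg = 2,
                               alignment_strength = 1, donor_noise_sd = 0,
                               seed = 7)
  sim <- simulate_expression(cfg, tm)
  tab <- sim$tables[[1]]
  asg <- assign_samples(tab, sim$region_points)
  prof <- morphosim:::aggregate_by_region(tab, asg)
  ord <- match(sim$region_points$region, rownames(prof))
  for (g in sim$truth$signal_pos) {
    expect_equal(cor(prof[ord, paste0("p_", g)], tm), 1, tolerance = 1e-12)
  }
  for (g in sim$truth$signal_neg) {
    expect_equal(cor(prof[ord, paste0("p_", g)], tm), -1, tolerance = 1e-12)
  }
})

test_that("identical donors give differential stability 1 for every probe", {
  tm <- cos(seq_len(12))
  cfg <- expression_sim_config(n_genes = 15, n_regions = 12, n_donors = 4,
                               n_signal_pos = 3, donor_noise_sd = 0, seed = 8)
  sim <- simulate_expression(cfg, tm)
  profs <- lapply(sim$tables, function(tab) {
    morphosim:::aggregate_by_region(tab, assign_samples(tab, sim$region_points))
  })
  ds <- differential_stability(profs)
  expect_equal(unname(ds), rep(1, 15))
})

test_that("signal-gene alignment strengthens with alignment_strength", {
  tm <- sin(seq(0, 2 * pi, length.out = 34))
  mean_abs_cor <- function(a) {
    cfg <- expression_sim_config(n_genes = 40, n_signal_pos = 20,
                                 alignment_strength = a, donor_noise_sd = 0.2,
                                 seed = 11)
    sim <- simulate_expression(cfg, tm)
    mean(abs(cor(tm, sim$truth$true_profiles[, sim$truth$signal_pos])))
  }
  expect_gt(mean_abs_cor(0.9), mean_abs_cor(0.3))
})

test_that("planted odds ratios are recovered across replicates", {
  ors <- vapply(1:150, function(r) {
    gs <- simulate_genesets(geneset_sim_config(2000, 150, 120,
                                               planted_odds_ratio = 5,
                                               seed = r))
    fisher_enrichment(gs$target_list, list(s = gs$gene_set),
                      gs$background)$odds_ratio
  }, numeric(1))
  expect_true(median(ors) >= 3 && median(ors) <= 8)
})

test_that("an empty gene set is flagged rather than tested", {
  gs <- simulate_genesets(geneset_sim_config(100, 0, 10, seed = 3))
  expect_length(gs$gene_set, 0)
  res <- fisher_enrichment(gs$target_list, list(empty = gs$gene_set),
                           gs$background)
  expect_true(is.na(res$odds_ratio))
  expect_equal(res$p, 1)
})
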