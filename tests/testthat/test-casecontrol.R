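# Case-control machinery: regional OLS, global comparison, aggregation,
# hub quadrants, cross-condition PCA and map correlations.

test_that("region models agree with lm and the normal-equation oracle", {
  coh <- toy_cohort(n_per_group = 5, n_regions = 4, seed = 13)
  pipe <- ms_pipeline(coh$subjects)
  map <- fit_region_models(pipe$regional, coh$metadata)
  for (j in seq_len(ncol(pipe$regional))) {
    oracle <- brute_ols_t(pipe$regional[, j], coh$metadata)
    expect_equal(map$t_stat[j], oracle$t, tolerance = 1e-10)
    expect_equal(map$p[j], oracle$p, tolerance = 1e-10)
    lmfit <- summary(lm(pipe$regional[, j] ~ I(coh$metadata$group == "case") +
                          age + sex + icv, data = coh$metadata))
    expect_equal(map$t_stat[j], lmfit$coefficients[2, "t value"],
                 tolerance = 1e-10)
  }
  expect_equal(map$cohen_d, map$t_stat * sqrt(1 / 5 + 1 / 5))
  expect_true(all(map$p_fdr >= map$p - 1e-15))
})

test_that("a response orthogonal to the group contrast has a null t", {
  coh <- toy_cohort(n_per_group = 10, n_regions = 3, seed = 17)
  meta <- coh$metadata
  set.seed(18)
  X <- cbind(1, as.numeric(meta$group == "case"), meta$age, meta$sex, meta$icv)
  e <- residuals(lm.fit(X, rnorm(nrow(meta))))  # orthogonal to the design
  y <- 2 + 0.1 * meta$age - 0.5 * meta$sex + 1e-6 * meta$icv + e
  map <- fit_region_models(cbind(r1 = y, r2 = y, r3 = y), meta)
  expect_true(all(abs(map$t_stat) < 1e-8))
})

test_that("rank-deficient designs fail loudly", {
  coh <- toy_cohort(n_per_group = 5, n_regions = 3, seed = 19)
  meta <- coh$metadata
  meta$icv <- meta$age  # collinear
  pipe <- ms_pipeline(coh$subjects)
  expect_error(fit_region_models(pipe$regional, meta), "collinear")
})

test_that("global comparison equals the region machinery on the 1-vector", {
  coh <- toy_cohort(n_per_group = 8, n_regions = 6, seed = 23)
  pipe <- ms_pipeline(coh$subjects)
  g <- global_comparison(pipe$global, coh$metadata)
  map1 <- fit_region_models(matrix(pipe$global, ncol = 1,
                                   dimnames = list(names(pipe$global), "g")),
                            coh$metadata)
  expect_equal(g$t_stat, map1$t_stat[1], tolerance = 1e-12)
  expect_equal(g$p, map1$p[1], tolerance = 1e-12)
})

test_that("a planted global MS shift is detected by the global comparison", {
  cfg <- morph_sim_config(60, 60, n_regions = 30,
                          effect_map = rep(0.012, 30), seed = 31)
  coh <- simulate_cohort(cfg)
  pipe <- ms_pipeline(coh$subjects)
  g <- global_comparison(pipe$global, coh$metadata)
  expect_gt(g$t_stat, 2)
  expect_lt(g$p, 0.05)
})

test_that("excluding either copy of a duplicated feature gives the same map", {
  coh <- toy_cohort(n_per_group = 6, n_regions = 8, n_features = 5, seed = 37)
  dup <- lapply(coh$subjects, function(s) {
    f <- cbind(s$features, f1_copy = s$features[, "f1"])
    toy_subject(s$subject_id, f, s$group, s$age, s$sex, s$icv)
  })
  lofo <- leave_one_feature_out(dup, coh$metadata)
  expect_equal(lofo$maps[["f1"]]$t_stat, lofo$maps[["f1_copy"]]$t_stat,
               tolerance = 1e-12)
  # self-correlation of the full map is exactly 1
  expect_equal(cor(lofo$full$t_stat, lofo$full$t_stat, method = "spearman"), 1)
})

test_that("the feature carrying a planted effect is flagged by leave-one-out", {
  coh <- toy_cohort(n_per_group = 30, n_regions = 12, n_features = 4,
                    seed = 41)
  set.seed(42)
  pattern <- rnorm(12, sd = 2)
  planted <- lapply(coh$subjects, function(s) {
    f <- s$features
    if (s$group == "case") f[, "f2"] <- f[, "f2"] + pattern
    toy_subject(s$subject_id, f, s$group, s$age, s$sex, s$icv)
  })
  lofo <- leave_one_feature_out(planted, coh$metadata)
  expect_equal(lofo$most_influential, "f2")
  expect_equal(names(which.min(lofo$rho)), "f2")
})

test_that("class aggregation degenerates to global MS for a single class", {
  coh <- toy_cohort(n_per_group = 6, n_regions = 6, seed = 43)
  pipe <- ms_pipeline(coh$subjects)
  one_class <- data.frame(region = colnames(pipe$regional), class = "all")
  agg <- aggregate_von_economo(pipe$regional, coh$metadata, one_class)
  g <- global_comparison(pipe$global, coh$metadata)
  expect_equal(agg$t_stat[1], g$t_stat, tolerance = 1e-12)
})

test_that("class statistics are invariant under class relabelling", {
  coh <- toy_cohort(n_per_group = 6, n_regions = 6, seed = 47)
  pipe <- ms_pipeline(coh$subjects)
  cmap <- data.frame(region = colnames(pipe$regional),
                     class = rep(c("a", "b", "c"), 2))
  agg1 <- aggregate_von_economo(pipe$regional, coh$metadata, cmap)
  cmap2 <- cmap
  cmap2$class <- c(a = "x", b = "y", c = "z")[cmap$class]
  agg2 <- aggregate_von_economo(pipe$regional, coh$metadata, cmap2)
  expect_equal(sort(agg1$t_stat), sort(agg2$t_stat), tolerance = 1e-12)
})

test_that("unmapped regions are a hard error", {
  coh <- toy_cohort(n_per_group = 4, n_regions = 4, seed = 53)
  pipe <- ms_pipeline(coh$subjects)
  cmap <- data.frame(region = colnames(pipe$regional)[-1], class = "a")
  expect_error(aggregate_von_economo(pipe$regional, coh$metadata, cmap),
               "region_1")
})

test_that("hub susceptibility quadrants match a hand tally and sum to 100", {
  ctrl <- c(-1, 2, -3, 4, -0.5, 1)
  delta <- c(0.2, 0.1, -0.2, -0.1, -0.3, 0.4)
  hs <- hub_susceptibility(setNames(delta, paste0("r", 1:6)), ctrl)
  expect_equal(unname(hs$quadrants$label),
               c("dedifferentiation", "hypercoupling", "hyperdifferentiation",
                 "decoupling", "hyperdifferentiation", "hypercoupling"))
  expect_equal(sum(hs$percentages), 100)
  # perfect anti-alignment: rho = -1, only dedifferentiation + decoupling
  hs2 <- hub_susceptibility(-ctrl, ctrl)
  expect_equal(hs2$rho, -1)
  expect_setequal(unique(hs2$quadrants$label),
                  c("dedifferentiation", "decoupling"))
  # labels depend only on signs, so positive rescaling changes nothing
  hs3 <- hub_susceptibility(delta * 7, ctrl * 0.1)
  expect_equal(hs3$quadrants$label, hs$quadrants$label)
  expect_error(hub_susceptibility(rep(0, 6), ctrl), "constant")
})

test_that("cross-condition PCA has correlation-matrix structure", {
  set.seed(59)
  base <- rnorm(68)
  # three identical maps: PC1 carries everything
  pc <- cross_condition_pca(cbind(a = base, b = base, c = base))
  expect_equal(pc$explained_variance_pct[1], 100)
  expect_equal(pc$eigenvalues[1], 3, tolerance = 1e-12)
  # long uncorrelated maps: roughly equal shares
  long <- matrix(rnorm(3000 * 3), 3000)
  pc2 <- cross_condition_pca(long)
  expect_true(all(abs(pc2$explained_variance_pct - 100 / 3) < 5))
  expect_equal(sum(pc2$explained_variance_pct), 100)
  expect_equal(sum(pc2$eigenvalues), 3, tolerance = 1e-12)
  # sign convention: PC1 scores align positively with the mean map
  zm <- cbind(base + rnorm(68, sd = 0.3), base + rnorm(68, sd = 0.3),
              base + rnorm(68, sd = 0.3))
  pc3 <- cross_condition_pca(zm)
  expect_gt(cor(pc3$pc_scores, rowMeans(scale(zm))), 0)
  expect_error(cross_condition_pca(cbind(base, rep(1, 68))), "constant")
})

test_that("map correlation matches a brute-force rank correlation", {
  set.seed(61)
  a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(correlate_maps(a, b)$rho, brute_spearman(a, b),
               tolerance = 1e-12)
  expect_equal(correlate_maps(a, a)$rho, 1)
  expect_equal(correlate_maps(a, -a)$rho, -1)
  expect_error(correlate_maps(a, rep(2, 30)), "constant")
})

test_that("BH adjustment is monotone and fixes equal p-values", {
  coh <- toy_cohort(n_per_group = 8, n_regions = 10, seed = 67)
  pipe <- ms_pipeline(coh$subjects)
  map <- fit_region_models(pipe$regional, coh$metadata)
  ord <- order(map$p)
  expect_true(all(diff(map$p_fdr[ord]) >= -1e-15))
  expect_equal(p.adjust(rep(0.2, 10), "BH"), rep(0.2, 10))
})
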