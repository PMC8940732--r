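#!/usr/bin/env Rscript

# Step 3: the cross-condition pattern.
#
# Correlates the three pain-like change maps with each other and with the
# depression-like map (spin-test p-values throughout), extracts the shared
# remodelling component by correlation-matrix PCA of the condition z-maps,
# and quantifies hub susceptibility per condition with its sign-quadrant
# decomposition.  Outputs: results/pc1_scores.csv, results/hub_summary.csv,
# results/map_correlations.csv.

library(morphosim)

pain <- c("oa_like", "clbp_like", "fm_like")
all_cohorts <- c(pain, "mdd_like")
maps <- lapply(all_cohorts, function(nm) {
  read.csv(file.path("results/maps", paste0(nm, "_map.csv")))
})
names(maps) <- all_cohorts

geo <- read_parcel_geometry()
stopifnot(identical(maps[[1]]$region, geo$region))
spins <- generate_spins(geo, 10000, seed = 73)

# pairwise map correlations with spatial-null inference
pairs <- t(combn(all_cohorts, 2))
cors <- apply(pairs, 1, function(pr) {
  sp <- spin_p(maps[[pr[1]]]$z_stat, maps[[pr[2]]]$z_stat, spins)
  c(rho = sp$rho, p_spin = sp$p_spin)
})
map_cor <- data.frame(a = pairs[, 1], b = pairs[, 2], t(cors))
write.csv(map_cor, "results/map_correlations.csv", row.names = FALSE)
print(map_cor, digits = 3)

# shared component across the pain-like conditions
zmat <- vapply(maps[pain], function(m) m$z_stat, numeric(68))
rownames(zmat) <- maps[[1]]$region
pca <- cross_condition_pca(zmat)
message(sprintf("PC1 explains %.2f%% (eigenvalue %.2f); PC2 %.2f%%; PC3 %.2f%%",
                pca$explained_variance_pct[1], pca$eigenvalues[1],
                pca$explained_variance_pct[2], pca$explained_variance_pct[3]))
write.csv(data.frame(region = rownames(zmat), pc1 = pca$pc_scores),
          "results/pc1_scores.csv", row.names = FALSE)

# hub susceptibility: change vs healthy-control hubness
hub_rows <- lapply(pain, function(nm) {
  ctrl <- read.csv(file.path("results/maps", paste0(nm, "_control_ms.csv")))
  hs <- hub_susceptibility(setNames(maps[[nm]]$cohen_d, maps[[nm]]$region),
                           ctrl$control_ms)
  sp <- spin_p(maps[[nm]]$cohen_d, ctrl$control_ms, spins)
  data.frame(cohort = nm, rho = hs$rho, p_spin = sp$p_spin,
             t(hs$percentages))
})
hub <- do.call(rbind, hub_rows)
write.csv(hub, "results/hub_summary.csv", row.names = FALSE)
print(hub, digits = 3)
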