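#!/usr/bin/env Rscript

# Step 5: gene-set enrichment of the PLS1 gene lists.
#
# Builds omnibus "cell-type" sets from simulated study lists enriched (or
# not) in the planted PLS1 genes, plus a pain-like panel with a planted
# odds ratio, then tests PLS1+ and PLS1- with Fisher's exact test
# (one-sided, BH-corrected per panel).  Outputs under results/enrichment/.

library(morphosim)

dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
seed <- 20260927L

gene_tab <- read.csv("results/pls/gene_table.csv")
background <- gene_tab$gene
pls1_plus <- readLines("results/pls/pls1_plus.txt")
pls1_minus <- readLines("results/pls/pls1_minus.txt")
planted_pos <- gene_tab$gene[gene_tab$planted == "pos"]
planted_neg <- gene_tab$gene[gene_tab$planted == "neg"]

set.seed(seed)
# Three "study" lists per cell type; glia-like types draw heavily from the
# positively planted genes, neuron-like types from the negative ones, and a
# control type from the null pool -- so the panel has known structure.
draw_set <- function(pool, n_pool, n_rand) {
  unique(c(sample(pool, n_pool), sample(background, n_rand)))
}
study_sets <- list(
  microglia_like = lapply(1:3, function(i) draw_set(planted_pos, 40, 60)),
  astrocyte_like = lapply(1:3, function(i) draw_set(planted_pos, 30, 70)),
  neuron_like    = lapply(1:3, function(i) draw_set(planted_neg, 40, 60)),
  unrelated      = lapply(1:3, function(i) sample(background, 100)))
celltypes <- build_omnibus_celltype_sets(study_sets, background)
write_gmt(celltypes$sets, "results/enrichment/celltypes.gmt")

# pain-like panel: one set enriched in PLS1+ by construction, one null
pain_sets <- list(
  pain_like = unique(c(sample(planted_pos, 50), sample(background, 250))),
  disorder_null = sample(background, 300))
panels <- list(celltypes = celltypes,
               pain = list(sets = pain_sets, background = background))

res <- run_enrichment_panels(list(pls1_plus = pls1_plus,
                                  pls1_minus = pls1_minus), panels)
for (panel in names(res)) {
  for (lst in names(res[[panel]])) {
    tab <- res[[panel]][[lst]]
    write.csv(tab, sprintf("results/enrichment/%s_%s.csv", panel, lst),
              row.names = FALSE)
    message(sprintf("-- %s / %s --", panel, lst))
    print(tab[, c("set", "overlap", "odds_ratio", "p", "p_fdr")], digits = 3)
  }
}
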