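#!/usr/bin/env Rscript
# Imaging-transcriptomics arm: rank-1 PLS of the 66 gene-expression maps
# against the left-hemisphere case-control t-map, with 10,000 response
# permutations, 10,000 region bootstraps for gene Z-scores, and the
# spin-anchored spatial correlation of PLS1 scores with the t-map.

suppressPackageStartupMessages(library(msntools))
dir.create("results/pls", recursive = TRUE, showWarnings = FALSE)
seed <- 20231005

parc <- read_parcellation("results/data/parcellation.tsv")
expr <- read_expression("results/data/expression.tsv")
table <- read_morphometry("results/data/morphometry.tsv",
                          "results/data/subjects.tsv")
stat_map <- fit_regional_contrast(cohort_strengths(table), table$subjects)

left <- parc$hemisphere == "L"
y <- setNames(stat_map$t[left], stat_map$region_id[left])
ensL <- make_spin_ensemble(parc, 10000, seed = stage_seed(seed, "spin_left"),
                           "left")

res <- pls1_analysis(expr, y, n_perm = 10000, n_boot = 10000,
                     seed = stage_seed(seed, "pls"), ensemble = ensL)
print(res)
cat("PLS1+ genes:", paste(res$sig_pos, collapse = ", "), "\n")
cat("PLS1- genes:", paste(res$sig_neg, collapse = ", "), "\n")
cat("planted genes and their |Z| ranks:\n")
print(rank(-abs(res$boot_z))[1:6])

write_stat_map(res$gene_table, "results/pls/gene_table.tsv")
jsonlite::write_json(
  list(varexp = res$varexp, p_perm = res$p_perm, r_spatial = res$r_spatial,
       p_spin_spatial = res$p_spin_spatial,
       sig_pos = res$sig_pos, sig_neg = res$sig_neg),
  "results/pls/summary.json", auto_unbox = TRUE, digits = NA)
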