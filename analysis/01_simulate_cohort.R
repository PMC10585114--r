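#!/usr/bin/env Rscript
# Build the synthetic study: a 308-region parcellation (152 left), a 24 + 24
# cohort with a decorrelating effect planted at 20 strength hubs, and 66
# spatially autocorrelated gene-expression maps of which 6 are planted
# against the expected contrast direction. Tables go to results/data/.

suppressPackageStartupMessages(library(msntools))
seed <- 20231005
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

parc <- make_parcellation(308, 152, seed = stage_seed(seed, "parcellation"))
write_parcellation(parc, "results/data/parcellation.tsv")

null_run <- simulate_morphometry(parc, 24, NULL, 0,
                                 seed = stage_seed(seed, "morphometry"))
eff <- hub_effect_map(null_run$table, n_affected = 20)
writeLines(as.character(eff$affected_regions), "results/data/affected_regions.txt")

sim <- simulate_morphometry(parc, 24, eff$effect_map, effect_scale = 1.5,
                            covariate_model = list(tiv = TRUE),
                            seed = stage_seed(seed, "morphometry"))
write_morphometry(sim$table, "results/data/morphometry.tsv",
                  "results/data/subjects.tsv")

expr <- simulate_expression(parc, 66, autocorr_length = 0.5,
                            effect_map = eff$association_map,
                            planted_pos = 0:2, planted_neg = 3:5,
                            association_strength = 0.7,
                            seed = stage_seed(seed, "expression"))
write_expression(expr, "results/data/expression.tsv")

cat(sprintf("cohort: %d subjects x %d regions; %d affected hub regions\n",
            nrow(sim$table$subjects), nrow(parc),
            length(eff$affected_regions)))
cat(sprintf("expression: %d left regions x %d genes (planted: %s)\n",
            nrow(expr), ncol(expr),
            paste(colnames(expr)[1:6], collapse = ", ")))
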