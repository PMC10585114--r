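#!/usr/bin/env Rscript
# Case-control inference: global strength comparison, per-region
# covariate-adjusted contrasts with BH-FDR, Yeo-7 / von Economo network
# aggregation, the TIV replication (Jaccard overlap of flags), the
# cortical-thickness contrast, and attendance correlations in users.

suppressPackageStartupMessages(library(msntools))
dir.create("results/contrasts", recursive = TRUE, showWarnings = FALSE)

parc <- read_parcellation("results/data/parcellation.tsv")
table <- read_morphometry("results/data/morphometry.tsv",
                          "results/data/subjects.tsv")
strengths <- cohort_strengths(table)
subjects <- table$subjects

global <- compare_global_ms(strengths, subjects)
cat(sprintf("global strength: t = %.2f (p = %.2g), KS D = %.3f (p = %.2g)\n",
            global$t, global$p_t, global$ks_statistic, global$p_ks))

stat_map <- fit_regional_contrast(strengths, subjects)
write_stat_map(stat_map, "results/contrasts/regional_ms.tsv")
truth <- readLines("results/data/affected_regions.txt")
flagged <- stat_map$region_id[stat_map$significant]
cat(sprintf("regional: %d FDR-flagged regions; %d/%d planted recovered\n",
            length(flagged), sum(truth %in% flagged), length(truth)))

stat_tiv <- fit_regional_contrast(strengths, subjects,
                                  extra_covariates = "tiv")
write_stat_map(stat_tiv, "results/contrasts/regional_ms_tiv.tsv")
cat(sprintf("TIV replication: Jaccard = %.2f, t-map r = %.3f\n",
            jaccard_flags(stat_map$significant, stat_tiv$significant),
            cor(stat_map$t, stat_tiv$t)))

ct <- feature_matrix(table, "CT")
ct_map <- fit_regional_contrast(ct, subjects, response = "ct")
write_stat_map(ct_map, "results/contrasts/regional_ct.tsv")
cat(sprintf("CT contrast: %d flagged regions; r(CT t, MS t) = %.3f\n",
            sum(ct_map$significant), cor(ct_map$t, stat_map$t)))

for (atlas in c("yeo7", "von_economo")) {
  net <- network_contrast(strengths, subjects, parc, atlas)
  write_stat_map(net, sprintf("results/contrasts/network_%s.tsv", atlas))
  hit <- net$label[net$significant]
  cat(sprintf("%s: significant labels: %s\n", atlas,
              if (length(hit)) paste(hit, collapse = ", ") else "none"))
}

freq <- frequency_correlation(strengths, subjects, stat_map)
write_stat_map(freq, "results/contrasts/attendance_spearman.tsv")
print(freq)

jsonlite::write_json(global, "results/contrasts/global_tests.json",
                     auto_unbox = TRUE, digits = NA)
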