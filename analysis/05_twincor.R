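#!/usr/bin/env Rscript
# The core twin statistics: per-CpG mean/SD and methylation classes, the
# two Spearman schemes (per-pair profiles across CpGs; per-CpG correlations
# across pairs), the unrelated-pair baseline, the stratified summary table,
# and the imprinted-DMR subset.

library(twinmeth)

ds <- read_fixture_bundle("results/fixture")
dir.create("results/twincor", showWarnings = FALSE, recursive = TRUE)

detp <- detection_pvalue(ds$signal, ds$negcontrols)
filt <- filter_probes(ds$signal, ds$manifest, detp)
adj <- quantile_normalize(filt$signal, ds$manifest)
beta <- bmiq_adjust(beta_matrix(adj), ds$manifest)
ann <- annotate_cpgs(ds$manifest[ds$manifest$probe_id %in% rownames(beta), ],
                     ds$genes, ds$tracks)

st <- cpg_stats(beta, ds$samples)
rho <- cross_pair_rho(beta, ds$samples)
var_ids <- st[most_variable == TRUE, probe_id]
cat(sprintf("%d CpGs analyzed; %d (%.1f%%) are most-variable (SD >= 0.05)\n",
            nrow(st), length(var_ids), 100 * length(var_ids) / nrow(st)))
cat(sprintf("methylation classes: %.1f%% hypo, %.1f%% intermediate, %.1f%% hyper\n",
            100 * mean(st$meth_class == "hypo", na.rm = TRUE),
            100 * mean(st$meth_class == "intermediate", na.rm = TRUE),
            100 * mean(st$meth_class == "hyper", na.rm = TRUE)))

prof_all <- pairwise_profile_rho(beta, ds$samples)
prof_var <- pairwise_profile_rho(beta, ds$samples, var_ids)
unrel_all <- unrelated_profile_rho(beta, ds$samples)
unrel_var <- unrelated_profile_rho(beta, ds$samples, var_ids)
cat(sprintf("\nPer-pair profile rho, all CpGs:      %.3f-%.3f (mean %.3f)\n",
            min(prof_all$rho), max(prof_all$rho), mean(prof_all$rho)))
cat(sprintf("Per-pair profile rho, variable CpGs: %.3f-%.3f (mean %.3f)\n",
            min(prof_var$rho), max(prof_var$rho), mean(prof_var$rho)))
cat(sprintf("Unrelated baseline (variable CpGs):  %.3f-%.3f (mean %.3f)\n",
            unrel_var$min, unrel_var$max, unrel_var$mean))

summ <- region_summaries(st, ann, rho = rho, variable_only = TRUE)
cat("\nStratified per-CpG twin correlations (most variable CpGs):\n")
print(summ[summ$axis %in% c("all", "cgi_class")])
imp <- imprinted_subset_summary(st, ann, rho = rho)
cat("\nImprinted-DMR CpGs at intermediate methylation:\n")
print(imp)

data.table::fwrite(st, "results/twincor/cpg_stats.tsv", sep = "\t")
data.table::fwrite(rho, "results/twincor/cross_pair_rho.tsv", sep = "\t")
data.table::fwrite(merge(prof_all, prof_var, by = "pair_id",
                         suffixes = c("_all", "_variable")),
                   "results/twincor/pair_profile_rho.tsv", sep = "\t")
data.table::fwrite(unrel_var$correlations,
                   "results/twincor/unrelated_profile_rho.tsv", sep = "\t")
data.table::fwrite(summ, "results/twincor/region_summaries.tsv", sep = "\t")
data.table::fwrite(imp, "results/twincor/imprinted_summary.tsv", sep = "\t")
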