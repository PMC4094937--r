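#!/usr/bin/env Rscript
# Sample- and probe-level quality control of the simulated study:
# negative-control detection p-values, overall signal checks, the ordered
# probe filters (ambiguous mapping, SNP at CpG, zero intensity, detection,
# bead count, success rate), and the complete-linkage sample dendrogram.

library(twinmeth)

ds <- read_fixture_bundle("results/fixture")
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

chk <- sample_signal_check(ds$signal, ds$negcontrols)
data.table::fwrite(chk, "results/qc/sample_signal_check.tsv", sep = "\t")
cat("Sample signal check: ", sum(chk$pass), "/", nrow(chk), " samples pass\n", sep = "")

detp <- detection_pvalue(ds$signal, ds$negcontrols)
filt <- filter_probes(ds$signal, ds$manifest, detp)
print(filt$report)
data.table::fwrite(filt$report$stages, "results/qc/probe_stages.tsv", sep = "\t")
data.table::fwrite(filt$report$sample_success, "results/qc/sample_success.tsv",
                   sep = "\t")

# cluster check on quantile-normalized beta (the probe subset uses SD > 0.10)
adj <- quantile_normalize(filt$signal, ds$manifest)
beta <- beta_matrix(adj)
cl <- sample_cluster_qc(beta, ds$manifest, ds$samples)
write_dendrogram_newick(cl$hclust, "results/qc/dendrogram.nwk")
data.table::fwrite(cl$first_merge, "results/qc/cluster_first_merge.tsv", sep = "\t")
cat(sprintf("\nClustering used %d probes; first-merge partner is the co-twin/replicate for %d/%d samples\n",
            cl$n_probes_used, sum(cl$first_merge$co_twin_first),
            nrow(cl$first_merge)))
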