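#' Familial-correlation parameter recovery experiment
#'
#' Simulates the four-island-class design of [recovery_sim_config()], runs
#' the measurement pipeline (detection p-values, probe filtering, channel
#' quantile normalization, beta computation), and compares the per-stratum
#' mean cross-pair Spearman correlation over the most variable CpGs with the
#' generating targets. The correlation is measured on the quantile-normalized
#' beta values; BMIQ is a within-sample map and is not part of the
#' between-sample correlation contract.
#'
#' @param seed integer seed for the generator.
#' @param n_pairs twin pairs (default 10).
#' @param n_cpgs CpGs per stratum (default 3500, sized so that at least
#'   2000 pass the variability filter per stratum).
#' @param sd_min variability cutoff (default 0.05).
#' @return list: `per_stratum` (data.table: stratum, cgi_class, target,
#'   n_variable, mean_rho, error), `dataset`, `stats`, `rho`.
#' @export
recovery_experiment <- function(seed = 1L, n_pairs = 10L, n_cpgs = 3500L,
                                sd_min = 0.05) {
  ds <- simulate_dataset(recovery_sim_config(n_pairs = n_pairs,
                                             n_cpgs = n_cpgs, seed = seed))
  detp <- detection_pvalue(ds$signal, ds$negcontrols)
  filt <- filter_probes(ds$signal, ds$manifest, detp)
  adj <- quantile_normalize(filt$signal, ds$manifest)
  beta <- beta_matrix(adj)
  st <- cpg_stats(beta, ds$samples, sd_min = sd_min)
  rho <- cross_pair_rho(beta, ds$samples)
  d <- merge(merge(st, rho, by = "probe_id"),
             ds$truth$cpg[, c("probe_id", "stratum")], by = "probe_id")
  d <- d[d$most_variable %in% TRUE & !is.na(d$rho)]
  per <- d[, list(n_variable = .N, mean_rho = mean(rho)), by = "stratum"]
  key <- ds$truth$strata[, c("stratum", "cgi_class", "target_spearman")]
  per <- merge(per, key, by = "stratum")
  per$error <- per$mean_rho - per$target_spearman
  per <- per[order(-per$target_spearman)]
  list(per_stratum = per[, c("stratum", "cgi_class", "target_spearman",
                             "n_variable", "mean_rho", "error")],
       dataset = ds, stats = st, rho = rho)
}
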