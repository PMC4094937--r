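#' Pipeline configuration
#'
#' Bundles every stage's inputs and thresholds. One global seed fans out to
#' per-stage child seeds so stages can be rerun in isolation reproducibly
#' (only the simulation stage consumes randomness).
#'
#' @param outdir output directory for all artifacts.
#' @param sim a [sim_config()] (used when `input_dir` is NULL).
#' @param input_dir optional fixture-bundle directory to analyse instead of
#'   simulating.
#' @param qc a [qc_thresholds()].
#' @param sd_min,hypo_max,hyper_min,min_pairs analysis thresholds passed to
#'   [cpg_stats()] and [cross_pair_rho()].
#' @param mixing_w_min threshold for [cell_composition_check()] (used only
#'   when a reference is supplied to [run_pipeline()]).
#' @param bmiq apply [bmiq_adjust()] (default TRUE).
#' @param m_offset offset for [compute_mvalue()].
#' @param seed global seed.
#' @param stages subset of the ordered stages to run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, sim = sim_config(), input_dir = NULL,
                            qc = qc_thresholds(), sd_min = 0.05,
                            hypo_max = 0.3, hyper_min = 0.7, min_pairs = 3L,
                            mixing_w_min = 0.8, bmiq = TRUE, m_offset = 1,
                            seed = 1L,
                            stages = c("simulate", "qc", "normalize",
                                       "annotate", "correlate", "report")) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(inherits(sim, "sim_config"), inherits(qc, "qc_thresholds"),
            sd_min >= 0, hypo_max < hyper_min, min_pairs >= 3)
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  structure(list(outdir = outdir, sim = sim, input_dir = input_dir, qc = qc,
                 sd_min = sd_min, hypo_max = hypo_max, hyper_min = hyper_min,
                 min_pairs = as.integer(min_pairs),
                 mixing_w_min = mixing_w_min, bmiq = isTRUE(bmiq),
                 m_offset = m_offset, seed = as.integer(seed),
                 stages = stages),
            class = "pipeline_config")
}

derive_seeds <- function(seed, n = 6L) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run the full twin-methylation workflow
#'
#' Executes simulate (or load) -> qc -> normalize -> annotate -> correlate
#' -> report, each stage reading only prior-stage results, and writes every
#' table under `config$outdir` together with a run manifest recording the
#' package version, seed and md5 digest of each artifact. Identical config
#' and seed give bit-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param composition_reference optional reference table for
#'   [cell_composition_check()].
#' @return invisibly, a list with the in-memory stage results and the
#'   artifact manifest.
#' @export
run_pipeline <- function(config, composition_reference = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed)
  paths <- character()
  out <- function(f) file.path(config$outdir, f)
  emit <- function(x, f) {
    data.table::fwrite(x, out(f), sep = "\t")
    paths[f] <<- out(f)
  }
  res <- list(config = config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # simulate / load
  ds <- stage("simulate", {
    if (!is.null(config$input_dir)) read_fixture_bundle(config$input_dir)
    else {
      cfg <- config$sim
      cfg$seed <- seeds[1]
      d <- simulate_dataset(cfg)
      if ("simulate" %in% config$stages)
        write_fixture_bundle(d, out("fixture"))
      d
    }
  })
  res$dataset <- ds

  # qc
  qc_res <- stage("qc", {
    detp <- detection_pvalue(ds$signal, ds$negcontrols)
    sig_check <- sample_signal_check(ds$signal, ds$negcontrols)
    filt <- filter_probes(ds$signal, ds$manifest, detp, config$qc)
    list(detp = detp, signal_check = sig_check, filtered = filt$signal,
         report = filt$report)
  })
  res$qc <- qc_res
  emit(qc_res$signal_check, "sample_signal_check.tsv")
  emit(qc_res$report$stages, "qc_probe_stages.tsv")
  emit(qc_res$report$cells, "qc_cells_missing.tsv")
  emit(qc_res$report$sample_success, "qc_sample_success.tsv")

  # normalize
  norm <- stage("normalize", {
    adj <- quantile_normalize(qc_res$filtered, ds$manifest)
    beta_raw <- beta_matrix(adj)
    beta <- if (config$bmiq) bmiq_adjust(beta_raw, ds$manifest) else beta_raw
    mval <- mvalue_matrix(adj, offset = config$m_offset)
    list(adjusted = adj, beta_raw = beta_raw, beta = beta, mvalues = mval)
  })
  res$normalize <- norm
  emit(precise_doubles(mat_to_dt(norm$beta)), "beta.tsv")
  emit(precise_doubles(mat_to_dt(norm$mvalues)), "mvalues.tsv")

  # cluster QC on normalized beta
  clus <- stage("qc", sample_cluster_qc(norm$beta, ds$manifest, ds$samples,
                                        config$qc))
  res$cluster <- clus
  emit(clus$first_merge, "cluster_first_merge.tsv")
  write_dendrogram_newick(clus$hclust, out("dendrogram.nwk"))
  paths["dendrogram.nwk"] <- out("dendrogram.nwk")

  # annotate
  ann <- stage("annotate", {
    man_kept <- ds$manifest[ds$manifest$probe_id %in% rownames(norm$beta), ]
    annotate_cpgs(man_kept, ds$genes, ds$tracks)
  })
  res$annotation <- ann
  emit(ann, "annotation.tsv")

  # correlate
  corr <- stage("correlate", {
    st <- cpg_stats(norm$beta, ds$samples, sd_min = config$sd_min,
                    hypo_max = config$hypo_max, hyper_min = config$hyper_min)
    rho <- cross_pair_rho(norm$beta, ds$samples, min_pairs = config$min_pairs)
    variable_ids <- st$probe_id[st$most_variable]
    prof_all <- pairwise_profile_rho(norm$beta, ds$samples)
    prof_var <- pairwise_profile_rho(norm$beta, ds$samples, variable_ids)
    unrel_all <- unrelated_profile_rho(norm$beta, ds$samples)
    unrel_var <- unrelated_profile_rho(norm$beta, ds$samples, variable_ids)
    list(stats = st, rho = rho, variable_ids = variable_ids,
         profile_all = prof_all, profile_variable = prof_var,
         unrelated_all = unrel_all, unrelated_variable = unrel_var)
  })
  res$correlate <- corr
  emit(corr$stats, "cpg_stats.tsv")
  emit(corr$rho, "cross_pair_rho.tsv")
  prof <- merge(corr$profile_all, corr$profile_variable, by = "pair_id",
                suffixes = c("_all", "_variable"))
  emit(prof, "pair_profile_rho.tsv")
  emit(corr$unrelated_all$correlations, "unrelated_profile_rho.tsv")

  # report
  rep_res <- stage("report", {
    summ <- region_summaries(corr$stats, ann, rho = corr$rho,
                             variable_only = TRUE)
    impr <- imprinted_subset_summary(corr$stats, ann, rho = corr$rho)
    comp <- if (!is.null(composition_reference))
      cell_composition_check(norm$beta, composition_reference,
                             config$mixing_w_min)
    list(summaries = summ, imprinted = impr, composition = comp)
  })
  res$report <- rep_res
  emit(rep_res$summaries, "region_summaries.tsv")
  emit(rep_res$imprinted, "imprinted_summary.tsv")
  if (!is.null(rep_res$composition))
    emit(rep_res$composition, "cell_composition.tsv")

  manifest <- list(
    package = "twinmeth",
    version = as.character(utils::packageVersion("twinmeth")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stage_seeds = seeds,
    artifacts = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$artifact_manifest <- manifest
  res$paths <- paths
  invisible(res)
}
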