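# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A small but complete study: all five gene regions, all four island
# classes, an imprinted cassette, 8 pairs + 3 replicates.
small_config <- function(seed = 42L) {
  strata <- list(
    stratum_spec("cgi_prox", "proximal_promoter", "CGI", 260,
                 c(0.6, 0.3, 0.1), 0.66, dhs = TRUE, tfbs = TRUE),
    stratum_spec("shore_body", "gene_body", "shore", 240,
                 c(0.3, 0.4, 0.3), 0.54),
    stratum_spec("shelf_body", "gene_body", "shelf", 200,
                 c(0.2, 0.3, 0.5), 0.50),
    stratum_spec("noncgi_inter", "intergenic", "nonCGI", 220,
                 c(0.1, 0.3, 0.6), 0.49),
    stratum_spec("noncgi_down", "downstream", "nonCGI", 120,
                 c(0.1, 0.3, 0.6), 0.49),
    stratum_spec("cgi_distal", "distal_promoter", "CGI", 120,
                 c(0.6, 0.3, 0.1), 0.66),
    stratum_spec("imprinted", "proximal_promoter", "CGI", 80,
                 c(0.05, 0.9, 0.05), 0.47, imprinted_gene = "IGDMR1")
  )
  sim_config(n_pairs = 8L, n_control_replicates = 3L, strata = strata,
             seed = seed)
}

small_sim <- function() cached("small_sim", simulate_dataset(small_config()))

# The small study taken through QC and normalization (no BMIQ).
small_norm <- function() cached("small_norm", {
  ds <- small_sim()
  detp <- detection_pvalue(ds$signal, ds$negcontrols)
  filt <- filter_probes(ds$signal, ds$manifest, detp)
  adj <- quantile_normalize(filt$signal, ds$manifest)
  list(dataset = ds, detp = detp, filtered = filt$signal,
       report = filt$report, adjusted = adj, beta = beta_matrix(adj))
})

# Long-format signal table from plain matrices.
as_long_signal <- function(meth, unmeth, beads) {
  data.table::data.table(
    probe_id = rep(rownames(meth), times = ncol(meth)),
    sample_id = rep(colnames(meth), each = nrow(meth)),
    meth = as.vector(meth), unmeth = as.vector(unmeth),
    beads = as.vector(beads))
}

# Minimal sample sheet for n twin pairs (+ optional replicates).
make_sheet <- function(n_pairs, n_reps = 0L) {
  pair_ids <- sprintf("p%02d", seq_len(n_pairs))
  rbind(
    data.table::data.table(
      sample_id = as.vector(t(outer(pair_ids, c("_a", "_b"), paste0))),
      pair_id = rep(pair_ids, each = 2), twin_index = rep(1:2, n_pairs),
      role = "twin", sex = "F", age_group = "8-12"),
    if (n_reps > 0)
      data.table::data.table(sample_id = sprintf("rep%d", seq_len(n_reps)),
                             pair_id = "control", twin_index = NA_integer_,
                             role = "control_replicate", sex = "F",
                             age_group = "adult"))
}

make_filter_fixture <- function(n_probes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("cg%04d", seq_len(n_probes))
    smp <- sprintf("s%02d", seq_len(n_samples))
    meth <- matrix(round(stats::rlnorm(n_probes * n_samples, log(4000), 0.3)),
                   n_probes, n_samples, dimnames = list(ids, smp))
    unmeth <- matrix(round(stats::rlnorm(n_probes * n_samples, log(4000), 0.3)),
                     n_probes, n_samples, dimnames = list(ids, smp))
    beads <- matrix(12L, n_probes, n_samples, dimnames = list(ids, smp))
    detp <- matrix(1e-8, n_probes, n_samples, dimnames = list(ids, smp))
    manifest <- data.table::data.table(
      probe_id = ids, chrom = "chr1", position = seq_len(n_probes) * 10L,
      probe_type = "II", ambiguous = FALSE, snp_at_cpg = FALSE)
    list(meth = meth, unmeth = unmeth, beads = beads, detp = detp,
         manifest = manifest, ids = ids, smp = smp)
  })
}

# A compressed-Type-II fixture: strong dynamic-range compression so the two
# chemistries differ clearly before harmonization.
bmiq_fixture <- function() cached("bmiq_fixture", {
  cfg <- sim_config(n_pairs = 6, n_control_replicates = 0,
                    strata = list(
                      stratum_spec("mix", "gene_body", "nonCGI", 1600,
                                   c(0.35, 0.3, 0.35), 0.5,
                                   probe_type_fraction_II = 0.5)),
                    type2_logit_scale = 0.6,
                    fail_fraction = 0, zero_fraction = 0, seed = 21L)
  ds <- simulate_dataset(cfg)
  sm <- signal_matrices(ds$signal)
  beta <- compute_beta(sm$meth, sm$unmeth)
  attr(beta, "bmiq") <- FALSE
  list(dataset = ds, beta = beta,
       type = ds$manifest$probe_type[match(rownames(beta),
                                           ds$manifest$probe_id)])
})
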