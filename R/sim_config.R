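#' Specify one genomic stratum for the synthetic generator
#'
#' A stratum is a homogeneous block of CpGs sharing a gene-centric context,
#' a CpG-island context and a familial correlation structure. The generator
#' lays each stratum out as its own genomic cassette (island, flanks and a
#' gene placed so that every CpG falls in the requested windows), which makes
#' the annotation step invertible: each simulated CpG is re-assigned to its
#' generating stratum.
#'
#' @param name unique stratum label.
#' @param gene_region one of `"intergenic"`, `"distal_promoter"`,
#'   `"proximal_promoter"`, `"gene_body"`, `"downstream"`.
#' @param cgi_class one of `"CGI"`, `"shore"`, `"shelf"`, `"nonCGI"`.
#' @param n_cpgs number of CpGs in the stratum.
#' @param meth_class_weights length-3 non-negative weights over the
#'   hypo / intermediate / hyper baseline classes; must sum to 1.
#' @param target_spearman familial rank correlation in `[-1, 1]` that the
#'   stratum's CpGs should exhibit between co-twins (across pairs).
#' @param logit_noise_sd individual-level (twin-specific) noise SD on the
#'   log-odds scale. When 0, co-twins share identical true methylation.
#' @param probe_type_fraction_II fraction of probes assigned the Type II
#'   chemistry.
#' @param dhs,tfbs logical; whether the stratum's span is covered by a
#'   DNase-hypersensitivity / transcription-factor-binding interval.
#' @param imprinted_gene optional gene id: when set, the stratum's span is
#'   emitted as an imprinted differentially methylated region for that gene.
#' @return a `stratum_spec` list.
#' @export
stratum_spec <- function(name, gene_region, cgi_class, n_cpgs,
                         meth_class_weights = c(hypo = 1/3, intermediate = 1/3, hyper = 1/3),
                         target_spearman = 0.5,
                         logit_noise_sd = 0.35,
                         probe_type_fraction_II = 0.72,
                         dhs = FALSE, tfbs = FALSE,
                         imprinted_gene = NA_character_) {
  gene_region <- match.arg(gene_region, gene_region_levels())
  cgi_class <- match.arg(cgi_class, cgi_class_levels())
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(length(n_cpgs) == 1L, n_cpgs >= 1)
  w <- as.numeric(meth_class_weights)
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("meth_class_weights must be 3 non-negative weights summing to 1")
  if (abs(target_spearman) > 1) stop("target_spearman must lie in [-1, 1]")
  if (logit_noise_sd < 0) stop("logit_noise_sd must be >= 0")
  if (probe_type_fraction_II < 0 || probe_type_fraction_II > 1)
    stop("probe_type_fraction_II must lie in [0, 1]")
  structure(list(
    name = name, gene_region = gene_region, cgi_class = cgi_class,
    n_cpgs = as.integer(n_cpgs),
    meth_class_weights = stats::setNames(w, c("hypo", "intermediate", "hyper")),
    target_spearman = target_spearman,
    logit_noise_sd = logit_noise_sd,
    probe_type_fraction_II = probe_type_fraction_II,
    dhs = isTRUE(dhs), tfbs = isTRUE(tfbs),
    imprinted_gene = imprinted_gene
  ), class = "stratum_spec")
}

gene_region_levels <- function() {
  c("intergenic", "distal_promoter", "proximal_promoter", "gene_body", "downstream")
}

cgi_class_levels <- function() c("CGI", "shore", "shelf", "nonCGI")

meth_class_levels <- function() c("hypo", "intermediate", "hyper")

#' Default study-design strata
#'
#' Emulates the qualitative picture of a buccal 450k dataset: CpG islands
#' mostly hypomethylated (promoter CGIs tightly so), shores spanning the
#' widest range of mean methylation, shelves and open-sea CpGs mostly
#' hypermethylated, and familial correlation decreasing from islands
#' (0.66) through shores (0.54) and shelves (0.50) to non-island CpGs
#' (0.49). One small imprinted cassette sits at intermediate methylation
#' with familial correlation 0.47.
#'
#' @return list of [stratum_spec()] objects.
#' @export
default_strata <- function() {
  list(
    stratum_spec("cgi_promoter", "proximal_promoter", "CGI", 1200,
                 c(0.70, 0.20, 0.10), target_spearman = 0.66,
                 dhs = TRUE, tfbs = TRUE),
    stratum_spec("cgi_distal", "distal_promoter", "CGI", 300,
                 c(0.60, 0.25, 0.15), target_spearman = 0.66),
    stratum_spec("shore_promoter", "proximal_promoter", "shore", 800,
                 c(0.30, 0.40, 0.30), target_spearman = 0.54, dhs = TRUE),
    stratum_spec("shore_body", "gene_body", "shore", 400,
                 c(0.25, 0.40, 0.35), target_spearman = 0.54),
    stratum_spec("shelf_body", "gene_body", "shelf", 600,
                 c(0.15, 0.30, 0.55), target_spearman = 0.50),
    stratum_spec("noncgi_body", "gene_body", "nonCGI", 700,
                 c(0.10, 0.25, 0.65), target_spearman = 0.49),
    stratum_spec("noncgi_intergenic", "intergenic", "nonCGI", 700,
                 c(0.10, 0.25, 0.65), target_spearman = 0.49),
    stratum_spec("noncgi_downstream", "downstream", "nonCGI", 250,
                 c(0.12, 0.28, 0.60), target_spearman = 0.49),
    stratum_spec("imprinted_cgi_promoter", "proximal_promoter", "CGI", 150,
                 c(0.05, 0.90, 0.05), target_spearman = 0.47,
                 imprinted_gene = "IGDMR1")
  )
}

#' Configuration of a synthetic twin-methylation dataset
#'
#' Defines the study design (number of monozygotic pairs, replicated control
#' DNA), the genomic strata, and the intensity-level technical model. The
#' defaults describe the emulated study: 10 MZ pairs, 4 replicates of one
#' control DNA, log-normal total probe signal well separated from a
#' truncated-normal background, and sporadic probe failures.
#'
#' @param n_pairs number of MZ twin pairs (>= 2).
#' @param n_control_replicates technical replicates of the control DNA.
#' @param strata list of [stratum_spec()]; names must be unique.
#' @param background_mean,background_sd intensity background (negative
#'   control) location and spread.
#' @param total_intensity_log_mean,total_intensity_log_sd parameters of the
#'   log-normal total (methylated + unmethylated) signal per probe.
#' @param bead_count_mean expected beads per probe (shifted Poisson, min 1).
#' @param fail_fraction proportion of probe-by-sample cells whose intensities
#'   are drawn from the background distribution only (detection failures).
#' @param zero_fraction proportion of cells forced to zero intensity
#'   (probe absent from the array).
#' @param n_negative_controls number of negative-control probes.
#' @param ambiguous_fraction,snp_fraction proportions of CpG probes flagged
#'   in the manifest as ambiguously mapped / carrying a SNP at the CpG.
#' @param type2_logit_scale log-odds compression applied to Type II probes
#'   before intensity generation (< 1 compresses towards 0.5, emulating the
#'   reduced dynamic range of the single-bead chemistry).
#' @param finite_pair_correction logical; calibrate the latent familial
#'   correlation against the exact finite-sample expectation of Spearman's
#'   rho at `n_pairs` pairs (default) rather than the asymptotic
#'   bivariate-normal identity. See the methods vignette.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pairs = 10L,
                       n_control_replicates = 4L,
                       strata = default_strata(),
                       background_mean = 150,
                       background_sd = 40,
                       total_intensity_log_mean = log(6000),
                       total_intensity_log_sd = 0.35,
                       bead_count_mean = 14,
                       fail_fraction = 0.002,
                       zero_fraction = 0.001,
                       n_negative_controls = 200L,
                       ambiguous_fraction = 0.01,
                       snp_fraction = 0.01,
                       type2_logit_scale = 0.8,
                       finite_pair_correction = TRUE,
                       seed = 1L) {
  stopifnot(n_pairs >= 2, n_control_replicates >= 0, length(strata) >= 1)
  if (!all(vapply(strata, inherits, logical(1), "stratum_spec")))
    stop("strata must be a list of stratum_spec objects")
  nms <- vapply(strata, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("stratum names must be unique")
  fracs <- c(fail_fraction, zero_fraction, ambiguous_fraction, snp_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  stopifnot(background_sd > 0, total_intensity_log_sd >= 0,
            bead_count_mean >= 1, n_negative_controls >= 0,
            type2_logit_scale > 0)
  structure(list(
    n_pairs = as.integer(n_pairs),
    n_control_replicates = as.integer(n_control_replicates),
    strata = stats::setNames(strata, nms),
    background_mean = background_mean, background_sd = background_sd,
    total_intensity_log_mean = total_intensity_log_mean,
    total_intensity_log_sd = total_intensity_log_sd,
    bead_count_mean = bead_count_mean,
    fail_fraction = fail_fraction, zero_fraction = zero_fraction,
    n_negative_controls = as.integer(n_negative_controls),
    ambiguous_fraction = ambiguous_fraction, snp_fraction = snp_fraction,
    type2_logit_scale = type2_logit_scale,
    finite_pair_correction = isTRUE(finite_pair_correction),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Four-stratum configuration for familial-correlation recovery
#'
#' One stratum per CpG-island class, all placed in gene bodies, with the
#' default familial rank-correlation targets 0.66 (CGI), 0.54 (shore),
#' 0.50 (shelf) and 0.49 (non-CGI) and methylation-class mixtures weighted
#' towards variable (intermediate and moderately hypo/hyper) CpGs so that
#' at least `n_variable_target` CpGs per stratum pass the SD >= 0.05
#' variability filter.
#'
#' @param n_pairs number of twin pairs.
#' @param n_cpgs CpGs per stratum (3500 leaves comfortably more than
#'   2000 variable CpGs per stratum after the SD filter).
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
recovery_sim_config <- function(n_pairs = 10L, n_cpgs = 3500L, seed = 1L) {
  w <- c(0.25, 0.50, 0.25)
  strata <- list(
    stratum_spec("rec_cgi", "gene_body", "CGI", n_cpgs, w, 0.66),
    stratum_spec("rec_shore", "gene_body", "shore", n_cpgs, w, 0.54),
    stratum_spec("rec_shelf", "gene_body", "shelf", n_cpgs, w, 0.50),
    stratum_spec("rec_noncgi", "gene_body", "nonCGI", n_cpgs, w, 0.49)
  )
  sim_config(n_pairs = n_pairs, strata = strata, seed = seed)
}

#' Invert the finite-sample expectation of Spearman's rho
#'
#' For bivariate-normal latent values the expected sample Spearman
#' correlation at sample size n is
#' `E(r_S) = 6 / (pi (n + 1)) * (asin(rho) + (n - 2) asin(rho / 2))`,
#' which tends to the familiar `(6 / pi) asin(rho / 2)` as n grows. This
#' returns the latent Pearson correlation `rho` whose expected sample
#' Spearman equals `target` at `n` observations; with `n = Inf` it returns
#' the asymptotic inversion `2 sin(pi target / 6)`.
#'
#' @param target desired rank correlation in `[-1, 1]`.
#' @param n number of paired observations (`Inf` for asymptotic).
#' @return latent Pearson correlation in `[-1, 1]`.
#' @export
latent_rho_for_spearman <- function(target, n = Inf) {
  stopifnot(abs(target) <= 1)
  if (!is.finite(n)) return(2 * sin(pi * target / 6))
  stopifnot(n >= 3)
  if (target == 0) return(0)
  if (abs(target) == 1) return(sign(target))
  f <- function(r) expected_sample_spearman(r, n) - target
  stats::uniroot(f, c(-1 + 1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' @rdname latent_rho_for_spearman
#' @param rho latent Pearson correlation.
#' @export
expected_sample_spearman <- function(rho, n) {
  6 / (pi * (n + 1)) * (asin(rho) + (n - 2) * asin(rho / 2))
}
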