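#' @import data.table
#' @importFrom stats rnorm rpois runif rlnorm pnorm qnorm median sd cor
#' @importFrom stats dbeta pbeta qbeta
NULL

# Baseline (between-CpG) distribution of the three methylation classes on
# the log-odds scale. Centers at beta = 0.10 / 0.50 / 0.90; spreads chosen
# so that class leakage across the 0.3 / 0.7 cutoffs stays small.
.class_centers <- c(hypo = stats::qlogis(0.10), intermediate = 0,
                    hyper = stats::qlogis(0.90))
.class_sds <- c(hypo = 0.6, intermediate = 0.45, hyper = 0.6)

plogis_ <- stats::plogis
qlogis_ <- stats::qlogis

# --- genomic layout -------------------------------------------------------

# Lay one cassette per stratum along a single chromosome: a CpG island, its
# shore/shelf flanks, and a gene placed so that every CpG position falls in
# the stratum's (gene_region, cgi_class) windows. Cassettes are separated by
# 30 kb so no gene window or island flank reaches a neighbouring stratum,
# which makes annotation invert the layout exactly.
layout_strata <- function(strata) {
  chrom <- "chr1"
  B <- 100001
  pos_list <- list(); isl <- list(); genes <- list()
  dhs <- list(); tfbs <- list(); impr <- list()
  strand_toggle <- TRUE
  for (st in strata) {
    n <- st$n_cpgs
    L <- if (st$cgi_class == "CGI") max(1000L, n + 200L) else 1000L
    s <- B + 22000L
    e <- s + L - 1L
    cand <- switch(st$cgi_class,
      CGI    = s:e,
      shore  = c((e + 1L):(e + 2000L), (s - 2000L):(s - 1L)),
      shelf  = c((e + 2001L):(e + 4000L), (s - 4000L):(s - 2001L)),
      nonCGI = (e + 4001L):(e + 4000L + n)
    )
    if (n > length(cand))
      stop(sprintf("non-invertible stratum layout: stratum '%s' needs %d CpGs but its %s window holds at most %d",
                   st$name, n, st$cgi_class, length(cand)))
    pos <- sort(cand[seq_len(n)])
    w1 <- min(pos); w2 <- max(pos); width <- w2 - w1
    strand <- if (strand_toggle) "+" else "-"
    if (st$gene_region != "intergenic") strand_toggle <- !strand_toggle
    g <- place_gene(st$gene_region, w1, w2, width, strand, st$name)
    if (!is.null(g)) {
      g$gene_id <- if (!is.na(st$imprinted_gene)) st$imprinted_gene
                   else paste0("GENE_", st$name)
      genes[[length(genes) + 1L]] <- g
    }
    pos_list[[st$name]] <- pos
    isl[[length(isl) + 1L]] <- data.table(chrom = chrom, start = s, end = e)
    span <- data.table(chrom = chrom, start = w1, end = w2)
    if (st$dhs) dhs[[length(dhs) + 1L]] <- span
    if (st$tfbs) tfbs[[length(tfbs) + 1L]] <- span
    if (!is.na(st$imprinted_gene))
      impr[[length(impr) + 1L]] <- data.table(chrom = chrom, start = w1, end = w2,
                                              name = st$imprinted_gene)
    used <- c(pos, s, e, if (!is.null(g)) c(g$tss, g$end3))
    B <- max(used) + 30000L
  }
  genes_dt <- if (length(genes))
    rbindlist(lapply(genes, function(g)
      data.table(gene_id = g$gene_id, chrom = chrom, strand = g$strand,
                 tss = g$tss, end3 = g$end3)))
  else data.table(gene_id = character(), chrom = character(),
                  strand = character(), tss = integer(), end3 = integer())
  empty_bed <- data.table(chrom = character(), start = integer(), end = integer())
  list(
    positions = pos_list,
    genes = genes_dt,
    tracks = list(
      cgi = rbindlist(isl),
      dhs = if (length(dhs)) rbindlist(dhs) else copy(empty_bed),
      tfbs = if (length(tfbs)) rbindlist(tfbs) else copy(empty_bed),
      imprinted = if (length(impr)) rbindlist(impr) else
        data.table(chrom = character(), start = integer(), end = integer(),
                   name = character())
    )
  )
}

# Choose TSS and 3'-end so every position in [w1, w2] lands in `region`
# relative to this gene, on either strand. Returns NULL for intergenic.
place_gene <- function(region, w1, w2, width, strand, name) {
  cap <- c(proximal_promoter = 2000L, distal_promoter = 8499L,
           gene_body = .Machine$integer.max, downstream = 4999L)
  if (region == "intergenic") return(NULL)
  if (width > cap[[region]])
    stop(sprintf("non-invertible stratum layout: stratum '%s' spans %d bp, too wide for a %s window",
                 name, width, region))
  if (strand == "+") {
    switch(region,
      proximal_promoter = list(strand = strand, tss = w1 + 1500L, end3 = w1 + 4500L),
      distal_promoter   = list(strand = strand, tss = w2 + 1501L, end3 = w2 + 3501L),
      gene_body         = list(strand = strand, tss = w1 - 600L,  end3 = w2 + 100L),
      downstream        = list(strand = strand, tss = w1 - 1501L, end3 = w1 - 1L))
  } else {
    switch(region,
      proximal_promoter = list(strand = strand, tss = w2 - 1500L, end3 = w2 - 4500L),
      distal_promoter   = list(strand = strand, tss = w1 - 1501L, end3 = w1 - 3501L),
      gene_body         = list(strand = strand, tss = w2 + 600L,  end3 = w1 - 100L),
      downstream        = list(strand = strand, tss = w2 + 1501L, end3 = w2 + 1L))
  }
}

# --- dataset generation ---------------------------------------------------

#' Simulate a twin-study methylation dataset with known ground truth
#'
#' Draws, for each CpG, a baseline log-odds methylation level from its
#' stratum's class mixture; for each twin pair a familial effect shared by
#' both co-twins; and for each subject an individual effect, so that the
#' latent co-twin correlation matches the stratum's `target_spearman` on the
#' rank scale. True methylation fractions are converted to methylated /
#' unmethylated bead intensities under a log-normal total-signal model with
#' additive truncated-normal background, sporadic detection failures and
#' zero-intensity cells, and negative-control probes. Control DNA is a
#' single additional subject re-measured with fresh technical noise in each
#' replicate.
#'
#' @param config a [sim_config()].
#' @return a `twin_sim` list with elements `signal` (long table: probe_id,
#'   sample_id, meth, unmeth, beads), `negcontrols` (same shape),
#'   `manifest`, `samples`, `genes`, `tracks` (cgi/dhs/tfbs/imprinted
#'   interval tables, 1-based inclusive), `truth` and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_(config))
}

simulate_dataset_ <- function(cfg) {
  strata <- cfg$strata
  layout <- layout_strata(strata)
  n_pairs <- cfg$n_pairs
  n_rep <- cfg$n_control_replicates

  pair_ids <- sprintf("pair%02d", seq_len(n_pairs))
  twin_samples <- as.vector(t(outer(pair_ids, c("_t1", "_t2"), paste0)))
  rep_samples <- if (n_rep > 0) sprintf("ctrl_rep%d", seq_len(n_rep)) else character()
  samples_all <- c(twin_samples, rep_samples)

  sexes <- rep(c("F", "M"), length.out = n_pairs)
  ages <- rep(c("8-12", "13-19"), length.out = n_pairs)
  sheet <- rbind(
    data.table(sample_id = twin_samples,
               pair_id = rep(pair_ids, each = 2L),
               twin_index = rep(1:2, n_pairs),
               role = "twin",
               sex = rep(sexes, each = 2L),
               age_group = rep(ages, each = 2L)),
    if (n_rep > 0)
      data.table(sample_id = rep_samples, pair_id = "control",
                 twin_index = NA_integer_, role = "control_replicate",
                 sex = "F", age_group = "adult")
  )

  # latent model per stratum
  cpg_rows <- list(); latent_cols <- list(); g_rows <- list(); strata_rows <- list()
  probe_counter <- 0L
  for (st in strata) {
    n <- st$n_cpgs
    t_sp <- st$target_spearman
    if (t_sp < 0)
      stop("the familial variance decomposition requires target_spearman >= 0")
    if (st$logit_noise_sd == 0) {
      sigma_e <- 0; sigma_f <- 0.5; rho <- 1
    } else {
      if (t_sp == 1)
        stop("target_spearman = 1 requires logit_noise_sd = 0 (no individual variance)")
      rho <- latent_rho_for_spearman(
        t_sp, n = if (cfg$finite_pair_correction) n_pairs else Inf)
      sigma_e <- st$logit_noise_sd
      sigma_f <- sigma_e * sqrt(rho / (1 - rho))
    }
    cls <- sample.int(3L, n, replace = TRUE, prob = st$meth_class_weights)
    m <- rnorm(n, .class_centers[cls], .class_sds[cls])
    g <- matrix(rnorm(n * n_pairs, 0, sigma_f), n, n_pairs)
    e <- matrix(rnorm(n * 2L * n_pairs, 0, sigma_e), n, 2L * n_pairs)
    lat_twins <- m + g[, rep(seq_len(n_pairs), each = 2L)] + e
    lat_ctrl <- m + rnorm(n, 0, sigma_f) + rnorm(n, 0, sigma_e)
    ctrl_cols <- if (n_rep > 0) matrix(rep(lat_ctrl, n_rep), n, n_rep)
                 else matrix(numeric(), n, 0)
    ids <- sprintf("cg%07d", probe_counter + seq_len(n))
    probe_counter <- probe_counter + n
    cpg_rows[[st$name]] <- data.table(
      probe_id = ids, stratum = st$name,
      position = layout$positions[[st$name]],
      meth_class_true = meth_class_levels()[cls],
      baseline_logit = m)
    latent_cols[[st$name]] <- cbind(lat_twins, ctrl_cols)
    g_rows[[st$name]] <- g
    strata_rows[[st$name]] <- data.table(
      stratum = st$name, gene_region = st$gene_region,
      cgi_class = st$cgi_class, n_cpgs = n,
      target_spearman = t_sp, latent_rho = rho,
      sigma_f = sigma_f, sigma_e = sigma_e)
  }
  cpg <- rbindlist(cpg_rows)
  latent <- do.call(rbind, latent_cols)
  dimnames(latent) <- list(cpg$probe_id, samples_all)
  pair_eff <- do.call(rbind, g_rows)
  dimnames(pair_eff) <- list(cpg$probe_id, pair_ids)
  truth_strata <- rbindlist(strata_rows)

  n_cpg <- nrow(cpg)
  beta_true <- plogis_(latent)

  # manifest: probe design type and QC flags
  probe_type <- ifelse(
    runif(n_cpg) < rep(vapply(strata, `[[`, numeric(1), "probe_type_fraction_II"),
                       times = vapply(strata, `[[`, integer(1), "n_cpgs")),
    "II", "I")
  manifest <- data.table(
    probe_id = cpg$probe_id, chrom = "chr1", position = cpg$position,
    probe_type = probe_type,
    ambiguous = runif(n_cpg) < cfg$ambiguous_fraction,
    snp_at_cpg = runif(n_cpg) < cfg$snp_fraction)

  # intensity layer: Type II chemistry compresses the dynamic range
  beta_assay <- beta_true
  ii <- probe_type == "II"
  if (any(ii))
    beta_assay[ii, ] <- plogis_(cfg$type2_logit_scale * latent[ii, , drop = FALSE])

  n_smp <- length(samples_all)
  total <- matrix(rlnorm(n_cpg * n_smp, cfg$total_intensity_log_mean,
                         cfg$total_intensity_log_sd), n_cpg, n_smp)
  bg <- function(k) pmax(0, round(rnorm(k, cfg$background_mean, cfg$background_sd)))
  meth <- round(beta_assay * total) + bg(n_cpg * n_smp)
  unmeth <- round((1 - beta_assay) * total) + bg(n_cpg * n_smp)

  u <- runif(n_cpg * n_smp)
  fail_idx <- which(u < cfg$fail_fraction)
  zero_idx <- which(u >= cfg$fail_fraction &
                    u < cfg$fail_fraction + cfg$zero_fraction)
  if (length(fail_idx)) {
    meth[fail_idx] <- bg(length(fail_idx))
    unmeth[fail_idx] <- bg(length(fail_idx))
  }
  if (length(zero_idx)) {
    meth[zero_idx] <- 0
    unmeth[zero_idx] <- 0
  }
  beads <- matrix(1L + rpois(n_cpg * n_smp, cfg$bead_count_mean - 1), n_cpg, n_smp)

  cell_dt <- function(idx) {
    if (!length(idx)) return(data.table(probe_id = character(), sample_id = character()))
    data.table(probe_id = cpg$probe_id[(idx - 1L) %% n_cpg + 1L],
               sample_id = samples_all[(idx - 1L) %/% n_cpg + 1L])
  }

  signal <- data.table(
    probe_id = rep(cpg$probe_id, times = n_smp),
    sample_id = rep(samples_all, each = n_cpg),
    meth = as.vector(meth), unmeth = as.vector(unmeth),
    beads = as.vector(beads))

  n_neg <- cfg$n_negative_controls
  negcontrols <- data.table(
    probe_id = rep(sprintf("negctl_%04d", seq_len(n_neg)), times = n_smp),
    sample_id = rep(samples_all, each = n_neg),
    meth = bg(n_neg * n_smp), unmeth = bg(n_neg * n_smp),
    beads = 1L + rpois(n_neg * n_smp, cfg$bead_count_mean - 1))

  # realized familial rank correlation of the latent values, per stratum
  t1 <- sheet[role == "twin" & twin_index == 1L, sample_id]
  t2 <- sheet[role == "twin" & twin_index == 2L, sample_id]
  rho_lat <- spearman_rows(latent[, t1, drop = FALSE], latent[, t2, drop = FALSE])
  truth_strata[, realized_latent_spearman :=
    vapply(truth_strata$stratum,
           function(s) mean(rho_lat[cpg$stratum == s], na.rm = TRUE), numeric(1))]

  structure(list(
    signal = signal, negcontrols = negcontrols, manifest = manifest,
    samples = sheet, genes = layout$genes, tracks = layout$tracks,
    truth = list(cpg = cpg, strata = truth_strata, latent = latent,
                 beta = beta_true, pair_effects = pair_eff,
                 fail_cells = cell_dt(fail_idx), zero_cells = cell_dt(zero_idx)),
    config = cfg
  ), class = "twin_sim")
}

#' @export
print.twin_sim <- function(x, ...) {
  cat(sprintf("twin_sim: %d CpGs x %d samples (%d pairs + %d control replicates), %d strata\n",
              nrow(x$truth$cpg), nrow(x$samples), x$config$n_pairs,
              x$config$n_control_replicates, length(x$config$strata)))
  invisible(x)
}

# Row-wise Spearman correlation between paired matrices (same dimensions),
# average ranks for ties, NA below `min_n` complete pairs or for
# zero-variance rows.
spearman_rows <- function(A, B, min_n = 3L) {
  stopifnot(all(dim(A) == dim(B)))
  n <- nrow(A)
  out <- rep(NA_real_, n)
  cc <- !(is.na(A) | is.na(B))
  complete <- rowSums(cc) == ncol(A)
  if (any(complete)) {
    rA <- t(apply(A[complete, , drop = FALSE], 1L, rank))
    rB <- t(apply(B[complete, , drop = FALSE], 1L, rank))
    rA <- rA - rowMeans(rA); rB <- rB - rowMeans(rB)
    num <- rowSums(rA * rB)
    den <- sqrt(rowSums(rA^2) * rowSums(rB^2))
    r <- ifelse(den > 0, num / den, NA_real_)
    out[complete] <- r
  }
  rest <- which(!complete & rowSums(cc) >= min_n)
  for (i in rest) {
    k <- cc[i, ]
    out[i] <- suppressWarnings(
      cor(A[i, k], B[i, k], method = "spearman"))
  }
  if (ncol(A) < min_n) out[] <- NA_real_
  out
}
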