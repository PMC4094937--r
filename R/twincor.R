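#' Per-CpG summary statistics across subjects
#'
#' For each CpG the mean and sample SD (n - 1 denominator) of beta across
#' twin subjects (control replicates are excluded), the methylation class
#' (hypomethylated: mean < 0.3; intermediate: 0.3 <= mean < 0.7;
#' hypermethylated: mean >= 0.7) and the variability flag
#' (most variable: SD >= `sd_min`, boundary inclusive). CpGs with fewer
#' than `min_subjects` non-missing values get missing statistics.
#'
#' @param beta CpG x sample beta matrix.
#' @param samples sample sheet with `sample_id` and `role` columns.
#' @param sd_min variability cutoff on the SD (default 0.05).
#' @param hypo_max,hyper_min methylation-class cutoffs (default 0.3 / 0.7).
#' @param min_subjects minimum non-missing subjects (default 3).
#' @return data.table: probe_id, n_subjects, mean_beta, sd_beta, meth_class,
#'   most_variable.
#' @export
cpg_stats <- function(beta, samples, sd_min = 0.05, hypo_max = 0.3,
                      hyper_min = 0.7, min_subjects = 3L) {
  subj <- subject_ids(samples)
  subj <- intersect(colnames(beta), subj)
  if (!length(subj)) stop("no twin subjects found in the beta matrix")
  b <- beta[, subj, drop = FALSE]
  n <- rowSums(!is.na(b))
  mu <- rowMeans(b, na.rm = TRUE)
  ssq <- rowSums(b^2, na.rm = TRUE)
  s2 <- (ssq - n * mu^2) / (n - 1)
  s <- sqrt(pmax(s2, 0))
  bad <- n < min_subjects
  mu[bad] <- NA_real_; s[bad] <- NA_real_
  cls <- rep(NA_character_, length(mu))
  cls[!bad & mu < hypo_max] <- "hypo"
  cls[!bad & mu >= hypo_max & mu < hyper_min] <- "intermediate"
  cls[!bad & mu >= hyper_min] <- "hyper"
  data.table::data.table(
    probe_id = rownames(beta), n_subjects = as.integer(n),
    mean_beta = mu, sd_beta = s, meth_class = cls,
    most_variable = !bad & s >= sd_min)
}

subject_ids <- function(samples) {
  s <- data.table::as.data.table(samples)
  s[s$role == "twin", ][["sample_id"]]
}

twin_columns <- function(samples) {
  s <- data.table::as.data.table(samples)
  s <- s[s$role == "twin"]
  data.table::setorderv(s, c("pair_id", "twin_index"))
  w <- data.table::dcast(s, pair_id ~ twin_index, value.var = "sample_id")
  data.table::setnames(w, c("pair_id", "twin1", "twin2"))
  w
}

#' Profile correlation within each twin pair
#'
#' Spearman correlation between the beta profiles of co-twins, across CpGs
#' (CpGs are the observations), using CpGs where both members are
#' non-missing.
#'
#' @param beta CpG x sample beta matrix.
#' @param samples sample sheet (pair_id, twin_index, role).
#' @param cpg_subset optional character vector of probe ids to restrict to
#'   (e.g. the most variable CpGs).
#' @return data.table: pair_id, rho, n_cpgs.
#' @export
pairwise_profile_rho <- function(beta, samples, cpg_subset = NULL) {
  tc <- twin_columns(samples)
  if (!is.null(cpg_subset)) {
    cpg_subset <- intersect(rownames(beta), cpg_subset)
    if (!length(cpg_subset)) {
      warning("empty CpG subset; profile correlations are missing")
      return(data.table::data.table(pair_id = tc$pair_id, rho = NA_real_,
                                    n_cpgs = 0L))
    }
    beta <- beta[cpg_subset, , drop = FALSE]
  }
  res <- lapply(seq_len(nrow(tc)), function(i) {
    x <- beta[, tc$twin1[i]]; y <- beta[, tc$twin2[i]]
    k <- !is.na(x) & !is.na(y)
    rho <- if (sum(k) >= 3)
      suppressWarnings(cor(x[k], y[k], method = "spearman")) else NA_real_
    data.table::data.table(pair_id = tc$pair_id[i], rho = rho,
                           n_cpgs = sum(k))
  })
  data.table::rbindlist(res)
}

#' Profile correlations between unrelated subjects
#'
#' Every subject-by-subject combination excluding self pairings and
#' co-twins (control replicates are not subjects).
#'
#' @inheritParams pairwise_profile_rho
#' @return list: `correlations` (data.table subject1, subject2, rho,
#'   n_cpgs), `mean`, `min`, `max`.
#' @export
unrelated_profile_rho <- function(beta, samples, cpg_subset = NULL) {
  s <- data.table::as.data.table(samples)
  s <- s[s$role == "twin"]
  if (length(unique(s$pair_id)) < 2) stop("need at least 2 twin pairs")
  if (!is.null(cpg_subset))
    beta <- beta[intersect(rownames(beta), cpg_subset), , drop = FALSE]
  ids <- s$sample_id
  cmb <- utils::combn(seq_along(ids), 2L)
  keep <- s$pair_id[cmb[1, ]] != s$pair_id[cmb[2, ]]
  cmb <- cmb[, keep, drop = FALSE]
  rho <- vapply(seq_len(ncol(cmb)), function(k) {
    x <- beta[, ids[cmb[1, k]]]; y <- beta[, ids[cmb[2, k]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(x[ok], y[ok], method = "spearman"))
  }, numeric(1))
  out <- data.table::data.table(subject1 = ids[cmb[1, ]],
                                subject2 = ids[cmb[2, ]], rho = rho)
  list(correlations = out, mean = mean(rho, na.rm = TRUE),
       min = suppressWarnings(min(rho, na.rm = TRUE)),
       max = suppressWarnings(max(rho, na.rm = TRUE)))
}

#' Cross-pair correlation per CpG
#'
#' For each CpG, the Spearman correlation between the beta value of twin 1
#' and of twin 2 across pairs (pairs are the observations); ties take
#' average ranks (Pearson on mid-ranks). The twin-1/twin-2 assignment is
#' read from the sample sheet; rank correlation is invariant to swapping
#' labels within any pair. CpGs with fewer than `min_pairs` complete pairs,
#' or with zero rank variance in either twin vector, are missing.
#'
#' @inheritParams pairwise_profile_rho
#' @param min_pairs minimum complete pairs per CpG (default 3).
#' @return data.table: probe_id, rho, n_pairs.
#' @export
cross_pair_rho <- function(beta, samples, min_pairs = 3L) {
  tc <- twin_columns(samples)
  A <- beta[, tc$twin1, drop = FALSE]
  B <- beta[, tc$twin2, drop = FALSE]
  n_ok <- rowSums(!(is.na(A) | is.na(B)))
  rho <- spearman_rows(A, B, min_n = min_pairs)
  rho[n_ok < min_pairs] <- NA_real_
  data.table::data.table(probe_id = rownames(beta), rho = rho,
                         n_pairs = as.integer(n_ok))
}

#' Stratified summaries of per-CpG twin correlations
#'
#' Summaries (count, percentage, mean / median / min / max of the
#' cross-pair rho) for all CpGs and for each gene-centric class, CpG-island
#' class, methylation class, and the island-by-methylation cross. CpGs with
#' missing rho are excluded; empty categories are omitted and listed in the
#' `omitted` attribute.
#'
#' @param stats per-CpG statistics from [cpg_stats()] merged with the rho
#'   column from [cross_pair_rho()] (or pass `rho` separately).
#' @param annotation per-CpG annotation from [annotate_cpgs()].
#' @param rho optional data.table (probe_id, rho) if `stats` lacks a rho
#'   column.
#' @param variable_only restrict to the most variable CpGs (default TRUE).
#' @return data.table: axis, category, n_cpgs, pct, mean_rho, median_rho,
#'   min_rho, max_rho.
#' @export
region_summaries <- function(stats, annotation, rho = NULL,
                             variable_only = TRUE) {
  st <- data.table::as.data.table(stats)
  if (!is.null(rho))
    st <- merge(st, data.table::as.data.table(rho)[, c("probe_id", "rho")],
                by = "probe_id")
  if (!"rho" %in% names(st))
    stop("stats must carry a rho column (or pass rho=)")
  d <- merge(st, data.table::as.data.table(annotation), by = "probe_id")
  if (variable_only) d <- d[d$most_variable %in% TRUE]
  d <- d[!is.na(d$rho)]
  if (!nrow(d)) stop("no CpGs with a defined cross-pair correlation")
  n_tot <- nrow(d)
  row1 <- function(axis, category, v) data.table::data.table(
    axis = axis, category = category, n_cpgs = length(v),
    pct = 100 * length(v) / n_tot,
    mean_rho = mean(v), median_rho = median(v),
    min_rho = min(v), max_rho = max(v))
  rows <- list(row1("all", "All CpGs", d$rho))
  omitted <- character()
  add_axis <- function(axis, labels, values) {
    for (lv in labels) {
      v <- d$rho[values == lv]
      if (!length(v)) omitted <<- c(omitted, paste(axis, lv, sep = ":"))
      else rows[[length(rows) + 1L]] <<- row1(axis, lv, v)
    }
  }
  add_axis("gene_region", gene_region_levels(), d$gene_region)
  add_axis("cgi_class", cgi_class_levels(), d$cgi_class)
  add_axis("meth_class", meth_class_levels(), d$meth_class)
  cross_lab <- paste(d$cgi_class, d$meth_class, sep = " / ")
  add_axis("cgi_x_meth",
           as.vector(outer(cgi_class_levels(), meth_class_levels(),
                           paste, sep = " / ")),
           cross_lab)
  out <- data.table::rbindlist(rows)
  attr(out, "omitted") <- omitted
  out
}

#' Imprinted-region CpG summary
#'
#' Restricts to CpGs in imprinted differentially methylated regions whose
#' mean methylation is in the intermediate range (the level expected when
#' one parental allele is methylated), and summarizes their cross-pair twin
#' correlation.
#'
#' @inheritParams region_summaries
#' @return data.table with one row: n_cpgs, n_genes, mean_rho, median_rho,
#'   min_rho, max_rho (zero row when no imprinted CpG qualifies).
#' @export
imprinted_subset_summary <- function(stats, annotation, rho = NULL) {
  st <- data.table::as.data.table(stats)
  if (!is.null(rho))
    st <- merge(st, data.table::as.data.table(rho)[, c("probe_id", "rho")],
                by = "probe_id")
  d <- merge(st, data.table::as.data.table(annotation), by = "probe_id")
  d <- d[!is.na(d$imprinted_gene) & d$meth_class %in% "intermediate"]
  d <- d[!is.na(d$rho)]
  if (!nrow(d))
    return(data.table::data.table(n_cpgs = 0L, n_genes = 0L,
                                  mean_rho = NA_real_, median_rho = NA_real_,
                                  min_rho = NA_real_, max_rho = NA_real_))
  data.table::data.table(
    n_cpgs = nrow(d), n_genes = length(unique(d$imprinted_gene)),
    mean_rho = mean(d$rho), median_rho = median(d$rho),
    min_rho = min(d$rho), max_rho = max(d$rho))
}

#' Two-tissue cell-composition check
#'
#' Using reference CpGs with known mean beta in the target tissue (buccal)
#' and a contaminating tissue (blood), estimates for each sample the mixing
#' weight `w` in `[0, 1]` minimizing the squared deviation of the observed
#' beta from `w * buccal + (1 - w) * blood` (closed-form projection,
#' clipped), and flags samples below `w_min`. This is a reconstruction of a
#' reference-based composition check, not a deconvolution against measured
#' reference panels.
#'
#' @param beta CpG x sample beta matrix.
#' @param reference data.frame: probe_id, buccal, blood (mean beta per
#'   tissue); at least 10 rows must intersect the beta matrix.
#' @param w_min flagging threshold on the buccal weight (default 0.8).
#' @return data.table: sample_id, w, flagged.
#' @export
cell_composition_check <- function(beta, reference, w_min = 0.8) {
  ref <- data.table::as.data.table(reference)
  ref <- ref[ref$probe_id %in% rownames(beta)]
  if (nrow(ref) < 10) stop("need at least 10 reference CpGs present in the beta matrix")
  bm <- beta[ref$probe_id, , drop = FALSE]
  dirv <- ref$buccal - ref$blood
  w <- vapply(seq_len(ncol(bm)), function(j) {
    obs <- bm[, j]
    ok <- !is.na(obs)
    if (sum(ok) < 10) return(NA_real_)
    ww <- sum((obs[ok] - ref$blood[ok]) * dirv[ok]) / sum(dirv[ok]^2)
    min(1, max(0, ww))
  }, numeric(1))
  data.table::data.table(sample_id = colnames(bm), w = w,
                         flagged = !is.na(w) & w < w_min)
}

#' Sensitivity re-run excluding flagged pairs
#'
#' Recomputes per-CpG statistics, cross-pair correlations and the
#' stratified summaries after dropping entire twin pairs (e.g. pairs whose
#' members were flagged by [cell_composition_check()]).
#'
#' @param beta CpG x sample beta matrix.
#' @param samples sample sheet.
#' @param annotation per-CpG annotation.
#' @param exclude_pairs character vector of pair ids to drop.
#' @param ... passed to [cpg_stats()].
#' @return list: samples (retained sheet), stats, rho, summaries.
#' @export
sensitivity_excluding_pairs <- function(beta, samples, annotation,
                                        exclude_pairs, ...) {
  s <- data.table::as.data.table(samples)
  keep <- s[!(s$role == "twin" & s$pair_id %in% exclude_pairs)]
  if (length(unique(keep$pair_id[keep$role == "twin"])) < 3)
    stop("fewer than 3 twin pairs would remain")
  st <- cpg_stats(beta, keep, ...)
  rh <- cross_pair_rho(beta, keep)
  list(samples = keep, stats = st, rho = rh,
       summaries = region_summaries(st, annotation, rho = rh))
}
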