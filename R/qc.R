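#' Quality-control thresholds
#'
#' @param detection_p_max maximum detection p-value for a cell to count as
#'   detected (default 0.01).
#' @param bead_count_min minimum beads per probe per sample (default 3;
#'   cells below are set missing).
#' @param probe_success_min minimum cross-sample success rate for a probe to
#'   survive (default 0.95).
#' @param ambiguous_overlap_bases documentation of the ambiguity definition
#'   used by the manifest flag (an alignment overlap of at least this many
#'   bases to a second locus); the flag itself comes from the manifest.
#' @param cluster_sd_min minimum beta SD for a probe to enter the sample
#'   clustering check (default 0.10).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(detection_p_max = 0.01, bead_count_min = 3L,
                          probe_success_min = 0.95,
                          ambiguous_overlap_bases = 47L,
                          cluster_sd_min = 0.10) {
  stopifnot(detection_p_max >= 0, detection_p_max <= 1,
            bead_count_min >= 0, probe_success_min >= 0,
            probe_success_min <= 1, cluster_sd_min >= 0)
  structure(list(detection_p_max = detection_p_max,
                 bead_count_min = bead_count_min,
                 probe_success_min = probe_success_min,
                 ambiguous_overlap_bases = ambiguous_overlap_bases,
                 cluster_sd_min = cluster_sd_min),
            class = "qc_thresholds")
}

#' Detection p-values from negative-control probes
#'
#' For each sample, the background of each channel is summarized by the mean
#' and SD of the negative-control intensities; a probe's detection p-value is
#' the upper-tail probability of its observed total signal (meth + unmeth)
#' under Normal(mu_M + mu_U, sqrt(sd_M^2 + sd_U^2)).
#'
#' @param signal long signal table (probe_id, sample_id, meth, unmeth).
#' @param negcontrols long table of negative-control rows, same columns.
#' @param min_controls minimum negative-control rows required per sample.
#' @return numeric matrix of p-values, probes x samples.
#' @export
detection_pvalue <- function(signal, negcontrols, min_controls = 20L) {
  sm <- signal_matrices(signal)
  neg <- data.table::as.data.table(negcontrols)
  bgn <- neg[, .(n = .N, mu_m = mean(meth), sd_m = sd(meth),
                 mu_u = mean(unmeth), sd_u = sd(unmeth)), by = sample_id]
  missing_smp <- setdiff(sm$samples, bgn$sample_id)
  short <- c(missing_smp, bgn[n < min_controls, sample_id])
  if (length(short))
    stop("fewer than ", min_controls, " negative-control probes for sample(s): ",
         paste(short, collapse = ", "))
  data.table::setkey(bgn, sample_id)
  total <- sm$meth + sm$unmeth
  p <- matrix(NA_real_, nrow(total), ncol(total), dimnames = dimnames(total))
  for (j in seq_along(sm$samples)) {
    b <- bgn[sm$samples[j]]
    p[, j] <- pnorm(total[, j], mean = b$mu_m + b$mu_u,
                    sd = sqrt(b$sd_m^2 + b$sd_u^2), lower.tail = FALSE)
  }
  p
}

#' Per-sample overall signal diagnostics
#'
#' Compares each sample's median methylated and unmethylated CpG-probe
#' intensities to the median background from negative controls. A sample
#' passes when its median total CpG signal exceeds the median background.
#'
#' @inheritParams detection_pvalue
#' @return data.table: sample_id, median_meth, median_unmeth,
#'   median_cpg_signal, background_median, pass.
#' @export
sample_signal_check <- function(signal, negcontrols) {
  s <- data.table::as.data.table(signal)
  neg <- data.table::as.data.table(negcontrols)
  d <- s[, .(median_meth = median(meth, na.rm = TRUE),
             median_unmeth = median(unmeth, na.rm = TRUE),
             median_cpg_signal = median(meth + unmeth, na.rm = TRUE)),
         by = sample_id]
  b <- neg[, .(background_median = median((meth + unmeth) / 2, na.rm = TRUE)),
           by = sample_id]
  out <- merge(d, b, by = "sample_id", all.x = TRUE)
  out[, pass := !is.na(median_cpg_signal) & !is.na(background_median) &
        median_cpg_signal > background_median]
  out[]
}

#' Probe-level filtering
#'
#' Applies, in a fixed documented order: (1) drop manifest-flagged
#' ambiguously mapped probes in all samples; (2) drop probes with a SNP at
#' the CpG (C or G position) in all samples, irrespective of allele
#' frequency; (3) per sample, set to missing cells with zero intensity,
#' detection p-value above `detection_p_max`, or bead count below
#' `bead_count_min`; (4) drop probes whose cross-sample success rate falls
#' below `probe_success_min`; (5) compute per-sample success rates over the
#' surviving probes. The order matters for the success-rate denominators and
#' is part of the contract.
#'
#' @param signal long signal table of CpG probes.
#' @param manifest probe manifest covering every probe in `signal`.
#' @param detp detection p-value matrix from [detection_pvalue()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `signal` (list of meth/unmeth/beads matrices with
#'   missing cells set to NA, restricted to surviving probes) and `report`
#'   (a `qc_report`: per-stage accounting, per-sample success rates,
#'   surviving probe ids).
#' @export
filter_probes <- function(signal, manifest, detp, thresholds = qc_thresholds()) {
  sm <- signal_matrices(signal)
  man <- data.table::as.data.table(manifest)
  missing_probes <- setdiff(sm$probes, man$probe_id)
  if (length(missing_probes))
    stop("probes present in signal but absent from manifest: ",
         paste(utils::head(missing_probes, 10), collapse = ", "),
         if (length(missing_probes) > 10) ", ...")
  man <- man[match(sm$probes, probe_id)]
  stopifnot(all(rownames(detp) == sm$probes),
            all(colnames(detp) == sm$samples))
  th <- thresholds
  n0 <- length(sm$probes)

  keep1 <- !man$ambiguous
  n_ambiguous <- sum(!keep1)
  keep2 <- keep1 & !man$snp_at_cpg
  n_snp <- sum(keep1) - sum(keep2)

  meth <- sm$meth[keep2, , drop = FALSE]
  unmeth <- sm$unmeth[keep2, , drop = FALSE]
  beads <- sm$beads[keep2, , drop = FALSE]
  dp <- detp[keep2, , drop = FALSE]

  zero_cell <- (meth == 0 | unmeth == 0)
  detfail_cell <- dp > th$detection_p_max
  bead_cell <- beads < th$bead_count_min
  bad <- zero_cell | detfail_cell | bead_cell
  bad[is.na(bad)] <- TRUE
  meth[bad] <- NA_real_
  unmeth[bad] <- NA_real_
  beads[bad] <- NA_real_

  success <- rowMeans(!bad)
  keep3 <- success >= th$probe_success_min
  n_success <- sum(!keep3)

  meth <- meth[keep3, , drop = FALSE]
  unmeth <- unmeth[keep3, , drop = FALSE]
  beads <- beads[keep3, , drop = FALSE]
  surviving <- rownames(meth)

  sample_success <- colMeans(!bad[keep3, , drop = FALSE])
  report <- structure(list(
    stages = data.table::data.table(
      stage = c("input", "ambiguous_mapping", "snp_at_cpg", "success_rate"),
      removed = c(0L, n_ambiguous, n_snp, n_success),
      remaining = c(n0, n0 - n_ambiguous, n0 - n_ambiguous - n_snp,
                    length(surviving))),
    cells = data.table::data.table(
      reason = c("zero_intensity", "detection_p", "low_beads"),
      n_cells = c(sum(zero_cell, na.rm = TRUE),
                  sum(detfail_cell & !zero_cell, na.rm = TRUE),
                  sum(bead_cell & !zero_cell & !detfail_cell, na.rm = TRUE))),
    sample_success = data.table::data.table(
      sample_id = colnames(meth), success_rate = as.numeric(sample_success)),
    surviving_probes = surviving,
    thresholds = th,
    bisulfite_conversion = "not assessed (no conversion-control chemistry in input)"
  ), class = "qc_report")

  list(signal = list(meth = meth, unmeth = unmeth, beads = beads,
                     probes = surviving, samples = sm$samples),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Probe QC accounting:\n")
  print(x$stages)
  cat("\nCells set missing:\n")
  print(x$cells)
  cat(sprintf("\nPer-sample success rate: %.4f-%.4f\n",
              min(x$sample_success$success_rate),
              max(x$sample_success$success_rate)))
  invisible(x)
}

#' Sample clustering check
#'
#' Clusters samples by complete linkage on the distance
#' `d = sqrt(2 (1 - r))` derived from pairwise sample correlations `r`
#' (the Euclidean distance between standardized methylation profiles),
#' computed over autosomal, SNP-free probes with beta SD above
#' `cluster_sd_min`. Flags, for each sample, whether the sister branch at
#' its first merge consists entirely of samples from its own pair (or of
#' fellow control replicates).
#'
#' @param beta beta matrix (CpG x sample).
#' @param manifest probe manifest (chrom, snp_at_cpg).
#' @param samples sample sheet (pair_id per sample).
#' @param thresholds a [qc_thresholds()].
#' @param distance `"transform"` (default) converts each correlation,
#'   `"corvec"` treats each sample's vector of correlations as coordinates
#'   and takes Euclidean distances between those vectors.
#' @return list: `hclust` (stats::hclust tree), `dist` (matrix),
#'   `first_merge` (data.table: sample_id, partners, co_twin_first),
#'   `n_probes_used`.
#' @export
sample_cluster_qc <- function(beta, manifest, samples,
                              thresholds = qc_thresholds(),
                              distance = c("transform", "corvec")) {
  distance <- match.arg(distance)
  if (ncol(beta) < 3) stop("sample clustering needs at least 3 samples")
  man <- data.table::as.data.table(manifest)
  man <- man[match(rownames(beta), probe_id)]
  auto <- !(man$chrom %in% c("chrX", "chrY", "X", "Y")) & !man$snp_at_cpg
  sds <- apply(beta, 1L, sd, na.rm = TRUE)
  use <- auto & !is.na(sds) & sds > thresholds$cluster_sd_min
  if (!any(use)) stop("no probes pass the clustering SD filter")
  r <- cor(beta[use, , drop = FALSE], use = "pairwise.complete.obs")
  d <- if (distance == "transform") sqrt(pmax(2 * (1 - r), 0))
       else as.matrix(stats::dist(r))
  hc <- stats::hclust(stats::as.dist(d), method = "complete")

  grp <- samples$pair_id[match(colnames(beta), samples$sample_id)]
  fm <- first_merge_partners(hc)
  partners_ok <- vapply(seq_along(hc$labels), function(i) {
    sib <- fm[[i]]
    length(sib) > 0 && all(grp[sib] == grp[i])
  }, logical(1))
  list(hclust = hc, dist = d,
       first_merge = data.table::data.table(
         sample_id = hc$labels,
         partners = vapply(fm, function(ix) paste(hc$labels[ix], collapse = ","),
                           character(1)),
         co_twin_first = partners_ok),
       n_probes_used = sum(use))
}

# For each leaf, the set of leaves in the sister cluster at its first merge.
first_merge_partners <- function(hc) {
  n <- length(hc$labels)
  members <- function(node) {
    if (node < 0) return(-node)
    unlist(lapply(hc$merge[node, ], members))
  }
  out <- vector("list", n)
  for (step in seq_len(nrow(hc$merge))) {
    a <- hc$merge[step, 1]; b <- hc$merge[step, 2]
    la <- members(a); lb <- members(b)
    for (i in la) if (is.null(out[[i]])) out[[i]] <- lb
    for (i in lb) if (is.null(out[[i]])) out[[i]] <- la
  }
  out
}

#' Export a clustering tree in Newick format
#'
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
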