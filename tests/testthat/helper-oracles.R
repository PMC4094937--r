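# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::cor for rank correlations) so that
# agreement is a real cross-check.

# Spearman as Pearson on average ranks, written out from the product-moment
# formula.
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(rx)
  sxy <- sum(rx * ry) - n * mean(rx) * mean(ry)
  sxx <- sum(rx^2) - n * mean(rx)^2
  syy <- sum(ry^2) - n * mean(ry)^2
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# Per-base gene-region classification: for one position, scan every gene and
# apply the window rules and precedence literally.
oracle_gene_region <- function(pos, chrom, genes) {
  prec <- c(proximal_promoter = 1, distal_promoter = 2, gene_body = 3,
            downstream = 4)
  best <- NULL
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    sgn <- if (genes$strand[i] == "+") 1 else -1
    d <- (pos - genes$tss[i]) * sgn
    len <- abs(genes$end3[i] - genes$tss[i])
    lab <- if (d >= -1500 && d <= 500) "proximal_promoter"
      else if (d >= -10000 && d < -1500) "distal_promoter"
      else if (d > 500 && d <= len) "gene_body"
      else if (d > len && d <= len + 5000) "downstream"
      else next
    cand <- list(lab = lab, ad = abs(d), id = genes$gene_id[i])
    if (is.null(best) ||
        prec[[cand$lab]] < prec[[best$lab]] ||
        (prec[[cand$lab]] == prec[[best$lab]] && cand$ad < best$ad) ||
        (prec[[cand$lab]] == prec[[best$lab]] && cand$ad == best$ad &&
         cand$id < best$id))
      best <- cand
  }
  if (is.null(best)) "intergenic" else best$lab
}

# Per-base CGI classification against merged islands by literal distance.
oracle_cgi_class <- function(pos, chrom, cgi) {
  dmin <- Inf
  for (i in seq_len(nrow(cgi))) {
    if (cgi$chrom[i] != chrom) next
    d <- if (pos >= cgi$start[i] && pos <= cgi$end[i]) 0
         else min(abs(pos - cgi$start[i]), abs(pos - cgi$end[i]))
    dmin <- min(dmin, d)
  }
  if (dmin == 0) "CGI"
  else if (dmin <= 2000) "shore"
  else if (dmin <= 4000) "shelf"
  else "nonCGI"
}

# Literal per-cell re-check of every probe-filter rule, in the documented
# order, over plain matrices.
oracle_filter <- function(meth, unmeth, beads, detp, ambiguous, snp, th) {
  keep <- !ambiguous & !snp
  ids <- rownames(meth)[keep]
  ok <- matrix(NA, length(ids), ncol(meth), dimnames = list(ids, colnames(meth)))
  for (i in ids) for (j in colnames(meth)) {
    m <- meth[i, j]; u <- unmeth[i, j]; b <- beads[i, j]; p <- detp[i, j]
    ok[i, j] <- !(is.na(m) || is.na(u) || m == 0 || u == 0 ||
                  p > th$detection_p_max || b < th$bead_count_min)
  }
  surv <- ids[rowMeans(ok) >= th$probe_success_min]
  list(surviving = surv, ok = ok)
}

# Kolmogorov-Smirnov distance between two samples (sup over the pooled
# support of the ecdf gap).
ks_distance <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

# Members (leaf indices) of the cluster created at each hclust merge step.
hclust_members <- function(hc) {
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    grab <- function(k) if (k < 0) -k else out[[k]]
    out[[s]] <- c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2]))
  }
  out
}
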