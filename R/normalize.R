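#' Quantile normalization of signal intensities
#'
#' Background and colour adjustment: the methylated and unmethylated
#' channels are quantile-normalized separately across samples, within each
#' probe-design-type stratum (Type I and Type II bead chemistries are never
#' mixed). After normalization every sample's sorted channel vector equals
#' the cross-sample mean of sorted vectors, and ranks within each sample are
#' preserved. Missing cells stay missing; any negative adjusted intensity is
#' clipped to 0.
#'
#' @param signal filtered signal (list with meth/unmeth matrices, probes,
#'   samples) as returned by [filter_probes()]`$signal`, or a long table.
#' @param manifest probe manifest carrying `probe_type`.
#' @return the same structure with adjusted meth / unmeth matrices.
#' @export
quantile_normalize <- function(signal, manifest) {
  if (is.data.frame(signal)) signal <- signal_matrices(signal)
  if (length(signal$samples) < 2) stop("quantile normalization needs >= 2 samples")
  all_missing <- colSums(!is.na(signal$meth)) == 0 |
    colSums(!is.na(signal$unmeth)) == 0
  if (any(all_missing))
    stop("sample(s) with all-missing intensities: ",
         paste(signal$samples[all_missing], collapse = ", "))
  man <- data.table::as.data.table(manifest)
  type <- man$probe_type[match(signal$probes, man$probe_id)]
  type[is.na(type)] <- "unknown"
  out <- signal
  for (tp in unique(type)) {
    rows <- type == tp
    for (ch in c("meth", "unmeth")) {
      x <- signal[[ch]][rows, , drop = FALSE]
      if (nrow(x) < 2) next
      out[[ch]][rows, ] <- pmax(0, limma::normalizeQuantiles(x, ties = TRUE))
    }
  }
  out
}

#' Methylation fraction (beta-value) from channel intensities
#'
#' `beta = meth / (meth + unmeth + offset)`, with the offset (default 100)
#' keeping probes with near-zero overall signal close to 0 rather than
#' undefined; beta lies in `[0, 1)`.
#'
#' @param meth,unmeth non-negative intensities (vectors or matrices of equal
#'   shape).
#' @param offset stabilizing constant added to the denominator.
#' @return beta values with the shape of the inputs; NA where either input
#'   is NA.
#' @export
compute_beta <- function(meth, unmeth, offset = 100) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("negative intensities: clip post-normalization values at 0 upstream")
  meth / (meth + unmeth + offset)
}

#' M-value from channel intensities
#'
#' `M = log2((meth + offset) / (unmeth + offset))` (intensity-ratio form,
#' offset default 1). `logit2 = TRUE` instead returns `log2(beta/(1-beta))`
#' computed from the offset-100 beta, the transform inherited from the
#' beta definition.
#'
#' @inheritParams compute_beta
#' @param logit2 use the logit2-of-beta form instead of the intensity ratio.
#' @return M-values, finite for all non-missing cells.
#' @export
compute_mvalue <- function(meth, unmeth, offset = 1, logit2 = FALSE) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("negative intensities: clip post-normalization values at 0 upstream")
  if (logit2) {
    b <- compute_beta(meth, unmeth)
    log2(pmax(b, 1e-12) / pmax(1 - b, 1e-12))
  } else {
    log2((meth + offset) / (unmeth + offset))
  }
}

#' Beta matrix from a normalized signal object
#'
#' @param signal list with meth/unmeth matrices.
#' @param offset passed to [compute_beta()].
#' @return CpG x sample beta matrix with attribute `bmiq = FALSE`.
#' @export
beta_matrix <- function(signal, offset = 100) {
  b <- compute_beta(signal$meth, signal$unmeth, offset)
  attr(b, "bmiq") <- FALSE
  b
}

#' M-value matrix from a normalized signal object
#'
#' @param signal list with meth/unmeth matrices.
#' @param offset,logit2 passed to [compute_mvalue()].
#' @return CpG x sample M-value matrix.
#' @export
mvalue_matrix <- function(signal, offset = 1, logit2 = FALSE) {
  compute_mvalue(signal$meth, signal$unmeth, offset, logit2)
}
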