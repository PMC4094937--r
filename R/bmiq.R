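#' Beta-mixture quantile harmonization of probe chemistries (BMIQ)
#'
#' The two 450k bead chemistries yield systematically different beta
#' distributions: Type II probes have a compressed dynamic range. Per
#' sample, a three-state (unmethylated / hemimethylated / methylated) beta
#' mixture is fitted to the Type I and Type II beta values separately; Type
#' II values in the unmethylated and methylated states are re-expressed by
#' quantile-mapping their state distribution onto the corresponding Type I
#' state fit, and hemimethylated values are rescaled linearly between the
#' two mapped state boundaries. Type I values are never altered, output
#' stays in `[0, 1]`, and the map is monotone within each sample's Type II
#' set. If a mixture fit fails to converge within `max_iter` EM iterations
#' (or yields a degenerate state ordering), that sample falls back to a
#' rank-based quantile mapping of Type II onto Type I, which is recorded.
#'
#' @param beta CpG x sample beta matrix.
#' @param manifest probe manifest carrying `probe_type` for every row of
#'   `beta`.
#' @param max_iter EM iteration cap per mixture fit.
#' @param tol relative log-likelihood convergence tolerance.
#' @param init_thresholds two beta cutpoints used to initialize the three
#'   states.
#' @return adjusted beta matrix with attributes `bmiq = TRUE` and
#'   `bmiq_fallback` (character vector of samples that used the rank-based
#'   fallback).
#' @export
bmiq_adjust <- function(beta, manifest, max_iter = 300L, tol = 1e-6,
                        init_thresholds = c(0.25, 0.75)) {
  man <- data.table::as.data.table(manifest)
  type <- man$probe_type[match(rownames(beta), man$probe_id)]
  i1 <- which(type == "I"); i2 <- which(type == "II")
  if (!length(i1) || !length(i2))
    stop("BMIQ needs both Type I and Type II probes")
  out <- beta
  fallback <- character()
  for (j in seq_len(ncol(beta))) {
    b1 <- beta[i1, j]; b2 <- beta[i2, j]
    ok2 <- which(!is.na(b2))
    v1 <- b1[!is.na(b1)]; v2 <- b2[ok2]
    if (length(v1) < 50 || length(v2) < 50)
      stop("too few non-missing Type I/II probes in sample ", colnames(beta)[j])
    mapped <- bmiq_map_sample(v1, v2, max_iter, tol, init_thresholds)
    if (is.null(mapped)) {
      mapped <- rank_map(v2, v1)
      fallback <- c(fallback, colnames(beta)[j])
    }
    out[i2[ok2], j] <- pmin(1, pmax(0, mapped))
  }
  attr(out, "bmiq") <- TRUE
  attr(out, "bmiq_fallback") <- fallback
  out
}

# Map type II values onto the type I mixture; NULL on any degeneracy.
bmiq_map_sample <- function(v1, v2, max_iter, tol, init) {
  f1 <- fit_beta_mixture(v1, init, max_iter, tol)
  f2 <- fit_beta_mixture(v2, init, max_iter, tol)
  if (is.null(f1) || is.null(f2)) return(NULL)
  # state membership of type II values, forced contiguous via cutpoints
  resp <- mixture_responsibilities(v2, f2)
  cls <- max.col(resp)
  if (!all(1:3 %in% cls)) return(NULL)
  c1 <- max(v2[cls == 1]); c2 <- min(v2[cls == 3])
  if (!(c1 < c2)) return(NULL)
  map_state <- function(x, k) {
    p <- pbeta(x, f2$shape1[k], f2$shape2[k])
    p <- pmin(1 - 1e-12, pmax(1e-12, p))
    qbeta(p, f1$shape1[k], f1$shape2[k])
  }
  uU <- map_state(c1, 1L)
  mM <- map_state(c2, 3L)
  if (!(uU < mM)) return(NULL)
  y <- numeric(length(v2))
  lo <- v2 <= c1; hi <- v2 >= c2; mid <- !lo & !hi
  y[lo] <- map_state(v2[lo], 1L)
  y[hi] <- map_state(v2[hi], 3L)
  y[mid] <- uU + (v2[mid] - c1) / (c2 - c1) * (mM - uU)
  y
}

# Monotone empirical-quantile fallback: map each type II value to the type I
# quantile of its own rank.
rank_map <- function(v2, v1) {
  p <- rank(v2, ties.method = "average") / (length(v2) + 1)
  as.numeric(stats::quantile(v1, probs = p, type = 7, na.rm = TRUE))
}

#' Fit a three-state beta mixture by EM with moment-matching updates
#'
#' States are initialized by thresholding at `init` (default 0.25 / 0.75)
#' and updated by weighted method-of-moments; convergence is declared when
#' the relative log-likelihood change drops below `tol`. Values are clamped
#' to (0, 1) before fitting. Components are returned ordered by mean
#' (unmethylated, hemimethylated, methylated).
#'
#' @param x beta values.
#' @param init two cutpoints for initialization.
#' @param max_iter,tol EM controls.
#' @return list(weights, shape1, shape2, loglik, iterations, converged), or
#'   NULL when the fit degenerates or fails to converge.
#' @export
fit_beta_mixture <- function(x, init = c(0.25, 0.75), max_iter = 300L,
                             tol = 1e-6) {
  x <- pmin(1 - 1e-6, pmax(1e-6, x[!is.na(x)]))
  n <- length(x)
  cls <- 1L + (x > init[1]) + (x > init[2])
  resp <- matrix(0, n, 3L)
  resp[cbind(seq_len(n), cls)] <- 1
  fit <- NULL
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    w <- colSums(resp)
    if (any(w < 3)) return(NULL)
    wts <- w / n
    mu <- colSums(resp * x) / w
    vv <- colSums(resp * (x - rep(mu, each = n))^2) / w
    vv <- pmax(vv, 1e-6)
    common <- mu * (1 - mu) / vv - 1
    common <- pmax(common, 0.1)
    a <- pmax(mu * common, 0.05)
    b <- pmax((1 - mu) * common, 0.05)
    dens <- vapply(1:3, function(k) wts[k] * dbeta(x, a[k], b[k]), numeric(n))
    tot <- rowSums(dens)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    fit <- list(weights = wts, shape1 = a, shape2 = b, loglik = ll,
                iterations = it, converged = FALSE)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      fit$converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (is.null(fit) || !fit$converged) return(NULL)
  ord <- order(fit$shape1 / (fit$shape1 + fit$shape2))
  list(weights = fit$weights[ord], shape1 = fit$shape1[ord],
       shape2 = fit$shape2[ord], loglik = fit$loglik,
       iterations = fit$iterations, converged = TRUE)
}

mixture_responsibilities <- function(x, fit) {
  x <- pmin(1 - 1e-6, pmax(1e-6, x))
  dens <- vapply(1:3, function(k)
    fit$weights[k] * dbeta(x, fit$shape1[k], fit$shape2[k]),
    numeric(length(x)))
  dens / pmax(rowSums(dens), .Machine$double.xmin)
}
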