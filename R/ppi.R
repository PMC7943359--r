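#' ROI time series container
#'
#' @param series numeric BOLD series (one value per volume).
#' @param tr sampling interval in seconds.
#' @export
roi_timeseries <- function(series, tr) {
  stopifnot(is.numeric(series), tr > 0)
  structure(list(series = as.numeric(series), tr = tr),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series: ", length(x$series), " volumes, TR ", x$tr, " s\n",
      sep = "")
  invisible(x)
}

#' Mean BOLD time course of a seed region
#'
#' Volume-wise mean over all in-mask voxels.
#'
#' @param bold 4-D array (x, y, z, time) or `n_volumes x n_voxels` matrix.
#' @param mask logical 3-D array (or voxel vector) selecting the region.
#' @param tr sampling interval in seconds.
#' @return A [roi_timeseries()].
#' @export
seed_timecourse <- function(bold, mask, tr = 2) {
  if (is.array(bold) && length(dim(bold)) == 4) {
    d <- dim(bold)
    bold <- t(matrix(bold, prod(d[1:3]), d[4]))
    mask <- as.vector(mask)
  }
  mask <- as.logical(mask)
  if (sum(mask) == 0) stop("empty seed mask")
  roi_timeseries(rowMeans(as.matrix(bold)[, mask, drop = FALSE]), tr)
}

#' Deconvolve a BOLD series to the neural level
#'
#' Ridge-regularized least-squares inversion of the HRF convolution:
#' `neural = (K'K + lambda * I)^-1 K'y` where `K` is the lower-triangular
#' convolution matrix of the gamma-variate kernel and
#' `lambda = ridge * trace(K'K) / T` (trace-normalized penalty).
#' Reconvolving the estimate approximates the input; the residual vanishes
#' as `ridge -> 0` on noiseless data.
#'
#' @param ts a [roi_timeseries()] (or numeric series).
#' @param params an [hrf_params()].
#' @param ridge regularization fraction.
#' @param tr sampling interval when `ts` is a bare numeric series.
#' @return Numeric neural-level series of the same length.
#' @export
deconvolve <- function(ts, params = hrf_params(), ridge = 1e-3, tr = NULL) {
  if (inherits(ts, "roi_timeseries")) {
    y <- ts$series
    tr <- ts$tr
  } else {
    y <- as.numeric(ts)
    if (is.null(tr)) stop("supply 'tr' for a bare series")
  }
  k <- gamma_hrf(params, tr)
  if (all(k == 0)) stop("all-zero HRF kernel")
  if (length(k) >= length(y)) k <- k[seq_len(length(y) - 1)]
  K <- convolution_matrix(k, length(y))
  KtK <- crossprod(K)
  lambda <- ridge * sum(diag(KtK)) / length(y)
  drop(solve(KtK + diag(lambda, length(y)), crossprod(K, y)))
}

#' Build the three-predictor PPI design
#'
#' The psychophysiological interaction design holds the seed BOLD time
#' course, the psychological condition regressor (masked = -1,
#' unmasked = +1 at volume resolution) and the interaction term: the
#' deconvolved (neural-level) seed multiplied by the condition and
#' reconvolved with the HRF. `interaction_level = "bold"` instead forms the
#' product directly on the BOLD series.
#'
#' @param seed_ts a [roi_timeseries()] for the seed region.
#' @param condition per-volume -1/+1 masking regressor.
#' @param params an [hrf_params()].
#' @param ridge deconvolution regularization.
#' @param interaction_level `"neural"` (deconvolve, multiply, reconvolve)
#'   or `"bold"` (multiply the BOLD series directly).
#' @return Object of class `"ppi_design"`: design matrix with columns
#'   `seed`, `condition`, `ppi` (plus intercept at fit time).
#' @export
build_ppi_design <- function(seed_ts, condition, params = hrf_params(),
                             ridge = 1e-3,
                             interaction_level = c("neural", "bold")) {
  interaction_level <- match.arg(interaction_level)
  stopifnot(inherits(seed_ts, "roi_timeseries"))
  if (!all(condition %in% c(-1, 1))) {
    stop("condition must be coded masked = -1, unmasked = +1")
  }
  if (length(condition) != length(seed_ts$series)) {
    stop("condition must have one value per volume")
  }
  if (interaction_level == "neural") {
    neural <- deconvolve(seed_ts, params, ridge)
    k <- gamma_hrf(params, seed_ts$tr)
    inter <- convolve_series(neural * condition, k)
  } else {
    inter <- seed_ts$series * condition
  }
  X <- cbind(seed = seed_ts$series, condition = condition, ppi = inter)
  if (qr(cbind(1, X))$rank < 4) {
    stop("collinear PPI design (is the condition regressor constant?)")
  }
  structure(list(X = X, tr = seed_ts$tr,
                 interaction_level = interaction_level),
            class = "ppi_design")
}

#' Fit the PPI model to target series
#'
#' Per-target ordinary least squares of the target BOLD on the
#' three-predictor PPI design (plus intercept); the coefficient of record
#' is the interaction (`ppi`) beta.
#'
#' @param target a [roi_timeseries()], numeric series, or
#'   `n_volumes x n_targets` matrix.
#' @param design a [build_ppi_design()].
#' @return Object of class `"ppi_fit"`: `betas` (named vector, or matrix
#'   for multiple targets) and `interaction_beta`.
#' @export
fit_ppi <- function(target, design) {
  stopifnot(inherits(design, "ppi_design"))
  y <- if (inherits(target, "roi_timeseries")) target$series else target
  Y <- as.matrix(y)
  X <- cbind(`(Intercept)` = 1, design$X)
  if (nrow(Y) != nrow(X)) stop("target length does not match design")
  B <- solve(crossprod(X), crossprod(X, Y))
  betas <- if (ncol(Y) == 1) drop(B) else B
  interaction <- if (ncol(Y) == 1) betas["ppi"] else B["ppi", ]
  structure(list(betas = betas, interaction_beta = unname(interaction)),
            class = "ppi_fit")
}

#' @export
print.ppi_fit <- function(x, digits = 3, ...) {
  cat("PPI fit: interaction beta = ",
      paste(round(x$interaction_beta, digits), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Link connectivity disruption to representational disruption
#'
#' Pearson correlation between per-subject PPI interaction betas and
#' per-subject \[unmasked - masked\] RSA beta difference scores, with the
#' one-tailed p for the directional hypothesis r > 0.
#'
#' @param ppi_betas per-subject (region-averaged) PPI interaction betas.
#' @param rsa_diff per-subject unmasked-minus-masked RSA beta differences.
#' @return Object of class `"link_result"`: `r`, `df`, one-tailed `p`, `n`.
#' @export
link_connectivity_representation <- function(ppi_betas, rsa_diff) {
  if (length(ppi_betas) != length(rsa_diff)) stop("inputs must be paired")
  n <- length(ppi_betas)
  if (n < 3) stop("need at least 3 subjects")
  if (stats::sd(ppi_betas) == 0 || stats::sd(rsa_diff) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(ppi_betas, rsa_diff)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  structure(list(r = r, df = n - 2,
                 p = stats::pt(tt, n - 2, lower.tail = FALSE), n = n),
            class = "link_result")
}

#' @export
print.link_result <- function(x, digits = 3, ...) {
  cat("Connectivity-representation link: r(", x$df, ") = ",
      round(x$r, digits), ", one-tailed p = ", signif(x$p, digits), "\n",
      sep = "")
  invisible(x)
}
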