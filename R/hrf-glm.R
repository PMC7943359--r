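#' Gamma-variate HRF parameters
#'
#' The gamma-variate hemodynamic response
#' `h(t) = (t / (p * q))^p * exp(p - t / q)` for `t >= 0`, which has unit
#' peak at `t = p * q` seconds. Defaults `p = 8.6`, `q = 0.547` s are the
#' conventional gamma-variate values (peak about 4.7 s).
#'
#' @param p shape parameter (> 0).
#' @param q scale parameter in seconds (> 0).
#' @param length_s kernel length in seconds.
#' @export
hrf_params <- function(p = 8.6, q = 0.547, length_s = 20) {
  if (p <= 0 || q <= 0 || length_s <= 0) stop("HRF parameters must be positive")
  structure(list(p = p, q = q, length_s = length_s), class = "hrf_params")
}

#' Sample the gamma-variate HRF kernel
#'
#' @param params an [hrf_params()].
#' @param dt sampling interval in seconds (e.g. the TR).
#' @return Numeric kernel sampled at `t = 0, dt, 2*dt, ...`; `h(0) = 0`,
#'   all entries non-negative, unit analytic peak.
#' @export
gamma_hrf <- function(params = hrf_params(), dt) {
  stopifnot(inherits(params, "hrf_params"), dt > 0)
  t <- seq(0, params$length_s, by = dt)
  h <- (t / (params$p * params$q))^params$p * exp(params$p - t / params$q)
  h[t == 0] <- 0
  h
}

# causal discrete convolution of a series with a kernel, truncated to the
# series length (kernel[1] aligned with the current sample)
convolve_series <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_along(kernel)) {
    if (kernel[k] == 0) next
    idx <- k:n
    out[idx] <- out[idx] + kernel[k] * x[seq_len(n - k + 1)]
  }
  out
}

# lower-triangular Toeplitz convolution matrix (T x T) of a kernel
convolution_matrix <- function(kernel, n) {
  K <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    if (k > n) break
    idx <- cbind(k:n, seq_len(n - k + 1))
    K[idx] <- kernel[k]
  }
  K
}

#' Build a GLM design matrix from an event schedule
#'
#' Condition regressors are event boxcars (duration 2000 ms by design)
#' convolved with the gamma-variate HRF at an oversampled time grid and
#' sampled back at the TR. Two crossing schemes are supported: the four
#' crossed conditions (angry_male, ...) or the four non-crossed categories
#' (angry, happy, male, female; each face event then loads on two columns).
#' Nuisance regressors are appended as supplied.
#'
#' @param schedule event table (columns `onset`, `duration`, `condition`);
#'   typically one run of [make_schedule()].
#' @param n_volumes number of volumes in the run.
#' @param tr repetition time in seconds.
#' @param params an [hrf_params()].
#' @param nuisance optional numeric matrix of nuisance regressors
#'   (`n_volumes` rows).
#' @param scheme `"crossed"` or `"categories"`.
#' @param oversample microtime resolution factor.
#' @return Design matrix (`n_volumes` x regressors) with condition columns
#'   first; attribute `"conditions"` names them.
#' @export
build_design <- function(schedule, n_volumes, tr, params = hrf_params(),
                         nuisance = NULL, scheme = c("crossed", "categories"),
                         oversample = 16) {
  scheme <- match.arg(scheme)
  ev <- schedule[schedule$condition != "null", , drop = FALSE]
  if (nrow(ev) > 0 && any(ev$onset + ev$duration > n_volumes * tr + 1e-9)) {
    stop("events extend beyond the scan duration")
  }
  cols <- if (scheme == "crossed") conditions() else response_categories()
  dt <- tr / oversample
  n_fine <- n_volumes * oversample
  kern <- gamma_hrf(params, dt)
  X <- matrix(0, n_volumes, length(cols), dimnames = list(NULL, cols))
  for (ci in seq_along(cols)) {
    if (scheme == "crossed") {
      rows <- ev$condition == cols[ci]
    } else {
      rows <- grepl(cols[ci], ev$condition)
    }
    u <- numeric(n_fine)
    for (i in which(rows)) {
      a <- floor(ev$onset[i] / dt) + 1
      b <- min(n_fine, ceiling((ev$onset[i] + ev$duration[i]) / dt))
      u[a:b] <- 1
    }
    conv <- convolve_series(u, kern)
    X[, ci] <- conv[seq(1, n_fine, by = oversample)]
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_volumes)
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    }
    X <- cbind(X, nuisance)
  }
  attr(X, "conditions") <- cols
  X
}

#' Voxelwise GLM fit
#'
#' Ordinary least squares per voxel with an intercept added to the supplied
#' design; returns per-regressor betas and t statistics
#' (`t = beta / SE(beta)`).
#'
#' @param bold `n_volumes x n_voxels` matrix, or a 4-D array (x, y, z, time).
#' @param design design matrix from [build_design()].
#' @return List of class `"glm_fit"`: `beta` and `t` (regressor x voxel),
#'   `df`, and `dims`/`conditions` bookkeeping.
#' @export
fit_glm <- function(bold, design) {
  dims <- NULL
  if (is.array(bold) && length(dim(bold)) == 4) {
    dims <- dim(bold)[1:3]
    bold <- t(matrix(bold, prod(dims), dim(bold)[4]))
  }
  Y <- as.matrix(bold)
  X <- cbind(`(Intercept)` = 1, design)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design matrix (", qr(X)$rank, " < ", ncol(X), ")")
  }
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(Y) - ncol(X)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(XtXi), sigma2))
  tmap <- B / se
  keep <- setdiff(rownames(B), "(Intercept)")
  structure(list(beta = B[keep, , drop = FALSE],
                 t = tmap[keep, , drop = FALSE],
                 df = df, dims = dims,
                 conditions = attr(design, "conditions")),
            class = "glm_fit")
}

#' Condition patterns from run-wise t maps
#'
#' Averages each condition's voxelwise t statistics across runs, then
#' z-normalizes each condition's map across in-mask voxels (population SD,
#' i.e. dividing by n), yielding the pattern rows used by the RSA stages.
#'
#' @param run_maps list (one per run) of condition x voxel t matrices (the
#'   `t` element of [fit_glm()], condition rows only).
#' @param mask optional logical vector of in-mask voxels.
#' @return A [voxel_pattern_set()] of z-normalized mean t values
#'   (in-mask columns only); each row has mean 0 and population SD 1.
#' @export
condition_patterns <- function(run_maps, mask = NULL) {
  stopifnot(length(run_maps) >= 1)
  nc <- ncol(run_maps[[1]])
  for (m in run_maps) {
    if (ncol(m) != nc || nrow(m) != nrow(run_maps[[1]])) {
      stop("inconsistent map dimensions across runs")
    }
  }
  avg <- Reduce(`+`, run_maps) / length(run_maps)
  if (!is.null(mask)) avg <- avg[, as.logical(mask), drop = FALSE]
  z <- t(apply(avg, 1, function(row) {
    s <- sqrt(mean((row - mean(row))^2))
    if (s == 0) stop("constant condition map: z-normalization undefined")
    (row - mean(row)) / s
  }))
  rownames(z) <- rownames(run_maps[[1]])
  voxel_pattern_set(z)
}
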