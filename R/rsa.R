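#' Neural dissimilarity matrix from voxel patterns
#'
#' Pearson correlation distance (1 - r) between all condition pairs over
#' the in-mask voxels.
#'
#' @param patterns a [voxel_pattern_set()] (condition x voxel matrix).
#' @param mask optional logical voxel selector.
#' @return A [dissimilarity_matrix()].
#' @export
neural_dm <- function(patterns, mask = NULL) {
  m <- unclass(patterns)
  if (!is.null(mask)) m <- m[, as.logical(mask), drop = FALSE]
  if (ncol(m) < 2) stop("need at least 2 in-mask voxels")
  pearson_distance_dm(m, labels = rownames(m))
}

#' Spearman rank-correlation RSA between two dissimilarity matrices
#'
#' Both DMs are vectorized in the shared pair order and compared by
#' Spearman rank correlation (average-rank ties), so no linear relationship
#' is assumed; the Fisher z transform `atanh(rho)` is attached for
#' group-level testing.
#'
#' @param dm_a,dm_b [dissimilarity_matrix()] objects (or pair vectors).
#' @return Object of class `"rsa_result"`: `rho`, `fisher_z`, `n_pairs`.
#' @export
spearman_rsa <- function(dm_a, dm_b) {
  va <- if (is.matrix(dm_a)) vectorize_dm(dm_a) else dm_a
  vb <- if (is.matrix(dm_b)) vectorize_dm(dm_b) else dm_b
  stopifnot(length(va) == length(vb))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("constant pair vector: Spearman correlation undefined")
  }
  rho <- stats::cor(va, vb, method = "spearman")
  structure(list(rho = rho,
                 fisher_z = atanh(max(min(rho, 1 - 1e-12), -1 + 1e-12)),
                 n_pairs = length(va)),
            class = "rsa_result")
}

#' @export
print.rsa_result <- function(x, digits = 3, ...) {
  cat("Spearman RSA: rho = ", round(x$rho, digits),
      " (Fisher z = ", round(x$fisher_z, digits), ", ",
      x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

#' Multiple-regression RSA with covariate DMs
#'
#' All pair vectors (neural outcome, predictor, covariates) are
#' rank-transformed (average ties), then the neural ranks are regressed on
#' an intercept, the predictor ranks and the covariate ranks by least
#' squares; the coefficient of the predictor of interest is returned.
#'
#' @param neural_dm outcome DM (or pair vector).
#' @param predictor_dm predictor DM of interest (or pair vector).
#' @param covariate_dms list of covariate DMs (or pair vectors).
#' @return Object of class `"rsa_regression"`: `beta` (predictor
#'   coefficient), all `coefficients`, `residuals`.
#' @export
regression_rsa <- function(neural_dm, predictor_dm, covariate_dms = list()) {
  as_vec <- function(d) if (is.matrix(d)) vectorize_dm(d) else d
  y <- rank(as_vec(neural_dm))
  xs <- lapply(c(list(predictor_dm), covariate_dms),
               function(d) rank(as_vec(d)))
  X <- cbind(1, do.call(cbind, xs))
  colnames(X) <- c("(Intercept)", "predictor",
                   if (length(covariate_dms) > 0)
                     paste0("covariate", seq_along(covariate_dms)))
  if (qr(X)$rank < ncol(X)) {
    stop("collinear predictors after rank transform")
  }
  fit <- stats::lm.fit(X, y)
  structure(list(beta = unname(fit$coefficients["predictor"]),
                 coefficients = fit$coefficients,
                 residuals = fit$residuals),
            class = "rsa_regression")
}

#' @export
print.rsa_regression <- function(x, digits = 3, ...) {
  cat("Rank-regression RSA: predictor beta = ", round(x$beta, digits), "\n",
      sep = "")
  invisible(x)
}

#' Group-level one-sample test of per-subject statistics
#'
#' One-sample t test of the (optionally Fisher-z transformed) per-subject
#' values against 0.
#'
#' @param values per-subject statistics (e.g. Spearman rhos or betas).
#' @param transform `"none"` or `"fisher_z"` (atanh before testing).
#' @return Object of class `"group_test"`: `mean` (of the tested values),
#'   `t`, `df`, `p`.
#' @export
group_test <- function(values, transform = c("none", "fisher_z")) {
  transform <- match.arg(transform)
  if (length(values) < 2) stop("need at least 2 subjects")
  v <- if (transform == "fisher_z") atanh(pmin(pmax(values, -1 + 1e-12), 1 - 1e-12)) else values
  if (stats::sd(v) == 0) stop("zero variance across subjects: t undefined")
  tt <- stats::t.test(v, mu = 0)
  structure(list(mean = mean(v), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 transform = transform),
            class = "group_test")
}

#' Paired contrast between two per-subject statistic vectors
#'
#' Paired t test on the differences `values_a - values_b`.
#'
#' @param values_a,values_b paired per-subject values (equal length).
#' @return A `"group_test"` on the differences.
#' @export
paired_contrast <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("paired vectors must have equal length")
  d <- values_a - values_b
  if (all(d == 0)) {
    # identical vectors: no difference anywhere, t is 0 by convention
    return(structure(list(mean = 0, t = 0, df = length(d) - 1, p = 1,
                          transform = "none"),
                     class = "group_test"))
  }
  group_test(d)
}

#' @export
print.group_test <- function(x, digits = 3, ...) {
  cat("One-sample test: mean = ", round(x$mean, digits),
      ", t(", x$df, ") = ", round(x$t, digits),
      ", p = ", signif(x$p, digits), "\n", sep = "")
  invisible(x)
}
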