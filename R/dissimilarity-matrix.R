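#' Construct a condition dissimilarity matrix
#'
#' A dissimilarity matrix (DM) holds pairwise Pearson correlation distances
#' (1 - r) among the four stimulus conditions. DMs appear in four roles in the
#' pipeline: subjective (from mouse-tracking bias vectors), neural (from
#' multi-voxel patterns), model (stereotype congruency) and group-average.
#'
#' @param values 4 x 4 numeric matrix; symmetric, zero diagonal, entries in
#'   \[0, 2\].
#' @param labels condition labels for rows/columns; defaults to [conditions()].
#' @param tol numeric tolerance for the symmetry / range checks.
#' @return An object of class `"dissimilarity_matrix"` (a labelled matrix).
#' @export
dissimilarity_matrix <- function(values, labels = conditions(), tol = 1e-8) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) != length(labels) ||
      ncol(values) != length(labels)) {
    stop("'values' must be a ", length(labels), " x ", length(labels),
         " numeric matrix")
  }
  if (any(abs(values - t(values)) > tol)) stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(values)) > tol)) stop("dissimilarity matrix must have a zero diagonal")
  if (any(values < -tol | values > 2 + tol)) {
    stop("correlation distances must lie in [0, 2]")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  values[values < 0] <- 0
  values[values > 2] <- 2
  dimnames(values) <- list(labels, labels)
  class(values) <- c("dissimilarity_matrix", "matrix")
  values
}

#' @export
print.dissimilarity_matrix <- function(x, digits = 3, ...) {
  cat("Condition dissimilarity matrix (1 - Pearson r)\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Vectorize a dissimilarity matrix
#'
#' Extracts the six condition pairs as a named vector in the fixed pair order
#' shared by every RSA routine in the package: row-major lower triangle of the
#' labelled matrix, diagonal excluded. With the canonical condition order this
#' is (HM,AM), (AF,AM), (AF,HM), (HF,AM), (HF,HM), (HF,AF).
#'
#' @param dm a [dissimilarity_matrix()] (or symmetric matrix coercible to one).
#' @return Named numeric vector of length `n*(n-1)/2`.
#' @export
vectorize_dm <- function(dm) {
  if (!inherits(dm, "dissimilarity_matrix")) dm <- dissimilarity_matrix(dm)
  m <- unclass(dm)
  labs <- rownames(m)
  n <- nrow(m)
  out <- numeric(0)
  nms <- character(0)
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1)) {
      out <- c(out, m[i, j])
      nms <- c(nms, paste(labs[i], labs[j], sep = "~"))
    }
  }
  names(out) <- nms
  out
}

#' Rebuild a dissimilarity matrix from its pair vector
#'
#' Inverse of [vectorize_dm()] for round-tripping.
#'
#' @param v numeric vector of length `n*(n-1)/2` in the fixed pair order.
#' @param labels condition labels.
#' @export
dm_from_vector <- function(v, labels = conditions()) {
  n <- length(labels)
  stopifnot(length(v) == n * (n - 1) / 2)
  m <- matrix(0, n, n)
  k <- 0
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1)) {
      k <- k + 1
      m[i, j] <- m[j, i] <- v[k]
    }
  }
  dissimilarity_matrix(m, labels)
}

#' Pearson correlation distance matrix of a set of row vectors
#'
#' @param x matrix whose rows (one per condition) are correlated.
#' @param labels row labels.
#' @return A [dissimilarity_matrix()] of 1 - Pearson r.
#' @export
pearson_distance_dm <- function(x, labels = rownames(x)) {
  if (is.null(labels)) labels <- conditions()
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance vector(s): ",
         paste(labels[sds == 0], collapse = ", "),
         "; Pearson distance undefined")
  }
  d <- 1 - stats::cor(t(x))
  dissimilarity_matrix(d, labels)
}
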