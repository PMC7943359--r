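#' Gaussian GEE with exchangeable working correlation
#'
#' Marginal (population-averaged) linear model estimated by generalized
#' estimating equations for clustered Gaussian outcomes: iterated
#' generalized least squares under an exchangeable working correlation,
#' with robust (sandwich) standard errors that remain valid whatever the
#' true within-cluster correlation. The exchangeable structure admits a
#' closed-form inverse, so cluster sums suffice and no per-cluster matrix
#' inversion is needed.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param id cluster identifier (bare column name or vector).
#' @param corstr working correlation: `"exchangeable"` (default) or
#'   `"independence"` (coefficients then equal OLS; only the robust SEs
#'   differ from a naive fit).
#' @param tol convergence tolerance on the coefficient change.
#' @param maxit maximum iterations.
#' @return Object of class `"gee_fit"` with `coefficients`, robust `se`,
#'   Wald `z`, 95% `ci`, `p`, robust `vcov`, working correlation `alpha`,
#'   residual variance `sigma2` and `n_clusters`.
#' @export
gee_gaussian <- function(formula, data, id,
                         corstr = c("exchangeable", "independence"),
                         tol = 1e-10, maxit = 50) {
  corstr <- match.arg(corstr)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  idvar <- eval(substitute(id), data, parent.frame())
  if (length(idvar) != nrow(data)) stop("'id' must match rows of 'data'")
  if (!is.null(attr(mf, "na.action"))) idvar <- idvar[-attr(mf, "na.action")]
  id <- factor(idvar)
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop("singular design matrix: rank ", qrX$rank, " < ", p,
         " columns (are both levels of every factor present?)")
  }
  beta <- qr.coef(qrX, y)
  ni <- as.vector(table(id))
  alpha <- 0
  for (it in seq_len(maxit)) {
    e <- y - drop(X %*% beta)
    sigma2 <- sum(e^2) / (n - p)
    Se <- rowsum(e, id)                       # per-cluster residual sums
    Se2 <- rowsum(e^2, id)
    cross <- (Se^2 - Se2) / 2                 # sum_{j<k} e_j e_k per cluster
    denom <- sum(ni * (ni - 1)) / 2 - p
    alpha <- if (corstr == "independence" || sigma2 <= 0) 0 else
      sum(cross) / (max(denom, 1) * sigma2)
    alpha <- max(min(alpha, 0.99), -0.99 / max(ni))
    kap <- alpha / (1 + (ni - 1) * alpha)     # per-cluster correction factor
    Sx <- rowsum(X, id)                       # clusters x p
    Sy <- rowsum(y, id)
    A <- (crossprod(X) - crossprod(Sx, Sx * kap)) / (1 - alpha)
    b <- (crossprod(X, y) - crossprod(Sx, kap * Sy)) / (1 - alpha)
    beta_new <- drop(solve(A, b))
    done <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    if (done) break
  }
  e <- y - drop(X %*% beta)
  Se <- rowsum(e, id)
  kap <- alpha / (1 + (ni - 1) * alpha)
  Sx <- rowsum(X, id)
  A <- (crossprod(X) - crossprod(Sx, Sx * kap)) / (1 - alpha)
  G <- (rowsum(X * e, id) - (kap * drop(Se)) * Sx) / (1 - alpha)
  Ainv <- solve(A)
  V <- Ainv %*% crossprod(G) %*% Ainv        # robust sandwich covariance
  se <- sqrt(diag(V))
  z <- beta / se
  fit <- list(coefficients = beta, se = se, z = z,
              ci = cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se),
              p = 2 * stats::pnorm(-abs(z)),
              vcov = V, alpha = alpha, sigma2 = sum(e^2) / (n - p),
              n = n, n_clusters = nlevels(id), iterations = it,
              corstr = corstr, formula = formula, terms = colnames(X))
  class(fit) <- "gee_fit"
  fit
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' @export
print.gee_fit <- function(x, digits = 4, ...) {
  cat("GEE (Gaussian, ", x$corstr, " working correlation), ",
      x$n, " observations in ", x$n_clusters, " clusters\n", sep = "")
  cat("Working correlation alpha = ", round(x$alpha, 3), "\n\n", sep = "")
  print(summary(x), digits = digits)
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, ...) {
  data.frame(term = object$terms,
             B = object$coefficients,
             SE = object$se,
             Z = object$z,
             ci_lower = object$ci[, "lower"],
             ci_upper = object$ci[, "upper"],
             p = object$p,
             row.names = NULL)
}
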