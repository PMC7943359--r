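#' Integer voxel offsets of a searchlight sphere
#'
#' All integer 3-vectors with Euclidean norm at most `radius` (inclusive
#' membership), including the origin; radius 3 yields the standard
#' 123-voxel sphere.
#'
#' @param radius sphere radius in voxels (>= 0).
#' @return Integer matrix (offsets x 3) with attribute `"radius"`.
#' @export
sphere_offsets <- function(radius = 3) {
  if (radius < 0) stop("radius must be non-negative")
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius^2
  off <- as.matrix(g[keep, , drop = FALSE])
  rownames(off) <- NULL
  attr(off, "radius") <- radius
  off
}

# shift-and-add sphere sums: for each in-grid voxel, the sum of `vol` over
# the sphere of offsets intersected with the grid
sphere_sum <- function(vol, offsets) {
  d <- dim(vol)
  out <- array(0, d)
  for (i in seq_len(nrow(offsets))) {
    dx <- offsets[i, 1]; dy <- offsets[i, 2]; dz <- offsets[i, 3]
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zs <- max(1, 1 - dz):min(d[3], d[3] - dz)
    out[xs, ys, zs] <- out[xs, ys, zs] +
      vol[xs + dx, ys + dy, zs + dz, drop = FALSE]
  }
  out
}

#' Searchlight regression RSA over a pattern volume
#'
#' Centers a sphere on every in-mask voxel; within each sphere (intersected
#' with the mask, shrinking at edges) a neural DM of Pearson correlation
#' distances between the four condition patterns is built, rank-regressed on
#' the predictor DM (controlling any covariate DMs) and the predictor's beta
#' written back to the center voxel. Spheres with fewer than `min_voxels`
#' usable voxels are marked missing (`NA`), not zero.
#'
#' @param pattern_volume 4-D array (x, y, z, condition).
#' @param mask logical 3-D array of usable voxels.
#' @param predictor_dm predictor [dissimilarity_matrix()].
#' @param covariate_dms list of covariate DMs.
#' @param radius sphere radius in voxels.
#' @param min_voxels minimum usable voxels per sphere.
#' @return Object of class `"stat_map"`: `map` (3-D beta array, `NA`
#'   outside mask or where missing), `n_map` (sphere sizes) and `mask`.
#' @export
run_searchlight <- function(pattern_volume, mask, predictor_dm,
                            covariate_dms = list(), radius = 3,
                            min_voxels = 2) {
  d4 <- dim(pattern_volume)
  stopifnot(length(d4) == 4, d4[4] == 4)
  d <- d4[1:3]
  stopifnot(identical(dim(mask), d))
  off <- sphere_offsets(radius)
  w <- array(as.numeric(mask), d)
  cond <- lapply(1:4, function(ci) pattern_volume[, , , ci] * w)
  # sphere sums of the mask count, the 4 condition sums and the 10 products
  n_s <- sphere_sum(w, off)
  S <- lapply(cond, sphere_sum, offsets = off)
  Q <- vector("list", 10)
  k <- 0
  qi <- matrix(0L, 4, 4)
  for (i in 1:4) for (j in i:4) {
    k <- k + 1
    Q[[k]] <- sphere_sum(cond[[i]] * cond[[j]], off)
    qi[i, j] <- qi[j, i] <- k
  }
  centers <- which(mask & n_s >= max(min_voxels, 2))
  n <- n_s[centers]
  pair_idx <- rbind(c(2, 1), c(3, 1), c(3, 2), c(4, 1), c(4, 2), c(4, 3))
  D <- matrix(NA_real_, 6, length(centers))
  ok <- rep(TRUE, length(centers))
  for (pi in seq_len(6)) {
    i <- pair_idx[pi, 1]; j <- pair_idx[pi, 2]
    num <- n * Q[[qi[i, j]]][centers] - S[[i]][centers] * S[[j]][centers]
    vi <- n * Q[[qi[i, i]]][centers] - S[[i]][centers]^2
    vj <- n * Q[[qi[j, j]]][centers] - S[[j]][centers]^2
    den <- sqrt(pmax(vi, 0) * pmax(vj, 0))
    good <- den > 0
    ok <- ok & good
    D[pi, good] <- 1 - num[good] / den[good]
  }
  # rank-transform; predictor/covariate ranks are center-invariant
  as_vec <- function(dmx) if (is.matrix(dmx)) vectorize_dm(dmx) else dmx
  X <- cbind(1, rank(as_vec(predictor_dm)))
  for (cv in covariate_dms) X <- cbind(X, rank(as_vec(cv)))
  if (qr(X)$rank < ncol(X)) stop("collinear predictors after rank transform")
  pinv <- solve(crossprod(X), t(X))
  beta <- rep(NA_real_, length(centers))
  use <- which(ok)
  if (length(use) > 0) {
    R <- apply(D[, use, drop = FALSE], 2, rank)
    beta[use] <- (pinv %*% R)[2, ]
  }
  map <- array(NA_real_, d)
  map[centers] <- beta
  n_map <- array(NA_real_, d)
  n_map[centers] <- n
  structure(list(map = map, n_map = n_map, mask = mask, radius = radius),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("Searchlight stat map ", paste(dim(x$map), collapse = " x "),
      "; ", sum(!is.na(x$map)), " defined centers\n", sep = "")
  invisible(x)
}

#' Gaussian smoothing of a statistic map
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 * sqrt(2 * log(2)))`
#' per axis, with mask-aware renormalization: the map is convolved weighted
#' by the validity mask and divided by the smoothed mask, so edges and
#' missing voxels do not drag estimates toward zero (a constant image stays
#' constant).
#'
#' @param map 3-D array (or `"stat_map"`).
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @return Smoothed array (or `"stat_map"` with smoothed `map`).
#' @export
smooth_map <- function(map, fwhm_mm, voxel_size_mm = 2) {
  is_sm <- inherits(map, "stat_map")
  m <- if (is_sm) map$map else map
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(map)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  w <- array(as.numeric(is.finite(m)), dim(m))
  mm <- m
  mm[!is.finite(mm)] <- 0
  conv1 <- function(a, along) {
    out <- array(0, dim(a))
    for (i in seq_along(k)) {
      sh <- i - r - 1
      d <- dim(a)[along]
      src <- max(1, 1 + sh):min(d, d + sh)
      dst <- src - sh
      if (along == 1) out[dst, , ] <- out[dst, , ] + k[i] * a[src, , , drop = FALSE]
      if (along == 2) out[, dst, ] <- out[, dst, ] + k[i] * a[, src, , drop = FALSE]
      if (along == 3) out[, , dst] <- out[, , dst] + k[i] * a[, , src, drop = FALSE]
    }
    out
  }
  for (ax in 1:3) {
    mm <- conv1(mm, ax)
    w <- conv1(w, ax)
  }
  sm <- ifelse(w > 1e-12, mm / w, NA_real_)
  sm[!is.finite(m)] <- NA_real_
  if (is_sm) {
    map$map <- sm
    map
  } else sm
}

#' Group-level sign-flip max-statistic permutation test
#'
#' Voxelwise one-sample t over subjects, with the family-wise null built by
#' randomly sign-flipping whole subject maps: each voxel's corrected p is
#' the rank of its observed t within the permutation distribution of the
#' image-wide maximum t (one-sided, positive direction). Only voxels with
#' finite values in every subject enter.
#'
#' @param subject_maps list of per-subject 3-D arrays (or `"stat_map"`s).
#' @param n_perm number of sign-flip permutations.
#' @param alpha family-wise significance level.
#' @param seed RNG seed.
#' @return Object of class `"permutation_result"`: `t_map`, corrected
#'   `p_map`, `significant` mask, `max_null` distribution.
#' @export
group_permutation <- function(subject_maps, n_perm = 5000, alpha = 0.05,
                              seed = 1L) {
  maps <- lapply(subject_maps, function(m) if (inherits(m, "stat_map")) m$map else m)
  S <- length(maps)
  if (S < 2) stop("need at least 2 subjects")
  if (n_perm < 100) warning("n_perm < 100: corrected p values are coarse")
  d <- dim(maps[[1]])
  M <- do.call(rbind, lapply(maps, as.vector))
  valid <- colSums(!is.finite(M)) == 0
  M <- M[, valid, drop = FALSE]
  V <- ncol(M)
  if (V == 0) stop("no voxels valid in all subjects")
  ss <- colSums(M^2)
  t_from_signs <- function(signs) {
    sm <- signs %*% M
    mean_ <- sm / S
    var_ <- (rep(ss, each = nrow(sm)) - S * mean_^2) / (S - 1)
    dim(var_) <- dim(mean_)
    mean_ / sqrt(pmax(var_, .Machine$double.eps) / S)
  }
  t_obs <- drop(t_from_signs(matrix(1, 1, S)))
  set.seed(seed)
  max_null <- numeric(n_perm)
  done <- 0
  while (done < n_perm) {
    chunk <- min(500, n_perm - done)
    signs <- matrix(sample(c(-1, 1), chunk * S, replace = TRUE), chunk, S)
    tp <- t_from_signs(signs)
    max_null[done + seq_len(chunk)] <- apply(tp, 1, max)
    done <- done + chunk
  }
  # rank of the observed t within the max-null distribution (identity
  # permutation included via the +1)
  p <- (1 + vapply(t_obs, function(tv) sum(max_null >= tv), numeric(1))) /
    (n_perm + 1)
  t_map <- array(NA_real_, d)
  p_map <- array(NA_real_, d)
  t_map[valid] <- t_obs
  p_map[valid] <- p
  structure(list(t_map = t_map, p_map = p_map,
                 significant = !is.na(p_map) & p_map <= alpha,
                 max_null = max_null, alpha = alpha, n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Sign-flip max-statistic permutation (", x$n_perm, " permutations): ",
      sum(x$significant), " voxels significant at corrected p <= ",
      x$alpha, "\n", sep = "")
  invisible(x)
}

#' Threshold a t map into clusters of minimum extent
#'
#' Binarizes a statistic map at a threshold and keeps 6-connected clusters
#' of at least `min_extent` voxels; the utility used to define liberal
#' seed-region masks from a univariate contrast.
#'
#' @param t_map 3-D statistic array.
#' @param threshold voxelwise threshold (values > threshold are kept).
#' @param min_extent minimum cluster size in voxels.
#' @return Logical array marking surviving-cluster voxels.
#' @export
cluster_threshold <- function(t_map, threshold, min_extent = 20) {
  d <- dim(t_map)
  above <- is.finite(t_map) & t_map > threshold
  labels <- array(0L, d)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cur <- 0L
  keep <- array(FALSE, d)
  idx_all <- which(above)
  coords <- arrayInd(idx_all, d)
  lin <- function(co) (co[, 3] - 1) * d[1] * d[2] + (co[, 2] - 1) * d[1] + co[, 1]
  for (start_i in seq_along(idx_all)) {
    start <- idx_all[start_i]
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    members <- start
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(v, d)
      for (nn in seq_len(6)) {
        cn <- co + nb[nn, , drop = FALSE]
        if (any(cn < 1) || any(cn > d)) next
        li <- lin(cn)
        if (above[li] && labels[li] == 0L) {
          labels[li] <- cur
          queue <- c(queue, li)
          members <- c(members, li)
        }
      }
    }
    if (length(members) >= min_extent) keep[members] <- TRUE
  }
  keep
}
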