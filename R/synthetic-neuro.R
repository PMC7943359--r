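#' Generate condition voxel patterns with a planted correlation structure
#'
#' Condition patterns are built by mixing independent unit-variance voxel
#' components through the matrix square root of the target correlation
#' matrix `1 - target_dm`, plus independent Gaussian noise, so the realized
#' Pearson-distance DM converges to `target_dm` as `n_voxels` grows and
#' `noise_sd` shrinks.
#'
#' @param target_dm a [dissimilarity_matrix()]; `1 - target_dm` must be
#'   positive semi-definite.
#' @param n_voxels number of voxels.
#' @param noise_sd SD of additive voxel noise.
#' @param seed RNG seed.
#' @return A `"voxel_pattern_set"`: condition x voxel matrix.
#' @export
gen_patterns <- function(target_dm, n_voxels, noise_sd = 0, seed = 1L) {
  target_dm <- dissimilarity_matrix(target_dm)
  C <- 1 - unclass(target_dm)
  diag(C) <- 1
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    stop("1 - target_dm is not positive semi-definite (min eigenvalue ",
         format(min(eg$values)), "); not a valid correlation structure")
  }
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  set.seed(seed)
  Z <- matrix(stats::rnorm(nrow(C) * n_voxels), nrow(C), n_voxels)
  X <- L %*% Z
  if (noise_sd > 0) {
    X <- X + noise_sd * matrix(stats::rnorm(length(X)), nrow(X))
  }
  rownames(X) <- rownames(target_dm)
  voxel_pattern_set(X)
}

#' Condition x voxel pattern set
#'
#' Light container for a condition x voxel matrix of pattern values
#' (simulated patterns, or z-normalized t statistics from the GLM stage).
#'
#' @param x condition x voxel numeric matrix with condition rownames.
#' @export
voxel_pattern_set <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- conditions()
  class(x) <- c("voxel_pattern_set", "matrix")
  x
}

#' @export
print.voxel_pattern_set <- function(x, ...) {
  cat("Voxel pattern set: ", nrow(x), " conditions x ", ncol(x),
      " voxels\n", sep = "")
  invisible(x)
}

#' Random per-subject target dissimilarity structures
#'
#' Draws a valid (positive semi-definite) random 4 x 4 correlation structure
#' per subject from low-dimensional factor scores and returns the
#' corresponding Pearson-distance DMs. Used to plant subject-specific
#' representational structure for RSA recovery simulations.
#'
#' @param n_subjects number of subjects.
#' @param seed RNG seed.
#' @param k number of factor-score samples (smaller = more idiosyncratic).
#' @return List of [dissimilarity_matrix()] objects.
#' @export
gen_subject_dms <- function(n_subjects, seed = 1L, k = 12) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(s) {
    f <- matrix(stats::rnorm(4 * k), 4, k)
    pearson_distance_dm(f, labels = conditions())
  })
}

#' Blend two dissimilarity matrices with a subject weight
#'
#' Convex combination on the correlation scale,
#' `1 - (w * (1 - a) + (1 - w) * (1 - b))`, which preserves positive
#' semi-definiteness. With `w = 0` the subject-specific structure drops out
#' entirely, the device used to plant the masked-condition null.
#'
#' @param a,b [dissimilarity_matrix()] objects.
#' @param w weight on `a` in \[0, 1\].
#' @export
blend_dms <- function(a, b, w) {
  stopifnot(w >= 0, w <= 1)
  dissimilarity_matrix(w * unclass(dissimilarity_matrix(a)) +
                         (1 - w) * unclass(dissimilarity_matrix(b)))
}

#' Generate a seed/target BOLD session with planted PPI coupling
#'
#' The seed region's neural series is the condition-evoked boxcar; its BOLD
#' series is the gamma-HRF convolution plus noise. The target's neural
#' series is `a * seed_neural + c * seed_neural * condition +
#' evoked_amp * evoked`, convolved and noised, where `condition` is the
#' masked = -1 / unmasked = +1 regressor at volume resolution and
#' `c = truth$ppi_coupling`.
#'
#' @param schedule event table from [make_schedule()]; must cover both
#'   masking conditions.
#' @param truth a [ground_truth()] (uses `ppi_coupling` and
#'   `noise_sds$bold`).
#' @param params an [hrf_params()].
#' @param noise_sd BOLD noise SD; defaults to `truth$noise_sds$bold`.
#' @param seed RNG seed.
#' @param a planted direct seed-to-target coupling.
#' @param target_evoked_amp amplitude of the target's own evoked response.
#' @return List with `seed` and `target` [roi_timeseries()] objects, the
#'   per-volume `condition` regressor, `tr` and the evoked neural series.
#' @export
gen_bold_session <- function(schedule, truth, params = hrf_params(),
                             noise_sd = NULL, seed = 1L, a = 1,
                             target_evoked_amp = 0) {
  if (length(unique(schedule$masking)) < 2) {
    stop("schedule must cover both masking conditions")
  }
  if (is.null(noise_sd)) noise_sd <- truth$noise_sds$bold
  tr <- unique(diff(sort(unique(schedule$onset[schedule$run == schedule$run[1]]))))[1]
  runs <- sort(unique(schedule$run))
  neural <- numeric(0)
  cond <- numeric(0)
  for (r in runs) {
    ev <- schedule[schedule$run == r, ]
    n_vol <- ceiling(max(ev$onset + ev$duration) / tr)
    u <- numeric(n_vol)
    face <- ev[ev$condition != "null", ]
    idx <- floor(face$onset / tr) + 1
    u[idx] <- u[idx] + 1
    neural <- c(neural, u)
    cond <- c(cond, rep(if (ev$masking[1] == "masked") -1 else 1, n_vol))
  }
  k <- gamma_hrf(params, tr)
  set.seed(seed)
  conv <- function(x) convolve_series(x, k)
  seed_bold <- conv(neural) + noise_sd * stats::rnorm(length(neural))
  target_neural <- a * neural + truth$ppi_coupling * neural * cond +
    target_evoked_amp * neural
  target_bold <- conv(target_neural) + noise_sd * stats::rnorm(length(neural))
  list(seed = roi_timeseries(seed_bold, tr),
       target = roi_timeseries(target_bold, tr),
       condition = cond, tr = tr, neural = neural)
}

#' Generate per-subject 4-D pattern volumes with planted signal regions
#'
#' Voxels inside each signal region carry condition patterns drawn by
#' [gen_patterns()] from the subject's planted DM; voxels outside carry pure
#' unit-variance noise.
#'
#' @param grid_dims length-3 integer grid size.
#' @param regions list of regions, each `list(center = c(x, y, z), radius)`;
#'   regions must fit in the grid and must not overlap.
#' @param subject_dms list (one per subject) of target
#'   [dissimilarity_matrix()] objects (recycled across regions), or a list of
#'   per-region lists.
#' @param noise_sd in-region additive noise SD passed to [gen_patterns()].
#' @param seed RNG seed.
#' @return List with `volumes` (per subject, a 4-D array x,y,z,condition),
#'   `mask` (all-`TRUE` logical array) and `region_masks`.
#' @export
gen_volume_dataset <- function(grid_dims, regions, subject_dms,
                               noise_sd = 1, seed = 1L) {
  stopifnot(length(grid_dims) == 3)
  region_masks <- lapply(regions, function(rg) {
    stopifnot(length(rg$center) == 3, rg$radius >= 0)
    if (any(rg$center - rg$radius < 1) || any(rg$center + rg$radius > grid_dims)) {
      stop("signal region does not fit inside the grid")
    }
    off <- sphere_offsets(rg$radius)
    m <- array(FALSE, grid_dims)
    m[cbind(off[, 1] + rg$center[1], off[, 2] + rg$center[2],
            off[, 3] + rg$center[3])] <- TRUE
    m
  })
  if (length(region_masks) > 1) {
    tot <- Reduce(`+`, lapply(region_masks, function(m) m * 1L))
    if (any(tot > 1)) stop("signal regions overlap")
  }
  set.seed(seed)
  n_sub <- length(subject_dms)
  volumes <- lapply(seq_len(n_sub), function(s) {
    vol <- array(stats::rnorm(prod(grid_dims) * 4), c(grid_dims, 4))
    for (ri in seq_along(region_masks)) {
      dm <- subject_dms[[s]]
      if (is.list(dm) && !inherits(dm, "dissimilarity_matrix")) dm <- dm[[ri]]
      idx <- which(region_masks[[ri]])
      pats <- gen_patterns(dm, length(idx), noise_sd = noise_sd,
                           seed = sample.int(.Machine$integer.max, 1))
      for (ci in 1:4) {
        plane <- vol[, , , ci]
        plane[idx] <- pats[ci, ]
        vol[, , , ci] <- plane
      }
    }
    vol
  })
  list(volumes = volumes, mask = array(TRUE, grid_dims),
       region_masks = region_masks)
}
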