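# Standard mouse-tracking coordinate space: start button at (0,0), response
# targets at (+/-1, 1.5); the chosen response is mapped to the right, so the
# direct path runs (0,0) -> (1,1.5) and the opposite response sits at (-1,1.5).
.chosen_target <- c(1, 1.5)
.line_norm <- sqrt(sum(.chosen_target^2))

#' Maximum possible perpendicular deviation
#'
#' The perpendicular distance from the direct start-to-chosen-response line
#' to the opposite response location: the farthest meaningful deviation,
#' used as the normalizing constant of MD.
#'
#' @export
max_possible_md <- function() {
  (.chosen_target[1] * 1.5 - .chosen_target[2] * (-1)) / .line_norm
}

#' Exclude timed-out and incorrect trials
#'
#' Retains trials with `rt_ms <= 2000` (the deadline is "exceeded", so a
#' response at exactly 2000 ms is kept) and `correct == TRUE`.
#'
#' @param trajset a `"trajectory_set"` from [gen_trajectories()] or a trials
#'   data frame with `rt_ms` and `correct` columns.
#' @param deadline_ms response deadline in ms.
#' @return The retained set, with an `"exclusion_report"` attribute carrying
#'   counts and fractions per rule. Errors if any subject x condition cell
#'   is left empty.
#' @export
exclude_trials <- function(trajset, deadline_ms = 2000) {
  is_set <- inherits(trajset, "trajectory_set")
  trials <- if (is_set) trajset$trials else trajset
  if (is.null(trials$rt_ms) || is.null(trials$correct)) {
    stop("trials must carry 'rt_ms' and 'correct'")
  }
  timeout <- trials$rt_ms > deadline_ms
  incorrect <- !trials$correct
  keep <- !timeout & !incorrect
  n <- nrow(trials)
  report <- data.frame(
    rule = c("timeout", "incorrect", "retained"),
    n = c(sum(timeout), sum(incorrect), sum(keep)),
    fraction = c(mean(timeout), mean(incorrect), mean(keep))
  )
  kept <- trials[keep, , drop = FALSE]
  cells <- table(factor(kept$subject, levels = unique(trials$subject)),
                 match_conditions(kept$condition))
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("no retained trials for subject ", rownames(cells)[bad[1]],
         ", condition ", colnames(cells)[bad[2]])
  }
  out <- if (is_set) {
    structure(list(trials = kept,
                   t = trajset$t[keep, , drop = FALSE],
                   x = trajset$x[keep, , drop = FALSE],
                   y = trajset$y[keep, , drop = FALSE],
                   stereotype_scores = trajset$stereotype_scores),
              class = "trajectory_set")
  } else kept
  attr(out, "exclusion_report") <- report
  out
}

#' Normalize a single trajectory into standard space and time bins
#'
#' Translates the path so it starts at (0, 0), mirrors it about the vertical
#' axis when the chosen response lies on the left (so the chosen response is
#' always on the right) and linearly interpolates to `n_bins + 1` equally
#' spaced time points (endpoints inclusive).
#'
#' @param t,x,y raw path samples; `t` strictly increasing.
#' @param response_side `"left"` or `"right"`.
#' @param n_bins number of time bins (default 100, i.e. 101 points).
#' @return `(n_bins + 1) x 2` matrix of (x, y) coordinates.
#' @export
normalize_trajectory <- function(t, x, y, response_side = "right",
                                 n_bins = 100) {
  if (length(t) < 2) stop("path must have at least 2 samples")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  x <- x - x[1]
  y <- y - y[1]
  if (response_side == "left") x <- -x
  tt <- seq(t[1], t[length(t)], length.out = n_bins + 1)
  cbind(x = stats::approx(t, x, xout = tt)$y,
        y = stats::approx(t, y, xout = tt)$y)
}

#' Maximum perpendicular deviation of a normalized trajectory
#'
#' The signed perpendicular distance, at the point of maximum absolute
#' deviation, of the path from the straight line joining the start (0, 0)
#' to the chosen-response location (1, 1.5); positive toward the opposite
#' (unchosen) response, negative when the largest deviation bows toward the
#' chosen side. `md_norm` is `MD / max(MD)` clamped to \[0, 1\], where
#' max(MD) is the perpendicular distance from that line to the opposite
#' response location.
#'
#' @param coords normalized `(x, y)` matrix from [normalize_trajectory()].
#' @return List with `md`, `md_norm` and `max_md`.
#' @export
compute_md <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("degenerate trajectory")
  s <- (.chosen_target[1] * coords[, 2] - .chosen_target[2] * coords[, 1]) /
    .line_norm
  md <- s[which.max(abs(s))]
  max_md <- max_possible_md()
  list(md = md, md_norm = min(1, max(0, md / max_md)), max_md = max_md)
}

# Vectorized normalize + MD over a whole trajectory_set. Raw samples are
# uniformly spaced in time within each trial, so time normalization is a
# shared linear interpolation and MD reduces to a row-wise maximum.
trajectory_md <- function(trajset, n_bins = 100) {
  stopifnot(inherits(trajset, "trajectory_set"))
  x <- trajset$x - trajset$x[, 1]
  y <- trajset$y - trajset$y[, 1]
  mirror <- trajset$trials$response_side == "left"
  x[mirror, ] <- -x[mirror, ]
  m <- ncol(x)
  # interpolation weights from the m uniform samples to n_bins + 1 bins
  pos <- seq(0, 1, length.out = n_bins + 1) * (m - 1) + 1
  lo <- pmin(floor(pos), m - 1)
  w <- pos - lo
  xi <- x[, lo, drop = FALSE] * (1 - rep(w, each = nrow(x))) +
    x[, lo + 1, drop = FALSE] * rep(w, each = nrow(x))
  yi <- y[, lo, drop = FALSE] * (1 - rep(w, each = nrow(y))) +
    y[, lo + 1, drop = FALSE] * rep(w, each = nrow(y))
  s <- (.chosen_target[1] * yi - .chosen_target[2] * xi) / .line_norm
  md <- s[cbind(seq_len(nrow(s)), max.col(abs(s), ties.method = "first"))]
  out <- trajset$trials
  out$md <- md
  out$md_norm <- pmin(1, pmax(0, md / max_possible_md()))
  out
}

#' Per-trial MD table for a trajectory set
#'
#' Applies standard preprocessing (translation, mirroring, time
#' normalization) and computes MD and normalized MD for every trial.
#'
#' @param trajset a `"trajectory_set"`.
#' @param n_bins number of time bins.
#' @return The trials data frame with `md` and `md_norm` columns.
#' @export
md_table <- function(trajset, n_bins = 100) {
  trajectory_md(trajset, n_bins = n_bins)
}

#' Category-bias vector for one stimulus condition
#'
#' Within each block the mean normalized MD is the similarity toward the
#' unselected response and its complement the similarity toward the selected
#' response; the four similarities are assembled in the fixed order
#' (angry, happy, male, female).
#'
#' @param condition the stimulus condition.
#' @param md_norm_emotion,md_norm_gender retained-trial `md_norm` values for
#'   the condition in the emotion and gender blocks.
#' @return Named similarity 4-vector.
#' @export
condition_bias_vector <- function(condition, md_norm_emotion, md_norm_gender) {
  condition <- as.character(match_conditions(condition))
  if (length(md_norm_emotion) == 0 || length(md_norm_gender) == 0) {
    stop("missing block data for condition ", condition)
  }
  v <- c(angry = NA_real_, happy = NA_real_, male = NA_real_, female = NA_real_)
  emo <- condition_emotion(condition)
  gen <- condition_gender(condition)
  m_e <- mean(md_norm_emotion)
  m_g <- mean(md_norm_gender)
  v[emo] <- 1 - m_e
  v[setdiff(c("angry", "happy"), emo)] <- m_e
  v[gen] <- 1 - m_g
  v[setdiff(c("male", "female"), gen)] <- m_g
  v
}

#' Bias vectors for all four conditions of one subject
#'
#' @param md_trials retained trials with `condition`, `block` and `md_norm`
#'   (one subject).
#' @return 4 x 4 matrix: conditions (rows) x response categories (columns).
#' @export
subject_bias_vectors <- function(md_trials) {
  vecs <- t(sapply(conditions(), function(cond) {
    rows <- md_trials$condition == cond
    condition_bias_vector(cond,
                          md_trials$md_norm[rows & md_trials$block == "emotion"],
                          md_trials$md_norm[rows & md_trials$block == "gender"])
  }))
  rownames(vecs) <- conditions()
  vecs
}

#' Subjective dissimilarity matrix from bias vectors
#'
#' Pearson correlation distance (1 - r) between the four condition bias
#' vectors.
#'
#' @param bias_vectors 4 x 4 condition x category matrix from
#'   [subject_bias_vectors()].
#' @return A [dissimilarity_matrix()].
#' @export
subjective_dm <- function(bias_vectors) {
  stopifnot(nrow(bias_vectors) == 4)
  pearson_distance_dm(bias_vectors, labels = rownames(bias_vectors))
}

#' Group-average dissimilarity matrix
#'
#' Averages the condition bias vectors element-wise across subjects first,
#' then computes Pearson distances on the averaged vectors (mean-then-
#' distance, not distance-then-mean).
#'
#' @param bias_vector_list list of per-subject 4 x 4 bias-vector matrices.
#' @return A [dissimilarity_matrix()].
#' @export
group_average_dm <- function(bias_vector_list) {
  stopifnot(length(bias_vector_list) >= 1)
  labs <- rownames(bias_vector_list[[1]])
  for (b in bias_vector_list) {
    if (!identical(rownames(b), labs)) {
      stop("mismatched condition sets across subjects")
    }
  }
  avg <- Reduce(`+`, bias_vector_list) / length(bias_vector_list)
  pearson_distance_dm(avg, labels = labs)
}

#' Subjective DMs for every subject in a trajectory set
#'
#' Convenience wrapper running exclusion, MD computation, bias vectors and
#' subjective DMs per subject, plus the group-average DM.
#'
#' @param trajset a `"trajectory_set"`.
#' @param n_bins number of time bins.
#' @return List with `md_trials`, `bias_vectors` (per subject),
#'   `subject_dms` (per subject) and `group_dm`.
#' @export
subjective_dms <- function(trajset, n_bins = 100) {
  kept <- exclude_trials(trajset)
  md_trials <- trajectory_md(kept, n_bins = n_bins)
  subjects <- unique(md_trials$subject)
  bias <- lapply(subjects, function(s) {
    subject_bias_vectors(md_trials[md_trials$subject == s, ])
  })
  names(bias) <- subjects
  dms <- lapply(bias, subjective_dm)
  list(md_trials = md_trials, bias_vectors = bias, subject_dms = dms,
       group_dm = group_average_dm(bias),
       exclusion_report = attr(kept, "exclusion_report"))
}
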