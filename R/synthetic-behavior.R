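#' Generate an event schedule for the masked/unmasked fMRI task
#'
#' Per run, half of the 140 faces (balanced across the four conditions) are
#' presented twice along with the null events, in seeded random order.
#' Onsets fall on the TR grid and masked runs precede unmasked runs.
#'
#' @param spec a [design_spec()].
#' @return Data frame with columns `run`, `masking` (`"masked"`/`"unmasked"`),
#'   `onset` (s), `duration` (s), `condition` (`"null"` for null events) and
#'   `face_id`.
#' @export
make_schedule <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(spec$seed)
  conds <- spec$conditions
  nf <- spec$n_faces_per_cell
  dur <- spec$trial_duration_ms / 1000
  # split each cell's faces into two halves; alternate ceil/floor across
  # cells so each half holds exactly half of all faces even when nf is odd
  halves <- lapply(seq_along(conds), function(ci) {
    ids <- sample(nf)
    k <- if (ci %% 2 == 1) ceiling(nf / 2) else floor(nf / 2)
    list(a = ids[seq_len(k)], b = ids[-seq_len(k)])
  })
  runs <- lapply(seq_len(spec$n_runs), function(r) {
    half <- if (r %% 2 == 1) "a" else "b"
    ev <- do.call(rbind, lapply(seq_along(conds), function(ci) {
      ids <- halves[[ci]][[half]]
      data.frame(condition = conds[ci],
                 face_id = paste0(conds[ci], "_", rep(ids, each = 2)),
                 stringsAsFactors = FALSE)
    }))
    if (spec$n_null_events > 0) {
      ev <- rbind(ev, data.frame(condition = rep("null", spec$n_null_events),
                                 face_id = NA_character_,
                                 stringsAsFactors = FALSE))
    }
    ev <- ev[sample(nrow(ev)), , drop = FALSE]
    ev$run <- r
    ev$masking <- if (r <= spec$n_runs %/% 2) "masked" else "unmasked"
    ev$onset <- (seq_len(nrow(ev)) - 1) * dur
    ev$duration <- dur
    rownames(ev) <- NULL
    ev[, c("run", "masking", "onset", "duration", "condition", "face_id")]
  })
  do.call(rbind, runs)
}

#' Generate descriptor-rating blocks with a planted stereotype score
#'
#' Each subject rates 30 descriptors for the four categories (angry, happy,
#' male, female) on the 1-7 scale. Ratings are built from a latent
#' 30-vector: angry and male load positively on it, happy and female
#' negatively, with the loading magnitude chosen so that the noiseless
#' stereotype score equals the subject's planted bias exactly (components
#' are orthonormalized, so pairwise correlations are analytic). Gaussian
#' rating noise is then added and values clamped to \[1, 7\].
#'
#' @param n_subjects number of subjects.
#' @param bias_mean mean planted stereotype score, in \[-2, 2\].
#' @param bias_sd between-subject SD of the planted score.
#' @param noise_sd SD of rating noise (rating-scale units); the default is
#'   kept small relative to the unit signal spread so measurement-error
#'   attenuation of the recovered score stays within a few percent.
#' @param seed RNG seed.
#' @param n_descriptors descriptors per category.
#' @return List of `"ratings_block"` objects: `subject_id`, a 4 x 30
#'   `ratings` matrix (rows angry, happy, male, female) and `true_bias`.
#' @export
gen_ratings <- function(n_subjects, bias_mean = 0.49, bias_sd = 0.62,
                        noise_sd = 0.25, seed = 1L, n_descriptors = 30) {
  if (bias_mean < -2 || bias_mean > 2) stop("bias_mean must lie in [-2, 2]")
  if (n_subjects < 1) stop("n_subjects must be positive")
  set.seed(seed)
  cats <- response_categories()
  lapply(seq_len(n_subjects), function(s) {
    b <- bias_mean + bias_sd * stats::rnorm(1)
    b <- min(2, max(-2, b))
    alpha <- sqrt(abs(b) / 2)
    beta <- sqrt(1 - alpha^2)
    sgn <- if (b >= 0) 1 else -1
    # orthonormal, mean-zero latent components (common axis + one per category)
    raw <- matrix(stats::rnorm(n_descriptors * 5), n_descriptors, 5)
    q <- qr.Q(qr(cbind(1, raw)))[, 2:6]
    u <- q[, 1]; z <- q[, 2:5]
    load <- c(angry = alpha, happy = -alpha, male = sgn * alpha,
              female = -sgn * alpha)
    x <- sapply(seq_along(cats), function(ci) {
      load[cats[ci]] * u + beta * z[, ci]
    })
    ratings <- 4 + sqrt(n_descriptors - 1) * t(x)
    if (noise_sd > 0) {
      ratings <- ratings + noise_sd * matrix(stats::rnorm(length(ratings)),
                                             nrow(ratings))
    }
    ratings[ratings < 1] <- 1
    ratings[ratings > 7] <- 7
    rownames(ratings) <- cats
    colnames(ratings) <- paste0("d", seq_len(n_descriptors))
    structure(list(subject_id = s, ratings = ratings, true_bias = b),
              class = "ratings_block")
  })
}

#' Generate mouse-tracking trajectories with a planted congruency effect
#'
#' Trajectories run from the start button at (0, 0) to the chosen response at
#' (+/-1, 1.5) as quadratic Bezier curves whose control point is displaced
#' perpendicular to the direct path, toward the opposite response. The
#' displacement is twice the target maximum perpendicular deviation (MD), so
#' planted MD means are analytic: per trial,
#' `MD = baseline + emotion_effect * e + congruency_effect * I(incongruent) +
#' moderation * score * I(incongruent) + subject intercept + noise`.
#' Designated fractions of trials exceed the 2000 ms deadline or end at the
#' wrong response.
#'
#' @param spec a [design_spec()].
#' @param truth a [ground_truth()].
#' @param timeout_rate fraction of trials exceeding the deadline.
#' @param error_rate fraction of trials with an incorrect response.
#' @param seed RNG seed.
#' @param stereotype_scores optional per-subject planted scores; drawn from
#'   `N(truth$stereotype_bias, truth$stereotype_bias_sd)` (clamped to
#'   \[-2, 2\]) when omitted.
#' @param n_samples raw samples per trajectory (roughly 60 ms spacing at
#'   typical response times).
#' @return A `"trajectory_set"`: `trials` data frame (subject, block,
#'   condition, face_id, chosen_response, response_side, rt_ms, correct) and
#'   aligned `t`, `x`, `y` sample matrices (one row per trial), plus the
#'   per-subject `stereotype_scores`.
#' @export
gen_trajectories <- function(spec, truth, timeout_rate = 0.0283,
                             error_rate = 0.037, seed = 1L,
                             stereotype_scores = NULL, n_samples = 25) {
  stopifnot(inherits(spec, "design_spec"), inherits(truth, "ground_truth"))
  if (timeout_rate < 0 || timeout_rate >= 1 || error_rate < 0 || error_rate >= 1) {
    stop("rates must lie in [0, 1)")
  }
  set.seed(seed)
  ns <- spec$n_subjects
  if (is.null(stereotype_scores)) {
    stereotype_scores <- pmin(2, pmax(-2, truth$stereotype_bias +
                                        truth$stereotype_bias_sd * stats::rnorm(ns)))
  }
  nf <- spec$n_faces_per_cell
  conds <- rep(spec$conditions, each = nf)
  face <- paste0(conds, "_", rep(seq_len(nf), times = 4))
  one_block <- data.frame(condition = conds, face_id = face,
                          stringsAsFactors = FALSE)
  trials <- do.call(rbind, lapply(seq_len(ns), function(s) {
    b <- rbind(cbind(one_block, block = "gender"),
               cbind(one_block, block = "emotion"))
    b <- b[sample(nrow(b)), ]
    b$subject <- s
    b
  }))
  n <- nrow(trials)
  trials$score <- stereotype_scores[trials$subject]
  e_code <- condition_emotion_code(trials$condition)
  incong <- as.numeric(is_incongruent(trials$condition))
  subj_int <- truth$noise_sds$subject_intercept * stats::rnorm(ns)
  md_mu <- truth$baseline_md + truth$emotion_effect * e_code +
    truth$congruency_effect * incong +
    truth$moderation * trials$score * incong +
    subj_int[trials$subject]
  # mean-one lognormal trial noise: keeps MD non-negative and right-skewed
  # (as empirical MD distributions are) while preserving conditional means,
  # so regression recovery is unbiased
  s_log <- truth$noise_sds$md
  md_target <- md_mu * exp(s_log * stats::rnorm(n) - s_log^2 / 2)

  timeout <- stats::runif(n) < timeout_rate
  wrong <- !timeout & stats::runif(n) < error_rate
  trials$rt_ms <- ifelse(timeout, stats::runif(n, 2010, 2400),
                         stats::runif(n, 900, 1900))
  correct_resp <- ifelse(trials$block == "gender",
                         condition_gender(trials$condition),
                         condition_emotion(trials$condition))
  other <- function(r) c(male = "female", female = "male",
                         angry = "happy", happy = "angry")[r]
  trials$chosen_response <- ifelse(wrong, other(correct_resp), correct_resp)
  trials$correct <- !wrong
  trials$response_side <- sample(c("left", "right"), n, replace = TRUE)

  # quadratic Bezier in chosen-at-right coordinates, sampled uniformly in time
  s_grid <- seq(0, 1, length.out = n_samples)
  w0 <- (1 - s_grid)^2; w1 <- 2 * s_grid * (1 - s_grid); w2 <- s_grid^2
  nhat <- c(-1.5, 1) / sqrt(3.25)           # unit normal toward the opposite response
  cx <- 0.5 + 2 * md_target * nhat[1]
  cy <- 0.75 + 2 * md_target * nhat[2]
  x <- outer(cx, w1) + outer(rep(1, n), w2 * 1)
  y <- outer(cy, w1) + outer(rep(1, n), w2 * 1.5)
  mirror <- trials$response_side == "left"
  x[mirror, ] <- -x[mirror, ]
  t_ms <- outer(trials$rt_ms, s_grid)

  rownames(trials) <- NULL
  structure(list(trials = trials[, c("subject", "block", "condition", "face_id",
                                     "chosen_response", "response_side",
                                     "rt_ms", "correct", "score")],
                 t = t_ms, x = x, y = y,
                 stereotype_scores = stereotype_scores),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set: ", nrow(x$trials), " trials, ",
      length(unique(x$trials$subject)), " subjects, ",
      ncol(x$x), " samples/trajectory\n", sep = "")
  invisible(x)
}

#' Generate masked-discrimination responses with planted sensitivity
#'
#' Each subject categorizes the gender of all 140 masked faces once. True
#' sensitivity is drawn per subject and responses follow the equal-variance
#' signal-detection model with a neutral criterion: P(respond male | male) =
#' Phi(d'/2), P(respond male | female) = Phi(-d'/2). Defaults reflect the
#' near-chance group performance of a successful masking manipulation.
#'
#' @param spec a [design_spec()].
#' @param dprime_mean,dprime_sd mean and SD of planted per-subject d'.
#' @param seed RNG seed.
#' @return Data frame of trials: subject, face_id, actual_gender, response,
#'   plus per-subject `true_dprime`.
#' @export
gen_discrimination <- function(spec, dprime_mean = 0.22, dprime_sd = 0.40,
                               seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(seed)
  nf <- spec$n_faces_per_cell
  conds <- rep(spec$conditions, each = nf)
  face <- paste0(conds, "_", rep(seq_len(nf), times = 4))
  gender <- condition_gender(conds)
  d_true <- dprime_mean + dprime_sd * stats::rnorm(spec$n_subjects)
  out <- do.call(rbind, lapply(seq_len(spec$n_subjects), function(s) {
    p_male <- ifelse(gender == "male", stats::pnorm(d_true[s] / 2),
                     stats::pnorm(-d_true[s] / 2))
    data.frame(subject = s, face_id = face, actual_gender = gender,
               response = ifelse(stats::runif(length(face)) < p_male,
                                 "male", "female"),
               true_dprime = d_true[s], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
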