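#' Study design specification
#'
#' Bundles the design constants of the 2 (sex) x 2 (emotion) masked-face
#' paradigm: 35 faces per cell (140 total), 2000 ms trials built from four
#' 500 ms sub-sequences (33 ms face/mask + 167 ms mask/face + 300 ms
#' fixation), 77 null events per run, TR = 2 s and four runs of which the
#' first two are masked. These defaults are the study conditions; generators
#' derive all sizes from this object.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_faces_per_cell faces per sex x emotion cell.
#' @param trial_duration_ms trial duration in ms; must equal
#'   `4 * (33 + 167 + 300)`.
#' @param n_null_events null (fixation) events per run.
#' @param tr repetition time in seconds.
#' @param n_runs number of runs; the first half are masked.
#' @param seed RNG seed used by generators that take the spec.
#' @return A list of class `"design_spec"`.
#' @export
design_spec <- function(n_subjects = 34,
                        n_faces_per_cell = 35,
                        trial_duration_ms = 2000,
                        n_null_events = 77,
                        tr = 2,
                        n_runs = 4,
                        seed = 1L) {
  if (n_subjects < 1 || n_faces_per_cell < 1 || n_runs < 1) {
    stop("counts must be positive")
  }
  if (n_null_events < 0) stop("counts must be positive")
  if (trial_duration_ms != 4 * (33 + 167 + 300)) {
    stop("trial_duration_ms must equal 4 * (33 + 167 + 300) = 2000 ms")
  }
  if (tr <= 0) stop("tr must be positive")
  spec <- list(
    n_subjects = as.integer(n_subjects),
    n_faces_per_cell = as.integer(n_faces_per_cell),
    conditions = conditions(),
    trial_duration_ms = trial_duration_ms,
    n_null_events = as.integer(n_null_events),
    tr = tr,
    n_runs = as.integer(n_runs),
    seed = as.integer(seed)
  )
  class(spec) <- "design_spec"
  spec
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design: ", x$n_subjects, " subjects; ",
      4 * x$n_faces_per_cell, " faces (", x$n_faces_per_cell, "/cell); ",
      x$trial_duration_ms, " ms trials; ", x$n_runs, " runs (",
      x$n_runs %/% 2, " masked); ", x$n_null_events,
      " null events/run; TR ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' Planted effect structure for the synthetic data
#'
#' Encodes the ground-truth effects the generators plant and the downstream
#' stages must recover. Defaults follow the reported study-scale effects:
#' stereotype score mean 0.49 and SD 0.62; a stereotype-congruency MD effect
#' and its moderation by stereotype strength sized so the implied
#' gender x emotion GEE coefficient is -0.15 and the three-way coefficient is
#' -0.057 (under the +/-0.5 effect coding, the coded interaction coefficient
#' equals -2 x the congruency contrast); an emotion main effect of -0.06 on
#' the coded scale; baseline (congruent-cell) MD of about 0.405 with mean-one lognormal
#' trial noise (log-scale SD 0.9, i.e. per-trial SD about 0.5), giving
#' condition MD means near 0.38-0.50 and SDs near 0.5.
#'
#' @param stereotype_bias mean of the per-subject planted stereotype score.
#' @param stereotype_bias_sd between-subject SD of the planted score.
#' @param congruency_effect planted MD difference (incongruent - congruent)
#'   net of the moderation term.
#' @param moderation planted slope of the congruency effect on the
#'   (uncentered) stereotype score.
#' @param emotion_effect planted emotion main effect on the +/-0.5 coded
#'   scale (happy minus angry MD difference).
#' @param baseline_md mean MD of congruent trials at zero stereotype score.
#' @param planted_dm optional per-subject 4 x 4 target dissimilarity
#'   structure (a [dissimilarity_matrix()] or list of them).
#' @param ppi_coupling planted seed x condition interaction coefficient of
#'   the target BOLD model.
#' @param noise_sds named list of per-channel noise scales.
#' @return A list of class `"ground_truth"`.
#' @export
ground_truth <- function(stereotype_bias = 0.49,
                         stereotype_bias_sd = 0.62,
                         congruency_effect = 0.061,
                         moderation = 0.0285,
                         emotion_effect = -0.06,
                         baseline_md = 0.405,
                         planted_dm = NULL,
                         ppi_coupling = 0.3,
                         noise_sds = list(md = 0.9, rating = 0.25,
                                          subject_intercept = 0.1,
                                          pattern = 1, bold = 0.1)) {
  if (!is.null(planted_dm)) {
    dms <- if (inherits(planted_dm, "dissimilarity_matrix")) list(planted_dm) else planted_dm
    lapply(dms, function(d) dissimilarity_matrix(d))  # validates
  }
  truth <- list(
    stereotype_bias = stereotype_bias,
    stereotype_bias_sd = stereotype_bias_sd,
    congruency_effect = congruency_effect,
    moderation = moderation,
    emotion_effect = emotion_effect,
    baseline_md = baseline_md,
    planted_dm = planted_dm,
    ppi_coupling = ppi_coupling,
    noise_sds = noise_sds
  )
  class(truth) <- "ground_truth"
  truth
}

#' Implied regression coefficients of a ground truth
#'
#' Under the +/-0.5 effect coding the stereotype-incongruent indicator equals
#' `0.5 - 2 * gender * emotion`, so a planted congruency effect `ce` (plus
#' moderation `m` times the mean planted score `b`) implies a
#' gender x emotion coefficient of `-2 * (ce + m * b)` and a three-way
#' coefficient of `-2 * m` once scores are mean-centered.
#'
#' @param truth a [ground_truth()].
#' @param mean_bias mean stereotype score of the fitted sample; defaults to
#'   the planted mean.
#' @return Named vector with the implied `gender:emotion` and
#'   `gender:emotion:stereotype` coefficients.
#' @export
implied_coefficients <- function(truth, mean_bias = truth$stereotype_bias) {
  c(gender_emotion = -2 * (truth$congruency_effect + truth$moderation * mean_bias),
    gender_emotion_stereotype = -2 * truth$moderation)
}
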