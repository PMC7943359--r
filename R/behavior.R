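#' Multi-level regression of trajectory deviation
#'
#' Regresses per-trial maximum perpendicular deviation onto face gender
#' (male = -0.5, female = +0.5), face emotion (angry = -0.5, happy = +0.5),
#' the subject's mean-centered stereotype score and all their interactions,
#' with subject as the clustering unit (GEE, exchangeable working
#' correlation, robust SEs).
#'
#' @param md_trials trial table with `subject`, `condition` and `md` columns
#'   (e.g. from [md_table()] after [exclude_trials()]).
#' @param scores per-subject stereotype scores: a data frame with `subject`
#'   and `score` (see [stereotype_scores()]) or a named vector.
#' @param response which deviation measure to model.
#' @return A `"gee_fit"` (see [gee_gaussian()]) with an added
#'   `score_sd` element (SD of the subject scores, for simple slopes).
#' @export
fit_md_model <- function(md_trials, scores, response = c("md", "md_norm")) {
  response <- match.arg(response)
  if (length(unique(md_trials$subject)) < 2) stop("need at least 2 subjects")
  if (is.data.frame(scores)) {
    sc <- scores$score[match(md_trials$subject, scores$subject)]
    subj_scores <- scores$score
  } else {
    sc <- scores[as.character(md_trials$subject)]
    subj_scores <- scores
  }
  if (anyNA(sc)) stop("missing stereotype score for some subjects")
  d <- data.frame(
    y = md_trials[[response]],
    gender = condition_gender_code(md_trials$condition),
    emotion = condition_emotion_code(md_trials$condition),
    stereotype = sc - mean(subj_scores),
    subject = md_trials$subject
  )
  if (length(unique(d$gender)) < 2 || length(unique(d$emotion)) < 2) {
    stop("singular design: both levels of gender and emotion must be present")
  }
  fit <- gee_gaussian(y ~ gender * emotion * stereotype, data = d,
                      id = subject)
  fit$score_sd <- stats::sd(subj_scores)
  fit
}

#' Gender x emotion simple slopes at +/-1 SD of stereotype strength
#'
#' Evaluates the gender x emotion interaction coefficient at stereotype
#' strength one SD above and below the mean, as the linear combination
#' `B_ge + s0 * B_ges` with its delta-method (sandwich) standard error.
#'
#' @param fit a `"gee_fit"` from [fit_md_model()] (must include the
#'   three-way term).
#' @param sd_stereotype SD of the stereotype scores; defaults to the SD
#'   stored by [fit_md_model()].
#' @return Data frame with the interaction `B`, `SE`, `Z`, CI and `p` at
#'   `-1 SD` and `+1 SD`.
#' @export
simple_slopes <- function(fit, sd_stereotype = fit$score_sd) {
  stopifnot(inherits(fit, "gee_fit"))
  if (is.null(sd_stereotype) || sd_stereotype == 0) {
    stop("zero-variance stereotype scores: simple slopes undefined")
  }
  terms <- fit$terms
  i_ge <- which(terms == "gender:emotion")
  i_ges <- which(terms == "gender:emotion:stereotype")
  if (length(i_ge) != 1 || length(i_ges) != 1) {
    stop("fit must contain gender:emotion and gender:emotion:stereotype terms")
  }
  out <- lapply(c(-1, 1), function(sgn) {
    L <- numeric(length(terms))
    L[i_ge] <- 1
    L[i_ges] <- sgn * sd_stereotype
    b <- sum(L * fit$coefficients)
    se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
    data.frame(at = sprintf("%+d SD", sgn), B = b, SE = se, Z = b / se,
               ci_lower = b - 1.96 * se, ci_upper = b + 1.96 * se,
               p = 2 * stats::pnorm(-abs(b / se)))
  })
  do.call(rbind, out)
}

#' Signal-detection analysis of the masked discrimination task
#'
#' Computes d-prime for gender discrimination with male faces arbitrarily
#' defined as signal: `d' = z(hit rate) - z(false-alarm rate)`. Rates use
#' the log-linear correction (0.5 added to each count, 1 to each total) so
#' extreme proportions stay z-transformable. Subjects whose |d'| reaches the
#' chance band (0 +/- 1.74) are flagged as excluded (showing sensitivity to
#' the masked faces).
#'
#' @param actual_gender `"male"`/`"female"` per trial (the face shown).
#' @param response `"male"`/`"female"` per trial (the categorization).
#' @param chance_band half-width of the chance performance band.
#' @return Object of class `"signal_detection"`: `hits`, `false_alarms`
#'   (corrected rates), `d_prime`, `chance_band`, `excluded`.
#' @export
dprime <- function(actual_gender, response, chance_band = 1.74) {
  stopifnot(length(actual_gender) == length(response))
  male <- actual_gender == "male"
  if (sum(male) == 0 || sum(!male) == 0) stop("need both male and female trials")
  h <- (sum(response[male] == "male") + 0.5) / (sum(male) + 1)
  f <- (sum(response[!male] == "male") + 0.5) / (sum(!male) + 1)
  d <- stats::qnorm(h) - stats::qnorm(f)
  structure(list(hits = h, false_alarms = f, d_prime = d,
                 chance_band = chance_band,
                 excluded = abs(d) >= chance_band),
            class = "signal_detection")
}

#' @export
print.signal_detection <- function(x, digits = 3, ...) {
  cat("d' = ", round(x$d_prime, digits),
      " (hits ", round(x$hits, digits), ", false alarms ",
      round(x$false_alarms, digits), ")",
      if (x$excluded) " -- above chance band, excluded" else "",
      "\n", sep = "")
  invisible(x)
}
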