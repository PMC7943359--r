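#' Stimulus conditions of the 2 (sex) x 2 (emotion) face design
#'
#' The four stimulus conditions, in the canonical order used throughout the
#' package (dissimilarity matrices, pattern sets, vectorized pair order).
#'
#' @return Character vector of the four condition labels.
#' @export
conditions <- function() {
  c("angry_male", "happy_male", "angry_female", "happy_female")
}

#' @rdname conditions
#' @export
response_categories <- function() {
  c("angry", "happy", "male", "female")
}

# Effect coding used by the multi-level MD regression:
# gender male = -0.5, female = +0.5; emotion angry = -0.5, happy = +0.5.
condition_gender_code <- function(condition) {
  ifelse(grepl("female", condition), 0.5, -0.5)
}

condition_emotion_code <- function(condition) {
  ifelse(grepl("happy", condition), 0.5, -0.5)
}

condition_emotion <- function(condition) {
  ifelse(grepl("happy", condition), "happy", "angry")
}

condition_gender <- function(condition) {
  ifelse(grepl("female", condition), "female", "male")
}

#' Stereotype congruency of a condition
#'
#' Angry-male and happy-female pair category with its stereotypical
#' associate (congruent); angry-female and happy-male pair against it
#' (incongruent).
#'
#' @param condition character vector of condition labels.
#' @return Logical vector, `TRUE` where the condition is stereotype-incongruent.
#' @export
is_incongruent <- function(condition) {
  condition %in% c("angry_female", "happy_male")
}

match_conditions <- function(x) {
  bad <- setdiff(unique(x), conditions())
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = conditions())
}
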