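#' Pairwise category correlations of a ratings block
#'
#' Pearson correlations between the 30-length descriptor-rating vectors of
#' all pairs of the four categories.
#'
#' @param ratings a `"ratings_block"` or a 4 x n matrix with rows named
#'   angry, happy, male, female.
#' @return Named vector of the six pairwise correlations.
#' @export
category_correlations <- function(ratings) {
  m <- if (inherits(ratings, "ratings_block")) ratings$ratings else as.matrix(ratings)
  cats <- response_categories()
  if (!all(cats %in% rownames(m))) {
    stop("ratings must have rows named ", paste(cats, collapse = ", "))
  }
  m <- m[cats, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance rating vector for category: ",
         paste(cats[sds == 0], collapse = ", "))
  }
  pairs <- utils::combn(cats, 2)
  r <- apply(pairs, 2, function(p) stats::cor(m[p[1], ], m[p[2], ]))
  names(r) <- apply(pairs, 2, paste, collapse = "_")
  r
}

#' Stereotype-strength score
#'
#' Subtracts the stereotypically incongruent pair correlations from the
#' congruent ones, `[r(angry,male) + r(happy,female)] - [r(angry,female) +
#' r(happy,male)]`, normalized to the \[-2, 2\] scale (the published range:
#' 2 for a full male = angry / female = happy bias, -2 for the
#' counterstereotypical reverse). `normalize = FALSE` returns the raw
#' difference of sums (range \[-4, 4\]).
#'
#' @param ratings a `"ratings_block"` or 4 x n ratings matrix.
#' @param normalize divide by 2 to match the published \[-2, 2\] range.
#' @return List of class `"stereotype_score"`: `score` and the four
#'   `components` correlations.
#' @export
stereotype_score <- function(ratings, normalize = TRUE) {
  r <- category_correlations(ratings)
  comp <- c(r_angry_male = unname(r["angry_male"]),
            r_happy_female = unname(r["happy_female"]),
            r_angry_female = unname(r["angry_female"]),
            r_happy_male = unname(r["happy_male"]))
  raw <- (comp[1] + comp[2]) - (comp[3] + comp[4])
  structure(list(score = unname(if (normalize) raw / 2 else raw),
                 components = comp, normalized = normalize),
            class = "stereotype_score")
}

#' @export
print.stereotype_score <- function(x, digits = 3, ...) {
  cat("Stereotype-strength score: ", round(x$score, digits),
      if (x$normalized) " (scale [-2, 2])" else " (raw sum, scale [-4, 4])",
      "\n", sep = "")
  print(round(x$components, digits))
  invisible(x)
}

#' Stereotype scores for a list of ratings blocks
#'
#' @param ratings_list list of `"ratings_block"` objects.
#' @param normalize see [stereotype_score()].
#' @return Data frame with `subject`, `score` and (where available) the
#'   planted `true_bias`.
#' @export
stereotype_scores <- function(ratings_list, normalize = TRUE) {
  data.frame(
    subject = vapply(ratings_list, function(b) b$subject_id, numeric(1)),
    score = vapply(ratings_list,
                   function(b) stereotype_score(b, normalize)$score,
                   numeric(1)),
    true_bias = vapply(ratings_list, function(b) {
      if (is.null(b$true_bias)) NA_real_ else b$true_bias
    }, numeric(1))
  )
}

#' Stereotype congruency model dissimilarity matrix
#'
#' The theoretical DM encoding stronger similarity between the congruent
#' pair (angry male, happy female; distance 1) than the incongruent pair
#' (angry female, happy male; distance 2). The four pairs the hypothesis
#' leaves unspecified (within-sex and within-emotion) sit at the midpoint
#' 1.5, encoding no directional prediction.
#'
#' @param unspecified value for the four unspecified pairs.
#' @return A [dissimilarity_matrix()].
#' @export
congruency_dm <- function(unspecified = 1.5) {
  labs <- conditions()
  m <- matrix(unspecified, 4, 4, dimnames = list(labs, labs))
  diag(m) <- 0
  m["angry_male", "happy_female"] <- m["happy_female", "angry_male"] <- 1
  m["angry_female", "happy_male"] <- m["happy_male", "angry_female"] <- 2
  dissimilarity_matrix(m, labs)
}
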