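# shared fixtures, built in code

small_design <- function(n_subjects = 4, seed = 1L) {
  design_spec(n_subjects = n_subjects, seed = seed)
}

# random valid dissimilarity matrix (distances of a random correlation matrix)
random_dm <- function(seed, k = 10) {
  set.seed(seed)
  pearson_distance_dm(matrix(rnorm(4 * k), 4, k), labels = conditions())
}

# build a one-trial trajectory_set by hand from a single path
one_trial_set <- function(t, x, y, condition = "angry_male",
                          block = "gender", chosen = "male",
                          side = "right", rt = max(t), correct = TRUE) {
  structure(list(
    trials = data.frame(subject = 1, block = block, condition = condition,
                        face_id = "f1", chosen_response = chosen,
                        response_side = side, rt_ms = rt, correct = correct),
    t = matrix(t, 1), x = matrix(x, 1), y = matrix(y, 1),
    stereotype_scores = 0), class = "trajectory_set")
}

# brute-force point-by-point MD oracle: walk the path tracking the point of
# largest absolute perpendicular distance from the line (0,0) -> (1, 1.5)
# (positive side faces the opposite response at (-1, 1.5)) and report its
# signed value
oracle_md <- function(coords) {
  best <- 0
  for (i in seq_len(nrow(coords))) {
    si <- (1 * coords[i, 2] - 1.5 * coords[i, 1]) / sqrt(1 + 1.5^2)
    if (abs(si) > abs(best)) best <- unname(si)
  }
  best
}

expect_valid_dm <- function(dm) {
  m <- unclass(dm)
  expect_true(isSymmetric(m, tol = 1e-10))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  expect_true(all(m >= -1e-12 & m <= 2 + 1e-12))
}
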