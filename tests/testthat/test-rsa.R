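test_that("neural DMs are Pearson distances over in-mask voxels", {
  set.seed(1)
  m <- matrix(rnorm(4 * 40), 4, 40, dimnames = list(conditions(), NULL))
  m[2, ] <- m[1, ]          # duplicated condition
  m[4, ] <- -m[3, ]         # sign-flipped pair
  dm <- neural_dm(voxel_pattern_set(m))
  expect_valid_dm(dm)
  expect_equal(dm[1, 2], 0)
  expect_equal(dm[3, 4], 2)
  # mask restriction
  mask <- rep(c(TRUE, FALSE), 20)
  dm_m <- neural_dm(voxel_pattern_set(m), mask)
  expect_equal(dm_m[1, 2], 0)
  expect_error(neural_dm(voxel_pattern_set(m), rep(FALSE, 40)), "2 in-mask")
  m[1, ] <- m[2, ] <- 1
  expect_error(neural_dm(voxel_pattern_set(m)), "zero-variance")
})

test_that("DM vectorization uses the fixed pair order and round-trips", {
  v <- vectorize_dm(congruency_dm())
  expect_equal(unname(v), c(1.5, 1.5, 2, 1, 1.5, 1.5))
  expect_equal(names(v)[3], "angry_female~happy_male")
  expect_equal(names(v)[4], "happy_female~angry_male")
  z <- dissimilarity_matrix(matrix(0, 4, 4))
  expect_equal(unname(vectorize_dm(z)), rep(0, 6))
  # round-trip
  dm <- random_dm(3)
  expect_equal(dm_from_vector(vectorize_dm(dm)), dm)
  expect_error(dissimilarity_matrix(matrix(1:16, 4)), "symmetric")
})

test_that("Spearman RSA matches a brute-force rank computation", {
  dm <- random_dm(5)
  expect_equal(spearman_rsa(dm, dm)$rho, 1)
  # reversed ranks
  v <- vectorize_dm(dm)
  rev_dm <- dm_from_vector(max(v) + min(v) - v)
  expect_equal(spearman_rsa(dm, rev_dm)$rho, -1)
  # tie handling vs brute-force average ranks
  a <- c(1, 2, 2, 3, 4, 5)
  b <- c(2, 1, 4, 4, 5, 6)
  r <- spearman_rsa(a, b)
  ra <- rank(a); rb <- rank(b)
  hand <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(r$rho, hand)
  expect_equal(r$fisher_z, atanh(hand))
  expect_equal(r$n_pairs, 6)
  expect_error(spearman_rsa(rep(1, 6), b), "constant")
})

test_that("Spearman RSA is invariant under monotone transforms", {
  set.seed(7)
  for (i in 1:20) {
    a <- runif(6); b <- runif(6)
    r0 <- spearman_rsa(a, b)$rho
    expect_equal(spearman_rsa(exp(3 * a), b)$rho, r0)
    expect_equal(spearman_rsa(a, b^3 + b)$rho, r0)
  }
})

test_that("regression RSA recovers exact and null relations", {
  dm <- random_dm(9)
  cov_dm <- random_dm(10)
  # neural equals predictor: exact fit, zero residuals
  r <- regression_rsa(dm, dm, list(cov_dm))
  expect_equal(r$beta, 1)
  expect_equal(unname(r$residuals), rep(0, 6), tolerance = 1e-10)
  # predictor with rank-orthogonal neural: beta ~ 0
  y <- c(1, 6, 2, 5, 3, 4)
  x <- c(1, 2, 3, 4, 5, 6)  # ranks orthogonal to centred y ranks? check beta
  rx <- rank(x) - mean(rank(x)); ry <- rank(y) - mean(rank(y))
  r2 <- regression_rsa(y, x)
  expect_equal(r2$beta, sum(rx * ry) / sum(rx^2))
  # collinear covariate is diagnosed
  expect_error(regression_rsa(dm, dm, list(dm)), "collinear")
})

test_that("rank regression without covariates equals Spearman rho", {
  set.seed(13)
  for (i in 1:20) {
    a <- random_dm(100 + i)
    b <- random_dm(200 + i)
    beta <- regression_rsa(a, b)$beta
    rho <- spearman_rsa(a, b)$rho
    # equal rank variances (no ties): the slope IS the rank correlation
    expect_equal(beta, rho, tolerance = 1e-10)
  }
})

test_that("group tests implement the textbook t and transforms", {
  v <- c(0.12, 0.3, -0.05, 0.21, 0.4)
  g <- group_test(v)
  hand_t <- mean(v) / (sd(v) / sqrt(5))
  expect_equal(g$t, hand_t)
  expect_equal(g$df, 4)
  expect_equal(g$p, 2 * pt(-abs(hand_t), 4))
  # fisher-z transform applied before testing
  gz <- group_test(v, transform = "fisher_z")
  expect_equal(gz$mean, mean(atanh(v)))
  # symmetric values around 0: t = 0
  expect_equal(group_test(c(-0.2, 0.2, -0.1, 0.1))$t, 0)
  expect_error(group_test(rep(0.3, 4)), "zero variance")
  expect_error(group_test(0.5), "2 subjects")
})

test_that("paired contrasts follow the hand-computed paired t", {
  a <- c(0.5, 0.7, 0.6, 0.9)
  b <- c(0.3, 0.5, 0.65, 0.4)
  pc <- paired_contrast(a, b)
  d <- a - b
  expect_equal(pc$t, mean(d) / (sd(d) / sqrt(4)))
  # identical vectors: t = 0 by convention
  expect_equal(paired_contrast(a, a)$t, 0)
  # nonzero constant difference: zero-variance error path
  expect_error(paired_contrast(a, a - 0.1), "zero variance")
  expect_error(paired_contrast(a, b[1:3]), "equal length")
})

test_that("subject-specific planted structure is recovered by RSA", {
  ns <- 24
  sdms <- gen_subject_dms(ns, seed = 31)
  gdm <- dissimilarity_matrix(Reduce(`+`, lapply(sdms, unclass)) / ns)
  betas <- function(w, seed0) {
    sapply(seq_len(ns), function(s) {
      tgt <- blend_dms(sdms[[s]], gdm, w)
      pat <- gen_patterns(tgt, 300, noise_sd = 1, seed = seed0 + s)
      tryCatch(regression_rsa(neural_dm(pat), sdms[[s]], list(gdm))$beta,
               error = function(e) NA_real_)
    })
  }
  b_un <- betas(1, 100)    # "unmasked": own structure planted
  b_ma <- betas(0, 400)    # "masked": group structure only
  ok <- complete.cases(b_un, b_ma)
  expect_gt(group_test(b_un[ok])$t, 2)             # strongly positive
  expect_lt(abs(group_test(b_ma[ok])$t), 2.5)      # near zero at group level
  expect_gt(paired_contrast(b_un[ok], b_ma[ok])$t, 2)
})
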