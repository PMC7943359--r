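test_that("gamma HRF peaks at p*q seconds with a causal nonneg kernel", {
  hp <- hrf_params()
  k <- gamma_hrf(hp, dt = 0.001)
  # calculus oracle: maximize log h on a fine grid
  t_peak <- (which.max(k) - 1) * 0.001
  expect_equal(t_peak, hp$p * hp$q, tolerance = 0.002)
  expect_equal(k[1], 0)
  expect_true(all(k >= 0))
  expect_equal(max(k), 1, tolerance = 1e-6)  # unit analytic peak
  expect_error(hrf_params(p = -1), "positive")
})

test_that("design matrices are boxcar-convolved and linear in events", {
  tr <- 2
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      condition = character(0))
  X0 <- build_design(empty, n_volumes = 20, tr = tr)
  expect_equal(dim(X0), c(20, 4))
  expect_true(all(X0 == 0))

  one <- data.frame(onset = 10, duration = 2, condition = "angry_male")
  X1 <- build_design(one, 40, tr)
  expect_true(all(X1[, setdiff(conditions(), "angry_male")] == 0))
  expect_equal(which(X1[, "angry_male"] > 1e-8)[1], 7)  # starts after onset

  # two overlapping events: column equals the sum of shifted responses
  two <- data.frame(onset = c(10, 12), duration = c(2, 2),
                    condition = "angry_male")
  X2 <- build_design(two, 40, tr)
  shift1 <- build_design(data.frame(onset = 10, duration = 2,
                                    condition = "angry_male"), 40, tr)
  shift2 <- build_design(data.frame(onset = 12, duration = 2,
                                    condition = "angry_male"), 40, tr)
  expect_equal(X2[, "angry_male"],
               shift1[, "angry_male"] + shift2[, "angry_male"],
               tolerance = 1e-12)

  # categories scheme loads each face event on two columns
  Xc <- build_design(one, 40, tr, scheme = "categories")
  expect_equal(colnames(Xc), response_categories())
  expect_equal(Xc[, "angry"], Xc[, "male"])
  expect_true(all(Xc[, "happy"] == 0))

  expect_error(build_design(data.frame(onset = 100, duration = 2,
                                       condition = "angry_male"), 20, tr),
               "beyond the scan")
})

test_that("voxelwise GLM recovers betas and scales linearly", {
  sch <- data.frame(onset = seq(0, 180, by = 20), duration = 2,
                    condition = rep(conditions(), length.out = 10))
  X <- build_design(sch, 100, 2)
  set.seed(8)
  B <- matrix(rnorm(4 * 30), 4, 30)
  Y <- X %*% B + 3
  g <- fit_glm(Y, X)
  expect_equal(unname(g$beta), unname(B), tolerance = 1e-8)
  # doubling a regressor's amplitude halves its beta for fixed data
  X2 <- X
  X2[, 1] <- 2 * X2[, 1]
  attr(X2, "conditions") <- attr(X, "conditions")
  g2 <- fit_glm(Y, X2)
  expect_equal(unname(g2$beta[1, ]), unname(g$beta[1, ]) / 2,
               tolerance = 1e-8)
  # rank deficiency is diagnosed
  X3 <- cbind(X, dup = X[, 1])
  expect_error(fit_glm(Y, X3), "rank-deficient")
})

test_that("pure-noise t statistics follow the central t distribution", {
  sch <- data.frame(onset = seq(0, 180, by = 20), duration = 2,
                    condition = rep(conditions(), length.out = 10))
  X <- build_design(sch, 100, 2)
  set.seed(9)
  Y <- matrix(rnorm(100 * 10000), 100)
  g <- fit_glm(Y, X)
  ks <- ks.test(g$t[1, ], pt, df = g$df)
  expect_gt(ks$p.value, 0.01)
})

test_that("condition patterns are run-averaged and z-normalized", {
  set.seed(10)
  m1 <- matrix(rnorm(4 * 50), 4, 50, dimnames = list(conditions(), NULL))
  m2 <- matrix(rnorm(4 * 50), 4, 50, dimnames = list(conditions(), NULL))
  # single run: z-normalized copy
  p1 <- condition_patterns(list(m1))
  zn <- t(apply(m1, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2))))
  expect_equal(unclass(p1), zn, ignore_attr = TRUE)
  # two runs: hand average then normalize
  p12 <- condition_patterns(list(m1, m2))
  avg <- (m1 + m2) / 2
  zn2 <- t(apply(avg, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2))))
  expect_equal(unclass(p12), zn2, ignore_attr = TRUE)
  # normalization conservation: mean 0, population SD 1 exactly
  expect_equal(unname(rowMeans(p12)), rep(0, 4))
  expect_equal(unname(apply(unclass(p12), 1,
                            function(r) sqrt(mean(r^2)))), rep(1, 4))
  # mask restriction and degenerate input
  mask <- c(rep(TRUE, 30), rep(FALSE, 20))
  expect_equal(ncol(condition_patterns(list(m1), mask)), 30)
  expect_error(condition_patterns(list(matrix(1, 4, 50))), "constant")
  expect_error(condition_patterns(list(m1, m2[, 1:10])), "inconsistent")
})

test_that("patterns estimated from synthetic BOLD recover planted patterns", {
  # each condition drives its own +/-1 spatial pattern; the z-normalized
  # estimated patterns must reproduce the planted signs voxelwise
  sch <- data.frame(onset = seq(0, 420, by = 6), duration = 2,
                    condition = rep(conditions(), length.out = 71))
  n_vol <- 240
  X <- build_design(sch, n_vol, 2)
  set.seed(11)
  P <- matrix(sample(c(-1, 1), 4 * 60, replace = TRUE), 4, 60)
  Y <- X %*% P + 0.5 * matrix(rnorm(n_vol * 60), n_vol, 60)
  g <- fit_glm(Y, X)
  pats <- condition_patterns(list(g$t))
  sign_agreement <- mean(sign(unclass(pats)) == sign(P))
  expect_gt(sign_agreement, 0.95)
  # and the estimated neural DM mirrors the planted one in rank order
  planted_dm <- pearson_distance_dm(P, labels = conditions())
  expect_gt(spearman_rsa(neural_dm(pats), planted_dm)$rho, 0.7)
})
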