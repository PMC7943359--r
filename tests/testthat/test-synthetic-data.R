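test_that("event schedules carry the design constants", {
  sp <- small_design(seed = 3)
  sch <- make_schedule(sp)
  expect_equal(unique(sch$duration), 2)   # four 500 ms sub-sequences = 2 s
  # per run: half the 140 faces twice + 77 nulls
  for (r in unique(sch$run)) {
    run <- sch[sch$run == r, ]
    expect_equal(sum(run$condition == "null"), 77)
    expect_equal(sum(run$condition != "null"), 140)
    # each presented face appears exactly twice
    expect_true(all(table(run$face_id[run$condition != "null"]) == 2))
    # onsets on the TR grid
    expect_true(all(run$onset %% sp$tr == 0))
  }
  # masked runs precede unmasked
  expect_true(max(sch$run[sch$masking == "masked"]) <
                min(sch$run[sch$masking == "unmasked"]))
})

test_that("schedules are deterministic under seed and reject bad counts", {
  expect_identical(make_schedule(small_design(seed = 9)),
                   make_schedule(small_design(seed = 9)))
  expect_error(design_spec(n_faces_per_cell = 0), "positive")
  expect_error(design_spec(n_null_events = -1), "positive")
  expect_error(design_spec(trial_duration_ms = 1900), "2000")
  sch0 <- make_schedule(design_spec(n_null_events = 0, seed = 1))
  expect_equal(sum(sch0$condition == "null"), 0)
})

test_that("noiseless rating construction attains the planted score exactly", {
  r <- gen_ratings(3, bias_mean = 2, bias_sd = 0, noise_sd = 0, seed = 1)
  for (b in r) expect_equal(stereotype_score(b)$score, 2, tolerance = 1e-12)
  # determinism
  r2 <- gen_ratings(3, bias_mean = 2, bias_sd = 0, noise_sd = 0, seed = 1)
  expect_identical(lapply(r, `[[`, "ratings"), lapply(r2, `[[`, "ratings"))
  expect_error(gen_ratings(2, bias_mean = 2.5), "\\[-2, 2\\]")
})

test_that("rating noise leaves the mean recovered score unbiased", {
  r <- gen_ratings(200, bias_mean = 0, bias_sd = 0.62, seed = 7)
  sc <- stereotype_scores(r)
  se <- sd(sc$score) / sqrt(nrow(sc))
  expect_lt(abs(mean(sc$score)), 2 * se + 1e-12)
  # planted per-subject bias is tracked closely
  expect_gt(cor(sc$score, sc$true_bias), 0.9)
})

test_that("null-effect trajectories have equal MD across conditions", {
  sp <- small_design(n_subjects = 2, seed = 2)
  tr <- ground_truth(congruency_effect = 0, moderation = 0,
                     emotion_effect = 0, stereotype_bias = 0,
                     stereotype_bias_sd = 0,
                     noise_sds = list(md = 0, rating = 0.5,
                                      subject_intercept = 0,
                                      pattern = 1, bold = 0.1))
  ts <- gen_trajectories(sp, tr, timeout_rate = 0, error_rate = 0, seed = 4)
  md <- md_table(ts)
  means <- tapply(md$md, md$condition, mean)
  expect_equal(max(means) - min(means), 0, tolerance = 1e-10)
  expect_equal(unname(means[1]), tr$baseline_md, tolerance = 1e-10)
})

test_that("planted congruency effect is recovered from trajectories", {
  sp <- design_spec(n_subjects = 40, seed = 5)
  tr <- ground_truth(moderation = 0, stereotype_bias = 0)
  ts <- gen_trajectories(sp, tr, seed = 6)
  md <- md_table(exclude_trials(ts))
  diff <- mean(md$md[is_incongruent(md$condition)]) -
    mean(md$md[!is_incongruent(md$condition)])
  # incongruent - congruent difference ~ congruency_effect (emotion effect
  # cancels across the balanced design)
  expect_lt(abs(diff - tr$congruency_effect), 0.02)
})

test_that("timeout flagging matches its binomial rate", {
  sp <- design_spec(n_subjects = 4, seed = 8)  # 1120 trials
  ts <- gen_trajectories(sp, ground_truth(), timeout_rate = 0.1,
                         error_rate = 0, seed = 9)
  n <- nrow(ts$trials)
  n_to <- sum(ts$trials$rt_ms > 2000)
  band <- qbinom(c(0.005, 0.995), n, 0.1)
  expect_gte(n_to, band[1])
  expect_lte(n_to, band[2])
  expect_error(gen_trajectories(sp, ground_truth(), timeout_rate = 1),
               "rates")
})

test_that("gen_patterns realizes its target correlation structure", {
  # identity correlation target: off-diagonal distances 1 +/- sampling error
  dm0 <- dissimilarity_matrix(matrix(1, 4, 4) - diag(1, 4))
  nd <- neural_dm(gen_patterns(dm0, 10000, noise_sd = 0, seed = 5))
  expect_true(all(abs(vectorize_dm(nd) - 1) < 0.05))
  # perfectly correlated pair: distance exactly 0 at zero noise
  m <- matrix(1, 4, 4) - diag(1, 4)
  m[1, 2] <- m[2, 1] <- 0
  p <- gen_patterns(dissimilarity_matrix(m), 100, noise_sd = 0, seed = 2)
  expect_equal(neural_dm(p)["angry_male", "happy_male"], 0, tolerance = 1e-8)
  # determinism
  expect_identical(gen_patterns(dm0, 50, 0.5, seed = 3),
                   gen_patterns(dm0, 50, 0.5, seed = 3))
  # non-PSD target diagnosed
  bad <- matrix(2, 4, 4) - 2 * diag(1, 4)
  bad[1, 2] <- bad[2, 1] <- 0
  expect_error(gen_patterns(dissimilarity_matrix(bad), 10),
               "positive semi-definite")
})

test_that("gen_bold_session plants the seed-target coupling structure", {
  sch <- make_schedule(small_design(n_subjects = 1, seed = 2))
  # noiseless, a = 1, c = 0: target equals the seed's evoked component
  tr0 <- ground_truth(ppi_coupling = 0)
  s0 <- gen_bold_session(sch, tr0, noise_sd = 0, seed = 1)
  expect_equal(s0$target$series, s0$seed$series, tolerance = 1e-12)
  # the condition regressor covers both masking levels
  expect_setequal(unique(s0$condition), c(-1, 1))
  expect_error(gen_bold_session(sch[sch$masking == "masked", ], tr0),
               "both masking conditions")
})

test_that("volume datasets respect region geometry and determinism", {
  dms <- gen_subject_dms(2, seed = 1)
  expect_error(gen_volume_dataset(c(8, 8, 8),
                                  list(list(center = c(2, 4, 4), radius = 3)),
                                  dms),
               "fit inside")
  expect_error(gen_volume_dataset(c(12, 12, 12),
                                  list(list(center = c(6, 6, 6), radius = 2),
                                       list(center = c(7, 6, 6), radius = 2)),
                                  dms),
               "overlap")
  v1 <- gen_volume_dataset(c(10, 10, 10),
                           list(list(center = c(5, 5, 5), radius = 2)),
                           dms, seed = 4)
  v2 <- gen_volume_dataset(c(10, 10, 10),
                           list(list(center = c(5, 5, 5), radius = 2)),
                           dms, seed = 4)
  expect_identical(v1$volumes, v2$volumes)
  # in-region voxels carry the planted structure
  idx <- which(v1$region_masks[[1]])
  pats <- sapply(1:4, function(ci) v1$volumes[[1]][, , , ci][idx])
  nd <- neural_dm(voxel_pattern_set(t(pats)))
  expect_valid_dm(nd)
})
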