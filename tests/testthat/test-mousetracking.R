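test_that("trial exclusion follows the deadline and accuracy rules", {
  trials <- data.frame(
    subject = 1,
    condition = rep(conditions(), length.out = 10),
    block = "gender",
    rt_ms = c(2100, rep(1500, 9)),
    correct = c(TRUE, FALSE, FALSE, rep(TRUE, 7))
  )
  kept <- exclude_trials(trials)
  expect_equal(nrow(kept), 7)
  rep <- attr(kept, "exclusion_report")
  expect_equal(rep$n[rep$rule == "timeout"], 1)
  expect_equal(rep$n[rep$rule == "incorrect"], 2)
  expect_equal(rep$fraction[rep$rule == "retained"], 0.7)

  # the deadline must be *exceeded*: exactly 2000 ms is retained
  trials$rt_ms[1] <- 2000
  expect_equal(nrow(exclude_trials(trials)), 8)

  # all clean -> identity
  trials$correct <- TRUE
  expect_equal(nrow(exclude_trials(trials)), 10)

  # an emptied subject x condition cell is diagnosed
  bad <- trials
  bad$correct[bad$condition == "angry_male"] <- FALSE
  expect_error(exclude_trials(bad), "angry_male")
})

test_that("trajectory normalization translates, mirrors and interpolates", {
  # straight line preserved, endpoints exact
  n <- normalize_trajectory(t = c(0, 500, 1000), x = c(0, 0.5, 1),
                            y = c(0, 0.75, 1.5), n_bins = 10)
  expect_equal(n[1, ], c(x = 0, y = 0))
  expect_equal(n[11, ], c(x = 1, y = 1.5))
  expect_equal(unname(n[, 2] / n[, 1])[-1], rep(1.5, 10))

  # left responses are mirrored about the vertical axis
  nl <- normalize_trajectory(t = c(0, 1000), x = c(0, -1), y = c(0, 1.5),
                             response_side = "left", n_bins = 4)
  expect_equal(unname(nl[5, ]), c(1, 1.5))

  # irregular sampling: hand-computed linear interpolation on 3 points
  # t = 0, 300, 1000; querying t = 500 mixes the last two samples
  ni <- normalize_trajectory(t = c(0, 300, 1000), x = c(0, 0.3, 1),
                             y = c(0, 0.1, 1.5), n_bins = 2)
  w <- (500 - 300) / (1000 - 300)
  expect_equal(unname(ni[2, ]), c(0.3 + w * 0.7, 0.1 + w * 1.4))

  expect_error(normalize_trajectory(t = 1, x = 0, y = 0), "2 samples")
  expect_error(normalize_trajectory(t = c(0, 0), x = c(0, 1), y = c(0, 1)),
               "strictly increasing")
})

test_that("maximum deviation matches the planar point-line oracle", {
  # straight-line trajectory: no deviation
  straight <- cbind(seq(0, 1, 0.1), 1.5 * seq(0, 1, 0.1))
  expect_equal(compute_md(straight)$md, 0)

  # worked example: path (0,0) -> (-0.5, 0.75) -> (1, 1.5)
  path <- rbind(c(0, 0), c(-0.5, 0.75), c(1, 1.5))
  m <- compute_md(path)
  expect_equal(m$md, 1.5 / sqrt(3.25), tolerance = 1e-12)
  expect_equal(m$md_norm, (1.5 / sqrt(3.25)) / max_possible_md())

  # bulge entirely toward the chosen side: negative MD, clamped norm
  chosen_side <- rbind(c(0, 0), c(0.6, 0.5), c(1, 1.5))
  m2 <- compute_md(chosen_side)
  expect_lt(m2$md, 0)
  expect_equal(m2$md_norm, 0)
})

test_that("MD equals the brute-force oracle on generated trajectories", {
  sp <- design_spec(n_subjects = 4, seed = 13)
  ts <- gen_trajectories(sp, ground_truth(), seed = 13)
  md <- md_table(ts)
  for (i in sample(nrow(ts$trials), 200)) {
    coords <- normalize_trajectory(ts$t[i, ], ts$x[i, ], ts$y[i, ],
                                   ts$trials$response_side[i])
    expect_equal(md$md[i], oracle_md(coords), tolerance = 1e-10)
  }
})

test_that("mirroring a path with its response side leaves MD unchanged", {
  set.seed(21)
  for (i in 1:20) {
    t <- sort(runif(12, 0, 1500)); t[1] <- 0
    x <- c(0, cumsum(rnorm(11, 0.1, 0.2)))
    y <- c(0, cumsum(abs(rnorm(11, 0.15, 0.1))))
    md_r <- compute_md(normalize_trajectory(t, x, y, "right"))$md
    md_l <- compute_md(normalize_trajectory(t, -x, y, "left"))$md
    expect_equal(md_r, md_l, tolerance = 1e-12)
  }
})

test_that("bias vectors implement the MD/max(MD) similarity bookkeeping", {
  v <- condition_bias_vector("angry_male", md_norm_emotion = 0.2,
                             md_norm_gender = 0.1)
  expect_equal(v, c(angry = 0.8, happy = 0.2, male = 0.9, female = 0.1))
  v5 <- condition_bias_vector("happy_female", 0.5, 0.5)
  expect_equal(unname(v5), rep(0.5, 4))
  v0 <- condition_bias_vector("happy_male", 0, 0)
  expect_equal(v0, c(angry = 0, happy = 1, male = 1, female = 0))
  expect_error(condition_bias_vector("angry_male", numeric(0), 0.1),
               "missing block")
})

test_that("subjective DMs are Pearson distances with their invariances", {
  b <- rbind(angry_male = c(0.8, 0.2, 0.9, 0.1),
             happy_male = c(0.3, 0.7, 0.8, 0.2),
             angry_female = c(0.6, 0.4, 0.3, 0.7),
             happy_female = c(0.1, 0.9, 0.2, 0.8))
  dm <- subjective_dm(b)
  expect_valid_dm(dm)
  # identical vectors -> 0; affine transform -> 0; reversal -> 2
  b2 <- b
  b2["happy_male", ] <- b["angry_male", ]
  expect_equal(subjective_dm(b2)["angry_male", "happy_male"], 0)
  b2["happy_male", ] <- 3 + 2 * b["angry_male", ]
  expect_equal(subjective_dm(b2)["angry_male", "happy_male"], 0)
  b2["happy_male", ] <- -b["angry_male", ]
  expect_equal(subjective_dm(b2)["angry_male", "happy_male"], 2)
  # zero-variance vector diagnosed
  b2["happy_male", ] <- 0.5
  expect_error(subjective_dm(b2), "zero-variance")
})

test_that("group-average DM averages vectors before distances", {
  b1 <- rbind(angry_male = c(0.9, 0.1, 0.8, 0.2),
              happy_male = c(0.2, 0.8, 0.7, 0.3),
              angry_female = c(0.7, 0.3, 0.2, 0.8),
              happy_female = c(0.1, 0.9, 0.1, 0.9))
  b2 <- b1 + 0.05 * matrix(c(1, -1), 4, 4)
  # single subject: equals that subject's own DM
  expect_equal(group_average_dm(list(b1)), subjective_dm(b1))
  # duplicated subject: unchanged
  expect_equal(group_average_dm(list(b1, b1)), subjective_dm(b1))
  # two subjects: mean-then-distance, not distance-then-mean
  expect_equal(unclass(group_average_dm(list(b1, b2))),
               unclass(pearson_distance_dm((b1 + b2) / 2)))
  rownames(b2) <- rev(rownames(b1))
  expect_error(group_average_dm(list(b1, b2)), "mismatched")
})

test_that("planted congruency raises incongruent-condition MD", {
  sp <- design_spec(n_subjects = 12, seed = 31)
  ts <- gen_trajectories(sp, ground_truth(), seed = 31)
  sdm <- subjective_dms(ts)
  md <- sdm$md_trials
  expect_gt(mean(md$md[is_incongruent(md$condition)]),
            mean(md$md[!is_incongruent(md$condition)]))
  for (d in sdm$subject_dms) expect_valid_dm(d)
  expect_valid_dm(sdm$group_dm)
})
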