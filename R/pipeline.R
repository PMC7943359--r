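#' Pipeline configuration
#'
#' Assembles (and validates) the full simulate-to-report configuration:
#' design constants, planted ground truth, module parameters and the master
#' seed. The configuration round-trips through YAML ([write_config()] /
#' [read_config()]).
#'
#' @param design named list of [design_spec()] arguments.
#' @param truth named list of [ground_truth()] arguments.
#' @param params named list of module parameters: `n_bins`, `radius`,
#'   `fwhm_mm`, `voxel_size_mm`, `n_perm`, `hrf` (list `p`, `q`,
#'   `length_s`), `ridge`, `n_voxels_roi`, `grid_dims`, `region_radius`,
#'   `pattern_noise_sd`.
#' @param seed master seed; stage seeds are derived by fixed offsets.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(design = list(), truth = list(),
                            params = list(), seed = 1L) {
  defaults <- list(
    n_bins = 100, radius = 3, fwhm_mm = 6, voxel_size_mm = 2,
    n_perm = 500, hrf = list(p = 8.6, q = 0.547, length_s = 20),
    ridge = 1e-3, n_voxels_roi = 200, grid_dims = c(14, 14, 14),
    region_radius = 3, pattern_noise_sd = 1
  )
  params <- utils::modifyList(defaults, params)
  cfg <- list(design = design, truth = truth, params = params,
              seed = as.integer(seed))
  # validate by construction
  do.call(design_spec, cfg$design)
  do.call(ground_truth, cfg$truth)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(design = raw$design, truth = raw$truth,
                  params = raw$params, seed = raw$seed)
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes simulate, mouse-tracking, stereotype scoring, behavioral models
#' (GEE and d'), ROI RSA, searchlight with group permutation, PPI and the
#' connectivity-representation link on one synthetic dataset, and returns a
#' machine-readable results list. With `out_dir` set, writes `results.json`
#' and a human-readable `summary.txt`.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param verbose log each stage.
#' @return Results list (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- function(...) if (verbose) message("[stereorsa] ", ...)
  stage <- function(name, expr) {
    log(name, " (seed ", cfg$seed, ")")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  p <- cfg$params
  hrf <- hrf_params(p$hrf$p, p$hrf$q, p$hrf$length_s)

  design <- do.call(design_spec, utils::modifyList(cfg$design,
                                                   list(seed = cfg$seed)))
  truth <- do.call(ground_truth, cfg$truth)
  ns <- design$n_subjects

  schedule <- stage("simulate: schedule", make_schedule(design))
  ratings <- stage("simulate: ratings",
                   gen_ratings(ns, bias_mean = truth$stereotype_bias,
                               bias_sd = truth$stereotype_bias_sd,
                               noise_sd = truth$noise_sds$rating,
                               seed = cfg$seed + 1))
  planted_bias <- vapply(ratings, function(b) b$true_bias, numeric(1))
  trajset <- stage("simulate: trajectories",
                   gen_trajectories(design, truth, seed = cfg$seed + 2,
                                    stereotype_scores = planted_bias))
  discrim <- stage("simulate: discrimination",
                   gen_discrimination(design, seed = cfg$seed + 3))

  scores <- stage("stereotype scores", stereotype_scores(ratings))
  sdm <- stage("mouse-tracking DMs",
               subjective_dms(trajset, n_bins = p$n_bins))
  gee <- stage("GEE model", fit_md_model(sdm$md_trials, scores))
  slopes <- stage("simple slopes", simple_slopes(gee))
  dp <- stage("d-prime", {
    by_sub <- split(discrim, discrim$subject)
    data.frame(subject = as.numeric(names(by_sub)),
               d_prime = vapply(by_sub, function(d)
                 dprime(d$actual_gender, d$response)$d_prime, numeric(1)),
               excluded = vapply(by_sub, function(d)
                 dprime(d$actual_gender, d$response)$excluded, logical(1)))
  })

  # plant per-subject neural structure: the subject's own subjective DM at
  # weight w_s in the unmasked arm, weight 0 (group structure only) masked;
  # the same w_s scales that subject's PPI coupling, creating the planted
  # connectivity-representation link
  set.seed(cfg$seed + 4)
  w_s <- stats::runif(ns, 0.2, 1)
  group_dm <- sdm$group_dm
  # a subject whose subjective-DM rank order exactly duplicates the group
  # average makes the rank regression singular; such subjects are dropped
  # from regression-RSA summaries (NA) rather than aborting the run
  safe_beta <- function(ndm, pred, covs) {
    tryCatch(regression_rsa(ndm, pred, covs)$beta,
             error = function(e) NA_real_)
  }
  roi <- stage("ROI RSA", {
    res <- lapply(seq_len(ns), function(s) {
      tgt_un <- blend_dms(sdm$subject_dms[[s]], group_dm, w_s[s])
      tgt_ma <- blend_dms(sdm$subject_dms[[s]], group_dm, 0)
      pat_un <- gen_patterns(tgt_un, p$n_voxels_roi,
                             noise_sd = p$pattern_noise_sd,
                             seed = cfg$seed + 100 + s)
      pat_ma <- gen_patterns(tgt_ma, p$n_voxels_roi,
                             noise_sd = p$pattern_noise_sd,
                             seed = cfg$seed + 200 + s)
      ndm_un <- neural_dm(pat_un)
      ndm_ma <- neural_dm(pat_ma)
      c(beta_unmasked = safe_beta(ndm_un, sdm$subject_dms[[s]],
                                  list(group_dm)),
        beta_masked = safe_beta(ndm_ma, sdm$subject_dms[[s]],
                                list(group_dm)),
        rho_congruency_unmasked = spearman_rsa(ndm_un, congruency_dm())$rho,
        rho_congruency_masked = spearman_rsa(ndm_ma, congruency_dm())$rho)
    })
    as.data.frame(do.call(rbind, res))
  })
  ok_s <- stats::complete.cases(roi[, c("beta_unmasked", "beta_masked")])
  roi_tests <- list(
    unmasked = group_test(roi$beta_unmasked[ok_s]),
    masked = group_test(roi$beta_masked[ok_s]),
    contrast = paired_contrast(roi$beta_unmasked[ok_s], roi$beta_masked[ok_s]),
    congruency_unmasked = group_test(roi$rho_congruency_unmasked, "fisher_z"),
    congruency_masked = group_test(roi$rho_congruency_masked, "fisher_z")
  )

  sl <- stage("searchlight", {
    center <- round(p$grid_dims / 2)
    vols <- gen_volume_dataset(
      p$grid_dims,
      regions = list(list(center = center, radius = p$region_radius)),
      subject_dms = lapply(seq_len(ns), function(s)
        blend_dms(sdm$subject_dms[[s]], group_dm, w_s[s])),
      noise_sd = p$pattern_noise_sd, seed = cfg$seed + 5)
    maps <- lapply(which(ok_s), function(s) {
      m <- run_searchlight(vols$volumes[[s]], vols$mask,
                           sdm$subject_dms[[s]],
                           covariate_dms = list(group_dm),
                           radius = p$radius)
      smooth_map(m, p$fwhm_mm, p$voxel_size_mm)
    })
    perm <- group_permutation(maps, n_perm = p$n_perm, seed = cfg$seed + 6)
    list(perm = perm, signal_mask = vols$region_masks[[1]])
  })

  ppi <- stage("PPI", {
    betas <- vapply(seq_len(ns), function(s) {
      tr_s <- utils::modifyList(unclass(truth),
                                list(ppi_coupling = truth$ppi_coupling * w_s[s]))
      class(tr_s) <- "ground_truth"
      sess <- gen_bold_session(schedule, tr_s, hrf,
                               noise_sd = truth$noise_sds$bold,
                               seed = cfg$seed + 300 + s)
      des <- build_ppi_design(sess$seed, sess$condition, hrf, p$ridge)
      fit_ppi(sess$target, des)$interaction_beta
    }, numeric(1))
    list(betas = betas, test = group_test(betas))
  })

  link <- stage("connectivity-representation link",
                link_connectivity_representation(
                  ppi$betas[ok_s],
                  roi$beta_unmasked[ok_s] - roi$beta_masked[ok_s]))

  null_truth <- truth$congruency_effect == 0 && truth$moderation == 0 &&
    truth$ppi_coupling == 0
  results <- list(
    design = list(n_subjects = ns,
                  n_faces = 4 * design$n_faces_per_cell,
                  n_mousetracking_trials = nrow(trajset$trials) / ns,
                  n_rating_trials = length(ratings[[1]]$ratings),
                  trial_duration_ms = design$trial_duration_ms,
                  n_null_events = design$n_null_events,
                  tr = design$tr, n_runs = design$n_runs),
    exclusions = sdm$exclusion_report,
    stereotype = list(mean_score = mean(scores$score),
                      sd_score = stats::sd(scores$score)),
    gee = summary(gee),
    simple_slopes = slopes,
    dprime = list(mean = mean(dp$d_prime), n_excluded = sum(dp$excluded)),
    roi_rsa = list(mean_beta_unmasked = mean(roi$beta_unmasked[ok_s]),
                   mean_beta_masked = mean(roi$beta_masked[ok_s]),
                   n_dropped_collinear = sum(!ok_s),
                   tests = lapply(roi_tests, unclass)),
    searchlight = list(
      n_significant = sum(sl$perm$significant),
      n_significant_in_region = sum(sl$perm$significant & sl$signal_mask),
      mean_t_in_region = mean(sl$perm$t_map[sl$signal_mask], na.rm = TRUE),
      mean_t_outside = mean(sl$perm$t_map[!sl$signal_mask], na.rm = TRUE),
      min_corrected_p = min(sl$perm$p_map, na.rm = TRUE)),
    ppi = list(mean_interaction_beta = mean(ppi$betas),
               test = unclass(ppi$test)),
    link = unclass(link),
    recovery_note = if (null_truth) "null as expected" else "effects planted",
    seed = cfg$seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      "stereorsa pipeline summary",
      sprintf("seed: %d; subjects: %d; faces: %d", cfg$seed, ns,
              4 * design$n_faces_per_cell),
      sprintf("mouse-tracking trials/subject: %d; rating trials/subject: %d",
              nrow(trajset$trials) / ns, length(ratings[[1]]$ratings)),
      sprintf("GEE gender:emotion B = %.4f (Z = %.2f)",
              gee$coefficients["gender:emotion"], gee$z["gender:emotion"]),
      sprintf("ROI RSA mean beta: unmasked %.3f, masked %.3f (contrast t = %.2f)",
              mean(roi$beta_unmasked[ok_s]), mean(roi$beta_masked[ok_s]),
              roi_tests$contrast$t),
      sprintf("searchlight: %d significant voxels (min corrected p = %.4f)",
              sum(sl$perm$significant), min(sl$perm$p_map, na.rm = TRUE)),
      sprintf("PPI mean interaction beta = %.3f; link r = %.3f (p = %.4f)",
              mean(ppi$betas), link$r, link$p),
      results$recovery_note
    ), file.path(out_dir, "summary.txt"))
    log("wrote ", file.path(out_dir, "results.json"))
    return(invisible(results))
  }
  results
}
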