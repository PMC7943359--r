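#' Write and read mouse-tracking trajectories as long-format CSV
#'
#' One row per sample: subject, block, condition, face_id, chosen_response,
#' response_side, rt_ms, correct, trial, t_ms, x, y.
#'
#' @param trajset a `"trajectory_set"`.
#' @param path output CSV path.
#' @export
write_trajectories_csv <- function(trajset, path) {
  stopifnot(inherits(trajset, "trajectory_set"))
  n <- nrow(trajset$trials)
  m <- ncol(trajset$t)
  long <- trajset$trials[rep(seq_len(n), each = m), ]
  long$trial <- rep(seq_len(n), each = m)
  long$t_ms <- as.vector(t(trajset$t))
  long$x <- as.vector(t(trajset$x))
  long$y <- as.vector(t(trajset$y))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @param scores optional per-subject stereotype scores to reattach.
#' @export
read_trajectories_csv <- function(path, scores = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts <- table(long$trial)
  m <- unique(as.vector(counts))
  if (length(m) != 1) stop("trials must have equal sample counts")
  ord <- order(long$trial, long$t_ms)
  long <- long[ord, ]
  trial_rows <- !duplicated(long$trial)
  trials <- long[trial_rows, c("subject", "block", "condition", "face_id",
                               "chosen_response", "response_side", "rt_ms",
                               "correct")]
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 t = matrix(long$t_ms, ncol = m, byrow = TRUE),
                 x = matrix(long$x, ncol = m, byrow = TRUE),
                 y = matrix(long$y, ncol = m, byrow = TRUE),
                 stereotype_scores = scores),
            class = "trajectory_set")
}

#' Write and read descriptor-rating blocks as CSV
#'
#' Long format: subject, category, descriptor, rating.
#'
#' @param ratings_list list of `"ratings_block"` objects.
#' @param path CSV path.
#' @export
write_ratings_csv <- function(ratings_list, path) {
  long <- do.call(rbind, lapply(ratings_list, function(b) {
    data.frame(subject = b$subject_id,
               category = rep(rownames(b$ratings), ncol(b$ratings)),
               descriptor = rep(colnames(b$ratings), each = nrow(b$ratings)),
               rating = as.vector(b$ratings))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(long, long$subject), function(d) {
    m <- tapply(d$rating, list(d$category, d$descriptor), identity)
    m <- m[response_categories(), unique(d$descriptor), drop = FALSE]
    structure(list(subject_id = d$subject[1], ratings = m, true_bias = NULL),
              class = "ratings_block")
  })
}

#' Write and read event schedules as TSV
#'
#' Columns: onset, duration, trial_type, run, masking.
#'
#' @param schedule event table from [make_schedule()].
#' @param path TSV path.
#' @export
write_events_tsv <- function(schedule, path) {
  out <- data.frame(onset = schedule$onset, duration = schedule$duration,
                    trial_type = schedule$condition, run = schedule$run,
                    masking = schedule$masking)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(run = d$run, masking = d$masking, onset = d$onset,
             duration = d$duration, condition = d$trial_type,
             face_id = NA_character_)
}

#' Write and read a dissimilarity matrix as labelled CSV
#'
#' @param dm a [dissimilarity_matrix()].
#' @param path CSV path.
#' @export
write_dm_csv <- function(dm, path) {
  utils::write.csv(as.data.frame(unclass(dm)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dm_csv
#' @export
read_dm_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1)
  dissimilarity_matrix(as.matrix(d), labels = rownames(d))
}

#' Write and read volumes as NIfTI-1
#'
#' @param vol 3-D or 4-D numeric array.
#' @param path `.nii` / `.nii.gz` path.
#' @param voxel_size_mm isotropic voxel size.
#' @export
write_volume <- function(vol, path, voxel_size_mm = 2) {
  img <- RNifti::asNifti(vol, pixdim = rep(voxel_size_mm, min(3, length(dim(vol)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}
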