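# Keypoint CSV interchange (long form: frame, landmark, x_mm, y_mm, z_mm) and
# cohort manifests.

#' Write a keypoint trajectory to long-form CSV
#'
#' Columns: \code{frame} (0-based), \code{landmark}, \code{x_mm}, \code{y_mm},
#' \code{z_mm}. One row per (frame, landmark); row order carries no meaning.
#'
#' @param traj A \code{\link{keypoint_trajectory}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_keypoints <- function(traj, path) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  n <- dim(traj$positions)[1]
  lms <- dimnames(traj$positions)[[3]]
  df <- do.call(rbind, lapply(lms, function(lm) {
    data.frame(frame = seq_len(n) - 1L, landmark = lm,
               x_mm = traj$positions[, 1L, lm],
               y_mm = traj$positions[, 2L, lm],
               z_mm = traj$positions[, 3L, lm], stringsAsFactors = FALSE)
  }))
  df <- df[order(df$frame, df$landmark), , drop = FALSE]
  tmp <- paste0(path, ".tmp")
  write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a keypoint trajectory from long-form CSV
#'
#' Frames missing any of the 7 canonical landmarks (or with non-finite
#' coordinates) are kept but marked invalid; rows naming landmarks outside
#' \code{allowed} raise a warning and are skipped; malformed rows (unparsable
#' coordinates) raise an error naming the offending line.
#'
#' @param path CSV file with columns \code{frame, landmark, x_mm, y_mm,
#'   z_mm}.
#' @param fps Sampling rate to record, Hz.
#' @param allowed Landmark names accepted (default the 7 canonical ones; pass
#'   e.g. the 20-marker montage names when reading raw motion-capture
#'   exports).
#' @param trial_id,subject_id,label Metadata attached to the trajectory.
#' @return A \code{\link{keypoint_trajectory}}.
#' @export
read_keypoints <- function(path, fps = 50, allowed = gait_landmarks(),
                           trial_id = NA_character_,
                           subject_id = NA_character_, label = "unknown") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(frame = "integer", landmark = "character",
                            x_mm = "character", y_mm = "character",
                            z_mm = "character")),
    error = function(e) stopf("cannot parse %s: %s", path, conditionMessage(e)))
  need <- c("frame", "landmark", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stopf("%s lacks required columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("empty keypoint file: %s", path)
  for (cc in c("x_mm", "y_mm", "z_mm")) {
    parsed <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(parsed) & !df[[cc]] %in% c("NA", ""))
    if (length(bad) > 0L) {
      stopf("malformed %s value at line %d of %s", cc, bad[1L] + 1L, path)
    }
    df[[cc]] <- parsed
  }
  unknown <- !df$landmark %in% allowed
  if (any(unknown)) {
    warning(sprintf("skipping %d row(s) with unknown landmark(s): %s",
                    sum(unknown),
                    paste(unique(df$landmark[unknown]), collapse = ", ")),
            call. = FALSE)
    df <- df[!unknown, , drop = FALSE]
  }
  if (nrow(df) == 0L) stopf("no usable keypoint rows in %s", path)
  frames <- sort(unique(df$frame))
  n <- length(frames)
  lms <- intersect(allowed, unique(df$landmark))
  pos <- array(NA_real_, dim = c(n, 3L, length(lms)),
               dimnames = list(NULL, c("x", "y", "z"), lms))
  fi <- match(df$frame, frames)
  li <- match(df$landmark, lms)
  pos[cbind(fi, 1L, li)] <- df$x_mm
  pos[cbind(fi, 2L, li)] <- df$y_mm
  pos[cbind(fi, 3L, li)] <- df$z_mm
  keypoint_trajectory(pos, fps = fps, trial_id = trial_id,
                      subject_id = subject_id, label = label)
}

#' Write a cohort to disk (keypoint CSVs + JSON manifest)
#'
#' Each trial goes to \code{<trial_id>.csv}; \code{manifest.json} records the
#' per-trial metadata and — when present — the generator's hidden ground
#' truth (reversal flag and ROM scale), which downstream validation can use.
#'
#' @param cohort A \code{\link{generate_cohort}} result (or list of trials).
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort, function(trial) {
    file <- paste0(trial$trial_id, ".csv")
    write_keypoints(trial$keypoints, file.path(dir, file))
    entry <- list(subject_id = trial$subject_id, trial_id = trial$trial_id,
                  label = trial$label, fps = trial$fps, file = file,
                  n_frames_total = dim(trial$keypoints$positions)[1],
                  n_frames_valid = sum(trial$keypoints$valid))
    if (!is.null(trial$truth)) {
      entry$truth <- list(reversed = trial$truth$reversed,
                          rom_scale = trial$truth$rom_scale)
    }
    entry
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir Directory containing \code{manifest.json} and the trial CSVs.
#' @return A list of trials (class \code{gait_cohort}).
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stopf("no manifest.json in %s", dir)
  entries <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  ids <- vapply(entries, function(e) e$trial_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate trial ids in manifest")
  trials <- lapply(entries, function(e) {
    f <- file.path(dir, e$file)
    if (!file.exists(f)) stopf("referenced keypoint file missing: %s", e$file)
    traj <- read_keypoints(f, fps = e$fps, trial_id = e$trial_id,
                           subject_id = e$subject_id, label = e$label)
    structure(list(keypoints = traj, label = e$label,
                   subject_id = e$subject_id, trial_id = e$trial_id,
                   fps = e$fps,
                   truth = if (!is.null(e$truth)) {
                     list(reversed = isTRUE(e$truth$reversed),
                          rom_scale = as.numeric(e$truth$rom_scale))
                   }),
              class = "gait_trial")
  })
  structure(trials, class = "gait_cohort")
}
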