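# Session data model and on-disk format.
#
# A session is one subject-visit: up to 14 task recordings, each a bundle of
# synchronized streams (camera skeleton at a nominal 30 Hz, IMUs at 64 Hz,
# force plate at 98 Hz, plus a marker event channel), all timestamped on one
# shared session clock. On disk a session is a directory holding
# manifest.json plus one UTF-8 comma-delimited table per stream, each with a
# header row and a leading time_s column.

abort_format <- function(msg) {
  rlang::abort(msg, class = "pdmotor_format_error")
}
abort_validation <- function(msg) {
  rlang::abort(msg, class = "pdmotor_validation_error")
}
abort_segmentation <- function(msg) {
  rlang::abort(msg, class = "pdmotor_segmentation_error")
}

camera_columns <- function() {
  joints <- skeleton_joints()
  c("time_s", paste0(rep(joints, each = 3L), "_", c("x", "y", "z")))
}

#' Construct a task recording
#'
#' Bundles the synchronized streams of one motor task. Streams are plain
#' tibbles: `camera` has columns `time_s` plus `<joint>_{x,y,z}` (meters) for
#' the 20 skeleton joints; each IMU has `time_s`, `gyro_{x,y,z}` (rad/s) and
#' `accel_{x,y,z}` (m/s^2); `plate` has `time_s`, `cop_ml_cm`, `cop_ap_cm`
#' (centimeters); `marker` has `time_s` and `label`.
#'
#' @param task Task id, one of `task_registry()$task`.
#' @param camera Optional camera tibble.
#' @param imus Named list of IMU tibbles; names are placements
#'   (`imu_placements()`).
#' @param plate Optional force-plate tibble.
#' @param marker Marker tibble (at least start and end events).
#' @param side Most-affected side, `"left"` or `"right"`.
#' @return An object of class `pd_task_recording`.
#' @export
task_recording <- function(task, camera = NULL, imus = list(), plate = NULL,
                           marker, side = "right") {
  structure(
    list(task = task, camera = camera, imus = imus, plate = plate,
         marker = marker, side = side),
    class = "pd_task_recording"
  )
}

#' Construct a session
#'
#' @param subject_id Non-empty subject identifier.
#' @param visit_day Visit day, 1 or 2.
#' @param recordings Named list of [task_recording()] objects keyed by task id.
#' @param updrs Optional one-row UPDRS tibble (columns `Q18`..`Q31`, `total`).
#' @param side Most-affected side, `"left"` or `"right"`.
#' @return An object of class `pd_session`.
#' @export
session <- function(subject_id, visit_day = 1L, recordings = list(),
                    updrs = NULL, side = "right") {
  structure(
    list(subject_id = subject_id, visit_day = as.integer(visit_day),
         side = side, recordings = recordings, updrs = updrs),
    class = "pd_session"
  )
}

#' @export
print.pd_session <- function(x, ...) {
  cat("<pd_session> subject", x$subject_id, "visit", x$visit_day,
      "side", x$side, "\n")
  cat("  recordings:", paste(names(x$recordings), collapse = " "), "\n")
  cat("  UPDRS-III:", if (is.null(x$updrs)) "absent" else
    paste0("total ", x$updrs$total), "\n")
  invisible(x)
}

#' Construct a UPDRS-III exam
#'
#' @param items Named integer vector of item scores; names must cover
#'   `updrs_items()` and every score must lie in 0..4.
#' @return One-row tibble with columns `Q18`..`Q31` and `total` (the item sum).
#' @export
#' @examples
#' updrs_exam(setNames(rep(1L, 14), updrs_items()))
updrs_exam <- function(items) {
  ids <- updrs_items()
  if (!all(ids %in% names(items))) {
    abort_validation("UPDRS exam is missing items")
  }
  scores <- as.integer(items[ids])
  if (any(is.na(scores)) || any(scores < 0L | scores > 4L)) {
    abort_validation("UPDRS item scores must be integers in 0..4")
  }
  out <- tibble::as_tibble(as.list(stats::setNames(scores, ids)))
  out$total <- sum(scores)
  out
}

check_stream <- function(df, name, cols, allow_na = FALSE) {
  if (!all(cols %in% names(df))) {
    abort_format(paste0("stream '", name, "' is missing columns: ",
                        paste(setdiff(cols, names(df)), collapse = ", ")))
  }
  t <- df$time_s
  if (length(t) > 1L && any(diff(t) <= 0)) {
    abort_validation(paste0("stream '", name,
                            "' has non-monotone timestamps"))
  }
  vals <- as.matrix(df[setdiff(cols, "label")])
  bad <- !is.finite(vals)
  if (any(bad) && !allow_na) {
    row <- which(rowSums(bad) > 0)[1L]
    abort_validation(paste0("stream '", name,
                            "' has non-finite values at row ", row))
  }
  invisible(df)
}

validate_recording <- function(rec) {
  req <- required_streams(rec$task)
  nm <- function(s) paste0(rec$task, "/", s)
  if (req$camera) {
    if (is.null(rec$camera)) {
      abort_validation(paste0("task ", rec$task, " requires a camera stream"))
    }
    # Missing camera frames are flagged as NA and handled downstream.
    check_stream(rec$camera, nm("camera"), camera_columns(), allow_na = TRUE)
  }
  if (req$plate) {
    if (is.null(rec$plate)) {
      abort_validation(paste0("task ", rec$task, " requires a force plate stream"))
    }
    check_stream(rec$plate, nm("plate"),
                 c("time_s", "cop_ml_cm", "cop_ap_cm"))
  }
  have <- names(rec$imus)
  for (p in req$imus) {
    ok <- if (identical(p, "ankle_any")) {
      any(c("ankle_right", "ankle_left") %in% have)
    } else {
      p %in% have
    }
    if (!ok) {
      abort_validation(paste0("task ", rec$task, " requires IMU placement '",
                              p, "'"))
    }
  }
  for (p in have) {
    check_stream(rec$imus[[p]], nm(paste0("imu_", p)),
                 c("time_s", "gyro_x", "gyro_y", "gyro_z",
                   "accel_x", "accel_y", "accel_z"))
  }
  if (is.null(rec$marker) || nrow(rec$marker) < 2L) {
    abort_validation(paste0("task ", rec$task,
                            " requires a marker channel with >= 2 events"))
  }
  if (any(diff(rec$marker$time_s) < 0)) {
    abort_validation(paste0("task ", rec$task, " has unsorted marker events"))
  }
  invisible(rec)
}

#' Validate a session against the protocol contract
#'
#' Checks subject/visit fields, per-stream monotone timestamps and finite
#' values, marker event counts, and the per-task required-stream registry.
#'
#' @param x A [session()].
#' @return `x`, invisibly; errors of class `pdmotor_validation_error`
#'   otherwise.
#' @export
validate_session <- function(x) {
  if (!inherits(x, "pd_session")) abort_validation("not a pd_session")
  if (!nzchar(x$subject_id)) abort_validation("subject_id must be non-empty")
  if (!x$visit_day %in% c(1L, 2L)) abort_validation("visit_day must be 1 or 2")
  for (task in names(x$recordings)) {
    rec <- x$recordings[[task]]
    if (!identical(rec$task, task)) {
      abort_validation(paste0("recording key ", task,
                              " does not match its task field"))
    }
    validate_recording(rec)
  }
  invisible(x)
}

#' Task window from the marker channel
#'
#' The active window of a task runs from the first to the last marker event;
#' event labels and any intermediate events are ignored.
#'
#' @param rec A [task_recording()].
#' @return Named numeric vector `c(t_start, t_end)` in seconds.
#' @export
#' @examples
#' m <- tibble::tibble(time_s = c(2, 5, 9), label = c("start", "x", "end"))
#' task_window(task_recording("T3", marker = m))  # c(2, 9)
task_window <- function(rec) {
  ev <- rec$marker$time_s
  if (length(ev) < 2L) {
    abort_segmentation("task window needs >= 2 marker events")
  }
  out <- c(t_start = min(ev), t_end = max(ev))
  if (diff(out) <= 0) {
    abort_segmentation("marker events give a non-positive task window")
  }
  out
}

crop_df <- function(df, window, tol) {
  if (is.null(df)) return(NULL)
  keep <- df$time_s >= window[1L] - tol & df$time_s <= window[2L] + tol
  df[keep, , drop = FALSE]
}

#' Crop all streams of a recording to a time window
#'
#' Timestamps are preserved (the session clock origin is unchanged); a skew
#' tolerance of one nominal sample is accepted at the window edges.
#'
#' @param rec A [task_recording()].
#' @param window Numeric `c(t_start, t_end)`, typically from [task_window()].
#' @param tol Edge tolerance in seconds (default one camera sample, 1/30 s).
#' @return The cropped recording.
#' @export
crop_streams <- function(rec, window, tol = 1 / 30) {
  out <- rec
  out$camera <- crop_df(rec$camera, window, tol)
  out$plate <- crop_df(rec$plate, window, tol)
  out$imus <- lapply(rec$imus, crop_df, window = window, tol = tol)
  streams <- c(list(out$camera, out$plate), out$imus)
  streams <- streams[!vapply(streams, is.null, logical(1L))]
  if (length(streams) > 0L &&
      any(vapply(streams, nrow, integer(1L)) == 0L)) {
    abort_validation("crop window lies outside the stream extent")
  }
  out
}

stream_files <- function(task, rec) {
  files <- list(marker = paste0(task, "_marker.csv"))
  if (!is.null(rec$camera)) files$camera <- paste0(task, "_camera.csv")
  if (!is.null(rec$plate)) files$plate <- paste0(task, "_plate.csv")
  if (length(rec$imus) > 0L) {
    files$imu <- paste0(task, "_imu_", names(rec$imus), ".csv")
  }
  files
}

#' Write a session directory
#'
#' Writes `manifest.json` plus one CSV per stream into `path` (created if
#' needed). The layout round-trips through [read_session()] exactly up to
#' floating-point text representation.
#'
#' @param x A validated [session()].
#' @param path Target directory.
#' @return `path`, invisibly.
#' @export
write_session <- function(x, path) {
  validate_session(x)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  streams <- list()
  for (task in names(x$recordings)) {
    rec <- x$recordings[[task]]
    files <- stream_files(task, rec)
    readr::write_csv(rec$marker, file.path(path, files$marker), progress = FALSE)
    if (!is.null(files$camera)) {
      readr::write_csv(rec$camera, file.path(path, files$camera), progress = FALSE)
    }
    if (!is.null(files$plate)) {
      readr::write_csv(rec$plate, file.path(path, files$plate), progress = FALSE)
    }
    if (!is.null(files$imu)) {
      for (i in seq_along(rec$imus)) {
        readr::write_csv(rec$imus[[i]], file.path(path, files$imu[i]),
                         progress = FALSE)
      }
    }
    streams[[task]] <- files
  }
  manifest <- list(
    subject_id = x$subject_id,
    visit_day = x$visit_day,
    side = x$side,
    tasks = as.list(names(x$recordings)),
    streams = streams,
    rates_hz = list(camera = 30, imu = 64, plate = 98)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(x$updrs)) {
    readr::write_csv(
      dplyr::bind_cols(
        tibble::tibble(subject_id = x$subject_id, visit_day = x$visit_day),
        x$updrs
      ),
      file.path(path, "updrs.csv"), progress = FALSE
    )
  }
  invisible(path)
}

read_stream_csv <- function(path, name) {
  if (!file.exists(path)) {
    abort_format(paste0("manifest references absent file: ", basename(path)))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tibble::as_tibble(df)
}

#' Read a session directory
#'
#' Reads `manifest.json` and every referenced stream table, reconstructs the
#' in-memory session, and validates it (monotone timestamps, finite values,
#' required streams per task, marker event counts).
#'
#' @param path Session directory written by [write_session()] or the
#'   simulator.
#' @return A validated [session()].
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    abort_format(paste0("no manifest.json in ", path))
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  recordings <- list()
  for (task in unlist(manifest$tasks)) {
    files <- manifest$streams[[task]]
    marker <- read_stream_csv(file.path(path, files$marker), "marker")
    camera <- if (!is.null(files$camera)) {
      read_stream_csv(file.path(path, files$camera), "camera")
    }
    plate <- if (!is.null(files$plate)) {
      read_stream_csv(file.path(path, files$plate), "plate")
    }
    imus <- list()
    for (f in unlist(files$imu)) {
      placement <- sub("\\.csv$", "", sub(paste0("^", task, "_imu_"), "", f))
      imus[[placement]] <- read_stream_csv(file.path(path, f), "imu")
    }
    recordings[[task]] <- task_recording(
      task, camera = camera, imus = imus, plate = plate, marker = marker,
      side = manifest$side
    )
  }
  updrs <- NULL
  uf <- file.path(path, "updrs.csv")
  if (file.exists(uf)) {
    u <- readr::read_csv(uf, show_col_types = FALSE, progress = FALSE)
    updrs <- u[c(updrs_items(), "total")]
  }
  out <- session(
    subject_id = manifest$subject_id,
    visit_day = manifest$visit_day,
    recordings = recordings,
    updrs = updrs,
    side = manifest$side
  )
  validate_session(out)
  out
}

#' Read a cohort UPDRS table
#'
#' @param path CSV with columns `subject_id`, `visit_day`, `Q18`..`Q31`,
#'   `total`.
#' @return Tibble with one exam per row; errors if scores fall outside 0..4
#'   or totals do not match the item sums.
#' @export
read_updrs_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ids <- updrs_items()
  if (!all(c("subject_id", "visit_day", ids, "total") %in% names(df))) {
    abort_format("UPDRS table is missing required columns")
  }
  scores <- as.matrix(df[ids])
  if (any(scores < 0 | scores > 4)) {
    abort_validation("UPDRS item scores must lie in 0..4")
  }
  if (any(rowSums(scores) != df$total)) {
    abort_validation("UPDRS totals do not equal the item sums")
  }
  tibble::as_tibble(df)
}
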