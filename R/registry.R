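# Static registries: the 20-joint skeleton, the 14-recording task protocol,
# per-task required streams, and the canonical 62-metric inventory.

#' The 20-joint skeleton
#'
#' Names of the 20 joints tracked by the camera system, in canonical order.
#' Positions are expressed in meters in the camera frame: x lateral (+ right),
#' y vertical (+ up), z depth (+ away from the camera).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' skeleton_joints()
skeleton_joints <- function() {
  c(
    "hip_center", "spine", "shoulder_center", "head",
    "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
    "wrist_l", "wrist_r", "hand_l", "hand_r",
    "hip_l", "hip_r", "knee_l", "knee_r",
    "ankle_l", "ankle_r", "foot_l", "foot_r"
  )
}

#' IMU placements
#'
#' @return Character vector of the four wearable sensor placements.
#' @export
imu_placements <- function() {
  c("index_finger", "L5", "ankle_right", "ankle_left")
}

#' The motor task registry
#'
#' The protocol comprises 7 motor tasks expanded into 14 recordings:
#' continuous (T1A) and discrete (T1B) elbow flexion/extension, hand
#' opening/closing at shoulder (T2A) and waist (T2B) level, a complex
#' multi-joint sequence (T3), hand-to-nose (T4), rest (T5A) and postural
#' (T5B) tremor holds, quiet standing with eyes open (T6_EO) and closed
#' (T6_EC), and four 10 m walks (T7_W1..T7_W4). Tasks T1-T5 are performed
#' seated and tracked with the camera plus an index-finger IMU; the balance
#' tasks use the force plate plus an L5 IMU; the walks use the L5 IMU
#' (walks 1-2) and ankle IMUs (walks 3-4).
#'
#' @return A tibble with one row per recording: `task`, `description`,
#'   `repetitions` (planned movement count, `NA` where not applicable),
#'   `needs_camera`, `needs_plate`, and `needs_imus` (list-column of
#'   required placements; `"ankle_any"` means at least one ankle IMU).
#' @export
#' @examples
#' task_registry()
task_registry <- function() {
  tibble::tibble(
    task = c(
      "T1A", "T1B", "T2A", "T2B", "T3", "T4", "T5A", "T5B",
      "T6_EO", "T6_EC", "T7_W1", "T7_W2", "T7_W3", "T7_W4"
    ),
    description = c(
      "continuous elbow flexion/extension",
      "discrete elbow flexion/extension",
      "hand opening/closing at shoulder level",
      "hand opening/closing at waist level",
      "complex multi-joint motor sequence",
      "hand-to-nose",
      "hand resting on table (rest tremor, 30 s)",
      "hand held in front of face (postural tremor, 15 s)",
      "quiet standing, eyes open (15 s)",
      "quiet standing, eyes closed (15 s)",
      "10 m walk 1", "10 m walk 2", "10 m walk 3", "10 m walk 4"
    ),
    repetitions = c(10L, 10L, 10L, 10L, 10L, 10L, NA, NA, NA, NA, NA, NA, NA, NA),
    needs_camera = c(rep(TRUE, 8L), rep(FALSE, 6L)),
    needs_plate = c(rep(FALSE, 8L), TRUE, TRUE, rep(FALSE, 4L)),
    needs_imus = list(
      "index_finger", "index_finger", "index_finger", "index_finger",
      "index_finger", "index_finger", "index_finger", "index_finger",
      "L5", "L5",
      "L5", "L5", "ankle_any", "ankle_any"
    )
  )
}

task_ids <- function() task_registry()$task

required_streams <- function(task) {
  reg <- task_registry()
  row <- reg[reg$task == task, ]
  if (nrow(row) == 0L) {
    stop("unknown task id: ", task, call. = FALSE)
  }
  list(
    camera = row$needs_camera,
    plate = row$needs_plate,
    imus = row$needs_imus[[1L]]
  )
}

#' The canonical 62-metric inventory
#'
#' The fixed inventory of the 62 motor metrics extracted from one
#' subject-visit, mapping each metric name to its source task, source
#' stream, and units. Reaching tasks (T1A, T1B, T4) each contribute 10
#' metrics (mean/SD of per-movement mean speed, max speed, duration and
#' smoothness, plus movement count and wrist path length); hand
#' opening/closing tasks (T2A, T2B) contribute movement time and the
#' mean/SD inter-peak interval; the complex sequence contributes its total
#' time; each tremor hold contributes multitaper and FFT band-power ratios;
#' each balance condition contributes six center-of-pressure sway metrics
#' and two trunk jerk metrics; gait contributes total walk time, normalized
#' jerk, stride duration mean/SD, and stride count.
#'
#' @return A tibble with 62 rows: `metric`, `task`, `stream`, `units`.
#' @export
#' @examples
#' nrow(metric_inventory())  # 62
metric_inventory <- function() {
  reach <- function(prefix, task) {
    tibble::tibble(
      metric = paste0(prefix, c(
        "mean_speed_mean", "mean_speed_sd", "max_speed_mean", "max_speed_sd",
        "duration_mean", "duration_sd", "smoothness_mean", "smoothness_sd",
        "n_movements", "path_length"
      )),
      task = task,
      stream = "camera",
      units = c("m/s", "m/s", "m/s", "m/s", "s", "s", "-", "-", "count", "m")
    )
  }
  open_close <- function(prefix, task) {
    tibble::tibble(
      metric = paste0(prefix, c("movement_time", "ipi_mean", "ipi_sd")),
      task = task, stream = "imu_index_finger", units = c("s", "s", "s")
    )
  }
  tremor <- function(prefix, task) {
    tibble::tibble(
      metric = paste0(prefix, c("power_ratio_mt", "power_ratio_fft")),
      task = task, stream = "imu_index_finger", units = c("-", "-")
    )
  }
  balance <- function(prefix, task) {
    tibble::tibble(
      metric = paste0(prefix, c(
        "cop_path_length", "cop_sd_ap", "cop_sd_ml",
        "ellipse_major", "ellipse_minor", "ellipse_area",
        "jerk_mean", "jerk_peak"
      )),
      task = task,
      stream = c(rep("plate", 6L), "imu_L5", "imu_L5"),
      units = c("cm", "cm", "cm", "cm", "cm", "cm^2", "m/s^3", "m/s^3")
    )
  }
  gait <- tibble::tibble(
    metric = paste0("gait_", c(
      "total_walk_time", "normalized_jerk",
      "stride_duration_mean", "stride_duration_sd", "stride_count"
    )),
    task = "T7",
    stream = c("marker", "imu_L5", "imu_ankle", "imu_ankle", "imu_ankle"),
    units = c("s", "1/s^2", "s", "s", "count")
  )
  out <- dplyr::bind_rows(
    reach("t1a_", "T1A"), reach("t1b_", "T1B"),
    open_close("t2a_", "T2A"), open_close("t2b_", "T2B"),
    tibble::tibble(metric = "t3_total_time", task = "T3",
                   stream = "marker", units = "s"),
    reach("t4_", "T4"),
    tremor("t5a_", "T5A"), tremor("t5b_", "T5B"),
    balance("t6_eo_", "T6_EO"), balance("t6_ec_", "T6_EC"),
    gait
  )
  stopifnot(nrow(out) == 62L, !anyDuplicated(out$metric))
  out
}

metric_names <- function() metric_inventory()$metric

#' UPDRS-III motor exam items
#'
#' Item identifiers Q18-Q31 of the classic UPDRS motor examination
#' (14 clinician-rated items, each scored 0-4).
#'
#' @return Character vector `"Q18"` ... `"Q31"`.
#' @export
updrs_items <- function() paste0("Q", 18:31)

# Item groups used by the tremor-dominant / akinetic-rigid subtype ratio.
updrs_tremor_items <- function() c("Q20", "Q21")
updrs_akinetic_items <- function() c("Q22", "Q23", "Q24", "Q25", "Q26", "Q31")
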