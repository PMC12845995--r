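#' @keywords internal
"_PACKAGE"

#' COCO-17 joint names
#'
#' The canonical 17-joint set produced by COCO-trained 2-D pose estimators,
#' in standard index order.
#'
#' @return Character vector of length 17.
#' @export
coco17_joints <- function() {
  c("nose",
    "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

.coco17 <- c("nose",
             "left_eye", "right_eye", "left_ear", "right_ear",
             "left_shoulder", "right_shoulder",
             "left_elbow", "right_elbow",
             "left_wrist", "right_wrist",
             "left_hip", "right_hip",
             "left_knee", "right_knee",
             "left_ankle", "right_ankle")

#' Construct a single-person pose frame
#'
#' A pose frame holds one person's COCO-17 keypoints in one video frame,
#' in image coordinates (origin top-left, y increasing downward), together
#' with the frame dimensions. Absent joints are kept explicitly with
#' confidence 0 rather than dropped.
#'
#' @param joints 17 x 3 numeric matrix (columns x, y, conf) with rows in
#'   COCO-17 order, or a named list mapping joint names to length-3 vectors;
#'   joints not listed are filled with confidence 0.
#' @param width,height Frame dimensions in pixels; both must be positive.
#' @param frame_index Non-negative integer frame number.
#' @param person_id Opaque person identifier.
#' @return An object of class `pose_frame`.
#' @export
pose_frame <- function(joints, width, height, frame_index = 0L, person_id = "p1") {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  m <- matrix(0, nrow = 17L, ncol = 3L,
              dimnames = list(.coco17, c("x", "y", "conf")))
  if (is.matrix(joints)) {
    if (nrow(joints) != 17L || ncol(joints) != 3L)
      stop("joint matrix must be 17 x 3 (x, y, conf)")
    m[, ] <- joints
  } else if (is.list(joints)) {
    bad <- setdiff(names(joints), .coco17)
    if (length(bad))
      stop("unknown joint name(s): ", paste(bad, collapse = ", "))
    for (j in names(joints)) m[j, ] <- as.numeric(joints[[j]])
  } else stop("joints must be a 17x3 matrix or a named list")
  if (any(m[, "conf"] < 0 | m[, "conf"] > 1))
    stop("joint confidences must lie in [0, 1]")
  if (any(m[, "conf"] > 0 & (!is.finite(m[, "x"]) | !is.finite(m[, "y"]))))
    stop("joints with positive confidence must have finite coordinates")
  structure(list(frame_index = as.integer(frame_index),
                 person_id = as.character(person_id),
                 joints = m,
                 width = as.numeric(width),
                 height = as.numeric(height)),
            class = "pose_frame")
}

#' Construct a per-visitor keypoint track
#'
#' A track is an ordered sequence of pose frames for one visitor, stored
#' column-wise as frame-by-joint matrices for efficient whole-track
#' classification, together with the seconds-per-frame interval and an
#' optional per-frame spatial-unit (zone) assignment.
#'
#' @param frames List of [pose_frame()] objects with strictly increasing
#'   frame indices and identical frame dimensions.
#' @param visitor_id Opaque visitor identifier.
#' @param dt Seconds per frame; default 1/30 (1080p footage at 30 fps).
#' @param zone_ids Optional per-frame zone id vector, same length as `frames`.
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(frames, visitor_id = NULL, dt = 1 / 30, zone_ids = NULL) {
  stopifnot(is.list(frames), length(frames) > 0, dt > 0)
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (any(diff(idx) <= 0)) stop("frame indices must be strictly increasing")
  W <- frames[[1L]]$width; H <- frames[[1L]]$height
  if (is.null(visitor_id)) visitor_id <- frames[[1L]]$person_id
  n <- length(frames)
  x <- y <- cf <- matrix(0, n, 17L, dimnames = list(NULL, .coco17))
  for (i in seq_len(n)) {
    jm <- frames[[i]]$joints
    x[i, ] <- jm[, "x"]; y[i, ] <- jm[, "y"]; cf[i, ] <- jm[, "conf"]
  }
  if (!is.null(zone_ids) && length(zone_ids) != n)
    stop("zone_ids must have one entry per frame")
  structure(list(visitor_id = as.character(visitor_id),
                 frame_index = as.integer(idx),
                 x = x, y = y, conf = cf,
                 width = W, height = H, dt = dt,
                 zone_ids = zone_ids),
            class = "pose_track")
}

# internal fast constructor from prebuilt matrices
new_track <- function(visitor_id, frame_index, x, y, conf, width, height,
                      dt = 1 / 30, zone_ids = NULL) {
  structure(list(visitor_id = as.character(visitor_id),
                 frame_index = as.integer(frame_index),
                 x = x, y = y, conf = conf,
                 width = width, height = height, dt = dt,
                 zone_ids = zone_ids),
            class = "pose_track")
}

#' Number of frames in a track
#' @param track A `pose_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(track) length(track$frame_index)

#' Extract one frame of a track as a pose frame
#' @param track A `pose_track`.
#' @param i Frame position (1-based within the track).
#' @return A `pose_frame`.
#' @export
track_frame <- function(track, i) {
  stopifnot(i >= 1, i <= n_frames(track))
  m <- cbind(x = track$x[i, ], y = track$y[i, ], conf = track$conf[i, ])
  rownames(m) <- .coco17
  structure(list(frame_index = track$frame_index[i],
                 person_id = track$visitor_id,
                 joints = m,
                 width = track$width, height = track$height),
            class = "pose_frame")
}

#' Restrict a track to a subset of frames
#' @param track A `pose_track`.
#' @param keep Logical or integer index over frames.
#' @return A `pose_track` with the selected frames (order preserved).
#' @export
subset_track <- function(track, keep) {
  new_track(track$visitor_id, track$frame_index[keep],
            track$x[keep, , drop = FALSE], track$y[keep, , drop = FALSE],
            track$conf[keep, , drop = FALSE],
            track$width, track$height, track$dt,
            if (!is.null(track$zone_ids)) track$zone_ids[keep])
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("pose_track '%s': %d frames, %gx%g px, dt = %.4g s%s\n",
              x$visitor_id, n_frames(x), x$width, x$height, x$dt,
              if (is.null(x$zone_ids)) "" else ", zoned"))
  invisible(x)
}

#' @export
print.pose_frame <- function(x, ...) {
  nv <- sum(x$joints[, "conf"] > 0)
  cat(sprintf("pose_frame %d (person %s): %d/17 joints detected, %gx%g px\n",
              x$frame_index, x$person_id, nv, x$width, x$height))
  invisible(x)
}

#' Joint validity rule
#'
#' Confidence threshold plus per-posture required-joint completeness, used to
#' gate frames before posture classification: under occlusion, missing
#' keypoints would otherwise cause spurious classifications.
#'
#' @param conf_min Minimum per-joint confidence in \[0, 1\]; default 0.3, a
#'   common operating point for bottom-up pose estimators.
#' @param required_joints Named list of joint-name sets per posture. Defaults:
#'   hips, knees and ankles for `squat` and `leg_lift`; shoulders, elbows,
#'   wrists and hips for `akimbo`.
#' @return An object of class `validity_rule`.
#' @export
validity_rule <- function(conf_min = 0.3, required_joints = NULL) {
  stopifnot(conf_min >= 0, conf_min <= 1)
  if (is.null(required_joints)) {
    lower <- c("left_hip", "right_hip", "left_knee", "right_knee",
               "left_ankle", "right_ankle")
    upper <- c("left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
               "left_wrist", "right_wrist", "left_hip", "right_hip")
    required_joints <- list(squat = lower, akimbo = upper, leg_lift = lower)
  }
  if (!all(vapply(required_joints, length, integer(1)) > 0))
    stop("required joint sets must be nonempty")
  bad <- setdiff(unlist(required_joints), .coco17)
  if (length(bad)) stop("unknown joint name(s): ", paste(bad, collapse = ", "))
  structure(list(conf_min = conf_min, required_joints = required_joints),
            class = "validity_rule")
}

#' Frame validity for a posture
#'
#' A frame is evaluated for a posture only when every joint that posture's
#' geometry needs is detected with sufficient confidence.
#'
#' @param frame A `pose_frame`.
#' @param rule A [validity_rule()].
#' @param posture One of `"squat"`, `"akimbo"`, `"leg_lift"`.
#' @return `TRUE` iff every required joint has confidence >= `conf_min`.
#' @export
is_valid <- function(frame, rule = validity_rule(), posture) {
  posture <- match.arg(posture, c("squat", "akimbo", "leg_lift"))
  req <- rule$required_joints[[posture]]
  if (is.null(req)) stop("no required-joint set for posture: ", posture)
  all(frame$joints[req, "conf"] >= rule$conf_min)
}

#' Normalize a frame's keypoints to dimensionless coordinates
#'
#' Divides x by the frame width and y by the frame height so measurements
#' transfer across camera resolutions; returns the shoulder width (pixels and
#' width-normalized) as an auxiliary scale when both shoulders are detected.
#'
#' @param frame A `pose_frame`.
#' @return List with `joints` (17 x 3 matrix, x/W, y/H, conf unchanged),
#'   `shoulder_width_px` and `shoulder_width` (NA when a shoulder is absent).
#' @export
normalize_frame <- function(frame) {
  m <- frame$joints
  out <- m
  out[, "x"] <- m[, "x"] / frame$width
  out[, "y"] <- m[, "y"] / frame$height
  sw_px <- NA_real_; sw <- NA_real_
  if (m["left_shoulder", "conf"] > 0 && m["right_shoulder", "conf"] > 0) {
    sw_px <- abs(m["left_shoulder", "x"] - m["right_shoulder", "x"])
    sw <- sw_px / frame$width
  }
  list(joints = out, shoulder_width_px = sw_px, shoulder_width = sw)
}

#' Read a per-frame keypoint stream into tracks
#'
#' Two plain-JSON dialects are supported. `"run"` is one file per recording:
#' a JSON array of records, one per (frame, person), each with fields
#' `frame`, `person`, `width`, `height` and either `keypoints` (flat list of
#' 51 numbers: x, y, confidence for the 17 COCO joints in order) or `joints`
#' (object mapping joint names to \[x, y, confidence\]; joints not listed are
#' recorded with confidence 0). `"frames"` is a pose-estimator-style
#' directory of one JSON file per video frame, each holding
#' `{"people": [{"person_id": ..., "pose_keypoints_2d": [51 numbers]}]}`;
#' files are taken in lexicographic order and frame dimensions must be
#' supplied since that dialect does not carry them.
#'
#' @param path File (`"run"`) or directory (`"frames"`).
#' @param layout `"run"` or `"frames"`.
#' @param width,height Frame dimensions, required for the `"frames"` layout
#'   and used as a fallback for `"run"` records that omit them.
#' @param fps Frames per second used to set each track's `dt`; default 30.
#' @return List of [pose_track()] objects, one per distinct person id, frames
#'   ordered by frame index, absent joints at confidence 0.
#' @export
read_keypoint_stream <- function(path, layout = c("run", "frames"),
                                 width = NULL, height = NULL, fps = 30) {
  layout <- match.arg(layout)
  recs <- if (layout == "run") .read_run_records(path, width, height)
          else .read_frame_records(path, width, height)
  if (!length(recs)) stop("no keypoint records found in ", path)
  pid <- vapply(recs, `[[`, character(1), "person")
  tracks <- lapply(split(seq_along(recs), pid), function(ii) {
    rr <- recs[ii]
    fi <- vapply(rr, `[[`, numeric(1), "frame")
    o <- order(fi)
    rr <- rr[o]; fi <- fi[o]
    if (anyDuplicated(fi))
      stop("duplicate frame index for person ", rr[[1L]]$person)
    n <- length(rr)
    x <- y <- cf <- matrix(0, n, 17L, dimnames = list(NULL, .coco17))
    for (i in seq_len(n)) {
      k <- rr[[i]]$kp
      x[i, ] <- k[, 1L]; y[i, ] <- k[, 2L]; cf[i, ] <- k[, 3L]
    }
    new_track(rr[[1L]]$person, fi, x, y, cf,
              rr[[1L]]$width, rr[[1L]]$height, dt = 1 / fps)
  })
  unname(tracks)
}

.kp_from_flat <- function(v, where) {
  v <- as.numeric(v)
  if (length(v) != 51L)
    stop("keypoint list in ", where, " has length ", length(v),
         "; expected 51 (17 joints x 3): unknown joint layout")
  matrix(v, ncol = 3L, byrow = TRUE)
}

.kp_from_named <- function(jl, where) {
  bad <- setdiff(names(jl), .coco17)
  if (length(bad))
    stop("unknown joint name(s) in ", where, ": ", paste(bad, collapse = ", "))
  m <- matrix(0, 17L, 3L, dimnames = list(.coco17, NULL))
  for (j in names(jl)) {
    v <- as.numeric(jl[[j]])
    if (length(v) != 3L) stop("joint '", j, "' in ", where,
                              " must be [x, y, confidence]")
    m[j, ] <- v
  }
  m
}

.read_run_records <- function(path, width, height) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed keypoint file ", path,
                                           ": ", conditionMessage(e)))
  lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    where <- sprintf("record %d of %s", i, path)
    if (is.null(r$frame) || is.null(r$person))
      stop("parse error in ", where, ": missing 'frame' or 'person'")
    W <- if (!is.null(r$width)) as.numeric(r$width) else width
    H <- if (!is.null(r$height)) as.numeric(r$height) else height
    if (is.null(W) || is.null(H))
      stop("parse error in ", where, ": no frame dimensions")
    kp <- if (!is.null(r$keypoints)) .kp_from_flat(unlist(r$keypoints), where)
          else if (!is.null(r$joints)) .kp_from_named(r$joints, where)
          else stop("parse error in ", where, ": no 'keypoints' or 'joints'")
    list(frame = as.numeric(r$frame), person = as.character(r$person),
         width = W, height = H, kp = kp)
  })
}

.read_frame_records <- function(path, width, height) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  if (is.null(width) || is.null(height))
    stop("the 'frames' layout carries no frame dimensions; supply width and height")
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stop("no .json files in ", path)
  recs <- list()
  for (i in seq_along(files)) {
    d <- tryCatch(jsonlite::read_json(files[i], simplifyVector = FALSE),
                  error = function(e) stop("malformed keypoint file ",
                                           files[i], ": ", conditionMessage(e)))
    fr <- if (!is.null(d$frame)) as.numeric(d$frame) else i - 1
    people <- d$people
    for (k in seq_along(people)) {
      p <- people[[k]]
      where <- sprintf("person %d of %s", k, basename(files[i]))
      pid <- if (!is.null(p$person_id)) as.character(p$person_id)
             else as.character(k)
      if (is.null(p$pose_keypoints_2d))
        stop("parse error in ", where, ": no 'pose_keypoints_2d'")
      recs[[length(recs) + 1L]] <-
        list(frame = fr, person = pid, width = width, height = height,
             kp = .kp_from_flat(unlist(p$pose_keypoints_2d), where))
    }
  }
  recs
}

#' Write tracks to the canonical track file
#'
#' Writes the single-file "run" dialect that [read_keypoint_stream()] reads
#' back, preserving coordinates and confidences exactly.
#'
#' @param tracks List of `pose_track` objects (or a single track).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "pose_track")) tracks <- list(tracks)
  recs <- list()
  for (tr in tracks) {
    for (i in seq_len(n_frames(tr))) {
      kp <- as.vector(t(cbind(tr$x[i, ], tr$y[i, ], tr$conf[i, ])))
      recs[[length(recs) + 1L]] <- list(
        frame = tr$frame_index[i], person = tr$visitor_id,
        width = tr$width, height = tr$height, keypoints = kp)
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Flatten tracks to a data frame
#'
#' One row per (frame, person, joint), for inspection or CSV export with
#' [utils::write.csv()].
#'
#' @param tracks List of `pose_track` objects (or a single track).
#' @return data.frame with columns frame, person, joint, x, y, conf.
#' @export
tracks_to_df <- function(tracks) {
  if (inherits(tracks, "pose_track")) tracks <- list(tracks)
  do.call(rbind, lapply(tracks, function(tr) {
    n <- n_frames(tr)
    data.frame(frame = rep(tr$frame_index, each = 17L),
               person = tr$visitor_id,
               joint = rep(.coco17, times = n),
               x = as.vector(t(tr$x)),
               y = as.vector(t(tr$y)),
               conf = as.vector(t(tr$conf)))
  }))
}

# neck proxy: COCO-17 has no explicit neck joint; the shoulder midpoint
# stands in for the 18-point layout's "neck" landmark
neck_proxy <- function(frame) {
  m <- frame$joints
  c(x = (m["left_shoulder", "x"] + m["right_shoulder", "x"]) / 2,
    y = (m["left_shoulder", "y"] + m["right_shoulder", "y"]) / 2)
}
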