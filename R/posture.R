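#' Posture classification thresholds
#'
#' Geometric thresholds for the three compensatory postures. Defaults follow
#' the rule set: squat when the frame-height-normalized hip-below-knee drop
#' exceeds `tau_squat` and the knee interior angles are below
#' `theta_knee_squat`; hands-on-hips when the shoulder-width-normalized
#' wrist-hip offset, the elbow interior angles and the normalized torso
#' length all fall inside their (open) ranges and the hip/wrist vertical
#' order holds; leg raise when one knee interior angle falls inside
#' `theta_raise_range` while the support knee flexion (180 degrees minus the
#' interior angle) stays at or below `theta_support_flexion_max` and the
#' width-normalized ankle separation exceeds `gamma_ankle`.
#'
#' All interval conditions are strict (open intervals): boundary values fail.
#'
#' @param tau_squat Squat vertical-ratio threshold (default 0.10).
#' @param theta_knee_squat Knee interior-angle threshold, degrees (default 120).
#' @param squat_knee_mode `"both"` (default: both knees below the threshold)
#'   or `"min"` (at least one knee below it).
#' @param eta_range Open interval for the wrist-hip ratio (default (0.30, 0.45)).
#' @param elbow_range Open interval for elbow interior angles, degrees
#'   (default (80, 120)).
#' @param torso_range Open interval for the normalized torso length
#'   (default (0.3, 0.7)).
#' @param theta_raise_range Open interval for the raised-leg knee interior
#'   angle, degrees (default (70, 130)).
#' @param gamma_ankle Ankle-separation threshold (default 0.05).
#' @param theta_support_flexion_max Maximum support-knee flexion, degrees
#'   (default 15; this bound is inclusive).
#' @param enforce_hip_wrist_order Require hip y below wrist y (image
#'   coordinates, y down) on both sides for hands-on-hips (default TRUE).
#' @return An object of class `posture_params`.
#' @export
posture_params <- function(tau_squat = 0.10,
                           theta_knee_squat = 120,
                           squat_knee_mode = c("both", "min"),
                           eta_range = c(0.30, 0.45),
                           elbow_range = c(80, 120),
                           torso_range = c(0.3, 0.7),
                           theta_raise_range = c(70, 130),
                           gamma_ankle = 0.05,
                           theta_support_flexion_max = 15,
                           enforce_hip_wrist_order = TRUE) {
  squat_knee_mode <- match.arg(squat_knee_mode)
  chk <- function(r, nm) if (length(r) != 2 || r[1] >= r[2])
    stop(nm, " must be a nonempty interval (lo, hi)")
  chk(eta_range, "eta_range"); chk(elbow_range, "elbow_range")
  chk(torso_range, "torso_range"); chk(theta_raise_range, "theta_raise_range")
  stopifnot(tau_squat > 0, theta_knee_squat > 0, gamma_ankle > 0,
            theta_support_flexion_max > 0)
  structure(list(tau_squat = tau_squat,
                 theta_knee_squat = theta_knee_squat,
                 squat_knee_mode = squat_knee_mode,
                 eta_range = eta_range,
                 elbow_range = elbow_range,
                 torso_range = torso_range,
                 theta_raise_range = theta_raise_range,
                 gamma_ankle = gamma_ankle,
                 theta_support_flexion_max = theta_support_flexion_max,
                 enforce_hip_wrist_order = isTRUE(enforce_hip_wrist_order)),
            class = "posture_params")
}

#' Posture labels
#'
#' The label set of the per-frame classifier, in detection priority order.
#' @return Character vector `c("SQUAT", "AKIMBO", "LEG_LIFT", "NONE")`.
#' @export
posture_labels <- function() c("SQUAT", "AKIMBO", "LEG_LIFT", "NONE")

.xy <- function(frame, joint) frame$joints[joint, c("x", "y")]

#' Interior angle at a vertex
#'
#' Angle between the rays vertex->a and vertex->b, in degrees within
#' \[0, 180\]. Used for knee and elbow interior angles (a straight limb is
#' about 180 degrees; flexion is 180 minus the interior angle).
#'
#' @param a,vertex,b Length-2 numeric (x, y) points.
#' @return Angle in degrees.
#' @export
interior_angle <- function(a, vertex, b) {
  u <- as.numeric(a[1:2]) - as.numeric(vertex[1:2])
  v <- as.numeric(b[1:2]) - as.numeric(vertex[1:2])
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate geometry: coincident points in interior_angle")
  cc <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cc))) * 180 / pi
}

# vectorized interior angle: all args n x 2 matrices; degenerate rows -> NA
.angle_vec <- function(ax, ay, vx, vy, bx, by) {
  ux <- ax - vx; uy <- ay - vy
  wx <- bx - vx; wy <- by - vy
  nu <- sqrt(ux^2 + uy^2); nw <- sqrt(wx^2 + wy^2)
  cc <- (ux * wx + uy * wy) / (nu * nw)
  out <- acos(pmin(1, pmax(-1, cc))) * 180 / pi
  out[nu == 0 | nw == 0] <- NA_real_
  out
}

#' Squat vertical-displacement ratio
#'
#' delta = (mean hip y - mean knee y) / H, where the means are the hip and
#' knee midpoints and H is the frame height. In image coordinates (y down) a
#' standing figure has hips above knees, hence delta < 0; a deep squat drives
#' the hip midpoint below the knee midpoint and delta positive.
#'
#' @param frame A `pose_frame` with both hips and knees detected.
#' @return Dimensionless ratio.
#' @export
squat_ratio <- function(frame) {
  m <- frame$joints
  req <- c("left_hip", "right_hip", "left_knee", "right_knee")
  if (any(m[req, "conf"] <= 0))
    stop("squat_ratio needs both hips and both knees detected")
  y_hip <- (m["left_hip", "y"] + m["right_hip", "y"]) / 2
  y_knee <- (m["left_knee", "y"] + m["right_knee", "y"]) / 2
  (y_hip - y_knee) / frame$height
}

#' Per-frame squat detection
#'
#' @param frame A `pose_frame` that passed [is_valid()] for `"squat"`.
#' @param params A [posture_params()].
#' @return `TRUE` iff the vertical ratio exceeds `tau_squat` and the knee
#'   interior angles are below `theta_knee_squat` (both knees by default;
#'   set `squat_knee_mode = "min"` to require only one).
#' @export
detect_squat <- function(frame, params = posture_params()) {
  d <- squat_ratio(frame)
  al <- interior_angle(.xy(frame, "left_hip"), .xy(frame, "left_knee"),
                       .xy(frame, "left_ankle"))
  ar <- interior_angle(.xy(frame, "right_hip"), .xy(frame, "right_knee"),
                       .xy(frame, "right_ankle"))
  knee_ok <- if (params$squat_knee_mode == "both")
    max(al, ar) < params$theta_knee_squat
  else min(al, ar) < params$theta_knee_squat
  (d > params$tau_squat) && knee_ok
}

#' Wrist-hip horizontal offset ratio
#'
#' eta = |x_wrist - x_hip| / W_shoulder for one body side, where W_shoulder
#' is the horizontal distance between the two shoulder keypoints (an
#' individual-scale normalizer). Arms hanging naturally give small eta;
#' hands on hips push the wrists laterally to an intermediate range.
#'
#' @param frame A `pose_frame`.
#' @param side `"left"` or `"right"`.
#' @return Dimensionless ratio.
#' @export
akimbo_eta <- function(frame, side = c("left", "right")) {
  side <- match.arg(side)
  m <- frame$joints
  req <- c(paste0(side, c("_wrist", "_hip")), "left_shoulder", "right_shoulder")
  if (any(m[req, "conf"] <= 0))
    stop("akimbo_eta needs wrist, hip and both shoulders detected")
  ws <- abs(m["left_shoulder", "x"] - m["right_shoulder", "x"])
  if (ws == 0) stop("degenerate geometry: zero shoulder width")
  abs(m[paste0(side, "_wrist"), "x"] - m[paste0(side, "_hip"), "x"]) / ws
}

#' Normalized torso length
#'
#' tau = distance from the neck proxy (shoulder midpoint; COCO-17 lacks an
#' explicit neck landmark) to the hip midpoint, divided by the frame height.
#' Keeps the hands-on-hips measurement within a plausible anthropometric
#' range for figures large enough to measure.
#'
#' @param frame A `pose_frame` with shoulders and hips detected.
#' @return Dimensionless ratio.
#' @export
torso_ratio <- function(frame) {
  m <- frame$joints
  req <- c("left_shoulder", "right_shoulder", "left_hip", "right_hip")
  if (any(m[req, "conf"] <= 0))
    stop("torso_ratio needs both shoulders and both hips detected")
  nk <- neck_proxy(frame)
  hx <- (m["left_hip", "x"] + m["right_hip", "x"]) / 2
  hy <- (m["left_hip", "y"] + m["right_hip", "y"]) / 2
  as.numeric(sqrt((nk["x"] - hx)^2 + (nk["y"] - hy)^2) / frame$height)
}

#' Per-frame hands-on-hips (akimbo) detection
#'
#' All conditions must hold simultaneously: eta inside `eta_range` on both
#' sides, both elbow interior angles inside `elbow_range`, the normalized
#' torso length inside `torso_range`, and (when
#' `enforce_hip_wrist_order`) hip y strictly below wrist y on each side in
#' image coordinates.
#'
#' @param frame A `pose_frame` that passed [is_valid()] for `"akimbo"`.
#' @param params A [posture_params()].
#' @return Logical.
#' @export
detect_akimbo <- function(frame, params = posture_params()) {
  el <- akimbo_eta(frame, "left"); er <- akimbo_eta(frame, "right")
  inopen <- function(x, r) x > r[1] && x < r[2]
  if (!(inopen(el, params$eta_range) && inopen(er, params$eta_range)))
    return(FALSE)
  al <- interior_angle(.xy(frame, "left_shoulder"), .xy(frame, "left_elbow"),
                       .xy(frame, "left_wrist"))
  ar <- interior_angle(.xy(frame, "right_shoulder"), .xy(frame, "right_elbow"),
                       .xy(frame, "right_wrist"))
  if (!(inopen(al, params$elbow_range) && inopen(ar, params$elbow_range)))
    return(FALSE)
  if (!inopen(torso_ratio(frame), params$torso_range)) return(FALSE)
  if (params$enforce_hip_wrist_order) {
    m <- frame$joints
    if (!(m["left_hip", "y"] < m["left_wrist", "y"] &&
          m["right_hip", "y"] < m["right_wrist", "y"])) return(FALSE)
  }
  TRUE
}

#' Normalized ankle separation
#'
#' gamma = |x_left_ankle - x_right_ankle| / W: horizontal distance between
#' the ankles as a fraction of the frame width. Guards the leg-raise rule
#' against overlapping or crossing legs.
#'
#' @param frame A `pose_frame` with both ankles detected.
#' @return Dimensionless ratio.
#' @export
ankle_separation <- function(frame) {
  m <- frame$joints
  if (any(m[c("left_ankle", "right_ankle"), "conf"] <= 0))
    stop("ankle_separation needs both ankles detected")
  abs(m["left_ankle", "x"] - m["right_ankle", "x"]) / frame$width
}

#' Per-frame single-leg-raise detection
#'
#' True when some leg's knee interior angle lies inside `theta_raise_range`
#' while the contralateral (support) knee flexion, 180 degrees minus its
#' interior angle, stays at or below `theta_support_flexion_max`, and the
#' normalized ankle separation exceeds `gamma_ankle`.
#'
#' @param frame A `pose_frame` that passed [is_valid()] for `"leg_lift"`.
#' @param params A [posture_params()].
#' @return Logical.
#' @export
detect_leg_lift <- function(frame, params = posture_params()) {
  g <- ankle_separation(frame)
  if (!(g > params$gamma_ankle)) return(FALSE)
  al <- interior_angle(.xy(frame, "left_hip"), .xy(frame, "left_knee"),
                       .xy(frame, "left_ankle"))
  ar <- interior_angle(.xy(frame, "right_hip"), .xy(frame, "right_knee"),
                       .xy(frame, "right_ankle"))
  inopen <- function(x, r) x > r[1] && x < r[2]
  fl <- 180 - al; fr <- 180 - ar
  (inopen(al, params$theta_raise_range) &&
     fr <= params$theta_support_flexion_max) ||
    (inopen(ar, params$theta_raise_range) &&
       fl <= params$theta_support_flexion_max)
}

#' Priority-ordered per-frame posture classification
#'
#' Evaluates the three detectors in fixed priority order
#' SQUAT > AKIMBO > LEG_LIFT, skipping any posture whose required joints
#' fail the validity rule, and returns the first match. Degenerate geometry
#' (coincident joints) inside a detector counts as a non-detection here
#' rather than an error.
#'
#' @param frame A `pose_frame`.
#' @param params A [posture_params()].
#' @param rule A [validity_rule()].
#' @return One of `"SQUAT"`, `"AKIMBO"`, `"LEG_LIFT"`, `"NONE"`.
#' @export
detect_pose <- function(frame, params = posture_params(),
                        rule = validity_rule()) {
  try_det <- function(f) tryCatch(f, error = function(e) FALSE)
  if (is_valid(frame, rule, "squat") &&
      try_det(detect_squat(frame, params))) return("SQUAT")
  if (is_valid(frame, rule, "akimbo") &&
      try_det(detect_akimbo(frame, params))) return("AKIMBO")
  if (is_valid(frame, rule, "leg_lift") &&
      try_det(detect_leg_lift(frame, params))) return("LEG_LIFT")
  "NONE"
}

#' Classify every frame of a track
#'
#' Vectorized equivalent of applying [detect_pose()] frame by frame; the
#' whole-track path is used by the fatigue pipeline so long recordings
#' classify in a single pass of matrix arithmetic.
#'
#' @param track A `pose_track`.
#' @param params A [posture_params()].
#' @param rule A [validity_rule()].
#' @return Character vector of per-frame labels.
#' @export
classify_frames <- function(track, params = posture_params(),
                            rule = validity_rule()) {
  x <- track$x; y <- track$y; cf <- track$conf
  W <- track$width; H <- track$height
  n <- nrow(x)
  valid_for <- function(posture) {
    req <- rule$required_joints[[posture]]
    rowSums(cf[, req, drop = FALSE] >= rule$conf_min) == length(req)
  }
  v_squat <- valid_for("squat")
  v_akimbo <- valid_for("akimbo")
  v_leg <- valid_for("leg_lift")

  kal <- .angle_vec(x[, "left_hip"], y[, "left_hip"],
                    x[, "left_knee"], y[, "left_knee"],
                    x[, "left_ankle"], y[, "left_ankle"])
  kar <- .angle_vec(x[, "right_hip"], y[, "right_hip"],
                    x[, "right_knee"], y[, "right_knee"],
                    x[, "right_ankle"], y[, "right_ankle"])

  # squat
  delta <- ((y[, "left_hip"] + y[, "right_hip"]) / 2 -
              (y[, "left_knee"] + y[, "right_knee"]) / 2) / H
  knee_ok <- if (params$squat_knee_mode == "both")
    (kal < params$theta_knee_squat) & (kar < params$theta_knee_squat)
  else pmin(kal, kar) < params$theta_knee_squat
  squat <- v_squat & !is.na(kal) & !is.na(kar) &
    (delta > params$tau_squat) & knee_ok

  # akimbo
  ws <- abs(x[, "left_shoulder"] - x[, "right_shoulder"])
  eta_l <- abs(x[, "left_wrist"] - x[, "left_hip"]) / ws
  eta_r <- abs(x[, "right_wrist"] - x[, "right_hip"]) / ws
  eal <- .angle_vec(x[, "left_shoulder"], y[, "left_shoulder"],
                    x[, "left_elbow"], y[, "left_elbow"],
                    x[, "left_wrist"], y[, "left_wrist"])
  ear <- .angle_vec(x[, "right_shoulder"], y[, "right_shoulder"],
                    x[, "right_elbow"], y[, "right_elbow"],
                    x[, "right_wrist"], y[, "right_wrist"])
  nx <- (x[, "left_shoulder"] + x[, "right_shoulder"]) / 2
  ny <- (y[, "left_shoulder"] + y[, "right_shoulder"]) / 2
  hx <- (x[, "left_hip"] + x[, "right_hip"]) / 2
  hy <- (y[, "left_hip"] + y[, "right_hip"]) / 2
  tau <- sqrt((nx - hx)^2 + (ny - hy)^2) / H
  inopen <- function(v, r) (v > r[1]) & (v < r[2])
  akimbo <- v_akimbo & (ws > 0) & !is.na(eal) & !is.na(ear) &
    inopen(eta_l, params$eta_range) & inopen(eta_r, params$eta_range) &
    inopen(eal, params$elbow_range) & inopen(ear, params$elbow_range) &
    inopen(tau, params$torso_range)
  if (params$enforce_hip_wrist_order)
    akimbo <- akimbo & (y[, "left_hip"] < y[, "left_wrist"]) &
      (y[, "right_hip"] < y[, "right_wrist"])

  # leg raise
  gam <- abs(x[, "left_ankle"] - x[, "right_ankle"]) / W
  leg <- v_leg & !is.na(kal) & !is.na(kar) & (gam > params$gamma_ankle) &
    ((inopen(kal, params$theta_raise_range) &
        (180 - kar) <= params$theta_support_flexion_max) |
       (inopen(kar, params$theta_raise_range) &
          (180 - kal) <= params$theta_support_flexion_max))

  squat[is.na(squat)] <- FALSE
  akimbo[is.na(akimbo)] <- FALSE
  leg[is.na(leg)] <- FALSE
  out <- rep("NONE", n)
  out[leg] <- "LEG_LIFT"
  out[akimbo] <- "AKIMBO"
  out[squat] <- "SQUAT"
  out
}

#' Mirror a pose frame horizontally
#'
#' Reflects x across the vertical centerline (x -> W - x) and swaps
#' left/right joints, producing the anatomically mirrored figure. All
#' posture detectors are invariant under this operation.
#'
#' @param frame A `pose_frame`.
#' @return The mirrored `pose_frame`.
#' @export
mirror_frame <- function(frame) {
  m <- frame$joints
  m[, "x"] <- frame$width - m[, "x"]
  swap <- function(a, b) { tmp <- m[a, ]; m[a, ] <<- m[b, ]; m[b, ] <<- tmp }
  for (part in c("eye", "ear", "shoulder", "elbow", "wrist", "hip",
                 "knee", "ankle"))
    swap(paste0("left_", part), paste0("right_", part))
  pose_frame(m, frame$width, frame$height, frame$frame_index, frame$person_id)
}

#' Write posture/fatigue parameters to a plain-text config
#'
#' Simple `key = value` format (intervals as `lo,hi`); readable back with
#' [read_params_config()]. Covers [posture_params()] and [fatigue_params()]
#' fields in one file.
#'
#' @param path Output file path.
#' @param posture A [posture_params()].
#' @param fatigue A [fatigue_params()].
#' @return `path`, invisibly.
#' @export
write_params_config <- function(path, posture = posture_params(),
                                fatigue = fatigue_params()) {
  fmt <- function(v) paste(format(v, digits = 15, scientific = FALSE,
                                  trim = TRUE), collapse = ",")
  kv <- c(
    tau_squat = fmt(posture$tau_squat),
    theta_knee_squat = fmt(posture$theta_knee_squat),
    squat_knee_mode = posture$squat_knee_mode,
    eta_range = fmt(posture$eta_range),
    elbow_range = fmt(posture$elbow_range),
    torso_range = fmt(posture$torso_range),
    theta_raise_range = fmt(posture$theta_raise_range),
    gamma_ankle = fmt(posture$gamma_ankle),
    theta_support_flexion_max = fmt(posture$theta_support_flexion_max),
    enforce_hip_wrist_order = fmt(posture$enforce_hip_wrist_order),
    w_squat = fmt(fatigue$weights[["SQUAT"]]),
    w_akimbo = fmt(fatigue$weights[["AKIMBO"]]),
    w_leg_lift = fmt(fatigue$weights[["LEG_LIFT"]]),
    m_confirm = fmt(fatigue$m_confirm),
    gamma_fatigue = fmt(fatigue$gamma_fatigue),
    f_min = fmt(fatigue$f_min),
    f_max = fmt(fatigue$f_max),
    norm_mode = fatigue$norm_mode,
    t_win = if (is.null(fatigue$t_win)) "" else fmt(fatigue$t_win))
  writeLines(paste(names(kv), "=", kv), path)
  invisible(path)
}

#' Read posture/fatigue parameters from a plain-text config
#'
#' @param path File written by [write_params_config()] (unknown keys are
#'   ignored; missing keys keep their defaults).
#' @return List with elements `posture` and `fatigue`.
#' @export
read_params_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- list()
  for (l in ln) {
    parts <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  num <- function(k, d) if (is.null(kv[[k]]) || !nzchar(kv[[k]])) d
    else as.numeric(strsplit(kv[[k]], ",")[[1]])
  chr <- function(k, d) if (is.null(kv[[k]]) || !nzchar(kv[[k]])) d else kv[[k]]
  pp <- posture_params(
    tau_squat = num("tau_squat", 0.10),
    theta_knee_squat = num("theta_knee_squat", 120),
    squat_knee_mode = chr("squat_knee_mode", "both"),
    eta_range = num("eta_range", c(0.30, 0.45)),
    elbow_range = num("elbow_range", c(80, 120)),
    torso_range = num("torso_range", c(0.3, 0.7)),
    theta_raise_range = num("theta_raise_range", c(70, 130)),
    gamma_ankle = num("gamma_ankle", 0.05),
    theta_support_flexion_max = num("theta_support_flexion_max", 15),
    enforce_hip_wrist_order = as.logical(chr("enforce_hip_wrist_order", "TRUE")))
  tw <- num("t_win", NA_real_)
  fp <- fatigue_params(
    weights = c(SQUAT = num("w_squat", 0.5),
                AKIMBO = num("w_akimbo", 0.2),
                LEG_LIFT = num("w_leg_lift", 0.3)),
    m_confirm = num("m_confirm", 5),
    gamma_fatigue = num("gamma_fatigue", 0.15),
    f_min = num("f_min", 0),
    f_max = num("f_max", 20),
    norm_mode = chr("norm_mode", "fixed"),
    t_win = if (is.na(tw)) NULL else tw)
  list(posture = pp, fatigue = fp)
}
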