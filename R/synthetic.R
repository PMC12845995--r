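# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.rot2 <- function(v, deg) {
  a <- deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

#' Pose a canonical stick figure
#'
#' Builds a 2-D figure with anthropometric segment ratios, posed to satisfy
#' (or, for `"NONE"`, to satisfy none of) the posture detectors' criteria
#' with explicit margins, in image coordinates (y down). The standing
#' figure has its torso at 0.35 of the frame height, inside the
#' hands-on-hips plausibility range; margins to each threshold are
#' parameters so boundary behavior is directly testable.
#'
#' @param label `"NONE"`, `"SQUAT"`, `"AKIMBO"` or `"LEG_LIFT"`.
#' @param width,height Frame dimensions in pixels.
#' @param margins List overriding pose margins: `squat_delta` (vertical
#'   ratio, default 0.2), `squat_knee` (knee interior angle, default 100),
#'   `akimbo_eta` (default 0.375), `akimbo_elbow` (default 100),
#'   `raise_knee` (raised-leg interior angle, default 100),
#'   `support_flexion` (support-leg flexion, default 2).
#' @return 17 x 3 joint matrix (x, y, conf), all confidences 1.
#' @export
pose_figure <- function(label = c("NONE", "SQUAT", "AKIMBO", "LEG_LIFT"),
                        width = 1920, height = 1080, margins = list()) {
  label <- match.arg(label)
  mg <- utils::modifyList(list(squat_delta = 0.2, squat_knee = 100,
                               akimbo_eta = 0.375, akimbo_elbow = 100,
                               raise_knee = 100, support_flexion = 2),
                          margins)
  W <- width; H <- height
  x0 <- W / 2
  m <- matrix(0, 17L, 3L, dimnames = list(.coco17, c("x", "y", "conf")))
  set_j <- function(j, x, y) m[j, ] <<- c(x, y, 1)

  # head, constant across poses
  set_j("nose", x0, 0.12 * H)
  set_j("left_eye", x0 - 15, 0.11 * H); set_j("right_eye", x0 + 15, 0.11 * H)
  set_j("left_ear", x0 - 35, 0.12 * H); set_j("right_ear", x0 + 35, 0.12 * H)

  sh_half <- 100; hip_half <- 70
  y_sh <- 0.27 * H; y_hip <- 0.62 * H; y_knee <- 0.80 * H; y_ank <- 0.97 * H
  shank <- 0.17 * H

  standing_legs <- function() {
    set_j("left_hip", x0 - hip_half, y_hip)
    set_j("right_hip", x0 + hip_half, y_hip)
    set_j("left_knee", x0 - hip_half, y_knee)
    set_j("right_knee", x0 + hip_half, y_knee)
    set_j("left_ankle", x0 - hip_half, y_ank)
    set_j("right_ankle", x0 + hip_half, y_ank)
  }
  hanging_arms <- function(y_sh_use = y_sh) {
    set_j("left_shoulder", x0 - sh_half, y_sh_use)
    set_j("right_shoulder", x0 + sh_half, y_sh_use)
    set_j("left_elbow", x0 - sh_half, y_sh_use + 0.16 * H)
    set_j("right_elbow", x0 + sh_half, y_sh_use + 0.16 * H)
    set_j("left_wrist", x0 - sh_half, y_sh_use + 0.32 * H)
    set_j("right_wrist", x0 + sh_half, y_sh_use + 0.32 * H)
  }

  if (label == "NONE") {
    standing_legs(); hanging_arms()
  } else if (label == "SQUAT") {
    yk <- 0.55 * H
    yh <- yk + mg$squat_delta * H
    for (s in c(-1, 1)) {
      side <- if (s < 0) "left" else "right"
      knee <- c(x0 + s * 90, yk)
      hip <- c(x0 + s * 40, yh)
      set_j(paste0(side, "_knee"), knee[1], knee[2])
      set_j(paste0(side, "_hip"), hip[1], hip[2])
      u <- (hip - knee) / sqrt(sum((hip - knee)^2))
      ank <- knee + shank * .rot2(u, s * mg$squat_knee)
      set_j(paste0(side, "_ankle"), ank[1], ank[2])
    }
    hanging_arms(yh - 0.35 * H)
  } else if (label == "AKIMBO") {
    standing_legs()
    set_j("left_shoulder", x0 - sh_half, y_sh)
    set_j("right_shoulder", x0 + sh_half, y_sh)
    for (s in c(-1, 1)) {
      side <- if (s < 0) "left" else "right"
      S <- c(x0 + s * sh_half, y_sh)
      Wr <- c(x0 + s * (hip_half + mg$akimbo_eta * 2 * sh_half), y_hip + 15)
      set_j(paste0(side, "_wrist"), Wr[1], Wr[2])
      cvec <- Wr - S
      clen <- sqrt(sum(cvec^2))
      h <- (clen / 2) / tan(mg$akimbo_elbow / 2 * pi / 180)
      mid <- (S + Wr) / 2
      perp <- c(-cvec[2], cvec[1]) / clen
      if (sign(perp[1]) != s) perp <- -perp   # bow the elbow outward
      E <- mid + h * perp
      set_j(paste0(side, "_elbow"), E[1], E[2])
    }
  } else if (label == "LEG_LIFT") {
    hanging_arms()
    set_j("left_hip", x0 - hip_half, y_hip)
    set_j("right_hip", x0 + hip_half, y_hip)
    # support leg (right): near-straight, small flexion
    set_j("right_knee", x0 + hip_half, y_knee)
    u <- c(0, 1)  # downward
    ank_s <- c(x0 + hip_half, y_knee) + shank * .rot2(u, mg$support_flexion)
    set_j("right_ankle", ank_s[1], ank_s[2])
    # raised leg (left): knee interior angle in the raise range, ankle
    # swung outward so the ankles separate clearly
    knee_r <- c(x0 - hip_half, y_knee)
    set_j("left_knee", knee_r[1], knee_r[2])
    up <- c(0, -1)  # toward the hip
    ank_r <- knee_r + shank * .rot2(up, -mg$raise_knee)
    set_j("left_ankle", ank_r[1], ank_r[2])
  }
  m
}

#' Script posture events for a synthetic track
#'
#' @param events data.frame with columns `start`, `end` (1-based frame
#'   positions, inclusive, non-overlapping) and `label` (posture names);
#'   frames outside any event show the neutral standing figure.
#' @param duration_frames Total track length in frames.
#' @param fps Frames per second (default 30).
#' @param noise_sd Gaussian jitter, pixels, added to every coordinate.
#' @param dropout_rate Per-joint per-frame probability of losing a joint
#'   (its confidence set to 0).
#' @param width,height Frame dimensions.
#' @param margins Pose margins, see [pose_figure()].
#' @param seed RNG seed making the generated track reproducible.
#' @return An object of class `posture_script`.
#' @export
posture_script <- function(events, duration_frames, fps = 30,
                           noise_sd = 0, dropout_rate = 0,
                           width = 1920, height = 1080,
                           margins = list(), seed = 1L) {
  if (is.null(events) || !nrow(events)) {
    events <- data.frame(start = integer(0), end = integer(0),
                         label = character(0))
  }
  stopifnot(all(c("start", "end", "label") %in% names(events)),
            duration_frames >= 1, fps > 0,
            noise_sd >= 0, dropout_rate >= 0, dropout_rate <= 1)
  if (nrow(events)) {
    stopifnot(all(events$start >= 1), all(events$end <= duration_frames),
              all(events$start <= events$end),
              all(events$label %in% c("SQUAT", "AKIMBO", "LEG_LIFT")))
    ev <- events[order(events$start), ]
    if (nrow(ev) > 1 && any(ev$start[-1] <= ev$end[-nrow(ev)]))
      stop("scripted events overlap")
  }
  structure(list(events = events, duration_frames = as.integer(duration_frames),
                 fps = fps, noise_sd = noise_sd, dropout_rate = dropout_rate,
                 width = width, height = height, margins = margins,
                 seed = as.integer(seed)),
            class = "posture_script")
}

#' Generate a keypoint track from a posture script
#'
#' During an event the joints are posed to satisfy the corresponding
#' detector's criteria with the script's margins; outside events the
#' neutral standing figure satisfies none. Gaussian jitter and Bernoulli
#' joint dropout are applied afterward. Deterministic given the script's
#' seed; the caller's RNG state is left untouched.
#'
#' @param script A [posture_script()].
#' @param visitor_id Visitor identifier for the track.
#' @param zone_id Optional single zone id assigned to every frame.
#' @return A `pose_track` with attribute `truth`: the scripted per-frame
#'   label vector.
#' @export
gen_track <- function(script, visitor_id = "v1", zone_id = NULL) {
  stopifnot(inherits(script, "posture_script"))
  n <- script$duration_frames
  truth <- rep("NONE", n)
  if (nrow(script$events))
    for (i in seq_len(nrow(script$events)))
      truth[script$events$start[i]:script$events$end[i]] <-
        script$events$label[i]
  poses <- lapply(c("NONE", "SQUAT", "AKIMBO", "LEG_LIFT"), pose_figure,
                  width = script$width, height = script$height,
                  margins = script$margins)
  names(poses) <- c("NONE", "SQUAT", "AKIMBO", "LEG_LIFT")
  x <- y <- cf <- matrix(0, n, 17L, dimnames = list(NULL, .coco17))
  for (i in seq_len(n)) {
    p <- poses[[truth[i]]]
    x[i, ] <- p[, "x"]; y[i, ] <- p[, "y"]; cf[i, ] <- p[, "conf"]
  }
  with_seed(script$seed, {
    if (script$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n * 17L, 0, script$noise_sd), n, 17L)
      y <- y + matrix(stats::rnorm(n * 17L, 0, script$noise_sd), n, 17L)
    }
    if (script$dropout_rate > 0)
      cf[matrix(stats::runif(n * 17L) < script$dropout_rate, n, 17L)] <- 0
  })
  tr <- new_track(visitor_id, seq_len(n) - 1L, x, y, cf,
                  script$width, script$height, dt = 1 / script$fps,
                  zone_ids = if (!is.null(zone_id)) rep(zone_id, n))
  attr(tr, "truth") <- truth
  tr
}

#' Generate a visitor population with known per-zone fatigue probabilities
#'
#' For each zone, `n` independent visitor tracks are generated; with the
#' zone's probability `p` a visitor receives a supra-threshold scripted
#' squat budget, otherwise a sub-threshold one, so the zone's true fatigue
#' proportion is a Bernoulli(p) draw per visitor. Budgets default to raw
#' scores of 3.5 weighted seconds (fatigued, safely above the 3.0 decision
#' boundary at the default normalization) and 1.0 (not fatigued): under the
#' default confirmation and weights the binomial truth is unambiguous.
#'
#' @param zone_ids Integer vector of zone ids.
#' @param n Visitors per zone.
#' @param p Per-zone fatigue probability, recycled over zones.
#' @param fps Frames per second (default 30).
#' @param budget_fatigued,budget_rest Target raw scores (weighted seconds)
#'   for fatigued and non-fatigued visitors.
#' @param m_confirm Confirmation length the budgets account for.
#' @param seed RNG seed.
#' @return List with `tracks` (flat list of zoned tracks), `truth`
#'   (data.frame zone_id, p, n_fatigued_true).
#' @export
gen_population <- function(zone_ids, n, p, fps = 30,
                           budget_fatigued = 3.5, budget_rest = 1.0,
                           m_confirm = 5L, seed = 1L) {
  stopifnot(n >= 1, all(p >= 0), all(p <= 1))
  p <- rep_len(p, length(zone_ids))
  w_squat <- 0.5; dt <- 1 / fps
  run_len <- function(budget) {
    conf_frames <- round(budget / (w_squat * dt))
    if (conf_frames == 0) 0L else as.integer(conf_frames + m_confirm - 1L)
  }
  len_f <- run_len(budget_fatigued); len_r <- run_len(budget_rest)
  tracks <- list(); truth <- NULL
  draws <- with_seed(seed, lapply(seq_along(zone_ids), function(zi)
    stats::runif(n) < p[zi]))
  for (zi in seq_along(zone_ids)) {
    fat <- draws[[zi]]
    for (v in seq_len(n)) {
      L <- if (fat[v]) len_f else len_r
      dur <- L + 30L
      ev <- if (L > 0) data.frame(start = 16L, end = 15L + L,
                                  label = "SQUAT") else NULL
      sc <- posture_script(ev, duration_frames = dur, fps = fps,
                           seed = seed + zi * 100000L + v)
      tracks[[length(tracks) + 1L]] <-
        gen_track(sc, visitor_id = sprintf("z%d_v%d", zone_ids[zi], v),
                  zone_id = zone_ids[zi])
    }
    truth <- rbind(truth, data.frame(zone_id = zone_ids[zi], p = p[zi],
                                     n_fatigued_true = sum(fat)))
  }
  list(tracks = tracks, truth = truth)
}

#' Generate a toy floor plan with camera candidates
#'
#' `"open-hall"`: a 20 x 12 m rectangular hall, 1 m cells, no obstacles;
#' candidate 1 sits at a corner with a 90-degree field of view and a radius
#' beyond the hall diagonal, so it alone sees every cell. `"partition-wall"`:
#' the same hall with a thin internal wall; cells behind the wall are
#' invisible to cameras in front of it. Candidates are placed on the
#' boundary heading inward; fields of view are drawn uniformly from
#' \[90, 120\] degrees under the seed.
#'
#' @param kind Layout name.
#' @param seed RNG seed for the sampled fields of view.
#' @return List with `grid` ([coverage_grid()]) and `candidates`.
#' @export
gen_floorplan <- function(kind = c("open-hall", "partition-wall"), seed = 1L) {
  kind <- match.arg(kind)
  domain <- rbind(c(0, 0), c(20, 0), c(20, 12), c(0, 12))
  obstacles <- if (kind == "partition-wall")
    list(rbind(c(9.9, 3), c(10.1, 3), c(10.1, 12), c(9.9, 12)))
  else list()
  grid <- coverage_grid(domain, cell_size = 1, obstacles = obstacles)
  pos <- rbind(c(0.05, 0.05), c(19.95, 0.05), c(19.95, 11.95), c(0.05, 11.95),
               c(10, 0.05), c(10, 11.95), c(0.05, 6), c(19.95, 6))
  head <- c(45, 135, 225, 315, 90, 270, 0, 180)
  fovs <- with_seed(seed, stats::runif(nrow(pos), 90, 120))
  fovs[1] <- 90
  cands <- lapply(seq_len(nrow(pos)), function(i)
    camera_candidate(i, pos[i, ], head[i],
                     fov = fovs[i],
                     radius = if (i == 1) 30 else 12))
  list(grid = grid, candidates = cands)
}

#' Generate deterministic test images
#'
#' Rasters with analytically known quality-metric values: `"constant"`
#' (all metrics 0), `"step"` (vertical step edge of known Sobel response),
#' `"checkerboard"`, `"gradient"` (pure low-frequency ramp), and
#' `"blurred"` (the checkerboard after `blur_passes` 3x3 box blurs).
#'
#' @param kind Image kind.
#' @param size Side length in pixels (square).
#' @param value Intensity for `"constant"`.
#' @param step_height Intensity jump for `"step"`.
#' @param period Checker square size in pixels.
#' @param blur_passes Number of box-blur passes for `"blurred"`.
#' @return Numeric intensity matrix.
#' @export
gen_test_images <- function(kind = c("constant", "step", "checkerboard",
                                     "gradient", "blurred"),
                            size = 32L, value = 128, step_height = 100,
                            period = 4L, blur_passes = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    constant = matrix(value, size, size),
    step = {
      img <- matrix(0, size, size)
      img[, (size %/% 2 + 1):size] <- step_height
      img
    },
    checkerboard = {
      idx <- (seq_len(size) - 1) %/% period
      outer(idx, idx, function(i, j) ((i + j) %% 2) * 255)
    },
    gradient = matrix(rep(seq(0, 255, length.out = size), each = size),
                      size, size),
    blurred = {
      img <- gen_test_images("checkerboard", size = size, period = period)
      for (k in seq_len(blur_passes)) img <- box_blur3(img)
      img
    })
}

#' 3x3 box blur with replicate borders
#' @param img Numeric intensity matrix.
#' @return Blurred matrix of the same size.
#' @export
box_blur3 <- function(img) conv3(img, matrix(1 / 9, 3, 3))
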