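test_that("interior_angle matches a closed-form oracle and handles degeneracy", {
  expect_equal(interior_angle(c(0, 0), c(0, 1), c(0, 2)), 180)
  expect_equal(interior_angle(c(0, 0), c(0, 1), c(1, 1)), 90)
  expect_error(interior_angle(c(1, 1), c(1, 1), c(0, 0)), "degenerate")

  set.seed(42)
  for (k in 1:100) {
    a <- runif(2, -10, 10); v <- runif(2, -10, 10); b <- runif(2, -10, 10)
    if (all(a == v) || all(b == v)) next
    # oracle: absolute difference of the two ray bearings, folded to [0, 180]
    th <- abs(atan2(a[2] - v[2], a[1] - v[1]) -
                atan2(b[2] - v[2], b[1] - v[1])) * 180 / pi
    if (th > 180) th <- 360 - th
    expect_lt(abs(interior_angle(a, v, b) - th), 1e-9)
  }
})

test_that("squat ratio follows the midpoint definition and the y-down sign", {
  m <- pose_figure("NONE", 1920, 1080)
  m["left_hip", "y"] <- 540; m["right_hip", "y"] <- 540
  m["left_knee", "y"] <- 324; m["right_knee", "y"] <- 324
  fr <- pose_frame(m, 1920, 1080)
  expect_equal(squat_ratio(fr), 0.2)

  m["left_knee", "y"] <- 540; m["right_knee", "y"] <- 540
  expect_equal(squat_ratio(pose_frame(m, 1920, 1080)), 0)

  # a standing figure keeps hips above knees in the image, so delta < 0
  expect_lt(squat_ratio(fig_frame("NONE")), 0)
  m["left_hip", "conf"] <- 0
  expect_error(squat_ratio(pose_frame(m, 1920, 1080)), "hips")
})

test_that("squat detection requires both the drop and the knee angles", {
  expect_true(detect_squat(legs_frame(0.2, 100, 95)))
  expect_false(detect_squat(legs_frame(0.05, 100, 95)))
  # one knee at 130: fails the both-knee reading, passes the min() reading
  fr <- legs_frame(0.2, 100, 130)
  expect_false(detect_squat(fr))
  expect_true(detect_squat(fr, posture_params(squat_knee_mode = "min")))
  # boundary: threshold comparisons are strict
  expect_false(detect_squat(legs_frame(0.1, 100, 100)))
})

test_that("akimbo ratio is shoulder-normalized, absolute, and mirror-symmetric", {
  m <- pose_figure("NONE", 1920, 1080)
  m["left_shoulder", "x"] <- 910; m["right_shoulder", "x"] <- 1010
  m["left_wrist", "x"] <- 130; m["left_hip", "x"] <- 100
  fr <- pose_frame(m, 1920, 1080)
  expect_equal(akimbo_eta(fr, "left"), 0.3)
  m["left_wrist", "x"] <- 100
  expect_equal(akimbo_eta(pose_frame(m, 1920, 1080), "left"), 0)

  fa <- fig_frame("AKIMBO")
  fm <- mirror_frame(fa)
  expect_equal(akimbo_eta(fm, "left"), akimbo_eta(fa, "right"))
  expect_equal(akimbo_eta(fm, "right"), akimbo_eta(fa, "left"))

  m["left_shoulder", "x"] <- m["right_shoulder", "x"]
  expect_error(akimbo_eta(pose_frame(m, 1920, 1080), "left"), "shoulder width")
})

test_that("torso ratio uses the neck proxy and frame height", {
  m <- pose_figure("NONE", 1920, 1080)
  m[c("left_shoulder", "right_shoulder"), "x"] <- c(900, 1020)
  m[c("left_shoulder", "right_shoulder"), "y"] <- 300
  m[c("left_hip", "right_hip"), "x"] <- 960
  m[c("left_hip", "right_hip"), "y"] <- 624
  expect_equal(torso_ratio(pose_frame(m, 1920, 1080)), 0.3)
  # degenerate zero-length torso falls outside the plausible range
  m[c("left_hip", "right_hip"), "y"] <- 300
  m[c("left_hip", "right_hip"), "x"] <- 960
  fr0 <- pose_frame(m, 1920, 1080)
  expect_equal(torso_ratio(fr0), 0)
  expect_false(detect_akimbo(fr0))
})

test_that("akimbo needs all four conditions; boundaries are open", {
  expect_true(detect_akimbo(fig_frame("AKIMBO")))
  # eta exactly at the lower bound fails (open interval)
  expect_false(detect_akimbo(fig_frame("AKIMBO",
                                       margins = list(akimbo_eta = 0.30))))
  # straight hanging arms fail the elbow range
  expect_false(detect_akimbo(fig_frame("AKIMBO",
                                       margins = list(akimbo_elbow = 170))))
  # hip/wrist vertical-order check can be relaxed: a vertically reflected
  # figure preserves eta, elbow angles and torso length but flips the order
  fa <- fig_frame("AKIMBO")
  m <- fa$joints
  m[, "y"] <- 1080 - m[, "y"]
  fr <- pose_frame(m, 1920, 1080)
  expect_false(detect_akimbo(fr))
  expect_true(detect_akimbo(fr,
                            posture_params(enforce_hip_wrist_order = FALSE)))
})

test_that("ankle separation is width-normalized with a strict threshold", {
  m <- pose_figure("NONE", 1920, 1080)
  m["left_ankle", "x"] <- 912; m["right_ankle", "x"] <- 1008
  fr <- pose_frame(m, 1920, 1080)
  expect_equal(ankle_separation(fr), 0.05)
  lf <- fig_frame("LEG_LIFT")
  m2 <- lf$joints
  # compress the stance to exactly gamma = 0.04: detection must fail
  mid <- mean(m2[c("left_ankle", "right_ankle"), "x"])
  sep <- 0.04 * 1920
  m2["left_ankle", "x"] <- mid - sep / 2
  m2["right_ankle", "x"] <- mid + sep / 2
  expect_false(detect_leg_lift(pose_frame(m2, 1920, 1080),
                               posture_params(theta_raise_range = c(10, 170),
                                              theta_support_flexion_max = 90)))
  m2["left_ankle", "x"] <- m2["right_ankle", "x"]
  expect_equal(ankle_separation(pose_frame(m2, 1920, 1080)), 0)
  expect_equal(ankle_separation(mirror_frame(lf)), ankle_separation(lf))
})

test_that("leg raise needs one flexed and one straight leg plus separation", {
  expect_true(detect_leg_lift(fig_frame("LEG_LIFT")))
  # both knees flexed to 100: no straight support leg
  both <- legs_frame(-0.18, 100, 100)
  expect_false(detect_leg_lift(both))
  # support leg flexed beyond the tolerance
  expect_false(detect_leg_lift(fig_frame("LEG_LIFT",
                                         margins = list(support_flexion = 20))))
  expect_true(detect_leg_lift(mirror_frame(fig_frame("LEG_LIFT"))))
})

test_that("detect_pose applies priority and survives invalid frames", {
  # a figure meeting squat (min mode) and leg-raise criteria at once -> SQUAT
  fr <- legs_frame(0.2, 100, 176)
  pp <- posture_params(squat_knee_mode = "min", gamma_ankle = 0.01)
  expect_true(detect_squat(fr, pp))
  expect_true(detect_leg_lift(fr, pp))
  expect_equal(detect_pose(fr, pp), "SQUAT")

  m <- pose_figure("NONE"); m[, "conf"] <- 0
  expect_equal(detect_pose(pose_frame(m, 1920, 1080)), "NONE")

  # compositional oracle over the scripted figure grid
  rule <- validity_rule()
  for (lab in c("NONE", "SQUAT", "AKIMBO", "LEG_LIFT")) {
    fr <- fig_frame(lab)
    expected <- if (is_valid(fr, rule, "squat") && detect_squat(fr)) "SQUAT"
      else if (is_valid(fr, rule, "akimbo") && detect_akimbo(fr)) "AKIMBO"
      else if (is_valid(fr, rule, "leg_lift") && detect_leg_lift(fr)) "LEG_LIFT"
      else "NONE"
    expect_equal(detect_pose(fr), expected)
    expect_equal(detect_pose(fr), lab)
  }
})

test_that("detectors are invariant under rescaling and mirroring", {
  for (lab in c("NONE", "SQUAT", "AKIMBO", "LEG_LIFT")) {
    fr <- fig_frame(lab)
    m2 <- fr$joints; m2[, c("x", "y")] <- 1.75 * m2[, c("x", "y")]
    scaled <- pose_frame(m2, 1.75 * 1920, 1.75 * 1080)
    expect_equal(detect_pose(scaled), detect_pose(fr))
    expect_equal(detect_pose(mirror_frame(fr)), detect_pose(fr))
  }
})

test_that("detectors are monotone in their own thresholds", {
  set.seed(5)
  for (k in 1:15) {
    d <- runif(1, 0.05, 0.3)
    fr <- legs_frame(d, runif(1, 80, 140), runif(1, 80, 140))
    lo <- detect_squat(fr, posture_params(tau_squat = 0.10))
    hi <- detect_squat(fr, posture_params(tau_squat = 0.25))
    expect_false(!lo && hi)  # raising tau_squat never creates detections
    th_lo <- detect_squat(fr, posture_params(theta_knee_squat = 100))
    th_hi <- detect_squat(fr, posture_params(theta_knee_squat = 140))
    expect_false(th_lo && !th_hi)  # widening the knee bound keeps detections
  }
})

test_that("whole-track classification agrees with the per-frame classifier", {
  ev <- data.frame(start = c(5, 40, 75), end = c(30, 60, 100),
                   label = c("SQUAT", "AKIMBO", "LEG_LIFT"))
  sc <- posture_script(ev, duration_frames = 110, noise_sd = 2,
                       dropout_rate = 0.05, seed = 99)
  tr <- gen_track(sc)
  vec <- classify_frames(tr)
  scalar <- vapply(seq_len(n_frames(tr)),
                   function(i) detect_pose(track_frame(tr, i)), character(1))
  expect_identical(vec, scalar)
})

test_that("parameter config files round-trip", {
  pp <- posture_params(tau_squat = 0.12, eta_range = c(0.25, 0.5),
                       squat_knee_mode = "min",
                       enforce_hip_wrist_order = FALSE)
  fp <- fatigue_params(m_confirm = 7, gamma_fatigue = 0.2,
                       norm_mode = "window", t_win = 60)
  f <- tempfile(fileext = ".cfg")
  write_params_config(f, pp, fp)
  back <- read_params_config(f)
  expect_equal(back$posture[names(back$posture)], pp[names(pp)])
  expect_equal(back$fatigue$m_confirm, 7L)
  expect_equal(back$fatigue$t_win, 60)
  expect_equal(back$fatigue$norm_mode, "window")
})
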