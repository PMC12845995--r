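sq_zone <- function(id, x0, y0, w = 10, h = 10)
  zone(id, rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h)))

test_that("zone assignment matches an independent point-in-polygon oracle", {
  zs <- list(sq_zone(1, 0, 0), sq_zone(2, 10, 0),
             zone(3, rbind(c(0, 10), c(20, 10), c(10, 25))))  # triangle
  expect_equal(assign_zone(c(5, 5), zs), 1L)
  expect_equal(assign_zone(zs[[3]]$rep_point, zs), 3L)
  expect_true(is.na(assign_zone(c(50, 50), zs)))

  set.seed(31)
  pts <- cbind(runif(1000, -2, 22), runif(1000, -2, 27))
  for (z in zs) {
    ours <- vapply(seq_len(nrow(pts)), function(i)
      fatiguemap:::point_in_polygon(pts[i, 1], pts[i, 2], z$polygon),
      logical(1))
    ref <- mgcv::in.out(rbind(z$polygon, z$polygon[1, ]), pts)
    expect_identical(ours, as.logical(ref))
  }
})

test_that("overlapping zones resolve to the lowest id with a warning", {
  zs <- list(sq_zone(4, 0, 0), sq_zone(2, 5, 5))
  expect_warning(id <- assign_zone(c(7, 7), zs), "overlap")
  expect_equal(id, 2L)
})

test_that("zone FI counts unique visitors and re-confirms within the zone", {
  # 10 visitors; 2 with supra-threshold in-zone squat time
  trs <- lapply(1:10, function(v) {
    ev <- if (v <= 2) data.frame(start = 11, end = 224, label = "SQUAT")
          else NULL
    gen_track(posture_script(ev, duration_frames = 240),
              visitor_id = paste0("v", v), zone_id = 1L)
  })
  st <- zone_fatigue_index(trs, 1L)
  expect_equal(st$n_total, 10L)
  expect_equal(st$n_fatigued, 2L)
  expect_equal(st$fi, 0.2)
  expect_equal(st$band, "low")
  expect_false(st$empty)

  empty <- zone_fatigue_index(trs, 99L)
  expect_equal(empty$fi, 0)
  expect_true(empty$empty)

  # a confirmed-length run split across two zones must re-confirm per zone:
  # 8 squat frames straddling a boundary leave runs of 4 in each zone
  tr <- gen_track(posture_script(
    data.frame(start = 21, end = 28, label = "SQUAT"), 48), visitor_id = "z")
  tr$zone_ids <- rep(c(1L, 2L), each = 24)
  r1 <- detect_fatigue(subset_track(tr, tr$zone_ids == 1L))
  r2 <- detect_fatigue(subset_track(tr, tr$zone_ids == 2L))
  expect_equal(r1$score_raw + r2$score_raw, 0)
  expect_equal(detect_fatigue(tr)$confirmed_durations[["SQUAT"]], 4 / 30)
})

test_that("FI bands follow the equal-interval closure", {
  expect_equal(classify_fi(0.20), "low")
  expect_equal(classify_fi(0.7407), "high")
  expect_equal(classify_fi(1 / 3), "low")        # boundary closes downward
  expect_equal(classify_fi(2 / 3), "medium")
  expect_equal(classify_fi(c(0, 1)), c("low", "high"))
  expect_error(classify_fi(1.2), "\\[0, 1\\]")
})

test_that("run comparison reproduces the percentage-point convention", {
  pre <- data.frame(zone_id = 1:2, fi = c(0.6000, 0.5684), n_total = 10)
  post <- data.frame(zone_id = 1:2, fi = c(0.3611, 0.5319), n_total = 10)
  cmp <- compare_runs(pre, post)
  expect_equal(cmp$per_zone$decrease_pp[1], 23.89)
  same <- compare_runs(pre, pre)
  expect_true(all(same$per_zone$decrease_pp == 0))
  # antisymmetry
  rev <- compare_runs(post, pre)
  expect_equal(rev$per_zone$decrease_pp, -cmp$per_zone$decrease_pp)
  expect_error(compare_runs(pre, post[1, ]), "zone ids")

  means <- compare_runs(data.frame(zone_id = 1, fi = 0.5842, n_total = 45),
                        data.frame(zone_id = 1, fi = 0.4465, n_total = 45))
  expect_equal(means$mean_decrease_abs, 0.1377)
})

test_that("descriptive arithmetic matches hand calculation", {
  expect_equal(round(relative_change(2933.89, 4084.87), 2), 39.23)
  expect_equal(relative_change(5, 5), 0)
  expect_error(relative_change(0, 1), "before")
  expect_equal(round(proportion(211, 233), 2), 90.56)
  expect_equal(proportion(0, 50), 0)
  expect_error(proportion(1, 0), "n = 0")
})

test_that("binomial FI recovery at moderate n stays within sampling error", {
  fis <- vapply(1:8, function(s) {
    pop <- gen_population(1L, n = 60, p = 0.5, seed = 100 + s)
    zone_fatigue_index(pop$tracks, 1L)$fi
  }, numeric(1))
  se <- sqrt(0.5 * 0.5 / 60)
  expect_lt(abs(mean(fis) - 0.5), 3 * se)
})

test_that("heatmap export round-trips FI values at full precision", {
  zs <- list(sq_zone(1, 0, 0), sq_zone(2, 10, 0), sq_zone(3, 0, 10))
  pop <- gen_population(c(1L, 2L), n = 6, p = c(1, 1 / 3), seed = 4)
  st <- zone_fi(pop$tracks, zs)
  expect_equal(nrow(st), 3L)
  expect_true(st$empty[3])
  csv <- tempfile(fileext = ".csv"); png <- tempfile(fileext = ".png")
  export_heatmap(st, csv_path = csv, png_path = png)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 3L)
  expect_identical(back$fi, st$fi)
  expect_true(file.exists(png))

  # degenerate all-zero FI map renders without error
  pop0 <- gen_population(c(1L, 2L), n = 3, p = 0, seed = 5)
  st0 <- zone_fi(pop0$tracks, zs[1:2])
  png0 <- tempfile(fileext = ".png")
  export_heatmap(st0, csv_path = NULL, png_path = png0)
  expect_true(file.exists(png0))
  expect_true(all(st0$fi == 0))
})

test_that("homography projection maps image points to the plan", {
  H <- rbind(c(2, 0, 1), c(0, 3, -1), c(0, 0, 1))
  out <- apply_homography(H, rbind(c(1, 1), c(0, 0)))
  expect_equal(out, rbind(c(3, 2), c(1, -1)))
})
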