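# shared fixtures and independent oracles

fig_frame <- function(label, margins = list(), W = 1920, H = 1080) {
  pose_frame(pose_figure(label, W, H, margins), W, H)
}

# build a frame with prescribed squat geometry: vertical hip-knee ratio and
# per-side knee interior angles, legs constructed by explicit rotation
legs_frame <- function(delta, ang_left, ang_right, W = 1920, H = 1080,
                       base = "NONE") {
  m <- pose_figure(base, W, H)
  rot <- function(v, deg) {
    a <- deg * pi / 180
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
  }
  yk <- 0.55 * H
  yh <- yk + delta * H
  for (s in c(-1, 1)) {
    side <- if (s < 0) "left" else "right"
    ang <- if (s < 0) ang_left else ang_right
    knee <- c(W / 2 + s * 90, yk)
    hip <- c(W / 2 + s * 40, yh)
    u <- (hip - knee) / sqrt(sum((hip - knee)^2))
    ank <- knee + 0.17 * H * rot(u, s * ang)
    m[paste0(side, "_knee"), ] <- c(knee, 1)
    m[paste0(side, "_hip"), ] <- c(hip, 1)
    m[paste0(side, "_ankle"), ] <- c(ank, 1)
  }
  pose_frame(m, W, H)
}

# direct trace of the multi-frame confirmation counter: a label accrues on
# frame t iff it equals the previous raw label on an unbroken run whose
# counter has reached m (independent re-derivation used as oracle)
confirm_trace <- function(labels, m) {
  out <- rep("NONE", length(labels))
  c_run <- 0L; prev <- "NONE"
  for (t in seq_along(labels)) {
    p <- labels[t]
    if (p == "NONE") { c_run <- 0L; prev <- "NONE" }
    else if (p == prev) c_run <- c_run + 1L
    else { c_run <- 1L; prev <- p }
    if (c_run >= m) out[t] <- p
  }
  out
}

# brute-force visibility oracle: per-cell distance/angle test plus dense
# sampling along the sightline for occlusion (independent of the package's
# segment-intersection routine)
visible_cells_oracle <- function(cam, grid, n_samples = 400) {
  ctr <- grid$centers
  ok <- logical(nrow(ctr))
  for (i in seq_len(nrow(ctr))) {
    dx <- ctr[i, 1] - cam$position[1]
    dy <- ctr[i, 2] - cam$position[2]
    d <- sqrt(dx^2 + dy^2)
    if (d > cam$radius) next
    if (d > 0) {
      ang <- atan2(dy, dx) * 180 / pi
      dang <- abs(((ang - cam$heading + 180) %% 360) - 180)
      if (dang > cam$fov / 2) next
    }
    blocked <- FALSE
    if (length(grid$obstacles) && d > 0) {
      ts <- seq(0, 1, length.out = n_samples)
      px <- cam$position[1] + ts * dx
      py <- cam$position[2] + ts * dy
      for (ob in grid$obstacles) {
        inside <- mgcv::in.out(rbind(ob, ob[1, ]), cbind(px, py))
        if (any(inside)) { blocked <- TRUE; break }
      }
    }
    ok[i] <- !blocked
  }
  which(ok)
}

# random planner instance: small hall, <= 30 cells, <= 12 candidates
random_coverage_instance <- function(seed) {
  set.seed(seed)
  nxc <- sample(4:6, 1); nyc <- sample(3:5, 1)
  domain <- rbind(c(0, 0), c(nxc, 0), c(nxc, nyc), c(0, nyc))
  obstacles <- if (runif(1) < 0.5) {
    ox <- runif(1, 0.8, nxc - 1.2); oy <- runif(1, 0.8, nyc - 1.2)
    list(rbind(c(ox, oy), c(ox + 0.4, oy), c(ox + 0.4, oy + 0.4),
               c(ox, oy + 0.4)))
  } else list()
  grid <- coverage_grid(domain, 1, obstacles)
  ncand <- sample(5:12, 1)
  cands <- lapply(seq_len(ncand), function(j)
    camera_candidate(j, c(runif(1, 0.1, nxc - 0.1), runif(1, 0.1, nyc - 0.1)),
                     heading = runif(1, 0, 360), fov = runif(1, 90, 120),
                     radius = runif(1, 1.5, 6)))
  list(grid = grid, candidates = cands)
}

# straight-line reimplementation of the IAQ feature vector (double loops and
# textbook formulas; independent of the package's vectorized code)
iaq_features_oracle <- function(g, prev = NULL, window = 16L, stride = 16L) {
  nr <- nrow(g); nc <- ncol(g)
  # DCT-II by direct summation
  co <- matrix(0, nr, nc)
  for (u in 0:(nr - 1)) for (v in 0:(nc - 1)) {
    s <- 0
    for (i in 0:(nr - 1)) for (j in 0:(nc - 1))
      s <- s + g[i + 1, j + 1] *
        cos(pi * (2 * i + 1) * u / (2 * nr)) *
        cos(pi * (2 * j + 1) * v / (2 * nc))
    au <- if (u == 0) sqrt(1 / nr) else sqrt(2 / nr)
    av <- if (v == 0) sqrt(1 / nc) else sqrt(2 / nc)
    co[u + 1, v + 1] <- au * av * s
  }
  e <- co^2
  lo <- sum(e[seq_len(ceiling(nr / 2)), seq_len(ceiling(nc / 2))])
  r_hf <- if (sum(e) == 0) 0 else 1 - lo / sum(e)
  # local contrast variance
  vals <- c()
  for (i in seq(1, nr - window + 1, by = stride))
    for (j in seq(1, nc - window + 1, by = stride)) {
      w <- g[i:(i + window - 1), j:(j + window - 1)]
      vals <- c(vals, sqrt(mean((w - mean(w))^2)))
    }
  sigma_lc <- if (length(vals)) mean((vals - mean(vals))^2) else 0
  # Laplacian variance with replicate borders, by loop
  L <- matrix(0, nr, nc)
  at <- function(i, j) g[min(max(i, 1), nr), min(max(j, 1), nc)]
  for (i in 1:nr) for (j in 1:nc)
    L[i, j] <- at(i - 1, j) + at(i + 1, j) + at(i, j - 1) + at(i, j + 1) -
      4 * at(i, j)
  v_lap <- mean((L - mean(L))^2)
  c_temp <- if (is.null(prev)) 1 else stats::cor(as.vector(g), as.vector(prev))
  c(r_hf = r_hf, sigma_lc = sigma_lc, v_lap = v_lap, delta_rgb = 0,
    c_temp = c_temp)
}
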