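#' Discretize a floor plan into coverage cells
#'
#' Lays a regular square grid over the domain polygon and keeps the cells
#' whose centers fall inside the domain and outside every occluder polygon;
#' coverage is then decided per cell at its center.
#'
#' @param domain Polygon (n x 2 matrix, meters) bounding the floor plan.
#' @param cell_size Cell edge length in meters.
#' @param obstacles Optional list of occluder polygons (n x 2 matrices),
#'   e.g. columns or partition walls; sightlines ending or passing inside
#'   them are blocked.
#' @return An object of class `coverage_grid` with fields `centers`
#'   (N x 2), `cell_size`, `obstacles`, `domain`.
#' @export
coverage_grid <- function(domain, cell_size, obstacles = list()) {
  domain <- as.matrix(domain)
  stopifnot(ncol(domain) == 2, cell_size > 0)
  xs <- seq(min(domain[, 1]) + cell_size / 2, max(domain[, 1]), by = cell_size)
  ys <- seq(min(domain[, 2]) + cell_size / 2, max(domain[, 2]), by = cell_size)
  centers <- as.matrix(expand.grid(x = xs, y = ys))
  keep <- vapply(seq_len(nrow(centers)), function(i) {
    p <- centers[i, ]
    if (!point_in_polygon(p[1], p[2], domain)) return(FALSE)
    for (ob in obstacles)
      if (point_in_polygon(p[1], p[2], ob)) return(FALSE)
    TRUE
  }, logical(1))
  centers <- centers[keep, , drop = FALSE]
  if (!nrow(centers)) stop("empty coverage grid: no cell center inside domain")
  structure(list(centers = unname(centers), cell_size = cell_size,
                 obstacles = obstacles, domain = domain),
            class = "coverage_grid")
}

#' Define a candidate camera pose
#'
#' A 2-D plan-view camera: position, heading, symmetric angular field of
#' view and maximum observation radius. Mounting height is folded into the
#' effective radius. The field of view is constrained to 90-120 degrees,
#' the feasible range for the surveillance optics considered.
#'
#' @param cam_id Integer id (used for deterministic tie-breaking).
#' @param position Length-2 (x, y) in meters.
#' @param heading Viewing direction in degrees (0 = +x, counterclockwise).
#' @param fov Angular field of view in degrees, in \[90, 120\].
#' @param radius Maximum observation radius in meters.
#' @return An object of class `camera_candidate`.
#' @export
camera_candidate <- function(cam_id, position, heading, fov = 100,
                             radius = 10) {
  stopifnot(fov >= 90, fov <= 120, radius > 0, length(position) == 2)
  structure(list(cam_id = as.integer(cam_id),
                 position = as.numeric(position),
                 heading = as.numeric(heading) %% 360,
                 fov = as.numeric(fov), radius = as.numeric(radius)),
            class = "camera_candidate")
}

# proper segment-segment intersection (shared endpoints / collinear overlap
# count as intersecting, so grazing an obstacle edge blocks the sightline)
.segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c)
    abs(d(a, b, c)) < 1e-12 &&
      min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  on_seg(q1, q2, p1) || on_seg(q1, q2, p2) ||
    on_seg(p1, p2, q1) || on_seg(p1, p2, q2)
}

.sightline_blocked <- function(from, to, obstacles) {
  for (ob in obstacles) {
    n <- nrow(ob)
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n))
      if (.segments_intersect(from, to, ob[j[k], ], ob[k, ])) return(TRUE)
  }
  FALSE
}

#' Cells visible to a camera
#'
#' A cell is visible when its center lies within the camera's radius
#' (closed), within the angular wedge of half the field of view about the
#' heading (closed), and the sightline from camera to center crosses no
#' obstacle edge.
#'
#' @param cam A [camera_candidate()].
#' @param grid A [coverage_grid()].
#' @return Integer vector of visible cell indices (rows of `grid$centers`).
#' @export
visible_cells <- function(cam, grid) {
  stopifnot(inherits(cam, "camera_candidate"), inherits(grid, "coverage_grid"))
  ctr <- grid$centers
  dx <- ctr[, 1] - cam$position[1]
  dy <- ctr[, 2] - cam$position[2]
  dist <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) * 180 / pi
  dang <- abs(((ang - cam$heading + 180) %% 360) - 180)
  cand <- which(dist <= cam$radius & (dang <= cam$fov / 2 | dist == 0))
  if (!length(grid$obstacles)) return(cand)
  keep <- vapply(cand, function(i)
    !.sightline_blocked(cam$position, ctr[i, ], grid$obstacles), logical(1))
  cand[keep]
}

# visibility matrix: cells x candidates (logical)
.vis_matrix <- function(candidates, grid) {
  N <- nrow(grid$centers)
  V <- matrix(FALSE, N, length(candidates))
  for (j in seq_along(candidates))
    V[visible_cells(candidates[[j]], grid), j] <- TRUE
  V
}

#' Covered Area Percentage
#'
#' Percent of grid cells seen by at least `r` of the selected cameras
#' (redundancy requirement r); exact rational arithmetic on cell counts.
#'
#' @param selection List of selected [camera_candidate()] objects.
#' @param grid A [coverage_grid()].
#' @param r Required redundancy level (>= 1).
#' @return CAP in percent.
#' @export
cap <- function(selection, grid, r = 1L) {
  stopifnot(r >= 1)
  N <- nrow(grid$centers)
  if (N == 0) stop("empty coverage grid")
  if (!length(selection)) return(0)
  V <- .vis_matrix(selection, grid)
  100 * sum(rowSums(V) >= r) / N
}

#' Uncovered Area Percentage
#'
#' The complement of coverage: UAP = 100 - CAP.
#'
#' @param cap_value CAP in percent, within \[0, 100\].
#' @return UAP in percent.
#' @export
uap <- function(cap_value) {
  if (!is.finite(cap_value) || cap_value < 0 || cap_value > 100)
    stop("CAP must lie in [0, 100]")
  100 - cap_value
}

.coverage_report <- function(selection, candidates, grid, r) {
  V <- if (length(selection)) .vis_matrix(candidates[selection], grid)
       else matrix(FALSE, nrow(grid$centers), 0)
  counts <- if (ncol(V)) rowSums(V) else rep(0L, nrow(grid$centers))
  cap_v <- 100 * sum(counts >= r) / nrow(grid$centers)
  structure(list(selection = vapply(candidates[selection], `[[`,
                                    integer(1), "cam_id"),
                 cap = cap_v, uap = 100 - cap_v, r = as.integer(r),
                 cell_counts = counts, grid = grid,
                 cameras = candidates[selection]),
            class = "coverage_plan")
}

#' Greedy camera-layout planner
#'
#' Iteratively selects the candidate giving the largest marginal increase in
#' the number of cells covered by at least `r` cameras, breaking ties by
#' lowest camera id, and stops at the budget or at zero marginal gain. For
#' r = 1 the objective is submodular, so the greedy CAP is within a factor
#' (1 - 1/e) of the optimal achievable with the same budget.
#'
#' @param candidates List of [camera_candidate()] objects.
#' @param grid A [coverage_grid()].
#' @param r Required redundancy (default 1).
#' @param budget Maximum number of cameras to select.
#' @return An object of class `coverage_plan`: selected ids, CAP/UAP,
#'   per-cell coverage counts.
#' @export
greedy_plan <- function(candidates, grid, r = 1L, budget = length(candidates)) {
  stopifnot(budget >= 1, length(candidates) > 0)
  V <- .vis_matrix(candidates, grid)
  ids <- vapply(candidates, `[[`, integer(1), "cam_id")
  chosen <- integer(0)
  counts <- rep(0L, nrow(grid$centers))
  covered <- function(cn) sum(cn >= r)
  while (length(chosen) < budget) {
    rest <- setdiff(seq_along(candidates), chosen)
    if (!length(rest)) break
    gain <- vapply(rest, function(j) covered(counts + V[, j]) - covered(counts),
                   numeric(1))
    best <- max(gain)
    if (best <= 0) break
    tied <- rest[gain == best]
    pick <- tied[which.min(ids[tied])]
    chosen <- c(chosen, pick)
    counts <- counts + V[, pick]
  }
  .coverage_report(chosen, candidates, grid, r)
}

#' Exhaustive camera-layout planner
#'
#' Enumerates every candidate subset of size up to `budget` (guarded at
#' 2^20 subsets), evaluating CAP for each, and returns the globally optimal
#' selection; ties are broken by fewer cameras, then lexicographically by
#' camera ids. Intended as the small-instance optimality oracle for
#' [greedy_plan()].
#'
#' @inheritParams greedy_plan
#' @return An object of class `coverage_plan`.
#' @export
exhaustive_plan <- function(candidates, grid, r = 1L,
                            budget = length(candidates)) {
  stopifnot(budget >= 1, length(candidates) > 0)
  nc <- length(candidates)
  budget <- min(budget, nc)
  n_subsets <- sum(choose(nc, 0:budget))
  if (n_subsets > 2^20)
    stop("instance too large for exhaustive search (", n_subsets,
         " subsets); use greedy_plan")
  V <- .vis_matrix(candidates, grid)
  ids <- vapply(candidates, `[[`, integer(1), "cam_id")
  best_sel <- integer(0); best_cap <- -1
  for (k in 0:budget) {
    sets <- utils::combn(nc, k, simplify = FALSE)
    for (s in sets) {
      counts <- if (k) rowSums(V[, s, drop = FALSE]) else
        rep(0L, nrow(grid$centers))
      cv <- 100 * sum(counts >= r) / nrow(grid$centers)
      better <- cv > best_cap + 1e-12 ||
        (abs(cv - best_cap) <= 1e-12 && length(s) < length(best_sel)) ||
        (abs(cv - best_cap) <= 1e-12 && length(s) == length(best_sel) &&
           length(s) > 0 &&
           .lex_less(sort(ids[s]), sort(ids[best_sel])))
      if (better) { best_sel <- s; best_cap <- cv }
    }
  }
  .coverage_report(best_sel, candidates, grid, r)
}

.lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' @export
print.coverage_plan <- function(x, ...) {
  cat(sprintf("coverage_plan: %d camera(s) [%s], r = %d, CAP = %.2f%%, UAP = %.2f%%\n",
              length(x$selection), paste(x$selection, collapse = ", "),
              x$r, x$cap, x$uap))
  invisible(x)
}

#' @export
plot.coverage_plan <- function(x, main = "Camera coverage", ...) {
  grid <- x$grid
  plot(NA, xlim = range(grid$domain[, 1]), ylim = range(grid$domain[, 2]),
       asp = 1, xlab = "x (m)", ylab = "y (m)", main = main, ...)
  graphics::polygon(grid$domain[, 1], grid$domain[, 2], border = "black")
  cols <- grDevices::hcl.colors(max(x$cell_counts) + 1, "YlGnBu", rev = TRUE)
  graphics::points(grid$centers[, 1], grid$centers[, 2], pch = 15,
                   col = cols[x$cell_counts + 1], cex = 1.2)
  for (ob in grid$obstacles)
    graphics::polygon(ob[, 1], ob[, 2], col = "grey40", border = NA)
  for (cam in x$cameras) {
    graphics::points(cam$position[1], cam$position[2], pch = 17,
                     col = "red", cex = 1.4)
    a <- (cam$heading + c(-1, 1) * cam$fov / 2) * pi / 180
    for (aa in a)
      graphics::segments(cam$position[1], cam$position[2],
                         cam$position[1] + cam$radius * cos(aa),
                         cam$position[2] + cam$radius * sin(aa),
                         col = "red", lty = 2)
  }
  invisible(x)
}

#' Read a floor-plan instance from JSON
#'
#' Expects fields `domain` (vertex list), `cell_size`, optional `obstacles`
#' (list of vertex lists) and `candidates` (list of objects with `cam_id`,
#' `position`, `heading`, `fov`, `radius`).
#'
#' @param path JSON file path.
#' @return List with `grid` ([coverage_grid()]) and `candidates`.
#' @export
read_floorplan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  mat <- function(v) do.call(rbind, lapply(v, function(p) as.numeric(unlist(p))))
  grid <- coverage_grid(mat(raw$domain), as.numeric(raw$cell_size),
                        lapply(raw$obstacles, mat))
  cands <- lapply(raw$candidates, function(cc)
    camera_candidate(cc$cam_id, as.numeric(unlist(cc$position)),
                     cc$heading, cc$fov, cc$radius))
  list(grid = grid, candidates = cands)
}
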