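#' Define a spatial analysis unit (zone)
#'
#' A zone is a non-self-intersecting polygon in floor-plan coordinates
#' (meters) with a representative display point used when mapping Fatigue
#' Indices onto the plan.
#'
#' @param zone_id Unique integer id.
#' @param polygon n x 2 numeric matrix of vertices (closed implicitly).
#' @param rep_point Representative (x, y); defaults to the vertex centroid.
#' @return An object of class `zone`.
#' @export
zone <- function(zone_id, polygon, rep_point = NULL) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3)
  if (is.null(rep_point)) rep_point <- colMeans(polygon)
  structure(list(zone_id = as.integer(zone_id),
                 polygon = unname(polygon),
                 rep_point = as.numeric(rep_point)),
            class = "zone")
}

#' Read zone definitions from JSON
#'
#' Expects a JSON array of objects with fields `zone_id`, `polygon`
#' (array of \[x, y\] vertex pairs) and optional `rep_point`.
#'
#' @param path JSON file path.
#' @return List of [zone()] objects.
#' @export
read_zones <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  zs <- lapply(raw, function(z) {
    poly <- do.call(rbind, lapply(z$polygon, function(v) as.numeric(unlist(v))))
    rp <- if (!is.null(z$rep_point)) as.numeric(unlist(z$rep_point)) else NULL
    zone(z$zone_id, poly, rp)
  })
  ids <- vapply(zs, function(z) z$zone_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate zone ids in ", path)
  zs
}

#' Write zone definitions to JSON
#' @param zones List of [zone()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zones <- function(zones, path) {
  out <- lapply(zones, function(z)
    list(zone_id = z$zone_id,
         polygon = lapply(seq_len(nrow(z$polygon)),
                          function(i) as.numeric(z$polygon[i, ])),
         rep_point = z$rep_point))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# even-odd (crossing number) point-in-polygon; points on an edge or vertex
# count as inside so zone boundaries are owned by the zone
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  # on-edge check
  for (k in seq_len(n)) {
    x1 <- xs[j[k]]; y1 <- ys[j[k]]; x2 <- xs[k]; y2 <- ys[k]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) < 1e-12 &&
        px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
        py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12)
      return(TRUE)
  }
  inside <- FALSE
  for (k in seq_len(n)) {
    x1 <- xs[j[k]]; y1 <- ys[j[k]]; x2 <- xs[k]; y2 <- ys[k]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

#' Assign a point to a zone
#'
#' Returns the id of the zone whose boundary contains the point (boundary
#' inclusive); `NA` when the point lies outside all zones. If zones overlap
#' at the point, the lowest zone id wins and a warning is issued.
#'
#' @param point Length-2 numeric (x, y) in floor-plan coordinates.
#' @param zones Nonempty list of [zone()] objects.
#' @return Integer zone id or `NA_integer_`.
#' @export
assign_zone <- function(point, zones) {
  stopifnot(length(zones) > 0)
  hits <- integer(0)
  for (z in zones)
    if (point_in_polygon(point[1], point[2], z$polygon))
      hits <- c(hits, z$zone_id)
  if (!length(hits)) return(NA_integer_)
  if (length(hits) > 1)
    warning("point lies in overlapping zones; assigning lowest id")
  min(hits)
}

#' Attach per-frame zone ids to a track
#'
#' @param track A `pose_track`.
#' @param positions n x 2 matrix of per-frame floor-plan positions (already
#'   projected from image coordinates, e.g. via [apply_homography()]).
#' @param zones List of [zone()] objects.
#' @return The track with `zone_ids` filled (NA where outside all zones).
#' @export
assign_track_zones <- function(track, positions, zones) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == n_frames(track), ncol(positions) == 2)
  track$zone_ids <- vapply(seq_len(nrow(positions)), function(i)
    assign_zone(positions[i, ], zones), integer(1))
  track
}

#' Apply a planar homography to 2-D points
#'
#' Maps camera-image coordinates to floor-plan coordinates through a 3 x 3
#' homography matrix (the projection step between camera view and plan,
#' supplied per camera by the user).
#'
#' @param H 3 x 3 homography matrix.
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  pts <- as.matrix(pts)
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

#' Classify a Fatigue Index into a band
#'
#' Equal-interval three-band scheme on \[0, 1\]: low for FI <= 1/3, medium
#' for 1/3 < FI <= 2/3, high above 2/3 (the continuous closure of the
#' published 0.00-0.33 / 0.34-0.66 / 0.67-1.00 bands at two-decimal
#' resolution).
#'
#' @param fi Numeric vector of Fatigue Index values in \[0, 1\].
#' @return Character vector `"low"`, `"medium"` or `"high"`.
#' @export
classify_fi <- function(fi) {
  if (any(!is.finite(fi) | fi < 0 | fi > 1))
    stop("Fatigue Index must lie in [0, 1]")
  ifelse(fi <= 1 / 3, "low", ifelse(fi <= 2 / 3, "medium", "high"))
}

#' Zone-level Fatigue Index
#'
#' For one zone: Nt counts the unique visitors with at least one frame
#' assigned to the zone; each such visitor's keypoint stream is restricted
#' to the frames spent inside the zone and the full fatigue chain
#' (classification, multi-frame confirmation, scoring) is re-run on that
#' subsequence, so posture runs split by a zone change must re-confirm
#' within the zone and fatigue does not carry over between zones. Nf counts
#' visitors flagged fatigued in-zone; FI = Nf / Nt. An unvisited zone
#' reports FI 0 with `empty = TRUE`.
#'
#' @param tracks List of `pose_track` objects with `zone_ids` attached.
#' @param zone A [zone()] (or bare integer zone id).
#' @inheritParams detect_fatigue
#' @return One-row data.frame: zone_id, n_total, n_fatigued, fi, band, empty.
#' @export
zone_fatigue_index <- function(tracks, zone,
                               posture_par = posture_params(),
                               rule = validity_rule(),
                               fatigue_par = fatigue_params()) {
  zid <- if (inherits(zone, "zone")) zone$zone_id else as.integer(zone)
  nt <- 0L; nf <- 0L
  seen <- character(0)
  for (tr in tracks) {
    if (is.null(tr$zone_ids)) stop("track '", tr$visitor_id,
                                   "' has no zone assignment")
    inz <- !is.na(tr$zone_ids) & tr$zone_ids == zid
    if (!any(inz) || tr$visitor_id %in% seen) next
    seen <- c(seen, tr$visitor_id)
    nt <- nt + 1L
    sub <- subset_track(tr, inz)
    res <- detect_fatigue(sub, posture_par, rule, fatigue_par)
    if (res$flag) nf <- nf + 1L
  }
  data.frame(zone_id = zid, n_total = nt, n_fatigued = nf,
             fi = if (nt > 0) nf / nt else 0,
             band = classify_fi(if (nt > 0) nf / nt else 0),
             empty = nt == 0L)
}

#' Fatigue Indices for all zones
#'
#' Applies [zone_fatigue_index()] over a zone list and returns the combined
#' table as a classed object with print and plot methods.
#'
#' @param tracks List of zoned `pose_track` objects.
#' @param zones List of [zone()] objects.
#' @inheritParams detect_fatigue
#' @return A `zone_fi` data.frame (one row per zone) carrying the zone
#'   geometry as an attribute.
#' @export
zone_fi <- function(tracks, zones,
                    posture_par = posture_params(),
                    rule = validity_rule(),
                    fatigue_par = fatigue_params()) {
  out <- do.call(rbind, lapply(zones, function(z)
    zone_fatigue_index(tracks, z, posture_par, rule, fatigue_par)))
  rownames(out) <- NULL
  attr(out, "zones") <- zones
  class(out) <- c("zone_fi", "data.frame")
  out
}

#' @export
print.zone_fi <- function(x, ...) {
  nz <- sum(!x$empty)
  cat(sprintf("zone_fi: %d zones (%d visited), mean FI %.4f\n",
              nrow(x), nz, mean(x$fi[!x$empty])))
  print.data.frame(x, digits = 4)
  invisible(x)
}

.band_palette <- c(low = "#2c9e4b", medium = "#e8a838", high = "#d7301f")

#' @export
plot.zone_fi <- function(x, main = "Zone Fatigue Index", ...) {
  zones <- attr(x, "zones")
  if (is.null(zones)) stop("no zone geometry attached")
  allv <- do.call(rbind, lapply(zones, `[[`, "polygon"))
  plot(NA, xlim = range(allv[, 1]), ylim = range(allv[, 2]),
       asp = 1, xlab = "x (m)", ylab = "y (m)", main = main, ...)
  for (z in zones) {
    row <- x[x$zone_id == z$zone_id, ]
    col <- if (nrow(row) && !row$empty) .band_palette[[row$band]] else "grey85"
    graphics::polygon(z$polygon[, 1], z$polygon[, 2], col = col,
                      border = "grey30")
    if (nrow(row))
      graphics::text(z$rep_point[1], z$rep_point[2],
                     sprintf("%d\n%.2f", z$zone_id, row$fi), cex = 0.6)
  }
  graphics::legend("topright", legend = names(.band_palette),
                   fill = .band_palette, bty = "n", cex = 0.8)
  invisible(x)
}

#' Export a zone Fatigue Index table and heatmap
#'
#' Writes (a) a CSV with one row per zone (zone_id, representative point,
#' Nt, Nf, FI at full precision, band) and (b) a PNG heatmap coloring each
#' zone polygon by its band.
#'
#' @param stats A [zone_fi()] table.
#' @param zones List of [zone()] objects (defaults to the geometry attached
#'   to `stats`).
#' @param csv_path,png_path Output paths; pass `NULL` to skip either.
#' @return Named character vector of the files written, invisibly.
#' @export
export_heatmap <- function(stats, zones = attr(stats, "zones"),
                           csv_path = "zone_fi.csv",
                           png_path = "zone_fi.png") {
  written <- character(0)
  if (!is.null(csv_path)) {
    rp <- do.call(rbind, lapply(zones, function(z) {
      i <- which(stats$zone_id == z$zone_id)
      c(z$rep_point[1], z$rep_point[2])
    }))
    ord <- match(stats$zone_id, vapply(zones, `[[`, integer(1), "zone_id"))
    df <- data.frame(zone_id = stats$zone_id,
                     rep_x = rp[ord, 1], rep_y = rp[ord, 2],
                     n_total = stats$n_total, n_fatigued = stats$n_fatigued,
                     fi = sprintf("%.17g", stats$fi), band = stats$band)
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
    written["csv"] <- csv_path
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(stats)
    written["png"] <- png_path
  }
  invisible(written)
}

#' Compare two analysis runs zone by zone
#'
#' Pairs pre- and post-intervention zone tables and computes per-zone
#' decreases in percentage points (100 * (FI_pre - FI_post)) plus
#' museum-wide means over visited zones. Positive decreases mean the
#' intervention lowered fatigue.
#'
#' @param pre,post `zone_fi` tables (or plain data.frames with `zone_id`,
#'   `fi`, `n_total`) covering the same zone ids.
#' @return An object of class `fi_comparison`: per-zone table plus fields
#'   `mean_fi_pre`, `mean_fi_post`, `mean_decrease_abs` (absolute FI units)
#'   and `mean_decrease_pp` (percentage points).
#' @export
compare_runs <- function(pre, post) {
  if (!setequal(pre$zone_id, post$zone_id))
    stop("pre and post runs cover different zone ids")
  post <- post[match(pre$zone_id, post$zone_id), ]
  per_zone <- data.frame(zone_id = pre$zone_id,
                         fi_pre = pre$fi, fi_post = post$fi,
                         decrease_pp = 100 * (pre$fi - post$fi))
  vis_pre <- if ("n_total" %in% names(pre)) pre$n_total > 0 else TRUE
  vis_post <- if ("n_total" %in% names(post)) post$n_total > 0 else TRUE
  mp <- mean(pre$fi[vis_pre]); mq <- mean(post$fi[vis_post])
  structure(list(per_zone = per_zone,
                 mean_fi_pre = mp, mean_fi_post = mq,
                 mean_decrease_abs = mp - mq,
                 mean_decrease_pp = 100 * (mp - mq)),
            class = "fi_comparison")
}

#' @export
print.fi_comparison <- function(x, ...) {
  cat(sprintf("fi_comparison over %d zones: mean FI %.4f -> %.4f (decrease %.4f, %.2f pp)\n",
              nrow(x$per_zone), x$mean_fi_pre, x$mean_fi_post,
              x$mean_decrease_abs, x$mean_decrease_pp))
  invisible(x)
}

#' Relative change between two scalars
#'
#' 100 * (after - before) / before, the convention used for image-metric
#' improvement reporting (e.g. a Tenengrad rise from 2933.89 to 4084.87 is
#' +39.23 percent).
#'
#' @param before,after Scalars; `before` must be nonzero.
#' @return Percent change.
#' @export
relative_change <- function(before, after) {
  if (before == 0) stop("relative change undefined for before = 0")
  100 * (after - before) / before
}

#' Proportion as a percentage
#'
#' @param k Count of successes (0 <= k <= n).
#' @param n Total count (> 0).
#' @return 100 * k / n.
#' @export
proportion <- function(k, n) {
  if (n <= 0) stop("proportion undefined for n = 0")
  stopifnot(k >= 0, k <= n)
  100 * k / n
}
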