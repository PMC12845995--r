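# 3x3 convolution with replicate (edge-clamped) borders; kernel applied as
# correlation, which is what the symmetric Laplacian / Sobel kernels need
conv3 <- function(img, kernel) {
  stopifnot(is.matrix(img), all(dim(kernel) == c(3, 3)))
  nr <- nrow(img); nc <- ncol(img)
  p <- rbind(img[1, , drop = FALSE], img, img[nr, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, nc, drop = FALSE])
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    w <- kernel[di + 1, dj + 1]
    if (w != 0)
      out <- out + w * p[di + seq_len(nr), dj + seq_len(nc)]
  }
  out
}

.lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
# rows = image rows (y), cols = image cols (x)
.sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
.sobel_y <- t(.sobel_x)

.check_img <- function(img, min_dim = 3) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop("image must be at least ", min_dim, "x", min_dim)
  if (any(!is.finite(img))) stop("image intensities must be finite")
}

#' Laplacian variance sharpness measure
#'
#' Population variance (1/N) of the 4-neighbor Laplacian response over the
#' whole image, with replicate borders. Higher values indicate richer
#' high-frequency content and sharper edges; a constant image scores 0.
#'
#' @param img Numeric intensity matrix (any scale), at least 3x3.
#' @return Nonnegative scalar.
#' @export
laplacian_variance <- function(img) {
  .check_img(img)
  L <- conv3(img, .lap_kernel)
  mean((L - mean(L))^2)
}

#' Mean Sobel edge-gradient magnitude
#'
#' Mean over all pixels of sqrt(Gx^2 + Gy^2) with the standard 3x3 Sobel
#' pair and replicate borders. Higher values indicate stronger average edge
#' gradients (less blur).
#'
#' @inheritParams laplacian_variance
#' @return Nonnegative scalar.
#' @export
edge_gradient_mean <- function(img) {
  .check_img(img)
  gx <- conv3(img, .sobel_x)
  gy <- conv3(img, .sobel_y)
  mean(sqrt(gx^2 + gy^2))
}

#' Tenengrad focus measure
#'
#' Mean squared Sobel gradient magnitude, mean(Gx^2 + Gy^2): the gradient
#' energy per pixel. Quadratically homogeneous in image contrast.
#'
#' @inheritParams laplacian_variance
#' @return Nonnegative scalar.
#' @export
tenengrad <- function(img) {
  .check_img(img)
  gx <- conv3(img, .sobel_x)
  gy <- conv3(img, .sobel_y)
  mean(gx^2 + gy^2)
}

#' RMS contrast
#'
#' Root of the population variance of intensities: the root-mean-square
#' deviation from the mean intensity. Invariant to constant offsets.
#'
#' @param img Numeric intensity matrix (nonempty).
#' @return Nonnegative scalar.
#' @export
rms_contrast <- function(img) {
  stopifnot(is.matrix(img) || is.numeric(img), length(img) > 0)
  sqrt(mean((img - mean(img))^2))
}

#' Color-cast index over a region of interest
#'
#' Computes the three channel means inside the ROI and their spread
#' D = max(R, G, B) - min(R, G, B) on the 8-bit 0-255 scale. For a region
#' expected to be neutral white (e.g. a display screen), D near 0 indicates
#' balanced channels; large D indicates a color cast.
#'
#' @param img H x W x 3 numeric array, 8-bit convention (0-255).
#' @param roi Optional ROI as `c(row, col, height, width)` (1-based);
#'   default whole image.
#' @return List with `D` and `means` (named R, G, B).
#' @export
color_cast_index <- function(img, roi = NULL) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4)
    if (roi[3] < 1 || roi[4] < 1) stop("empty ROI")
    r <- roi[1]:(roi[1] + roi[3] - 1)
    c <- roi[2]:(roi[2] + roi[4] - 1)
    if (max(r) > dim(img)[1] || max(c) > dim(img)[2] ||
        min(r) < 1 || min(c) < 1)
      stop("ROI exceeds image bounds")
    img <- img[r, c, , drop = FALSE]
  }
  means <- c(R = mean(img[, , 1]), G = mean(img[, , 2]), B = mean(img[, , 3]))
  list(D = max(means) - min(means), means = means)
}

# orthonormal DCT-II basis matrix (n x n)
.dct_mat <- function(n) {
  k <- 0:(n - 1)
  M <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

# 2-D DCT-II of a matrix
dct2 <- function(img) {
  Dr <- .dct_mat(nrow(img)); Dc <- .dct_mat(ncol(img))
  Dr %*% img %*% t(Dc)
}

#' Frame-quality (IAQ) feature extraction
#'
#' Five deterministic per-frame features used by the risk gate:
#' `r_hf`, the fraction of 2-D DCT coefficient energy outside the
#' lowest-frequency quadrant (rows and columns in the lower half);
#' `sigma_lc`, the variance of per-window RMS contrast over a sliding grid
#' (window and stride 16 px by default); `v_lap`, the Laplacian variance;
#' `delta_rgb`, the spread of the global channel means (0 for grayscale
#' input); and `c_temp`, the Pearson correlation with the previous frame
#' (1 when no previous frame is given; if either frame is constant, 1 when
#' the frames are identical and 0 otherwise).
#'
#' @param frame Intensity matrix or H x W x 3 array.
#' @param prev Optional previous frame of the same size.
#' @param window,stride Local-contrast window geometry in pixels.
#' @return An object of class `iaq_features` (named numeric vector of the
#'   five features).
#' @export
iaq_features <- function(frame, prev = NULL, window = 16L, stride = 16L) {
  gray <- function(im) if (length(dim(im)) == 3)
    (im[, , 1] + im[, , 2] + im[, , 3]) / 3 else im
  g <- gray(frame)
  .check_img(g)
  if (!is.null(prev) && !all(dim(gray(prev)) == dim(g)))
    stop("frame and prev have different sizes")

  co <- dct2(g)
  e <- co^2
  lo_r <- seq_len(ceiling(nrow(e) / 2)); lo_c <- seq_len(ceiling(ncol(e) / 2))
  tot <- sum(e)
  r_hf <- if (tot == 0) 0 else 1 - sum(e[lo_r, lo_c]) / tot

  rs <- seq(1, nrow(g) - window + 1, by = stride)
  cs <- seq(1, ncol(g) - window + 1, by = stride)
  if (!length(rs) || !length(cs)) {
    sigma_lc <- 0
  } else {
    vals <- as.vector(outer(rs, cs, Vectorize(function(i, j)
      rms_contrast(g[i:(i + window - 1), j:(j + window - 1)]))))
    sigma_lc <- mean((vals - mean(vals))^2)
  }

  v_lap <- laplacian_variance(g)

  delta_rgb <- if (length(dim(frame)) == 3)
    color_cast_index(frame)$D else 0

  if (is.null(prev)) {
    c_temp <- 1
  } else {
    pg <- gray(prev)
    if (stats::sd(g) == 0 || stats::sd(pg) == 0)
      c_temp <- if (isTRUE(all.equal(as.vector(g), as.vector(pg)))) 1 else 0
    else
      c_temp <- stats::cor(as.vector(g), as.vector(pg))
  }

  structure(c(r_hf = r_hf, sigma_lc = sigma_lc, v_lap = v_lap,
              delta_rgb = delta_rgb, c_temp = c_temp),
            class = "iaq_features")
}

#' IAQ risk gate
#'
#' Z-scores the five frame features against calibration statistics, fuses
#' them linearly with the weight vector, and routes the frame: `"BYPASS"`
#' when the fused risk score is at or above the threshold (high-risk frame,
#' skip the sensitive model), `"ROBUST"` otherwise. The calibration means
#' and standard deviations must be supplied or fitted on a calibration clip
#' with [fit_iaq_stats()]; there are no hidden defaults.
#'
#' @param feats An [iaq_features()] vector.
#' @param stats List with numeric vectors `mean` and `sd` (5 each,
#'   matching the feature order); all sds must be nonzero.
#' @param w Fusion weight vector (length 5).
#' @param tau Risk threshold.
#' @return List with `decision` (`"ROBUST"` or `"BYPASS"`) and `score`.
#' @export
iaq_gate <- function(feats, stats, w, tau) {
  stopifnot(length(feats) == 5, length(w) == 5,
            length(stats$mean) == 5, length(stats$sd) == 5)
  if (any(stats$sd == 0)) stop("calibration sd of zero: cannot z-score")
  z <- (as.numeric(feats) - as.numeric(stats$mean)) / as.numeric(stats$sd)
  s <- sum(z * as.numeric(w))
  list(decision = if (s >= tau) "BYPASS" else "ROBUST", score = s)
}

#' Fit IAQ calibration statistics on a clip
#'
#' @param frames List of frames (matrices or H x W x 3 arrays) from a
#'   calibration clip; consecutive frames supply the temporal feature.
#' @param ... Passed to [iaq_features()].
#' @return List with `mean` and `sd` over the per-frame feature vectors.
#' @export
fit_iaq_stats <- function(frames, ...) {
  stopifnot(length(frames) >= 2)
  F <- t(vapply(seq_along(frames), function(i)
    as.numeric(iaq_features(frames[[i]],
                            if (i > 1) frames[[i - 1]] else NULL, ...)),
    numeric(5)))
  list(mean = colMeans(F), sd = apply(F, 2, stats::sd))
}

#' External-enhancer interface
#'
#' The deblurring / illumination-enhancement networks are external,
#' pluggable components: an enhancer is described by a shell command
#' template with `{input}` and `{output}` placeholders, invoked per frame.
#'
#' @param command Command template, e.g.
#'   `"my_enhancer --in {input} --out {output}"`.
#' @return A function `(input, output)` running the command and returning
#'   the output path.
#' @export
make_enhancer <- function(command) {
  stopifnot(grepl("{input}", command, fixed = TRUE),
            grepl("{output}", command, fixed = TRUE))
  function(input, output) {
    cmd <- gsub("{input}", shQuote(input), command, fixed = TRUE)
    cmd <- gsub("{output}", shQuote(output), cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0) stop("enhancer command failed (exit ", status, ")")
    output
  }
}

#' Gate and route a frame sequence
#'
#' Applies [iaq_gate()] to each frame (using its predecessor for the
#' temporal feature) and partitions the sequence: every frame is routed
#' exactly once, to the enhanced path when the gate says ROBUST and to the
#' fallback path on BYPASS.
#'
#' @param frames List of frames.
#' @inheritParams iaq_gate
#' @return data.frame with columns `frame`, `score`, `decision`.
#' @export
iaq_route <- function(frames, stats, w, tau) {
  rows <- lapply(seq_along(frames), function(i) {
    f <- iaq_features(frames[[i]], if (i > 1) frames[[i - 1]] else NULL)
    g <- iaq_gate(f, stats, w, tau)
    data.frame(frame = i, score = g$score, decision = g$decision)
  })
  do.call(rbind, rows)
}

#' Read an image file as intensity matrix or RGB array
#'
#' Reads PNG rasters; grayscale files come back as a matrix, color files as
#' an H x W x 3 array. Values are rescaled from the 0-1 PNG convention to
#' 0-255.
#'
#' @param path PNG file path.
#' @return Matrix or 3-d array on the 0-255 scale.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , seq_len(min(3, dim(a)[3])), drop = FALSE]
  if (length(dim(a)) == 3 && dim(a)[3] == 1) a <- a[, , 1]
  a * 255
}

#' Frame-quality metric table for a set of images
#'
#' One row per image: Laplacian variance, mean edge gradient, Tenengrad,
#' RMS contrast, and (for color input) channel means and color-cast D over
#' the ROI.
#'
#' @param paths Character vector of PNG paths.
#' @param roi Optional ROI `c(row, col, height, width)` for the color-cast
#'   index.
#' @return data.frame of metrics.
#' @export
qc_metrics <- function(paths, roi = NULL) {
  rows <- lapply(paths, function(p) {
    im <- read_image(p)
    g <- if (length(dim(im)) == 3) (im[, , 1] + im[, , 2] + im[, , 3]) / 3
         else im
    row <- data.frame(image = basename(p),
                      lv = laplacian_variance(g),
                      egm = edge_gradient_mean(g),
                      tg = tenengrad(g),
                      rms = rms_contrast(g),
                      r_mean = NA_real_, g_mean = NA_real_,
                      b_mean = NA_real_, d = NA_real_)
    if (length(dim(im)) == 3) {
      cc <- color_cast_index(im, roi)
      row$r_mean <- cc$means[["R"]]; row$g_mean <- cc$means[["G"]]
      row$b_mean <- cc$means[["B"]]; row$d <- cc$D
    }
    row
  })
  do.call(rbind, rows)
}
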