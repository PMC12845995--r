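#' Fatigue accumulation parameters
#'
#' Weights, confirmation length and normalization constants for per-visitor
#' fatigue scoring. The default weights (squat 0.5, hands-on-hips 0.2,
#' single-leg raise 0.3) follow the compensatory-intensity ordering
#' squat > leg raise > hands-on-hips formalized as a 5:3:2 scheme and
#' normalized to sum to one. A posture accrues credit only after it has
#' persisted `m_confirm` consecutive frames; confirmed durations are
#' weighted, summed and min-max normalized to \[0, 1\], and a visitor is
#' flagged fatigued when the normalized score reaches `gamma_fatigue`.
#'
#' Two normalizations are available. `"fixed"` (default) uses the
#' pilot-calibrated score ceiling `f_max` (20 weighted seconds) against
#' which the decision threshold 0.15 was calibrated. `"window"` instead
#' scales by `max(weights) * t_win`, the largest score attainable inside an
#' observation window of `t_win` seconds.
#'
#' @param weights Named positive weights for `SQUAT`, `AKIMBO`, `LEG_LIFT`.
#' @param m_confirm Consecutive-frame confirmation count (default 5).
#' @param gamma_fatigue Decision threshold on the normalized score
#'   (default 0.15); the comparison is inclusive (>=).
#' @param f_min,f_max Score floor and ceiling in weighted seconds
#'   (defaults 0 and 20) for the fixed normalization.
#' @param norm_mode `"fixed"` or `"window"`.
#' @param t_win Observation-window length in seconds (window mode only).
#' @return An object of class `fatigue_params`.
#' @export
fatigue_params <- function(weights = c(SQUAT = 0.5, AKIMBO = 0.2,
                                       LEG_LIFT = 0.3),
                           m_confirm = 5L,
                           gamma_fatigue = 0.15,
                           f_min = 0, f_max = 20,
                           norm_mode = c("fixed", "window"),
                           t_win = NULL) {
  norm_mode <- match.arg(norm_mode)
  stopifnot(all(c("SQUAT", "AKIMBO", "LEG_LIFT") %in% names(weights)),
            all(weights > 0), m_confirm >= 1,
            gamma_fatigue >= 0, gamma_fatigue <= 1, f_max > f_min)
  if (!is.null(t_win)) stopifnot(t_win > 0)
  structure(list(weights = weights[c("SQUAT", "AKIMBO", "LEG_LIFT")],
                 m_confirm = as.integer(m_confirm),
                 gamma_fatigue = gamma_fatigue,
                 f_min = f_min, f_max = f_max,
                 norm_mode = norm_mode, t_win = t_win),
            class = "fatigue_params")
}

#' Multi-frame posture confirmation
#'
#' Suppresses transient detections: a frame carries a confirmed label only
#' when it sits at position >= m within an unbroken run of that raw label
#' (a NONE or a different label resets the run counter). Hence a run of
#' length L contributes max(0, L - m + 1) confirmed frames, starting at the
#' m-th; runs shorter than m are suppressed entirely.
#'
#' @param labels Character vector of per-frame posture labels.
#' @param m Required consecutive-frame count (>= 1); `m = 1` is the identity.
#' @return Character vector of confirmed labels, same length, with
#'   unconfirmed positions set to `"NONE"`.
#' @export
confirm_states <- function(labels, m = 5L) {
  stopifnot(m >= 1)
  n <- length(labels)
  out <- rep("NONE", n)
  if (n == 0) return(out)
  r <- rle(labels)
  pos <- 1L
  for (k in seq_along(r$lengths)) {
    len <- r$lengths[k]; lab <- r$values[k]
    if (lab != "NONE" && len >= m)
      out[(pos + m - 1L):(pos + len - 1L)] <- lab
    pos <- pos + len
  }
  out
}

#' Accumulate the weighted raw fatigue score
#'
#' Each confirmed frame of posture i contributes dt seconds to that
#' posture's duration f_i; the raw score is F = sum_i w_i * f_i.
#'
#' @param confirmed Confirmed per-frame label vector (from
#'   [confirm_states()]).
#' @param params A [fatigue_params()].
#' @param dt Seconds per frame.
#' @return List with `score_raw` (weighted seconds) and
#'   `confirmed_durations` (named seconds per posture).
#' @export
accumulate_score <- function(confirmed, params = fatigue_params(),
                             dt = 1 / 30) {
  stopifnot(dt > 0)
  postures <- c("SQUAT", "AKIMBO", "LEG_LIFT")
  durs <- vapply(postures, function(p) sum(confirmed == p) * dt, numeric(1))
  list(score_raw = sum(params$weights[postures] * durs),
       confirmed_durations = durs)
}

#' Normalize a raw fatigue score to \[0, 1\]
#'
#' Fixed mode: (F - f_min) / (f_max - f_min), clamped to \[0, 1\]. Window
#' mode: F / (max(weights) * t_win), clamped, i.e. relative to the largest
#' score a visitor could accrue in the observation window.
#'
#' @param F Raw score in weighted seconds.
#' @param params A [fatigue_params()].
#' @return Normalized score in \[0, 1\].
#' @export
normalize_score <- function(F, params = fatigue_params()) {
  if (params$norm_mode == "window") {
    if (is.null(params$t_win))
      stop("window normalization requires t_win")
    s_max <- max(params$weights) * params$t_win
    s <- (F - 0) / s_max
  } else {
    s <- (F - params$f_min) / (params$f_max - params$f_min)
  }
  min(1, max(0, s))
}

#' Per-visitor fatigue detection
#'
#' The full per-visitor chain: per-frame posture classification (priority
#' SQUAT > AKIMBO > LEG_LIFT with validity gating), multi-frame
#' confirmation, weighted accumulation of confirmed durations, min-max
#' normalization, and thresholding of the normalized score. Invalid frames
#' classify as NONE rather than erroring.
#'
#' @param track A `pose_track`.
#' @param posture_par A [posture_params()].
#' @param rule A [validity_rule()].
#' @param fatigue_par A [fatigue_params()].
#' @return An object of class `fatigue_result` with fields `visitor_id`,
#'   `score_raw` (weighted seconds), `score_norm` in \[0, 1\], `flag`
#'   (TRUE iff `score_norm >= gamma_fatigue`), `confirmed_durations`
#'   (seconds per posture), `labels` and `confirmed` per-frame label
#'   vectors, and `n_frames`.
#' @export
detect_fatigue <- function(track,
                           posture_par = posture_params(),
                           rule = validity_rule(),
                           fatigue_par = fatigue_params()) {
  stopifnot(inherits(track, "pose_track"), n_frames(track) > 0)
  labels <- classify_frames(track, posture_par, rule)
  confirmed <- confirm_states(labels, fatigue_par$m_confirm)
  acc <- accumulate_score(confirmed, fatigue_par, track$dt)
  sv <- normalize_score(acc$score_raw, fatigue_par)
  structure(list(visitor_id = track$visitor_id,
                 score_raw = acc$score_raw,
                 score_norm = sv,
                 flag = sv >= fatigue_par$gamma_fatigue,
                 confirmed_durations = acc$confirmed_durations,
                 labels = labels,
                 confirmed = confirmed,
                 n_frames = n_frames(track),
                 params = fatigue_par),
            class = "fatigue_result")
}

#' @export
print.fatigue_result <- function(x, ...) {
  cat(sprintf("fatigue_result '%s': F = %.3f weighted s, Sv = %.4f, %s\n",
              x$visitor_id, x$score_raw, x$score_norm,
              if (x$flag) "FATIGUED" else "not fatigued"))
  d <- x$confirmed_durations
  cat(sprintf("  confirmed: squat %.2f s, akimbo %.2f s, leg raise %.2f s (%d frames)\n",
              d[["SQUAT"]], d[["AKIMBO"]], d[["LEG_LIFT"]], x$n_frames))
  invisible(x)
}

#' @export
summary.fatigue_result <- function(object, ...) {
  out <- data.frame(visitor_id = object$visitor_id,
                    F = object$score_raw,
                    Sv = object$score_norm,
                    fatigued = object$flag,
                    squat_s = object$confirmed_durations[["SQUAT"]],
                    akimbo_s = object$confirmed_durations[["AKIMBO"]],
                    leg_lift_s = object$confirmed_durations[["LEG_LIFT"]],
                    n_frames = object$n_frames,
                    row.names = NULL)
  class(out) <- c("summary.fatigue_result", "data.frame")
  out
}

#' Fatigue results for many visitors as a table
#'
#' Runs [detect_fatigue()] over a list of tracks and binds the one-row
#' summaries; the natural input for zone aggregation or CSV export.
#'
#' @param tracks List of `pose_track` objects.
#' @inheritParams detect_fatigue
#' @return data.frame, one row per visitor (columns as in
#'   [summary.fatigue_result()]).
#' @export
fatigue_table <- function(tracks,
                          posture_par = posture_params(),
                          rule = validity_rule(),
                          fatigue_par = fatigue_params()) {
  rows <- lapply(tracks, function(tr)
    summary(detect_fatigue(tr, posture_par, rule, fatigue_par)))
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}
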