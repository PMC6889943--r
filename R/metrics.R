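#' Zero-phase low-pass Butterworth filtering
#'
#' Forward-backward application of a Butterworth low-pass filter, the
#' standard treatment of kinematic time series before differentiation.
#' The two passes cancel the phase lag (symmetric effective impulse
#' response) and square the magnitude response. Defaults follow the common
#' kinematics setting: 6 Hz cutoff, 6th order.
#'
#' @param x Numeric vector or matrix (columns filtered independently),
#'   uniformly sampled.
#' @param fs Sampling rate, Hz.
#' @param fc Cutoff frequency, Hz; must satisfy `fc < fs/2`.
#' @param order Filter order of a single pass.
#' @return Filtered signal, same shape as `x`.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' x <- sin(2 * pi * 1 * t) + 0.2 * sin(2 * pi * 30 * t)
#' xf <- lowpass_zero_phase(x, fs = 100)
#' @export
lowpass_zero_phase <- function(x, fs, fc = 6, order = 6) {
  stopifnot(fs > 2 * fc, fc > 0, order >= 1)
  one <- function(v) {
    if (sum(is.finite(v)) < 3 * order + 1)
      stop("series too short for zero-phase filtering (need > 3x order)")
    bf <- signal::butter(order, fc / (fs / 2), type = "low")
    ## reflective padding tames the end transients of filtfilt
    npad <- min(length(v) - 1, 3 * order * 10)
    vp <- c(2 * v[1] - rev(v[2:(npad + 1)]), v,
            2 * v[length(v)] - rev(v[(length(v) - npad):(length(v) - 1)]))
    out <- signal::filtfilt(bf, vp)
    out[(npad + 1):(npad + length(v))]
  }
  if (is.matrix(x)) apply(x, 2, one) else one(as.numeric(x))
}

#' Circular target on the board
#'
#' @param cx_mm,cy_mm Centre, board mm.
#' @param r_mm Radius, mm (targets default to 14 cm diameter).
#' @return Object of class `target_circle`.
#' @export
target_circle <- function(cx_mm, cy_mm, r_mm = 70) {
  stopifnot(r_mm > 0)
  structure(list(cx_mm = cx_mm, cy_mm = cy_mm, r_mm = r_mm),
            class = "target_circle")
}

#' Task specification
#'
#' Describes one recorded task: point-to-point transport between two
#' circular targets, or continuous tracing of a figure-eight template made
#' of two tangent circles. Difficulty levels follow the cup designs:
#' 1 = no ball, 2 = 70 mm dish with safety rim, 3 = 70 mm dish rimless,
#' 4 = 140 mm (flatter) dish.
#'
#' @param kind `"point-to-point"` or `"figure-8"`.
#' @param targets List of [target_circle()]s; exactly 2 for
#'   point-to-point.
#' @param go_cues Strictly increasing go-cue times, s.
#' @param level Difficulty level 1-4.
#' @param fig8 For figure-8 tasks, the template from [figure8_template()].
#' @return Object of class `task_spec`.
#' @export
task_spec <- function(kind = c("point-to-point", "figure-8"),
                      targets = list(), go_cues = numeric(), level = 1L,
                      fig8 = NULL) {
  kind <- match.arg(kind)
  stopifnot(level %in% 1:4)
  if (kind == "point-to-point" && length(targets) != 2)
    stop("point-to-point tasks need exactly 2 targets")
  if (length(go_cues) > 1 && any(diff(go_cues) <= 0))
    stop("go cues must be strictly increasing")
  if (kind == "figure-8" && is.null(fig8)) fig8 <- figure8_template()
  structure(list(kind = kind, targets = targets, go_cues = go_cues,
                 level = as.integer(level), fig8 = fig8),
            class = "task_spec")
}

#' Figure-eight template
#'
#' Two circles of equal diameter tangent at one point; the default is the
#' 25 cm diameter pair used in the continuous tracing task, laid out along
#' the x axis and tangent at `centre`.
#'
#' @param centre Tangency point, board mm.
#' @param diameter_mm Circle diameter, mm.
#' @param axis Unit direction along which the two centres lie (default x).
#' @return Object of class `figure8_template` with the two centres and
#'   common radius.
#' @export
figure8_template <- function(centre = c(457, 304.5), diameter_mm = 250,
                             axis = c(1, 0)) {
  stopifnot(diameter_mm > 0)
  axis <- axis / sqrt(sum(axis^2))
  r <- diameter_mm / 2
  structure(list(c1 = centre + r * axis, c2 = centre - r * axis, r_mm = r),
            class = "figure8_template")
}

#' Reach time of one point-to-point trial
#'
#' Time from the go cue until the cup centre first lies inside the target
#' circle (closed disc test). A trial is a success when the cup reaches
#' the target without the ball having escaped beforehand; if the cup never
#' enters the target within the trial window the result is a failure, not
#' an error.
#'
#' @param t Sample times, s.
#' @param cup_xy n x 2 matrix of cup positions, board mm (NA rows allowed;
#'   they can never satisfy the entry test).
#' @param target A [target_circle()].
#' @param go_cue Go-cue time, s.
#' @param t_end End of the trial window (default end of series).
#' @param escape_time Optional time at which the ball escaped (NA if it
#'   did not); entry after escape is counted as a failure.
#' @return List with `reach_time` (s, NA on failure), `success`,
#'   `entry_time` (absolute, NA on failure).
#' @export
reach_time <- function(t, cup_xy, target, go_cue, t_end = max(t),
                       escape_time = NA_real_) {
  stopifnot(inherits(target, "target_circle"), length(t) == nrow(cup_xy))
  idx <- which(t >= go_cue & t <= t_end)
  if (length(idx) == 0)
    stop("series does not cover the trial window")
  d2 <- (cup_xy[idx, 1] - target$cx_mm)^2 + (cup_xy[idx, 2] - target$cy_mm)^2
  inside <- !is.na(d2) & d2 <= target$r_mm^2
  if (!any(inside))
    return(list(reach_time = NA_real_, success = FALSE,
                entry_time = NA_real_))
  entry <- t[idx[which(inside)[1]]]
  ok <- is.na(escape_time) || escape_time > entry
  list(reach_time = entry - go_cue, success = ok, entry_time = entry)
}

#' Distance of samples from a figure-eight template
#'
#' Per-sample Euclidean distance to the nearest point of the union of the
#' two circle outlines, plus the RMS over the trial — the tracking error of
#' the continuous figure-eight task.
#'
#' @param xy n x 2 matrix of positions, board mm.
#' @param template A [figure8_template()].
#' @return List with `distance` (per-sample, mm) and `rms_mm`.
#' @export
figure8_error <- function(xy, template) {
  stopifnot(inherits(template, "figure8_template"))
  xy <- as.matrix(xy)
  d1 <- abs(sqrt((xy[, 1] - template$c1[1])^2 +
                 (xy[, 2] - template$c1[2])^2) - template$r_mm)
  d2 <- abs(sqrt((xy[, 1] - template$c2[1])^2 +
                 (xy[, 2] - template$c2[2])^2) - template$r_mm)
  d <- pmin(d1, d2)
  list(distance = d, rms_mm = sqrt(mean(d^2, na.rm = TRUE)))
}

## Resample a polyline to n points equally spaced in arc length.
.resample_arclength <- function(xy, n) {
  xy <- as.matrix(xy)
  keep <- stats::complete.cases(xy)
  xy <- xy[keep, , drop = FALSE]
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(matrix(xy[1, ], n, 2, byrow = TRUE))
  grid <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, xy[, 1], grid, ties = "ordered")$y,
        stats::approx(s, xy[, 2], grid, ties = "ordered")$y)
}

#' Path variability of repeated point-to-point reaches
#'
#' Dispersion of a set of paths sharing start and end targets. Each path
#' is resampled to `n_stations` points equally spaced in arc length; the
#' variability is the mean over stations of the mean distance of the
#' per-path station points from the station centroid. Identical paths give
#' 0; the measure is invariant to rigid motions applied to all paths.
#'
#' @param paths List of n x 2 matrices (board mm); at least 2.
#' @param n_stations Number of arc-length stations (default 50).
#' @return List with `variability_mm` (scalar) and `per_station_mm`.
#' @export
path_variability <- function(paths, n_stations = 50) {
  if (length(paths) < 2) stop("need at least 2 paths")
  rs <- lapply(paths, .resample_arclength, n = n_stations)
  per_station <- vapply(seq_len(n_stations), function(i) {
    pts <- t(vapply(rs, function(p) p[i, ], numeric(2)))
    ctr <- colMeans(pts)
    mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
  }, numeric(1))
  list(variability_mm = mean(per_station), per_station_mm = per_station)
}

#' Velocity from a filtered position series
#'
#' Central differences after zero-phase low-pass filtering; one-sided
#' differences at the endpoints.
#'
#' @param xy n x 2 position matrix, mm.
#' @param fs Sampling rate, Hz.
#' @param fc,order Filter settings, see [lowpass_zero_phase()].
#' @return n x 2 velocity matrix, mm/s.
#' @export
filtered_velocity <- function(xy, fs, fc = 6, order = 6) {
  xyf <- lowpass_zero_phase(as.matrix(xy), fs, fc, order)
  n <- nrow(xyf)
  v <- matrix(NA_real_, n, 2)
  v[2:(n - 1), ] <- (xyf[3:n, ] - xyf[1:(n - 2), ]) * fs / 2
  v[1, ] <- (xyf[2, ] - xyf[1, ]) * fs
  v[n, ] <- (xyf[n, ] - xyf[n - 1, ]) * fs
  v
}

#' Per-trial metrics of a tracked session
#'
#' Segments a session at the go cues (each trial ends at the next go cue
#' or the series end) and computes reach time, success, path length and,
#' when the ball is tracked and a model is supplied, the minimum angular
#' escape margin. For point-to-point tasks trial directions alternate
#' outward/inward, matching the back-and-forth protocol; the reach target
#' of trial k is `targets[[2 - k %% 2]]` (trial 1 goes to target 2).
#'
#' @param series A `track_series` (see [track_video()]) or a data frame
#'   with columns `t_s`, `cup_x_mm`, `cup_y_mm` (and optionally ball
#'   columns).
#' @param task A [task_spec()].
#' @param params Optional [cupball_params()] for margin estimation from
#'   ball angles inferred by [simulate_kinematic()].
#' @param fs Sampling rate (inferred from timestamps when NULL).
#' @param fc,order Filter settings for velocity computation.
#' @return Data frame with one row per trial: `trial`, `direction`,
#'   `reach_time_s`, `success`, `min_margin_rad`, `path_length_mm`,
#'   `fig8_rms_mm`.
#' @export
session_metrics <- function(series, task, params = NULL, fs = NULL,
                            fc = 6, order = 6) {
  df <- as.data.frame(series)
  stopifnot(all(c("t_s", "cup_x_mm", "cup_y_mm") %in% names(df)))
  tt <- df$t_s
  if (is.null(fs)) fs <- 1 / median(diff(tt))
  cues <- task$go_cues
  if (length(cues) == 0) cues <- tt[1]
  ends <- c(cues[-1], max(tt))

  has_ball <- all(c("ball_x_mm", "ball_y_mm") %in% names(df)) &&
    any(is.finite(df$ball_x_mm))
  rows <- lapply(seq_along(cues), function(k) {
    sel <- tt >= cues[k] & tt <= ends[k]
    xy <- as.matrix(df[sel, c("cup_x_mm", "cup_y_mm")])
    seg <- sqrt(rowSums(diff(xy)^2))
    plen <- sum(seg, na.rm = TRUE)
    min_margin <- NA_real_
    esc_t <- NA_real_
    if (!is.null(params) && task$level >= 2 && sum(sel) >= 5) {
      cup_m <- data.frame(t = tt[sel], x = xy[, 1] / 1000, y = xy[, 2] / 1000)
      ok <- stats::complete.cases(cup_m)
      if (sum(ok) >= 5 && all(ok)) {
        cup_m[, 2:3] <- lowpass_zero_phase(as.matrix(cup_m[, 2:3]),
                                           fs, fc, order)
        sim <- simulate_kinematic(params, cup_m)
        mg <- escape_margin(sim, params)
        min_margin <- mg$min_margin
        if (mg$escaped) esc_t <- attr(sim, "escape_time")
      }
    }
    if (task$kind == "point-to-point") {
      target <- task$targets[[1 + k %% 2]]
      direction <- if (k %% 2 == 1) "outward" else "inward"
      rt <- reach_time(tt, as.matrix(df[, c("cup_x_mm", "cup_y_mm")]),
                       target, cues[k], ends[k], escape_time = esc_t)
      data.frame(trial = k, direction = direction,
                 reach_time_s = rt$reach_time, success = rt$success,
                 min_margin_rad = min_margin, path_length_mm = plen,
                 fig8_rms_mm = NA_real_)
    } else {
      fe <- figure8_error(xy, task$fig8)
      data.frame(trial = k, direction = NA_character_,
                 reach_time_s = NA_real_, success = NA,
                 min_margin_rad = min_margin, path_length_mm = plen,
                 fig8_rms_mm = fe$rms_mm)
    }
  })
  do.call(rbind, rows)
}
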