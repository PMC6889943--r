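#' Resample a trajectory onto a uniform time grid
#'
#' Linear interpolation of each coordinate onto a uniform grid at
#' `target_fs`, spanning the series (or, given `span`, the overlap window
#' of two recordings).
#'
#' @param t Sample times, s (monotone increasing).
#' @param xy n x 2 coordinate matrix.
#' @param target_fs Target sampling rate, Hz.
#' @param span Optional `c(t0, t1)` window; default full range of `t`.
#' @return List with `t` (uniform grid) and `xy`.
#' @export
resample_uniform <- function(t, xy, target_fs, span = range(t)) {
  stopifnot(target_fs > 0, !is.unsorted(t, strictly = TRUE))
  xy <- as.matrix(xy)
  if (span[2] <= span[1]) stop("empty overlap window")
  grid <- seq(span[1], span[2], by = 1 / target_fs)
  out <- cbind(stats::approx(t, xy[, 1], grid, ties = "ordered")$y,
               stats::approx(t, xy[, 2], grid, ties = "ordered")$y)
  list(t = grid, xy = out)
}

#' Time lag between two recordings from their velocity peaks
#'
#' Lag, in samples, between the global speed maxima of two uniformly
#' sampled recordings of the same movement. Positive lag means `b` starts
#' later than `a`. Inputs are expected to be low-pass filtered
#' ([lowpass_zero_phase()]) so that the speed maximum is well defined.
#' With `refine = TRUE` a parabolic interpolation around each peak gives a
#' sub-sample lag; the default matches clocks at sample resolution.
#'
#' @param a,b n x 2 coordinate matrices at a common sampling rate.
#' @param refine Logical, parabolic sub-sample refinement (default off).
#' @return Lag in samples (integer unless `refine`).
#' @export
sync_velocity_peaks <- function(a, b, refine = FALSE) {
  speed <- function(xy) {
    xy <- as.matrix(xy)
    v <- diff(xy)
    sqrt(rowSums(v^2))
  }
  peak <- function(s) {
    if (max(s) - min(s) < 1e-12 * max(abs(s), 1))
      stop("speed has no unique peak (constant-speed or static series)")
    i <- which.max(s)
    if (refine && i > 1 && i < length(s)) {
      denom <- s[i - 1] - 2 * s[i] + s[i + 1]
      if (abs(denom) > 0) i <- i + 0.5 * (s[i - 1] - s[i + 1]) / denom
    }
    i
  }
  pb <- peak(speed(b)); pa <- peak(speed(a))
  if (refine) pb - pa else as.integer(pb - pa)
}

#' Procrustes alignment of two point sets
#'
#' Closed-form least-squares similarity transform (rotation, isotropic
#' scale, translation) minimizing `sum || X - (s R Y + t) ||^2`, solved via
#' the singular value decomposition of the cross-covariance matrix. By
#' default the rotation is constrained to be proper (no reflection).
#'
#' @param x,y n x 2 point matrices, matched row-wise (n >= 2).
#' @param allow_reflection Permit an improper rotation if it fits better.
#' @return List with `rotation` (2x2), `scale`, `translation`,
#'   `y_aligned` (`s R Y + t`), and `residual` (root mean squared point
#'   error after alignment).
#' @export
procrustes_align <- function(x, y, allow_reflection = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 2, ncol(x) == 2, ncol(y) == 2)
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  ssy <- sum(y0^2)
  if (ssy < 1e-24 || sum(x0^2) < 1e-24)
    stop("degenerate input: point set has (near) zero variance")
  a <- crossprod(x0, y0)            # 2x2 cross-covariance (unnormalized)
  sv <- svd(a)
  d <- diag(2)
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) d[2, 2] <- -1
  r <- sv$u %*% d %*% t(sv$v)
  s <- sum(diag(d) * sv$d) / ssy
  t_vec <- cx - s * as.numeric(r %*% cy)
  y_al <- s * y %*% t(r) + matrix(t_vec, nrow(y), 2, byrow = TRUE)
  list(rotation = r, scale = s, translation = t_vec, y_aligned = y_al,
       residual = sqrt(mean(rowSums((x - y_al)^2))))
}

#' Alignment and agreement of two recordings of one movement
#'
#' The trajectory verification pipeline: low-pass filter both recordings,
#' synchronize them by their velocity peaks, restrict to the overlap
#' window, resample to a common uniform grid, reconcile coordinate frames
#' by Procrustes alignment, then report the point error and the 2-D
#' correlation.
#'
#' The error is reported in the units of `a` (mm in this package) as the
#' mean Euclidean point error (`mse_mm`, the convention used for this
#' verification despite the name) together with the RMS variant
#' (`rmse_mm`). `r` is the Pearson correlation of the flattened coordinate
#' arrays (2-D array correlation); per-axis correlations are reported
#' alongside.
#'
#' @param t_a,t_b Sample times of the two recordings, s.
#' @param a,b n x 2 coordinate matrices (reference first).
#' @param fs Common resampling rate, Hz.
#' @param fc,order Filter settings ([lowpass_zero_phase()]).
#' @param filter Logical; set `FALSE` if the inputs are already filtered.
#' @return Object of class `alignment_result`: `lag_samples`, `lag_s`,
#'   `rotation`, `scale`, `translation`, `mse_mm`, `rmse_mm`, `r`,
#'   `r_axis`, `n`.
#' @export
compare_trajectories <- function(t_a, a, t_b, b, fs = 100, fc = 6,
                                 order = 6, filter = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  ## the two devices have independent clocks: re-zero both time axes and
  ## recover the offset from the movement itself
  ra <- resample_uniform(t_a - t_a[1], a, fs)
  rb <- resample_uniform(t_b - t_b[1], b, fs)
  fa <- if (filter) lowpass_zero_phase(ra$xy, fs, fc, order) else ra$xy
  fb <- if (filter) lowpass_zero_phase(rb$xy, fs, fc, order) else rb$xy

  lag <- sync_velocity_peaks(fa, fb)
  ## shift b's clock so the peaks coincide, then use the common window
  tb_shift <- rb$t - lag / fs
  span <- c(max(ra$t[1], tb_shift[1]),
            min(ra$t[length(ra$t)], tb_shift[length(tb_shift)]))
  if (span[2] <= span[1]) stop("no overlap after synchronization")
  ua <- resample_uniform(ra$t, fa, fs, span)
  ub <- resample_uniform(tb_shift, fb, fs, span)
  n <- min(nrow(ua$xy), nrow(ub$xy))
  pa <- ua$xy[seq_len(n), , drop = FALSE]
  pb <- ub$xy[seq_len(n), , drop = FALSE]

  pr <- procrustes_align(pa, pb)
  err <- sqrt(rowSums((pa - pr$y_aligned)^2))
  res <- list(lag_samples = lag, lag_s = lag / fs,
              rotation = pr$rotation, scale = pr$scale,
              translation = pr$translation,
              mse_mm = mean(err), rmse_mm = sqrt(mean(err^2)),
              r = stats::cor(as.numeric(pa), as.numeric(pr$y_aligned)),
              r_axis = c(x = stats::cor(pa[, 1], pr$y_aligned[, 1]),
                         y = stats::cor(pa[, 2], pr$y_aligned[, 2])),
              n = n)
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Trajectory alignment over %d samples\n", x$n))
  cat(sprintf("  lag: %s samples (%.4g s)\n",
              format(x$lag_samples), x$lag_s))
  ang <- atan2(x$rotation[2, 1], x$rotation[1, 1]) * 180 / pi
  cat(sprintf("  similarity: scale %.6g, rotation %.3f deg, translation (%.3g, %.3g) mm\n",
              x$scale, ang, x$translation[1], x$translation[2]))
  cat(sprintf("  mean point error %.4g mm (RMS %.4g mm), R = %.6f\n",
              x$mse_mm, x$rmse_mm, x$r))
  invisible(x)
}
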