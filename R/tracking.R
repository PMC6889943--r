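## Hexcone RGB->HSV for one colour triple in [0,1]; H in degrees.
.rgb1_to_hsv <- function(rgb) {
  v <- max(rgb); mn <- min(rgb); d <- v - mn
  s <- if (v > 0) d / v else 0
  h <- if (d == 0) 0
  else if (v == rgb[1]) 60 * (((rgb[2] - rgb[3]) / d) %% 6)
  else if (v == rgb[2]) 60 * ((rgb[3] - rgb[1]) / d + 2)
  else 60 * ((rgb[1] - rgb[2]) / d + 4)
  c(h = h, s = s, v = v)
}

#' Convert an RGB frame to HSV
#'
#' Standard hexcone conversion, vectorized over the frame. Hue is in
#' degrees `[0, 360)`; saturation and value in `[0, 1]`.
#'
#' @param frame `[H, W, 3]` numeric array in `[0, 1]`.
#' @return `[H, W, 3]` array with channels H, S, V.
#' @examples
#' px <- array(c(1, 0, 0), dim = c(1, 1, 3))  # pure red
#' to_hsv(px)[1, 1, ]                          # H = 0, S = 1, V = 1
#' @export
to_hsv <- function(frame) {
  if (length(dim(frame)) != 3 || dim(frame)[3] != 3)
    stop("expected a [H, W, 3] RGB array")
  nr <- dim(frame)[1]; nc <- dim(frame)[2]
  r <- matrix(frame[, , 1], nr, nc)
  g <- matrix(frame[, , 2], nr, nc)
  b <- matrix(frame[, , 3], nr, nc)
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- v - mn
  s <- d / v
  s[v == 0] <- 0
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  rmax <- nz & (v == r)
  gmax <- nz & !rmax & (v == g)
  bmax <- nz & !rmax & !gmax
  h[rmax] <- 60 * (((g[rmax] - b[rmax]) / d[rmax]) %% 6)
  h[gmax] <- 60 * ((b[gmax] - r[gmax]) / d[gmax] + 2)
  h[bmax] <- 60 * ((r[bmax] - g[bmax]) / d[bmax] + 4)
  out <- array(0, dim = dim(frame))
  out[, , 1] <- h; out[, , 2] <- s; out[, , 3] <- v
  out
}

#' Colour profile for HSV masking
#'
#' HSV bounds identifying one tracked object. Hue is in degrees and the
#' hue interval may wrap through 0 (e.g. `hsv_low[1] = 350`,
#' `hsv_high[1] = 10` selects reds).
#'
#' @param name Label.
#' @param hsv_low,hsv_high Length-3 lower/upper bounds `(H_deg, S, V)`.
#' @param min_area_px Minimum blob area accepted by the detector.
#' @return Object of class `color_profile`.
#' @export
color_profile <- function(name, hsv_low, hsv_high, min_area_px = 25L) {
  stopifnot(length(hsv_low) == 3, length(hsv_high) == 3, min_area_px >= 1)
  if (hsv_low[2] > hsv_high[2] || hsv_low[3] > hsv_high[3])
    stop("S and V bounds must be ordered low <= high")
  structure(list(name = name, hsv_low = as.numeric(hsv_low),
                 hsv_high = as.numeric(hsv_high),
                 min_area_px = as.integer(min_area_px)),
            class = "color_profile")
}

#' Default colour profiles matching the synthetic scene
#'
#' @param scene A [scene_spec()]; hue windows are centred on the scene's
#'   cup and ball colours. For real footage, profiles must be tuned to the
#'   actual objects.
#' @return Named list with `cup` and `ball` [color_profile()]s.
#' @export
default_profiles <- function(scene = scene_spec()) {
  win <- function(name, col, min_area) {
    h <- .rgb1_to_hsv(col)
    color_profile(name, c((h[1] - 18) %% 360, max(0.25, h[2] - 0.35),
                          max(0.15, h[3] - 0.4)),
                  c((h[1] + 18) %% 360, 1, 1), min_area)
  }
  list(cup = win("cup", scene$cup_color, 200L),
       ball = win("ball", scene$ball_color, 25L))
}

#' Apply an HSV colour mask
#'
#' A pixel is on iff all three channels lie inside the profile bounds;
#' the hue interval wraps through 0 when `hsv_low[1] > hsv_high[1]`.
#'
#' @param hsv `[H, W, 3]` HSV array from [to_hsv()].
#' @param profile A [color_profile()].
#' @return Binary (0/1) matrix `[H, W]`.
#' @export
color_mask <- function(hsv, profile) {
  nr <- dim(hsv)[1]; nc <- dim(hsv)[2]
  h <- matrix(hsv[, , 1], nr, nc)
  s <- matrix(hsv[, , 2], nr, nc)
  v <- matrix(hsv[, , 3], nr, nc)
  lo <- profile$hsv_low; hi <- profile$hsv_high
  hue_ok <- if (lo[1] <= hi[1]) h >= lo[1] & h <= hi[1]
            else h >= lo[1] | h <= hi[1]
  (hue_ok & s >= lo[2] & s <= hi[2] & v >= lo[3] & v <= hi[3]) * 1
}

## Count of on-pixels in the k x k box around every pixel (pixels outside
## the image count as 0), via a summed-area table.
.box_count <- function(m, k) {
  half <- (k - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 1, nc + 1)
  p[-1, -1] <- apply(m, 2, cumsum)
  p[-1, -1] <- t(apply(p[-1, -1, drop = FALSE], 1, cumsum))
  r2 <- pmin(seq_len(nr) + half, nr) + 1
  r1 <- pmax(seq_len(nr) - half - 1, 0) + 1
  c2 <- pmin(seq_len(nc) + half, nc) + 1
  c1 <- pmax(seq_len(nc) - half - 1, 0) + 1
  p[r2, c2] - p[r1, c2] - p[r2, c1] + p[r1, c1]
}

#' Morphological cleanup of a binary mask
#'
#' Erosion followed by dilation (opening) with a square structuring
#' element, removing speckle noise smaller than the kernel while
#' preserving the tracked blobs. Default: 5x5 kernel, one iteration each.
#' Implemented as separable running min/max filters; pixels outside the
#' image count as background.
#'
#' @param mask Binary matrix.
#' @param kernel_px Side of the square structuring element (default 5,
#'   odd).
#' @param erode_iter,dilate_iter Iteration counts.
#' @return Cleaned binary matrix.
#' @export
morph_clean <- function(mask, kernel_px = 5, erode_iter = 1,
                        dilate_iter = 1) {
  rng <- range(mask)
  if (!all(rng %in% c(0, 1))) stop("mask must be binary (0/1)")
  stopifnot(kernel_px %% 2 == 1)
  m <- mask * 1
  full <- kernel_px^2
  for (i in seq_len(erode_iter))
    m <- (.box_count(m, kernel_px) == full) * 1
  for (i in seq_len(dilate_iter))
    m <- (.box_count(m, kernel_px) > 0) * 1
  m
}

#' Best circular blob in a mask
#'
#' Labels connected components, keeps those with at least `min_area_px`
#' pixels, and returns the moment-based ellipse fit of the component
#' maximizing a circularity-weighted area score
#' (`area * (minor/major)^2`). Ties go to the larger area, then to the
#' lower fit residual. The quality is the radial fit residual of the blob
#' boundary (sd of boundary radius / mean radius).
#'
#' @param mask Binary matrix (cleaned).
#' @param min_area_px Minimum component area.
#' @return List with `found`; when found: `center_px` (`(x, y)` pixel
#'   point), `axes_px` (semi-major, semi-minor), `area_px`, `quality`.
#' @export
best_circle_center <- function(mask, min_area_px = 25L) {
  not_found <- list(found = FALSE)
  if (sum(mask) < min_area_px) return(not_found)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) return(not_found)

  best <- NULL
  for (k in keep) {
    idx <- which(lab == k, arr.ind = TRUE)   # (row, col), 1-based
    u <- idx[, 2] - 0.5; v <- idx[, 1] - 0.5
    cu <- mean(u); cv <- mean(v)
    du <- u - cu; dv <- v - cv
    cov <- matrix(c(mean(du^2), mean(du * dv), mean(du * dv), mean(dv^2)),
                  2, 2)
    ev <- eigen(cov, symmetric = TRUE)$values
    ev[ev < 1e-12] <- 1e-12
    semi <- 2 * sqrt(ev)                     # solid-ellipse moment axes
    circ <- (semi[2] / semi[1])^2
    rad <- sqrt(du^2 + dv^2)
    border <- rad > stats::quantile(rad, 0.85)  # outer ring approximates boundary
    quality <- stats::sd(rad[border]) / mean(rad[border])
    score <- areas[k] * circ
    cand <- list(found = TRUE, center_px = c(cu, cv),
                 axes_px = c(semi[1], semi[2]), area_px = areas[k],
                 quality = quality, score = score)
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score &&
         (cand$area_px > best$area_px ||
          (cand$area_px == best$area_px && cand$quality < best$quality))))
      best <- cand
  }
  best
}

#' Track cup and ball in one frame
#'
#' The per-frame detection pipeline: RGB to HSV, colour mask per object,
#' morphological opening, best circular blob, then pixel-to-mm mapping
#' through the registration. When the cup is found, the ball is searched
#' first inside a window of twice the cup radius around the cup (the ball
#' cannot leave the dish without escaping); the search falls back to the
#' full frame otherwise.
#'
#' @param frame `[H, W, 3]` RGB array.
#' @param map A `planar_map`.
#' @param cup,ball [color_profile()]s (`ball = NULL` to skip).
#' @param frame_idx Frame index (0-based).
#' @param t Timestamp, s.
#' @param morph Arguments passed to [morph_clean()].
#' @return One-row data frame in the session schema (see
#'   [track_video()]).
#' @export
track_frame <- function(frame, map, cup, ball = NULL, frame_idx = 0L,
                        t = 0, morph = list()) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  ## coarse-to-fine: a stride-4 subsampled mask proposes a region of
  ## interest; detection then runs at full resolution inside it (whole
  ## frame when the coarse pass finds nothing)
  detect_in <- function(profile, rows = NULL, cols = NULL) {
    if (is.null(rows)) {
      ri <- seq(1, h, by = 4); ci <- seq(1, w, by = 4)
      cm <- color_mask(to_hsv(frame[ri, ci, , drop = FALSE]), profile)
      on <- which(cm > 0, arr.ind = TRUE)
      if (nrow(on) > 0) {
        margin <- 12
        rows <- max(1, ri[min(on[, 1])] - margin):
          min(h, ri[max(on[, 1])] + margin)
        cols <- max(1, ci[min(on[, 2])] - margin):
          min(w, ci[max(on[, 2])] + margin)
      } else {
        rows <- seq_len(h); cols <- seq_len(w)
      }
    }
    hsv <- to_hsv(frame[rows, cols, , drop = FALSE])
    m <- do.call(morph_clean, c(list(color_mask(hsv, profile)), morph))
    det <- best_circle_center(m, profile$min_area_px)
    if (det$found)
      det$center_px <- det$center_px + c(cols[1] - 1, rows[1] - 1)
    det
  }
  cup_det <- detect_in(cup)
  ball_det <- list(found = FALSE)
  if (!is.null(ball)) {
    if (cup_det$found) {
      r_win <- 2 * cup_det$axes_px[1]
      rows <- max(1, floor(cup_det$center_px[2] - r_win)):
        min(h, ceiling(cup_det$center_px[2] + r_win))
      cols <- max(1, floor(cup_det$center_px[1] - r_win)):
        min(w, ceiling(cup_det$center_px[1] + r_win))
      ball_det <- detect_in(ball, rows, cols)
    }
    if (!ball_det$found) ball_det <- detect_in(ball)
  }
  cup_mm <- if (cup_det$found) pixel_to_board(map, cup_det$center_px)
            else c(NA_real_, NA_real_)
  ball_mm <- if (ball_det$found) pixel_to_board(map, ball_det$center_px)
             else c(NA_real_, NA_real_)
  data.frame(frame_idx = as.integer(frame_idx), t_s = t,
             cup_found = cup_det$found,
             cup_x_mm = cup_mm[1], cup_y_mm = cup_mm[2],
             ball_found = ball_det$found,
             ball_x_mm = ball_mm[1], ball_y_mm = ball_mm[2],
             cup_px_x = if (cup_det$found) cup_det$center_px[1] else NA_real_,
             cup_px_y = if (cup_det$found) cup_det$center_px[2] else NA_real_,
             ball_px_x = if (ball_det$found) ball_det$center_px[1] else NA_real_,
             ball_px_y = if (ball_det$found) ball_det$center_px[2] else NA_real_)
}

#' Track a whole recording
#'
#' Runs [track_frame()] over every frame of a source and assembles a
#' session table. The source may be a list of in-memory frames, a
#' directory containing PNG frames (with an optional `manifest.csv`
#' giving `frame_idx`, `t_s`, `file`), or the list returned by
#' [generate_session()]. Undecodable frames are logged — never silently
#' skipped — and reported in the `dropped_frames` attribute and the
#' returned counts.
#'
#' @param source Frames: list of arrays, directory path, or a
#'   `generate_session()` result.
#' @param map A `planar_map`; its image size must match the frames.
#' @param cup,ball [color_profile()]s.
#' @param board A [board_spec()] (size check).
#' @param fps Nominal frame rate, used when the source carries no
#'   timestamps.
#' @param morph Arguments passed to [morph_clean()].
#' @return Data frame of class `track_series` (one row per decodable
#'   frame) with attributes `board`, `fps`, `source`,
#'   `dropped_frames` (integer indices).
#' @export
track_video <- function(source, map, cup, ball = NULL,
                        board = board_spec(), fps = 30, morph = list()) {
  ts <- NULL
  if (is.list(source) && !is.null(source$frames)) {
    fps <- source$fps
    ts <- source$truth$t_s
    source_label <- "generate_session"
    frames <- source$frames
    get_frame <- function(i) frames[[i]]
    n <- length(frames)
  } else if (is.character(source)) {
    if (!dir.exists(source)) stop("unreadable source: ", source)
    man_path <- file.path(source, "manifest.csv")
    if (file.exists(man_path)) {
      man <- read.csv(man_path)
      files <- file.path(source, man$file)
      ts <- man$t_s
    } else {
      files <- list.files(source, pattern = "\\.png$", full.names = TRUE)
      files <- sort(files)
    }
    if (length(files) == 0) {
      warning("no frames found in ", source)
      files <- character()
    }
    source_label <- source
    get_frame <- function(i) png::readPNG(files[i])[, , 1:3, drop = FALSE]
    n <- length(files)
  } else if (is.list(source)) {
    source_label <- "in-memory frames"
    get_frame <- function(i) source[[i]]
    n <- length(source)
  } else stop("unreadable source")

  if (n == 0) {
    warning("zero-length video")
    out <- track_frame(array(0, c(2, 2, 3)), map, cup, ball)[0, ]
  } else {
    rows <- vector("list", n)
    dropped <- integer()
    for (i in seq_len(n)) {
      fr <- tryCatch(get_frame(i), error = function(e) NULL)
      if (is.null(fr) || length(dim(fr)) != 3) {
        dropped <- c(dropped, i - 1L)
        next
      }
      if (dim(fr)[3] > 3) fr <- fr[, , 1:3]
      if (dim(fr)[1] != board$image_height_px ||
          dim(fr)[2] != board$image_width_px)
        stop(sprintf("frame %d is %dx%d but registration expects %dx%d",
                     i - 1L, dim(fr)[2], dim(fr)[1],
                     board$image_width_px, board$image_height_px))
      t_i <- if (!is.null(ts)) ts[i] else (i - 1) / fps
      rows[[i]] <- track_frame(fr, map, cup, ball, frame_idx = i - 1L,
                               t = t_i, morph = morph)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (length(dropped) > 0)
      warning(sprintf("%d undecodable frame(s) dropped (indices: %s)",
                      length(dropped),
                      paste(utils::head(dropped, 10), collapse = ", ")))
    attr(out, "dropped_frames") <- dropped
  }
  attr(out, "board") <- board
  attr(out, "fps") <- fps
  attr(out, "source") <- source_label
  class(out) <- c("track_series", "data.frame")
  out
}

#' @export
print.track_series <- function(x, ...) {
  cat(sprintf("Tracked session: %d frames at %g fps, cup found in %.1f%%\n",
              nrow(x), attr(x, "fps"), 100 * mean(x$cup_found)))
  dropped <- attr(x, "dropped_frames")
  if (length(dropped) > 0)
    cat(sprintf("  %d dropped frame(s)\n", length(dropped)))
  if (any(x$ball_found))
    cat(sprintf("  ball found in %.1f%% of frames\n",
                100 * mean(x$ball_found)))
  print(utils::head(as.data.frame(x), 3))
  invisible(x)
}
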