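#' Synthetic scene specification
#'
#' Describes a renderable overhead view of the board: registration map,
#' object colours and sizes, pixel noise and the random seed. The default
#' scene mirrors the reference prototype: a 914 x 609 mm board imaged at
#' 640 x 480 with a mild perspective (corner displacement about 2% of the
#' image width), a 140 mm diameter orange cup dish, a 25.4 mm green ball
#' and 140 mm diameter blue drawn targets on a near-white board.
#'
#' @param board A [board_spec()].
#' @param map A `planar_map`; default a mildly perspective view.
#' @param background RGB triple in `[0, 1]`.
#' @param cup_color,ball_color,target_color,obstacle_color RGB triples.
#'   Hues must be pairwise distinct by at least 20 degrees.
#' @param cup_radius_mm,ball_radius_mm Rendered disc radii, mm.
#' @param noise_sd Per-channel Gaussian pixel noise sd in `[0, 1]` units.
#' @param seed Integer RNG seed controlling all stochastic rendering.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(board = board_spec(),
                       map = perspective_map(board),
                       background = c(0.93, 0.93, 0.90),
                       cup_color = c(0.95, 0.55, 0.10),
                       ball_color = c(0.15, 0.75, 0.20),
                       target_color = c(0.15, 0.25, 0.80),
                       obstacle_color = c(0.65, 0.15, 0.60),
                       cup_radius_mm = 70, ball_radius_mm = 12.7,
                       noise_sd = 0, seed = 1L) {
  cols <- list(cup = cup_color, ball = ball_color, target = target_color,
               obstacle = obstacle_color)
  hues <- vapply(cols, function(co) .rgb1_to_hsv(co)[1], numeric(1))
  for (i in seq_along(hues)) for (j in seq_len(i - 1)) {
    dh <- abs(hues[i] - hues[j]); dh <- min(dh, 360 - dh)
    if (dh < 20)
      stop("object colours too close in hue: ", names(cols)[j], " vs ",
           names(cols)[i])
  }
  structure(list(board = board, map = map, background = background,
                 cup_color = cup_color, ball_color = ball_color,
                 target_color = target_color,
                 obstacle_color = obstacle_color,
                 cup_radius_mm = cup_radius_mm,
                 ball_radius_mm = ball_radius_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Mildly perspective registration map for synthetic scenes
#'
#' A homography in which the board corners land near, but not exactly on,
#' the image corners (fixed small displacements, about 2% of the image
#' width), emulating an imperfectly squared camera.
#'
#' @param board A [board_spec()].
#' @return A `planar_map` (pixel to mm).
#' @export
perspective_map <- function(board = board_spec()) {
  w <- board$image_width_px; h <- board$image_height_px
  img <- rbind(c(8, 6), c(w - 12, 10), c(w - 6, h - 8), c(10, h - 12),
               c(w / 2 + 3, h / 2 - 2))
  brd <- rbind(c(0, 0), c(board$width_mm, 0),
               c(board$width_mm, board$height_mm), c(0, board$height_mm),
               c(board$width_mm / 2, board$height_mm / 2))
  fit_planar_map(img, brd)
}

## Board-mm coordinates of a 4x supersampled pixel patch.
## rows/cols are 1-based pixel index ranges; returns list of matrices
## x_mm, y_mm of dim (4*nr, 4*nc) and the patch extents.
.patch_board_coords <- function(map, rows, cols) {
  sub <- (seq_len(4) - 0.5) / 4
  u <- rep(cols - 1, each = 4) + rep(sub, times = length(cols))
  v <- rep(rows - 1, each = 4) + rep(sub, times = length(rows))
  grid <- cbind(rep(u, times = length(v)), rep(v, each = length(u)))
  mm <- pixel_to_board(map, grid)
  list(x = matrix(mm[, 1], length(v), length(u), byrow = TRUE),
       y = matrix(mm[, 2], length(v), length(u), byrow = TRUE))
}

## Downsample a (4m x 4n) coverage matrix of 0/1 to (m x n) means.
.block_mean4 <- function(m) {
  nr <- nrow(m) / 4; nc <- ncol(m) / 4
  m2 <- matrix(colMeans(matrix(m, nrow = 4)), nr, nc * 4, byrow = FALSE)
  ## m2[i, ] holds row-block means laid out along columns; fold columns
  t(matrix(colMeans(matrix(t(m2), nrow = 4)), nc, nr))
}

## Composite an anti-aliased filled disc (centre mm, radius mm) into img.
.draw_disc <- function(img, scene, center_mm, r_mm, color) {
  c_px <- board_to_pixel(scene$map, center_mm)
  s <- mm_per_pixel(scene$map, center_mm)
  r_px <- r_mm / s
  h <- dim(img)[1]; w <- dim(img)[2]
  rows <- max(1, floor(c_px[2] - r_px - 1)):min(h, ceiling(c_px[2] + r_px + 2))
  cols <- max(1, floor(c_px[1] - r_px - 1)):min(w, ceiling(c_px[1] + r_px + 2))
  if (length(rows) == 0 || length(cols) == 0) return(img)
  pc <- .patch_board_coords(scene$map, rows, cols)
  inside <- (pc$x - center_mm[1])^2 + (pc$y - center_mm[2])^2 <= r_mm^2
  cov <- .block_mean4(inside * 1)
  for (ch in 1:3) {
    patch <- img[rows, cols, ch]
    img[rows, cols, ch] <- patch * (1 - cov) + color[ch] * cov
  }
  img
}

## Vectorized even-odd point-in-polygon test.
.in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Composite an anti-aliased filled polygon (vertices mm) into img.
.draw_polygon <- function(img, scene, vertices_mm, color) {
  v_px <- board_to_pixel(scene$map, vertices_mm)
  h <- dim(img)[1]; w <- dim(img)[2]
  rows <- max(1, floor(min(v_px[, 2]) - 1)):min(h, ceiling(max(v_px[, 2]) + 2))
  cols <- max(1, floor(min(v_px[, 1]) - 1)):min(w, ceiling(max(v_px[, 1]) + 2))
  if (length(rows) == 0 || length(cols) == 0) return(img)
  pc <- .patch_board_coords(scene$map, rows, cols)
  inside <- matrix(.in_polygon(as.numeric(pc$x), as.numeric(pc$y),
                               vertices_mm[, 1], vertices_mm[, 2]),
                   nrow(pc$x), ncol(pc$x))
  cov <- .block_mean4(inside * 1)
  for (ch in 1:3) {
    patch <- img[rows, cols, ch]
    img[rows, cols, ch] <- patch * (1 - cov) + color[ch] * cov
  }
  img
}

#' Render one synthetic frame
#'
#' Draws the board background, target discs, obstacle polygons, the cup
#' disc and the ball disc (last, on top), all projected through the
#' scene's registration map with 4x supersampled anti-aliasing, then adds
#' optional Gaussian pixel noise from the current RNG stream. Positions
#' off the board are still rendered (with a warning) if they fall inside
#' the frame.
#'
#' @param scene A [scene_spec()].
#' @param cup_mm Cup centre, board mm, or NULL.
#' @param ball_mm Ball centre, board mm, or NULL.
#' @param targets List of [target_circle()]s.
#' @param obstacles List of vertex matrices (mm), drawn as filled
#'   polygons.
#' @param base Optional pre-rendered static background (board, targets,
#'   obstacles) to composite onto, as returned by a previous
#'   [render_frame()] call without cup and ball; `targets`/`obstacles`
#'   are ignored when given.
#' @return `[H, W, 3]` numeric array in `[0, 1]` with attribute `truth`
#'   echoing the exact input positions.
#' @export
render_frame <- function(scene, cup_mm = NULL, ball_mm = NULL,
                         targets = list(), obstacles = list(),
                         base = NULL) {
  stopifnot(inherits(scene, "scene_spec"))
  b <- scene$board
  if (is.null(base)) {
    img <- array(rep(scene$background,
                     each = b$image_height_px * b$image_width_px),
                 dim = c(b$image_height_px, b$image_width_px, 3))
    for (tg in targets)
      img <- .draw_disc(img, scene, c(tg$cx_mm, tg$cy_mm), tg$r_mm,
                        scene$target_color)
    for (ob in obstacles)
      img <- .draw_polygon(img, scene, as.matrix(ob), scene$obstacle_color)
  } else {
    img <- base
    attr(img, "truth") <- NULL
  }
  on_board <- function(p)
    p[1] >= 0 && p[1] <= b$width_mm && p[2] >= 0 && p[2] <= b$height_mm
  if (!is.null(cup_mm)) {
    if (!on_board(cup_mm)) warning("cup position off the board")
    img <- .draw_disc(img, scene, cup_mm, scene$cup_radius_mm,
                      scene$cup_color)
  }
  if (!is.null(ball_mm)) {
    if (!on_board(ball_mm)) warning("ball position off the board")
    img <- .draw_disc(img, scene, ball_mm, scene$ball_radius_mm,
                      scene$ball_color)
  }
  if (scene$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, scene$noise_sd),
                       dim = dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  attr(img, "truth") <- list(cup_mm = cup_mm, ball_mm = ball_mm,
                             targets = targets, obstacles = obstacles)
  img
}

#' Minimum-jerk point-to-point trajectory
#'
#' Fifth-order polynomial profile with zero velocity and acceleration at
#' both ends — the standard smooth model of a natural reaching movement.
#' Peak speed is `1.875 * ||p1 - p0|| / T` at mid-movement.
#'
#' @param p0,p1 Endpoints (any unit).
#' @param T_dur Movement duration, s.
#' @param fs Sampling rate, Hz.
#' @return Data frame `t`, `x`, `y`.
#' @export
min_jerk <- function(p0, p1, T_dur, fs) {
  stopifnot(T_dur > 0, fs > 0)
  t <- seq(0, T_dur, by = 1 / fs)
  tau <- t / T_dur
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  data.frame(t = t, x = p0[1] + s * (p1[1] - p0[1]),
             y = p0[2] + s * (p1[2] - p0[2]))
}

#' Archimedean spiral trajectory
#'
#' Radius grows linearly with angle from `r0` to `r1` over `turns` full
#' revolutions traversed at constant angular rate — the movement used for
#' accuracy verification sessions.
#'
#' @param center Centre, mm.
#' @param r0,r1 Start and end radius, mm (`r1 > r0 >= 0`).
#' @param turns Number of revolutions.
#' @param T_dur Duration, s.
#' @param fs Sampling rate, Hz.
#' @return Data frame `t`, `x`, `y`.
#' @export
spiral_trajectory <- function(center, r0, r1, turns, T_dur, fs) {
  stopifnot(r1 > r0, r0 >= 0, turns > 0, T_dur > 0)
  t <- seq(0, T_dur, by = 1 / fs)
  tau <- t / T_dur
  r <- r0 + (r1 - r0) * tau
  a <- 2 * pi * turns * tau
  data.frame(t = t, x = center[1] + r * cos(a), y = center[2] + r * sin(a))
}

#' Figure-eight trajectory on a two-circle template
#'
#' Traverses the two tangent circles at constant angular rate, one circle
#' per half period, passing through the tangency point between them; every
#' sample lies exactly on the template outline.
#'
#' @param template A [figure8_template()].
#' @param period Duration of one full figure-eight, s.
#' @param cycles Number of repetitions.
#' @param fs Sampling rate, Hz.
#' @return Data frame `t`, `x`, `y`.
#' @export
figure8_trajectory <- function(template, period, cycles = 1, fs = 100) {
  stopifnot(inherits(template, "figure8_template"), period > 0, cycles > 0)
  t <- seq(0, period * cycles, by = 1 / fs)
  tau <- (t / period) %% 1
  r <- template$r_mm
  ## tangency point is the midpoint of the two centres
  axis <- (template$c1 - template$c2) / sqrt(sum((template$c1 - template$c2)^2))
  base <- atan2(-axis[2], -axis[1])  # angle from c1 to the tangency point
  first <- tau < 0.5
  a1 <- base + 2 * pi * (tau / 0.5)         # ccw around circle 1
  a2 <- (base + pi) - 2 * pi * ((tau - 0.5) / 0.5)  # cw around circle 2
  x <- ifelse(first, template$c1[1] + r * cos(a1),
              template$c2[1] + r * cos(a2))
  y <- ifelse(first, template$c1[2] + r * sin(a1),
              template$c2[2] + r * sin(a2))
  data.frame(t = t, x = x, y = y)
}

#' Generate a full synthetic session
#'
#' Builds the cup trajectory for a task, optionally drives the ball with
#' the pendulum model, renders every frame and assembles the ground-truth
#' table in the tracker session schema. All randomness (pixel noise) flows
#' from the scene seed, so identical inputs give byte-identical outputs.
#'
#' For point-to-point tasks the cup rests at one target, a go cue sounds,
#' and a minimum-jerk reach of `reach_duration` carries it to the other
#' target; trials alternate outward/inward between the two targets.
#'
#' @param scene A [scene_spec()].
#' @param task A [task_spec()].
#' @param source `"min_jerk"`, `"spiral"`, `"figure8"` or `"dynamics"`
#'   (minimum-jerk cup with the ball simulated by
#'   [simulate_kinematic()]).
#' @param fps Frame rate of the rendered session.
#' @param n_trials Number of trials (point-to-point; default 30 = 15
#'   outward + 15 inward).
#' @param reach_duration Duration of each reach, s.
#' @param hold_duration Rest between go cues, s.
#' @param params A [cupball_params()] when `source = "dynamics"`.
#' @param render If `FALSE`, skip rendering and return only trajectories.
#' @param out_dir If non-NULL, write frames as PNG plus `manifest.csv` and
#'   `truth.csv` there and drop frames from the return value.
#' @param spiral_args,figure8_args Overrides for the trajectory
#'   generators.
#' @return List with `frames` (list of arrays, or NULL), `truth` (session
#'   schema data frame), `task` (with go cues filled in), `scene`.
#' @export
generate_session <- function(scene, task, source = c("min_jerk", "spiral",
                                                     "figure8", "dynamics"),
                             fps = 20, n_trials = 30, reach_duration = 1,
                             hold_duration = 0.5, params = NULL,
                             render = TRUE, out_dir = NULL,
                             spiral_args = list(), figure8_args = list()) {
  stopifnot(inherits(scene, "scene_spec"), inherits(task, "task_spec"))
  source <- match.arg(source)
  set.seed(scene$seed)

  go_cues <- numeric()
  if (source %in% c("min_jerk", "dynamics")) {
    stopifnot(task$kind == "point-to-point")
    tg <- task$targets
    pos <- list()
    t_cursor <- 0
    start <- c(tg[[1]]$cx_mm, tg[[1]]$cy_mm)
    for (k in seq_len(n_trials)) {
      from <- if (k %% 2 == 1) tg[[1]] else tg[[2]]
      to <- if (k %% 2 == 1) tg[[2]] else tg[[1]]
      hold_t <- seq(0, hold_duration - 1 / fps, by = 1 / fps)
      pos[[length(pos) + 1]] <-
        data.frame(t = t_cursor + hold_t,
                   x = from$cx_mm, y = from$cy_mm)
      t_cursor <- t_cursor + hold_duration
      go_cues <- c(go_cues, t_cursor)
      mj <- min_jerk(c(from$cx_mm, from$cy_mm), c(to$cx_mm, to$cy_mm),
                     reach_duration, fps)
      mj$t <- mj$t + t_cursor
      pos[[length(pos) + 1]] <- mj[-nrow(mj), ]
      t_cursor <- t_cursor + reach_duration
    }
    traj <- if (length(pos) > 0) do.call(rbind, pos)
            else data.frame(t = numeric(0), x = numeric(0), y = numeric(0))
  } else if (source == "spiral") {
    sa <- modifyList(list(center = c(scene$board$width_mm / 2,
                                     scene$board$height_mm / 2),
                          r0 = 15, r1 = 85, turns = 2, T_dur = 4, fs = fps),
                     spiral_args)
    traj <- do.call(spiral_trajectory, sa)
    go_cues <- 0
  } else {
    fa <- modifyList(list(template = task$fig8, period = 1.66, cycles = 3,
                          fs = fps), figure8_args)
    traj <- do.call(figure8_trajectory, fa)
    go_cues <- 0
  }
  task$go_cues <- go_cues

  n <- nrow(traj)
  ball <- NULL
  if (source == "dynamics" && task$level >= 2) {
    if (is.null(params)) params <- cupball_params()
    sim <- simulate_kinematic(params, data.frame(t = traj$t,
                                                 x = traj$x / 1000,
                                                 y = traj$y / 1000))
    ball <- cbind(sim$x_b * 1000, sim$y_b * 1000)
  }

  truth <- data.frame(frame_idx = seq_len(n) - 1L, t_s = traj$t,
                      cup_found = rep(TRUE, n),
                      cup_x_mm = traj$x, cup_y_mm = traj$y,
                      ball_found = rep(!is.null(ball), n),
                      ball_x_mm = if (is.null(ball)) rep(NA_real_, n)
                                  else ball[, 1],
                      ball_y_mm = if (is.null(ball)) rep(NA_real_, n)
                                  else ball[, 2],
                      cup_px_x = rep(NA_real_, n),
                      cup_px_y = rep(NA_real_, n),
                      ball_px_x = rep(NA_real_, n),
                      ball_px_y = rep(NA_real_, n))
  if (n > 0) {
    px <- board_to_pixel(scene$map, cbind(traj$x, traj$y))
    truth$cup_px_x <- px[, 1]; truth$cup_px_y <- px[, 2]
    if (!is.null(ball)) {
      bpx <- board_to_pixel(scene$map, ball)
      truth$ball_px_x <- bpx[, 1]; truth$ball_px_y <- bpx[, 2]
    }
  }

  frames <- NULL
  if (render && n > 0) {
    quiet <- scene
    quiet$noise_sd <- 0
    static <- render_frame(quiet, targets = task$targets)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      frames[[i]] <- render_frame(
        scene, cup_mm = c(traj$x[i], traj$y[i]),
        ball_mm = if (!is.null(ball)) ball[i, ] else NULL,
        base = static)
      attr(frames[[i]], "truth") <- NULL
    }
  }

  if (!is.null(out_dir) && !is.null(frames)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- sprintf("frame_%05d.png", truth$frame_idx)
    for (i in seq_len(n))
      png::writePNG(frames[[i]], file.path(out_dir, files[i]))
    write.csv(data.frame(frame_idx = truth$frame_idx, t_s = truth$t_s,
                         file = files),
              file.path(out_dir, "manifest.csv"), row.names = FALSE)
    write_session(truth, file.path(out_dir, "truth.csv"))
    frames <- NULL
  }

  list(frames = frames, truth = truth, task = task, scene = scene, fps = fps)
}
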