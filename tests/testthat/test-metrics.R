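test_that("zero-phase filtering has unit DC gain, no lag, sharp rolloff", {
  ## constant signal is unchanged
  x <- rep(3.7, 400)
  expect_equal(lowpass_zero_phase(x, fs = 100), x, tolerance = 1e-9)

  ## 20 Hz tone at fs 80 under fc 6: double-pass Butterworth attenuates
  ## by |H|^2 = 1/(1 + (f/fc)^(2n)), far beyond 60 dB
  t <- seq(0, 5, by = 1 / 80)
  tone <- sin(2 * pi * 20 * t)
  y <- lowpass_zero_phase(tone, fs = 80, fc = 6, order = 6)
  mid <- y[100:(length(y) - 100)]
  expect_lt(max(abs(mid)), 1e-3)     # > 60 dB down

  ## symmetric pulse keeps its peak location (zero phase)
  tt <- seq(0, 4, by = 0.01)
  pulse <- exp(-((tt - 2) / 0.3)^2)
  yf <- lowpass_zero_phase(pulse, fs = 100)
  expect_equal(which.max(yf), which.max(pulse))

  expect_error(lowpass_zero_phase(rep(1, 10), fs = 100), "short")
  expect_error(lowpass_zero_phase(x, fs = 10, fc = 6), "fs")
})

test_that("filtering and differentiation commute on band-limited signals", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t) + 0.5 * cos(2 * pi * 2.5 * t)
  cd <- function(v) (c(v[-1], NA) - c(NA, v[-length(v)])) * fs / 2
  a <- cd(lowpass_zero_phase(x, fs))
  b <- lowpass_zero_phase(cd(x)[2:(length(x) - 1)], fs)
  ## compare away from the ends, where the finite-length filter
  ## transients live
  mid <- 150:(length(x) - 150)
  expect_lt(max(abs(a[mid] - b[mid - 1])), 1e-6)
})

test_that("reach time is the first closed-disc entry after the go cue", {
  tg <- target_circle(500, 300, 70)
  t <- seq(0, 3, by = 0.02)

  ## cup already inside the target at the cue
  inside <- matrix(rep(c(505, 295), each = length(t)), ncol = 2)
  r0 <- reach_time(t, inside, tg, go_cue = 0.5)
  expect_equal(r0$reach_time, 0)
  expect_true(r0$success)

  ## never enters: failure, not an error
  away <- matrix(rep(c(100, 100), each = length(t)), ncol = 2)
  rf <- reach_time(t, away, tg, go_cue = 0.5)
  expect_false(rf$success)
  expect_true(is.na(rf$reach_time))

  ## a 52 cm minimum-jerk reach into a 14 cm target, checked against an
  ## independent linear scan over the samples
  mj <- min_jerk(c(197, 454.5), c(717, 154.5), T_dur = 1, fs = 50)
  tg2 <- target_circle(717, 154.5, 70)
  t2 <- mj$t + 0.5
  xy <- cbind(mj$x, mj$y)
  r1 <- reach_time(t2, xy, tg2, go_cue = 0.5)
  scan <- which(sqrt((mj$x - 717)^2 + (mj$y - 154.5)^2) <= 70)[1]
  expect_equal(r1$reach_time, t2[scan] - 0.5)
  expect_true(r1$success)

  ## entry after a ball escape demotes the trial to failure
  r2 <- reach_time(t2, xy, tg2, go_cue = 0.5, escape_time = 0.9)
  expect_false(r2$success)
  expect_equal(r2$reach_time, r1$reach_time)

  ## delaying the go cue by dt (before entry) shortens reach time by dt
  dt_shift <- 0.2
  r3 <- reach_time(t2, xy, tg2, go_cue = 0.5 + dt_shift)
  expect_equal(r3$reach_time, r1$reach_time - dt_shift)
})

test_that("figure-eight error is the distance to the template outline", {
  tpl <- figure8_template(centre = c(457, 304.5), diameter_mm = 250)
  ## samples exactly on the outline
  a <- seq(0, 2 * pi, length.out = 73)
  on1 <- cbind(tpl$c1[1] + 125 * cos(a), tpl$c1[2] + 125 * sin(a))
  expect_lt(max(figure8_error(on1, tpl)$distance), 1e-9)

  ## circle centre is one radius away
  expect_equal(figure8_error(rbind(tpl$c1), tpl)$distance, 125)

  ## random samples against a dense discretization of the template
  set.seed(5)
  pts <- cbind(runif(50, 200, 700), runif(50, 100, 500))
  dense_a <- seq(0, 2 * pi, length.out = 5e4)
  dense <- rbind(cbind(tpl$c1[1] + 125 * cos(dense_a),
                       tpl$c1[2] + 125 * sin(dense_a)),
                 cbind(tpl$c2[1] + 125 * cos(dense_a),
                       tpl$c2[2] + 125 * sin(dense_a)))
  d_got <- figure8_error(pts, tpl)$distance
  d_brute <- apply(pts, 1, function(p)
    sqrt(min((dense[, 1] - p[1])^2 + (dense[, 2] - p[2])^2)))
  expect_equal(d_got, d_brute, tolerance = 1e-4)

  ## invariance to sample order and rigid motion
  perm <- sample(nrow(pts))
  expect_equal(figure8_error(pts[perm, ], tpl)$rms_mm,
               figure8_error(pts, tpl)$rms_mm)
  th <- 0.7; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  shift <- c(31, -17)
  move <- function(m) sweep(m %*% t(R), 2, -shift)
  tpl_m <- figure8_template(centre = move(rbind((tpl$c1 + tpl$c2) / 2))[1, ],
                            diameter_mm = 250,
                            axis = as.numeric(R %*% c(1, 0)))
  expect_equal(figure8_error(move(pts), tpl_m)$rms_mm,
               figure8_error(pts, tpl)$rms_mm, tolerance = 1e-9)
})

test_that("path variability measures dispersion across repeated reaches", {
  line <- cbind(seq(0, 100, length.out = 60), rep(0, 60))
  expect_equal(path_variability(list(line, line))$variability_mm, 0)

  ## two parallel straight paths offset by d: dispersion d/2 everywhere
  d <- 14
  up <- cbind(line[, 1], rep(d, 60))
  pv <- path_variability(list(line, up))
  expect_equal(pv$per_station_mm, rep(d / 2, 50), tolerance = 1e-9)

  ## rigid rotation of all paths leaves the measure unchanged
  th <- 1.1; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  pv_rot <- path_variability(list(line %*% t(R), up %*% t(R)))
  expect_equal(pv_rot$variability_mm, pv$variability_mm, tolerance = 1e-9)

  expect_error(path_variability(list(line)), "at least 2")
})

test_that("session metrics segments trials at the go cues", {
  task <- standard_task(level = 1)
  tg <- task$targets
  fps <- 25
  sess <- generate_session(fixture_scene(), task, source = "min_jerk",
                           fps = fps, n_trials = 4, render = FALSE)
  m <- session_metrics(sess$truth, sess$task)
  expect_equal(nrow(m), 4)
  expect_equal(m$direction, c("outward", "inward", "outward", "inward"))
  expect_true(all(m$success))
  ## a 1 s minimum-jerk reach crosses the 70 mm target boundary at
  ## s = (520 - 70)/520 = 0.865 of the path, i.e. around 0.7 of the
  ## movement; reach times must match that and repeat exactly
  expect_true(all(m$reach_time_s > 0.5 & m$reach_time_s <= 0.9))
  expect_equal(sd(m$reach_time_s), 0)
  ## path length of a straight reach ~ target separation
  expect_equal(mean(m$path_length_mm), 520, tolerance = 0.02)
})

test_that("figure-8 sessions report template tracking error", {
  task <- task_spec("figure-8", level = 1)
  sess <- generate_session(fixture_scene(), task, source = "figure8",
                           fps = 40, render = FALSE)
  m <- session_metrics(sess$truth, sess$task)
  expect_equal(nrow(m), 1)
  expect_lt(m$fig8_rms_mm, 1e-9)
})
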