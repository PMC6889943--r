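test_that("RGB to HSV follows the hexcone formula", {
  red <- array(c(1, 0, 0), dim = c(1, 1, 3))
  expect_equal(as.numeric(to_hsv(red)), c(0, 1, 1))
  gray <- array(c(0.5, 0.5, 0.5), dim = c(1, 1, 3))
  expect_equal(as.numeric(to_hsv(gray))[2], 0)

  ## hand-evaluated reference: (0, 0.5, 1) -> H 210, S 1, V 1
  px <- array(c(0, 0.5, 1), dim = c(1, 1, 3))
  expect_equal(as.numeric(to_hsv(px)), c(210, 1, 1))

  ## random pixels against the scalar reference implementation
  set.seed(7)
  for (i in 1:20) {
    v <- runif(3)
    got <- as.numeric(to_hsv(array(v, dim = c(1, 1, 3))))
    expect_equal(got, as.numeric(reference_hsv(v[1], v[2], v[3])),
                 tolerance = 1e-12)
  }
  expect_error(to_hsv(matrix(0, 4, 4)), "RGB")
})

test_that("colour masks honour bounds and hue wrap", {
  hsv <- array(0, dim = c(2, 2, 3))
  hsv[, , 1] <- 30; hsv[, , 2] <- 0.8; hsv[, , 3] <- 0.9
  pr <- color_profile("x", c(20, 0.5, 0.5), c(40, 1, 1))
  expect_true(all(color_mask(hsv, pr) == 1))

  wrap <- color_profile("red", c(350, 0.2, 0.2), c(10, 1, 1))
  h5 <- hsv; h5[, , 1] <- 5
  h180 <- hsv; h180[, , 1] <- 180
  expect_true(all(color_mask(h5, wrap) == 1))
  expect_true(all(color_mask(h180, wrap) == 0))

  ## disc area recovered within 5% on a rendered frame
  scene <- fixture_scene()
  fr <- render_frame(scene, cup_mm = c(450, 300))
  m <- color_mask(to_hsv(fr), fixture_profiles(scene)$cup)
  r_px <- scene$cup_radius_mm / mm_per_pixel(scene$map)
  expect_equal(sum(m), pi * r_px^2, tolerance = 0.05)
})

test_that("morphological opening matches the brute-force oracle", {
  z <- matrix(0, 30, 30)
  expect_equal(morph_clean(z), z)

  speck <- z; speck[15, 15] <- 1
  expect_equal(morph_clean(speck), z)   # sub-kernel speckle removed

  sq <- z; sq[6:25, 6:25] <- 1
  got <- morph_clean(sq)
  oracle <- brute_morph(brute_morph(sq, 5, "erode"), 5, "dilate")
  expect_equal(got, oracle)
  expect_equal(sum(got), sum(sq))       # interior square is preserved

  ## irregular random blob vs oracle, including an extra dilation
  set.seed(11)
  blob <- z; blob[sample(900, 200)] <- 1
  expect_equal(morph_clean(blob),
               brute_morph(brute_morph(blob, 5, "erode"), 5, "dilate"))
  expect_equal(morph_clean(blob, dilate_iter = 2),
               brute_morph(brute_morph(brute_morph(blob, 5, "erode"),
                                       5, "dilate"), 5, "dilate"))
})

test_that("pipeline masks are idempotent under repeated cleaning", {
  scene <- fixture_scene(noise_sd = 5 / 255)
  profiles <- fixture_profiles(scene)
  set.seed(3)
  agree <- replicate(20, {
    cup <- c(runif(1, 100, 800), runif(1, 100, 500))
    fr <- render_frame(scene, cup_mm = cup)
    m1 <- morph_clean(color_mask(to_hsv(fr), profiles$cup))
    m2 <- morph_clean(m1)
    mean(m1 == m2)
  })
  expect_true(all(agree >= 0.99))
})

test_that("the best circular blob is found with sub-pixel accuracy", {
  ## synthetic mask: disc of radius 50 at (100, 100) in pixel coords
  uu <- matrix(rep(1:300 - 0.5, each = 200), 200, 300)
  vv <- matrix(rep(1:200 - 0.5, times = 300), 200, 300)
  disc <- ((uu - 100)^2 + (vv - 100)^2 <= 50^2) * 1
  det <- best_circle_center(disc)
  expect_true(det$found)
  expect_lt(sqrt(sum((det$center_px - c(100, 100))^2)), 0.5)
  expect_equal(det$axes_px[1], 50, tolerance = 0.05)

  expect_false(best_circle_center(matrix(0, 50, 50))$found)

  ## two discs: the larger wins the circularity-weighted area score
  two <- disc
  two[(uu - 250)^2 + (vv - 60)^2 <= 10^2] <- 1
  det2 <- best_circle_center(two)
  expect_lt(sqrt(sum((det2$center_px - c(100, 100))^2)), 0.5)

  ## min_area filters out everything
  expect_false(best_circle_center(disc, min_area_px = 1e6)$found)
})

test_that("track_frame recovers cup and ball positions from rendered frames", {
  scene <- fixture_scene()
  profiles <- fixture_profiles(scene)
  s <- track_frame(render_frame(scene, cup_mm = c(300, 200)),
                   scene$map, profiles$cup, profiles$ball)
  expect_true(s$cup_found)
  expect_false(s$ball_found)
  expect_lt(sqrt((s$cup_x_mm - 300)^2 + (s$cup_y_mm - 200)^2), 2)

  ## ball inside the cup dish: both recovered
  s2 <- track_frame(render_frame(scene, cup_mm = c(300, 200),
                                 ball_mm = c(312, 194)),
                    scene$map, profiles$cup, profiles$ball)
  expect_true(s2$cup_found && s2$ball_found)
  expect_lt(sqrt((s2$ball_x_mm - 312)^2 + (s2$ball_y_mm - 194)^2), 2)

  ## frame without cup or ball colours
  s3 <- track_frame(render_frame(scene), scene$map, profiles$cup,
                    profiles$ball)
  expect_false(s3$cup_found)
  expect_false(s3$ball_found)
  expect_true(is.na(s3$cup_x_mm) && is.na(s3$ball_x_mm))
})

test_that("tracking is accurate on clean frames and robust to pixel noise", {
  n_frames <- 40
  scene <- fixture_scene()
  noisy <- fixture_scene(noise_sd = 5 / 255)
  profiles <- fixture_profiles(scene)
  set.seed(21)
  errs <- matrix(NA_real_, n_frames, 2)
  for (i in seq_len(n_frames)) {
    cup <- c(runif(1, 120, 790), runif(1, 120, 490))
    truth_px <- board_to_pixel(scene$map, cup)
    s_clean <- track_frame(render_frame(scene, cup_mm = cup), scene$map,
                           profiles$cup)
    s_noisy <- track_frame(render_frame(noisy, cup_mm = cup), noisy$map,
                           profiles$cup)
    errs[i, 1] <- sqrt((s_clean$cup_px_x - truth_px[1])^2 +
                         (s_clean$cup_px_y - truth_px[2])^2)
    errs[i, 2] <- sqrt((s_noisy$cup_px_x - truth_px[1])^2 +
                         (s_noisy$cup_px_y - truth_px[2])^2)
  }
  expect_lt(max(errs[, 1]), 0.5)     # noiseless: sub-half-pixel
  expect_lt(median(errs[, 2]), 2)    # sigma = 5/255 noise: median <= 2 px
})

test_that("tracking is equivariant under board translations", {
  scene <- fixture_scene()
  profiles <- fixture_profiles(scene)
  base <- c(350, 250)
  shift <- c(80, -40)
  s0 <- track_frame(render_frame(scene, cup_mm = base), scene$map,
                    profiles$cup)
  s1 <- track_frame(render_frame(scene, cup_mm = base + shift), scene$map,
                    profiles$cup)
  moved <- c(s1$cup_x_mm - s0$cup_x_mm, s1$cup_y_mm - s0$cup_y_mm)
  expect_lt(max(abs(moved - shift)), 2)
})

test_that("track_video processes sessions, logs drops, flags empties", {
  scene <- fixture_scene()
  profiles <- fixture_profiles(scene)
  task <- standard_task()
  sess <- generate_session(scene, task, source = "spiral", fps = 10,
                           spiral_args = list(T_dur = 2))
  series <- track_video(sess, scene$map, profiles$cup, board = scene$board)
  expect_equal(nrow(series), nrow(sess$truth))
  expect_gte(mean(series$cup_found), 0.99)
  err <- sqrt((series$cup_x_mm - sess$truth$cup_x_mm)^2 +
                (series$cup_y_mm - sess$truth$cup_y_mm)^2)
  expect_lt(median(err, na.rm = TRUE), 2)

  ## zero-length source warns and returns an empty series
  expect_warning(empty <- track_video(list(), scene$map, profiles$cup,
                                      board = scene$board), "zero-length")
  expect_equal(nrow(empty), 0)

  ## corrupted frames in a directory source are logged, not silently lost
  dir <- withr::local_tempdir()
  sess_dir <- generate_session(scene, task, source = "spiral", fps = 10,
                               spiral_args = list(T_dur = 2),
                               out_dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  corrupt <- c(3, 10, 15)
  for (i in corrupt)
    writeLines("not a png", file.path(dir, man$file[i]))
  expect_warning(
    series2 <- track_video(dir, scene$map, profiles$cup,
                           board = scene$board),
    "3 undecodable")
  expect_equal(nrow(series2), nrow(man) - 3)
  expect_equal(attr(series2, "dropped_frames"), corrupt - 1L)

  ## frame size mismatch against the registration is an error
  small <- list(array(0.5, c(10, 10, 3)))
  expect_error(track_video(small, scene$map, profiles$cup,
                           board = scene$board), "registration expects")
})
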