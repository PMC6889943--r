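test_that("hanging equilibrium is a fixed point and light bobs decouple", {
  p <- cupball_params()
  d <- equations_of_motion(sim_state(), c(0, 0), p)
  expect_equal(max(abs(d)), 0)

  ## m_b -> 0: cart acceleration approaches F / m_c
  p_light <- cupball_params(m_c = 0.5, m_b = 1e-12)
  d2 <- equations_of_motion(sim_state(theta = 0.4, dtheta = 1), c(2, -1),
                            p_light)
  expect_equal(d2[["vx_c"]], 2 / 0.5, tolerance = 1e-9)
  expect_equal(d2[["vy_c"]], -1 / 0.5, tolerance = 1e-9)
})

test_that("planar restriction matches the independent cart-pendulum oracle", {
  p <- cupball_params(theta_esc = 89 * pi / 180)
  cases <- list(
    list(th = 0.3, dth = 0, vx = 0, F = 0),
    list(th = 0.7, dth = -1.2, vx = 0.4, F = 2.5),
    list(th = 1.2, dth = 2.0, vx = -0.1, F = -1.0))
  for (cs in cases) {
    st <- sim_state(vx_c = cs$vx, theta = cs$th, dtheta = cs$dth)
    d <- equations_of_motion(st, c(cs$F, 0), p)
    o <- planar_cart_pendulum_deriv(0, cs$vx, cs$th, cs$dth, cs$F, p)
    expect_lt(abs(d[["vx_c"]] - o$ddx), 1e-9)
    expect_lt(abs(d[["dtheta"]] - o$ddth), 1e-9)
    expect_equal(d[["vy_c"]], 0)
    expect_equal(d[["dphi"]], 0)
  }
})

test_that("unforced undamped runs conserve energy and momentum", {
  p <- cupball_params(theta_esc = 89 * pi / 180)
  ## release from rest at a range of amplitudes and azimuths, with the
  ## cart drifting; conical near-axis orbits are excluded (they pass
  ## arbitrarily close to the coordinate singularity)
  for (th0 in c(5, 30, 60) * pi / 180) {
    tr <- simulate_forced(p, sim_state(theta = th0, phi = 0.3,
                                       vx_c = 0.1),
                          c(0, 0), t_end = 10, dt = 0.001)
    cols <- c("x_c", "y_c", "vx_c", "vy_c", "theta", "phi", "dtheta", "dphi")
    e <- apply(tr[, cols], 1, total_energy, params = p)
    expect_lt(max(abs(e - e[1])) / abs(e[1]), 1e-6)

    ## horizontal momentum of cart + bob
    l <- p$l
    vbx <- tr$vx_c + l * (tr$dtheta * cos(tr$theta) * cos(tr$phi) -
                            tr$dphi * sin(tr$theta) * sin(tr$phi))
    vby <- tr$vy_c + l * (tr$dtheta * cos(tr$theta) * sin(tr$phi) +
                            tr$dphi * sin(tr$theta) * cos(tr$phi))
    px <- p$m_c * tr$vx_c + p$m_b * vbx
    py <- p$m_c * tr$vy_c + p$m_b * vby
    scale <- max(abs(px[1]), p$m_b * sqrt(p$g * p$l))
    expect_lt(max(abs(px - px[1])) / scale, 1e-9)
    expect_lt(max(abs(py - py[1])) / scale, 1e-9)
  }
})

test_that("a stationary cup gives the textbook small-angle period", {
  p <- cupball_params(theta_esc = 89 * pi / 180)
  tt <- seq(0, 3, by = 1e-3)
  cup <- data.frame(t = tt, x = 0 * tt, y = 0 * tt)
  tr <- simulate_kinematic(p, cup, theta0 = 1 * pi / 180)
  th <- tr$theta - mean(range(tr$theta))
  zc <- which(diff(sign(th)) != 0)
  period <- 2 * mean(diff(tr$t[zc]))
  expect_equal(period, 2 * pi * sqrt(p$l / p$g), tolerance = 0.01)
  ## energy of the swing is conserved (planar pendulum under gravity)
  expect_equal(max(tr$theta), 1 * pi / 180, tolerance = 1e-3)
})

test_that("azimuthal symmetry: rotating the problem rotates the solution", {
  p <- cupball_params(theta_esc = 89 * pi / 180)
  beta <- 0.9
  rot <- function(v) c(cos(beta) * v[1] - sin(beta) * v[2],
                       sin(beta) * v[1] + cos(beta) * v[2])
  force <- function(t) c(1.2 * sin(3 * t), 0)
  force_rot <- function(t) rot(force(t))
  tr1 <- simulate_forced(p, sim_state(theta = 0.2, phi = 0.1),
                         force, t_end = 1.5, dt = 1e-3)
  tr2 <- simulate_forced(p, sim_state(theta = 0.2, phi = 0.1 + beta),
                         force_rot, t_end = 1.5, dt = 1e-3)
  b1 <- cbind(tr1$x_b, tr1$y_b)
  b1r <- t(apply(b1, 1, rot))
  expect_lt(max(abs(cbind(tr2$x_b, tr2$y_b) - b1r)), 1e-9)
  c1r <- t(apply(cbind(tr1$x_c, tr1$y_c), 1, rot))
  expect_lt(max(abs(cbind(tr2$x_c, tr2$y_c) - c1r)), 1e-9)
})

test_that("RK4 halving the step shrinks the endpoint error ~16x", {
  p <- cupball_params(theta_esc = 89 * pi / 180)
  force <- function(t) c(0.8 * sin(2 * t), 0.3 * cos(3 * t))
  run <- function(dt) {
    tr <- simulate_forced(p, sim_state(theta = 0.3), force,
                          t_end = 1, dt = dt)
    unlist(tr[nrow(tr), c("x_c", "vx_c", "theta", "dtheta", "phi", "dphi")])
  }
  ref <- run(1e-4 / 4)
  e1 <- max(abs(run(4e-3) - ref))
  e2 <- max(abs(run(2e-3) - ref))
  expect_gt(e1 / e2, 10)   # 4th-order: ~16, allow slack for noise floor
  expect_lt(e1 / e2, 24)
})

test_that("solutions agree with an adaptive reference integrator", {
  skip_if_not_installed("deSolve")
  p <- cupball_params(theta_esc = 89 * pi / 180)
  force <- function(t) c(0.5 * sin(2 * t), 0.2 * cos(t))
  deriv <- function(t, y, parms) {
    list(as.numeric(equations_of_motion(
      stats::setNames(y, c("x_c", "y_c", "vx_c", "vy_c", "theta", "phi",
                           "dtheta", "dphi")), force(t), p)))
  }
  y0 <- sim_state(theta = 0.5, phi = 0.5, dphi = 14)
  ref <- deSolve::ode(unclass(y0), seq(0, 2, by = 0.01), deriv, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  tr <- simulate_forced(p, y0, force, t_end = 2, dt = 1e-3)
  idx <- match(round(ref[, "time"], 6), round(tr$t, 6))
  expect_lt(max(abs(tr$theta[idx] - ref[, "theta"])), 1e-5)
  expect_lt(max(abs(tr$x_c[idx] - ref[, "x_c"])), 1e-5)
})

test_that("escape is flagged at the first threshold crossing", {
  p <- cupball_params(theta_esc = 20 * pi / 180)
  force <- function(t) c(3 * t, 0)   # growing ramp guarantees escape
  tr <- simulate_forced(p, sim_state(), force, t_end = 2, dt = 1e-3)
  et <- attr(tr, "escape_time")
  expect_false(is.na(et))
  i <- which(tr$t == et)
  expect_gte(abs(tr$theta[i]), p$theta_esc)
  expect_true(all(abs(tr$theta[seq_len(i - 1)]) < p$theta_esc))
  expect_true(all(tr$escaped[tr$t >= et]))
  ## halted run freezes the angles from the crossing on
  expect_equal(tr$theta[nrow(tr)], tr$theta[i], tolerance = 1e-12)
  ## continuing run keeps integrating through the threshold
  tr2 <- simulate_forced(p, sim_state(), force, t_end = 2, dt = 1e-3,
                         on_escape = "continue")
  expect_gt(max(abs(tr2$theta)), p$theta_esc + 0.1)
  expect_equal(attr(tr2, "escape_time"), et)
})

test_that("kinematic ball inference is self-consistent and handles rest", {
  p <- cupball_params(theta_esc = 89 * pi / 180)
  ## cup trace taken from a forced run reproduces that run's angles
  trf <- simulate_forced(p, sim_state(theta = 0.3, phi = 0.4, dphi = 2),
                         function(t) c(0.8 * sin(4 * t), 0.3 * cos(3 * t)),
                         t_end = 2, dt = 1e-3)
  trk <- simulate_kinematic(p, data.frame(t = trf$t, x = trf$x_c,
                                          y = trf$y_c),
                            theta0 = 0.3, phi0 = 0.4, dphi0 = 2)
  expect_lt(max(abs(trk$theta - trf$theta)), 0.01)

  ## quasi-static: constant acceleration a deflects by atan(a/g) opposite
  ## the acceleration (with light damping to settle the swing)
  a <- 0.5
  tt <- seq(0, 4, by = 1e-3)
  cup <- data.frame(t = tt, x = 0.5 * a * tt^2, y = 0 * tt)
  pd <- cupball_params(theta_esc = 89 * pi / 180, damping = 3e-4)
  tr <- simulate_kinematic(pd, cup, theta0 = -atan(a / pd$g))
  expect_equal(mean(tail(tr$theta, 300)), -atan(a / pd$g),
               tolerance = 0.05)

  ## gaps in the cup samples are refused
  gap <- data.frame(t = c(0, 0.01, 0.02, 0.2, 0.21, 0.22),
                    x = rep(0, 6), y = rep(0, 6))
  expect_error(simulate_kinematic(p, gap), "gap")
})

test_that("escape geometry matches the spherical-cap rim angle", {
  expect_equal(escape_angle(70, 70), 90)
  expect_equal(escape_angle(70, 0), 0)
  ## a 70 mm dish with a 40 deg rim, rebuilt with doubled curvature
  ## radius and the same aperture, escapes near 19 deg
  aperture <- 70 * sin(40 * pi / 180)
  expect_equal(escape_angle(70, aperture), 40, tolerance = 1e-12)
  flat <- escape_angle(140, aperture)
  expect_equal(flat, asin(0.5 * sin(40 * pi / 180)) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(round(flat), 19)
  expect_error(escape_angle(70, 80), "exceed")
})

test_that("escape margin is the pointwise angular distance to escape", {
  p <- cupball_params(theta_esc = 0.6)
  m0 <- escape_margin(rep(0, 100), p)
  expect_true(all(m0$margin == 0.6))
  expect_false(m0$escaped)

  th <- c(0.1, 0.4, 0.6, 0.2)
  m1 <- escape_margin(th, p)
  expect_equal(m1$min_margin, 0)
  expect_true(m1$escaped)

  ## brute-force linear scan over a simulated trial
  tr <- simulate_forced(p, sim_state(theta = 0.3, dtheta = 1), c(0, 0),
                        t_end = 1, dt = 1e-3, on_escape = "continue")
  m2 <- escape_margin(tr, p)
  brute <- min(sapply(tr$theta, function(x) p$theta_esc - x))
  expect_equal(m2$min_margin, brute)
})

test_that("force profile descriptions parse into functions", {
  expect_equal(parse_force_profile("zero")(1), c(0, 0))
  expect_equal(parse_force_profile("const:fx=2,fy=-1")(5), c(2, -1))
  f <- parse_force_profile("sine:A=2,f=0.5,axis=y")
  expect_equal(f(0.5), c(0, 2 * sin(pi * 0.5)))
  expect_equal(parse_force_profile("ramp:rate=3")(2), c(6, 0))
  expect_error(parse_force_profile("sawtooth:A=1"), "unknown")
})
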