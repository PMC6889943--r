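#' Parameters of the cup-and-ball dynamical model
#'
#' The cup sliding on the board is modelled as a planar cart of mass `m_c`
#' actuated by an external horizontal force; the ball rolling in the
#' spherical dish is modelled as a pendulum bob of mass `m_b` suspended
#' from the cart by a massless rod of length `l` (the effective pendulum
#' length is the dish radius of curvature minus the ball radius). The polar
#' angle `theta` is measured from the downward vertical; the ball escapes
#' the dish when `theta` reaches `theta_esc`.
#'
#' @param m_c Cart (cup) mass, kg.
#' @param m_b Bob (ball) mass, kg. Default 0.067 (a 1-inch steel ball).
#' @param l Pendulum length, m. Default 0.0573: a 70 mm dish radius minus
#'   a 12.7 mm ball radius.
#' @param g Gravitational acceleration, m/s^2.
#' @param theta_esc Escape angle, rad. Default corresponds to a rimless
#'   70 mm dish with a 40 degree rim angle.
#' @param damping Viscous damping coefficient applied to the angular
#'   rates, N m s. Default 0 (conservative model).
#' @param rolling Logical; if `TRUE`, multiply the bob's effective inertia
#'   by 7/5 to account for the rolling of a solid sphere. Off by default:
#'   the reference model treats the ball as a point bob.
#' @return An object of class `cupball_params`.
#' @examples
#' cupball_params()
#' @export
cupball_params <- function(m_c = 0.2, m_b = 0.067, l = 0.0573, g = 9.81,
                           theta_esc = 40 * pi / 180, damping = 0,
                           rolling = FALSE) {
  stopifnot(m_c > 0, m_b > 0, l > 0, g > 0,
            theta_esc > 0, theta_esc < pi / 2, damping >= 0)
  structure(list(m_c = m_c, m_b = m_b, l = l, g = g, theta_esc = theta_esc,
                 damping = damping, rolling = isTRUE(rolling)),
            class = "cupball_params")
}

#' @export
print.cupball_params <- function(x, ...) {
  cat(sprintf(
    "Cup-and-ball model: m_c=%.3g kg, m_b=%.3g kg, l=%.4g m, g=%.3g m/s^2\n",
    x$m_c, x$m_b, x$l, x$g))
  cat(sprintf("  escape angle %.2f deg, damping %.3g N m s%s\n",
              x$theta_esc * 180 / pi, x$damping,
              if (x$rolling) ", rolling-sphere inertia (7/5)" else ""))
  invisible(x)
}

#' Model state vector
#'
#' Generalized coordinates of the cart-and-spherical-pendulum system:
#' cart position and velocity on the board plane, and the pendulum angles.
#' `theta` is the polar angle from the downward vertical (negative z axis),
#' `phi` the azimuth from the positive x axis. The bob position in the
#' world frame is `x_b = x_c + l sin(theta) cos(phi)`,
#' `y_b = y_c + l sin(theta) sin(phi)`, `z_b = -l cos(theta)`.
#'
#' @param x_c,y_c Cart position, m.
#' @param vx_c,vy_c Cart velocity, m/s.
#' @param theta Polar angle, rad, in `[0, pi)`.
#' @param phi Azimuth, rad.
#' @param dtheta,dphi Angular rates, rad/s.
#' @return Named numeric state vector of class `sim_state`.
#' @export
sim_state <- function(x_c = 0, y_c = 0, vx_c = 0, vy_c = 0,
                      theta = 0, phi = 0, dtheta = 0, dphi = 0) {
  stopifnot(theta >= 0, theta < pi)
  structure(c(x_c = x_c, y_c = y_c, vx_c = vx_c, vy_c = vy_c,
              theta = theta, phi = phi, dtheta = dtheta, dphi = dphi),
            class = "sim_state")
}

#' Bob position for a given state
#'
#' @param state A `sim_state` (or plain named vector with the same names).
#' @param params A `cupball_params`.
#' @return Named vector `(x_b, y_b, z_b)` in m (z measured from the
#'   suspension point, downward negative).
#' @export
ball_position <- function(state, params) {
  l <- params$l
  st <- sin(state[["theta"]]); ct <- cos(state[["theta"]])
  c(x_b = state[["x_c"]] + l * st * cos(state[["phi"]]),
    y_b = state[["y_c"]] + l * st * sin(state[["phi"]]),
    z_b = -l * ct)
}

## |sin(theta)| below which the azimuth is treated as undefined and the
## phi equation is frozen for the evaluation (spherical-coordinate
## singularity at the hanging state). Near a planar zero crossing the
## azimuthal rate obeys dphi ~ 1/sin(theta)^2 (conservation of the
## vertical angular momentum), with local growth rate 2*cot(theta)*dtheta
## that exceeds the stability limit of an explicit integrator; freezing
## once |sin(theta)| < 0.01 keeps that rate bounded at millisecond steps
## while only suppressing angular momenta that are physically negligible
## (|theta| < 0.6 deg).
.SIN_THETA_EPS <- 1e-2

#' Equations of motion of the cart and spherical pendulum
#'
#' Time derivative of the state under an external horizontal force applied
#' to the cart. The dynamics follow from the Lagrangian of a planar cart
#' of mass `m_c` with a spherical pendulum (mass `m_b`, length `l`)
#' suspended from it: with generalized coordinates
#' `q = (x_c, y_c, theta, phi)` the mass matrix has entries
#' `M[1,1] = M[2,2] = m_c + m_b`,
#' `M[1,3] = m_b l cos(theta) cos(phi)`, `M[1,4] = -m_b l sin(theta) sin(phi)`,
#' `M[2,3] = m_b l cos(theta) sin(phi)`, `M[2,4] = m_b l sin(theta) cos(phi)`,
#' `M[3,3] = m_b l^2`, `M[4,4] = m_b l^2 sin(theta)^2`, `M[3,4] = 0`,
#' and the equations `M qdd = Q - grad(V) - m_b J' (Jdot qd)` are solved
#' for the accelerations at every evaluation (`J` is the Jacobian of the
#' bob position with respect to `q`; the identity
#' `Mdot qd - grad_q T = m_b J' (Jdot qd)` for kinetic energies of the
#' form `T = qd' M(q) qd / 2` removes the need for explicit Christoffel
#' symbols). Optional viscous damping contributes generalized torques
#' `-damping * dtheta` and `-damping * sin(theta)^2 * dphi`.
#'
#' At the coordinate singularity `sin(theta) ~ 0` the azimuth is
#' undefined; `dphi` is held and its equation skipped for that evaluation.
#'
#' @param state A `sim_state` or named numeric vector.
#' @param force Length-2 numeric, horizontal force `(F_x, F_y)` on the
#'   cart, N.
#' @param params A `cupball_params`.
#' @return Named numeric vector of the 8 state derivatives.
#' @examples
#' p <- cupball_params()
#' equations_of_motion(sim_state(), c(0, 0), p)  # hanging equilibrium
#' @export
equations_of_motion <- function(state, force, params) {
  s <- unclass(state)
  th <- s[["theta"]]; ph <- s[["phi"]]
  dth <- s[["dtheta"]]; dph <- s[["dphi"]]
  m_c <- params$m_c; m_b <- params$m_b; l <- params$l; g <- params$g
  kin <- if (params$rolling) 7 / 5 else 1  # rolling-sphere inertia factor

  st <- sin(th); ct <- cos(th); cp <- cos(ph); sp <- sin(ph)
  singular <- abs(st) < .SIN_THETA_EPS

  ## Jacobian columns of the bob position wrt (x_c, y_c, theta, phi)
  a1 <- l * ct * cp; a2 <- -l * st * sp
  b1 <- l * ct * sp; b2 <- l * st * cp

  ## Jdot %*% qd: bob acceleration terms independent of qdd
  jx <- -l * ((dth^2 + dph^2) * st * cp + 2 * dth * dph * ct * sp)
  jy <- -l * ((dth^2 + dph^2) * st * sp - 2 * dth * dph * ct * cp)
  jz <- l * dth^2 * ct

  if (singular) {
    ## 3x3 system in (ax, ay, ddtheta); phi frozen
    m <- rbind(c(m_c + m_b, 0, m_b * a1),
               c(0, m_c + m_b, m_b * b1),
               c(m_b * a1, m_b * b1, kin * m_b * l^2))
    rhs <- c(force[1] - m_b * jx,
             force[2] - m_b * jy,
             -m_b * (a1 * jx + b1 * jy + l * st * jz) -
               m_b * g * l * st - params$damping * dth)
    acc <- solve(m, rhs)
    ddph <- 0
  } else {
    m <- rbind(c(m_c + m_b, 0, m_b * a1, m_b * a2),
               c(0, m_c + m_b, m_b * b1, m_b * b2),
               c(m_b * a1, m_b * b1, kin * m_b * l^2, 0),
               c(m_b * a2, m_b * b2, 0, kin * m_b * l^2 * st^2))
    rhs <- c(force[1] - m_b * jx,
             force[2] - m_b * jy,
             -m_b * (a1 * jx + b1 * jy + l * st * jz) -
               m_b * g * l * st - params$damping * dth,
             -m_b * (a2 * jx + b2 * jy) - params$damping * st^2 * dph)
    acc <- solve(m, rhs)
    ddph <- acc[4]
  }
  c(x_c = s[["vx_c"]], y_c = s[["vy_c"]],
    vx_c = acc[1], vy_c = acc[2],
    theta = dth, phi = if (singular) 0 else dph,
    dtheta = acc[3], dphi = ddph)
}

#' Mechanical energy of a state
#'
#' Kinetic plus gravitational potential energy of cart and bob; conserved
#' when force and damping are zero. Used by the simulator's verification
#' tests.
#'
#' @inheritParams equations_of_motion
#' @return Energy in joules (potential zero at `theta = pi/2`).
#' @export
total_energy <- function(state, params) {
  s <- unclass(state)
  th <- s[["theta"]]; ph <- s[["phi"]]
  dth <- s[["dtheta"]]; dph <- s[["dphi"]]
  l <- params$l
  kin <- if (params$rolling) 7 / 5 else 1
  vxb <- s[["vx_c"]] + l * (dth * cos(th) * cos(ph) - dph * sin(th) * sin(ph))
  vyb <- s[["vy_c"]] + l * (dth * cos(th) * sin(ph) + dph * sin(th) * cos(ph))
  vzb <- l * dth * sin(th)
  extra <- (kin - 1) * 0.5 * params$m_b * l^2 * (dth^2 + dph^2 * sin(th)^2)
  0.5 * params$m_c * (s[["vx_c"]]^2 + s[["vy_c"]]^2) +
    0.5 * params$m_b * (vxb^2 + vyb^2 + vzb^2) + extra -
    params$m_b * params$g * l * cos(th)
}

## One classical RK4 step of f over dt.
.rk4_step <- function(f, y, t, dt) {
  k1 <- f(y, t)
  k2 <- f(y + dt / 2 * k1, t + dt / 2)
  k3 <- f(y + dt / 2 * k2, t + dt / 2)
  k4 <- f(y + dt * k3, t + dt)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate the forced cup-and-ball system
#'
#' Integrates the equations of motion with a fixed-step classical
#' Runge-Kutta (RK4) scheme under a time-varying horizontal force applied
#' to the cart. The first sample at which `theta >= theta_esc` is flagged
#' as the ball escape; by default the angular states are frozen from that
#' sample on (`on_escape = "halt"`), or the integration can continue
#' through the threshold (`on_escape = "continue"`).
#'
#' @param params A `cupball_params`.
#' @param initial A `sim_state`.
#' @param force Either a function `t -> c(F_x, F_y)` in newtons, or a
#'   length-2 constant force.
#' @param t_end Simulation end time, s.
#' @param dt Time step, s.
#' @param on_escape `"halt"` (freeze the angular states at escape) or
#'   `"continue"`.
#' @return A data.frame of class `sim_trajectory` with columns `t`, the 8
#'   state components, derived bob positions `x_b`, `y_b`, `z_b` and a
#'   logical `escaped`; attribute `escape_time` (NA if no escape).
#' @examples
#' p <- cupball_params()
#' tr <- simulate_forced(p, sim_state(theta = 0.2), c(0, 0),
#'                       t_end = 1, dt = 0.001)
#' range(tr$theta)
#' @export
simulate_forced <- function(params, initial, force, t_end, dt,
                            on_escape = c("halt", "continue")) {
  stopifnot(inherits(params, "cupball_params"), dt > 0, t_end > 0)
  on_escape <- match.arg(on_escape)
  f_fun <- if (is.function(force)) force else function(t) force
  deriv <- function(y, t) equations_of_motion(y, f_fun(t), params)

  times <- seq(0, t_end, by = dt)
  n <- length(times)
  y <- unclass(initial)
  out <- matrix(NA_real_, n, 8, dimnames = list(NULL, names(y)))
  out[1, ] <- y
  escaped_at <- NA_real_
  frozen <- FALSE
  for (i in seq_len(n - 1)) {
    if (frozen) {
      ## cart continues under the external force alone; angles frozen
      cart <- function(y2, t) {
        fr <- f_fun(t)
        c(x_c = y2[["vx_c"]], y_c = y2[["vy_c"]],
          vx_c = fr[1] / params$m_c, vy_c = fr[2] / params$m_c,
          theta = 0, phi = 0, dtheta = 0, dphi = 0)
      }
      y <- .rk4_step(cart, y, times[i], dt)
    } else {
      y <- .rk4_step(deriv, y, times[i], dt)
    }
    if (!all(is.finite(y)))
      stop(sprintf("non-finite state at step %d (t = %.6g s)", i, times[i + 1]))
    if (!frozen && is.na(escaped_at) && abs(y[["theta"]]) >= params$theta_esc) {
      escaped_at <- times[i + 1]
      if (on_escape == "halt") {
        y[["dtheta"]] <- 0; y[["dphi"]] <- 0
        frozen <- TRUE
      }
    }
    out[i + 1, ] <- y
  }
  l <- params$l
  st <- sin(out[, "theta"])
  traj <- data.frame(t = times, out,
                     x_b = out[, "x_c"] + l * st * cos(out[, "phi"]),
                     y_b = out[, "y_c"] + l * st * sin(out[, "phi"]),
                     z_b = -l * cos(out[, "theta"]),
                     escaped = !is.na(escaped_at) & times >= escaped_at)
  attr(traj, "escape_time") <- escaped_at
  attr(traj, "params") <- params
  class(traj) <- c("sim_trajectory", "data.frame")
  traj
}

#' Infer ball angles from measured cup motion
#'
#' Integrates only the pendulum equations with the cart acceleration
#' prescribed by a measured (filtered) cup trajectory, obtained by central
#' finite differencing. This is how ball state and safety margins are
#' estimated from tracked sessions in which only the cup is measured
#' reliably.
#'
#' @param params A `cupball_params`.
#' @param cup_motion Data frame with columns `t` (s, uniformly sampled)
#'   and `x`, `y` (cup position, m).
#' @param theta0,phi0,dtheta0,dphi0 Initial pendulum state.
#' @param on_escape As in [simulate_forced()].
#' @param max_gap Maximum tolerated sampling gap, in multiples of the
#'   median sampling interval (default 3); larger gaps are an error.
#' @param dt_int Internal integration step, s (default 1 ms). The cup is
#'   typically sampled at video rate, far too coarse for the pendulum
#'   dynamics, so each sample interval is integrated in substeps with the
#'   cart acceleration interpolated linearly.
#' @return A `sim_trajectory` data frame (cart columns echo the input).
#' @export
simulate_kinematic <- function(params, cup_motion, theta0 = 0, phi0 = 0,
                               dtheta0 = 0, dphi0 = 0,
                               on_escape = c("halt", "continue"),
                               max_gap = 3, dt_int = 1e-3) {
  stopifnot(inherits(params, "cupball_params"),
            all(c("t", "x", "y") %in% names(cup_motion)))
  on_escape <- match.arg(on_escape)
  tt <- cup_motion$t
  n <- length(tt)
  if (n < 5) stop("cup motion too short to differentiate")
  dtv <- diff(tt)
  dt <- median(dtv)
  if (any(dtv > max_gap * dt))
    stop(sprintf("sampling gap of %.4g s exceeds %g frames", max(dtv), max_gap))

  ## central second differences; one-sided copies at the ends
  ax <- ay <- numeric(n)
  ax[2:(n - 1)] <- (cup_motion$x[3:n] - 2 * cup_motion$x[2:(n - 1)] +
                      cup_motion$x[1:(n - 2)]) / dt^2
  ay[2:(n - 1)] <- (cup_motion$y[3:n] - 2 * cup_motion$y[2:(n - 1)] +
                      cup_motion$y[1:(n - 2)]) / dt^2
  ax[1] <- ax[2]; ax[n] <- ax[n - 1]
  ay[1] <- ay[2]; ay[n] <- ay[n - 1]
  acc_fun <- function(t) {
    ## linear interpolation so RK4 mid-stage evaluations see a smooth input
    u <- min(max(t / dt, 0), n - 1)
    i0 <- floor(u); fr <- u - i0
    i0 <- i0 + 1; i1 <- min(i0 + 1, n)
    c((1 - fr) * ax[i0] + fr * ax[i1], (1 - fr) * ay[i0] + fr * ay[i1])
  }

  m_b <- params$m_b; l <- params$l; g <- params$g
  kin <- if (params$rolling) 7 / 5 else 1
  deriv <- function(y, t) {
    th <- y[[1]]; ph <- y[[2]]; dth <- y[[3]]; dph <- y[[4]]
    st <- sin(th); ct <- cos(th); cp <- cos(ph); sp <- sin(ph)
    a <- acc_fun(t)
    ## angular block of the full system with prescribed cart acceleration
    ddth <- (-(ct * cp) * a[1] / l - (ct * sp) * a[2] / l +
               dph^2 * st * ct - (g / l) * st) / kin -
      params$damping * dth / (kin * m_b * l^2)
    if (abs(st) < .SIN_THETA_EPS) {
      ddph <- 0; dph_eff <- 0
    } else {
      ddph <- ((st * sp) * a[1] - (st * cp) * a[2] -
                 2 * l * dth * dph * ct * st) / (kin * l * st^2) -
        params$damping * dph / (kin * m_b * l^2)
      dph_eff <- dph
    }
    c(dth, dph_eff, ddth, ddph)
  }

  y <- c(theta0, phi0, dtheta0, dphi0)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("theta", "phi", "dtheta", "dphi")))
  out[1, ] <- y
  escaped_at <- NA_real_
  frozen <- FALSE
  n_sub <- max(1L, ceiling(dt / dt_int))
  h <- dt / n_sub
  for (i in seq_len(n - 1)) {
    if (!frozen) {
      t0 <- tt[i] - tt[1]
      for (k in seq_len(n_sub)) {
        y <- .rk4_step(deriv, y, t0 + (k - 1) * h, h)
        if (frozen) break
        if (is.na(escaped_at) && abs(y[1]) >= params$theta_esc) {
          escaped_at <- tt[i + 1]
          if (on_escape == "halt") { y[3] <- 0; y[4] <- 0; frozen <- TRUE }
        }
      }
      if (!all(is.finite(y)))
        stop(sprintf("non-finite state at step %d", i))
    }
    out[i + 1, ] <- y
  }
  st <- sin(out[, "theta"])
  traj <- data.frame(t = tt,
                     x_c = cup_motion$x, y_c = cup_motion$y,
                     vx_c = c(diff(cup_motion$x) / dtv, NA),
                     vy_c = c(diff(cup_motion$y) / dtv, NA),
                     out,
                     x_b = cup_motion$x + l * st * cos(out[, "phi"]),
                     y_b = cup_motion$y + l * st * sin(out[, "phi"]),
                     z_b = -l * cos(out[, "theta"]),
                     escaped = !is.na(escaped_at) & tt >= escaped_at)
  attr(traj, "escape_time") <- escaped_at
  attr(traj, "params") <- params
  class(traj) <- c("sim_trajectory", "data.frame")
  traj
}

#' Escape angle of a spherical dish
#'
#' Rim angle from the vertical of a spherical-cap dish: the polar angle at
#' which a ball rolling in a dish of the given radius of curvature reaches
#' the dish aperture, `asin(aperture / curvature_radius)`. Doubling the
#' radius of curvature at a fixed aperture roughly halves the sine of the
#' escape angle, which is how flatter dishes make the task harder.
#'
#' @param curvature_radius_mm Dish radius of curvature, mm.
#' @param aperture_radius_mm Aperture (rim) radius, mm.
#' @return Escape angle in degrees.
#' @examples
#' escape_angle(70, 70 * sin(40 * pi / 180))   # 40 deg dish
#' escape_angle(140, 70 * sin(40 * pi / 180))  # flatter dish, ~19 deg
#' @export
escape_angle <- function(curvature_radius_mm, aperture_radius_mm) {
  stopifnot(curvature_radius_mm > 0, aperture_radius_mm >= 0)
  if (any(aperture_radius_mm > curvature_radius_mm))
    stop("aperture radius cannot exceed the radius of curvature")
  asin(aperture_radius_mm / curvature_radius_mm) * 180 / pi
}

#' Angular escape margin of a trial
#'
#' Instantaneous safety margin of the ball, defined here as the angular
#' distance to the escape condition,
#' `margin(t) = theta_esc - |theta(t)|` (the simulators use a signed
#' planar chart in which negative `theta` means deflection at azimuth
#' `phi + pi`, so the physical polar angle is `|theta|`). The minimum over
#' the trial summarizes how close the ball came to escaping; a
#' non-positive minimum means the ball escaped.
#'
#' @param theta_series Numeric vector of polar angles, rad (or a
#'   `sim_trajectory`, whose `theta` column is used).
#' @param params A `cupball_params`.
#' @return List with `margin` (vector, rad), `min_margin` (rad) and
#'   `escaped` (logical).
#' @export
escape_margin <- function(theta_series, params) {
  if (inherits(theta_series, "sim_trajectory"))
    theta_series <- theta_series$theta
  stopifnot(all(is.finite(theta_series)))
  m <- params$theta_esc - abs(theta_series)
  list(margin = m, min_margin = min(m), escaped = min(m) <= 0)
}

#' Parse a force-profile description
#'
#' Small helper for configuration files and the command line. Supported
#' forms: `"zero"`, `"const:fx=..,fy=.."`, `"sine:A=..,f=..[,axis=x|y]"`,
#' `"ramp:rate=..[,axis=x|y]"`.
#'
#' @param text Profile description string.
#' @return Function of time returning `c(F_x, F_y)`.
#' @export
parse_force_profile <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  kv <- list()
  if (length(parts) > 1) {
    for (item in strsplit(parts[2], ",", fixed = TRUE)[[1]]) {
      p <- strsplit(item, "=", fixed = TRUE)[[1]]
      kv[[p[1]]] <- p[2]
    }
  }
  num <- function(name, default = 0)
    if (!is.null(kv[[name]])) as.numeric(kv[[name]]) else default
  axis_vec <- function() if (identical(kv[["axis"]], "y")) c(0, 1) else c(1, 0)
  switch(kind,
    zero = function(t) c(0, 0),
    const = function(t) c(num("fx"), num("fy")),
    sine = {
      a <- num("A", 1); fr <- num("f", 1); ax <- axis_vec()
      function(t) a * sin(2 * pi * fr * t) * ax
    },
    ramp = {
      r <- num("rate", 1); ax <- axis_vec()
      function(t) r * t * ax
    },
    stop("unknown force profile: ", kind))
}
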