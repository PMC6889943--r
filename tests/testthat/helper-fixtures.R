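# Shared fixtures: a small default scene, matched colour profiles, and an
# independently derived planar cart-pendulum oracle used to validate the
# spherical model in its planar restriction.

fixture_scene <- function(...) scene_spec(...)

fixture_profiles <- function(scene = fixture_scene()) default_profiles(scene)

# Planar cart-pendulum (1 DOF pendulum on a driven cart), derived directly
# from the textbook equations (theta measured from the downward vertical):
#   (m_c + m_b) xdd + m_b l (thdd cos th - thd^2 sin th) = F
#   l thdd + xdd cos th + g sin th = 0
# Solved as a 2x2 linear system per evaluation. Independent of the
# package's Lagrangian mass-matrix formulation.
planar_cart_pendulum_deriv <- function(x, vx, th, dth, F, p) {
  A <- rbind(c(p$m_c + p$m_b, p$m_b * p$l * cos(th)),
             c(cos(th), p$l))
  b <- c(F + p$m_b * p$l * dth^2 * sin(th), -p$g * sin(th))
  acc <- solve(A, b)
  list(ddx = acc[1], ddth = acc[2])
}

# Brute-force k x k binary morphology (pixelwise min/max over the window),
# the oracle for morph_clean.
brute_morph <- function(mask, k, op = c("erode", "dilate")) {
  op <- match.arg(op)
  half <- (k - 1) %/% 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - half):min(nr, i + half)
    ci <- max(1, j - half):min(nc, j + half)
    win <- mask[ri, ci]
    ## pixels outside the image are background (0)
    full <- length(ri) == k && length(ci) == k
    out[i, j] <- if (op == "erode") as.numeric(all(win == 1) && full)
                 else as.numeric(any(win == 1))
  }
  out
}

# Hand-evaluated hexcone RGB -> HSV for a single pixel (reference formula).
reference_hsv <- function(r, g, b) {
  v <- max(r, g, b); mn <- min(r, g, b); d <- v - mn
  s <- if (v > 0) d / v else 0
  h <- if (d == 0) 0
  else if (v == r) 60 * (((g - b) / d) %% 6)
  else if (v == g) 60 * ((b - r) / d + 2)
  else 60 * ((r - g) / d + 4)
  c(h, s, v)
}
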