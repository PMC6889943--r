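## "Ink" mask: pixels whose colour differs from the estimated board
## background (per-channel median) by more than `thresh` in RGB distance.
.ink_mask <- function(frame, thresh = 0.18) {
  bg <- apply(frame, 3, median)
  d2 <- (frame[, , 1] - bg[1])^2 + (frame[, , 2] - bg[2])^2 +
    (frame[, , 3] - bg[3])^2
  m <- d2 > thresh^2
  mode(m) <- "numeric"
  m
}

## Edge pixels of a binary mask (mask minus its erosion).
.edge_pixels <- function(mask) {
  er <- EBImage::erode(mask, EBImage::makeBrush(3, "box"))
  which(mask > 0 & er == 0, arr.ind = TRUE)   # (row, col)
}

## Kasa algebraic circle fit; returns c(cx, cy, r) or NULL.
.fit_circle <- function(x, y) {
  if (length(x) < 3) return(NULL)
  a <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(a, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) return(NULL)
  c(sol[1], sol[2], sqrt(r2))
}

## Circular Hough transform on edge pixels. Returns data.frame
## (cx_px, cy_px, r_px, score) of accepted peaks, score = votes
## normalized by the circle circumference.
.hough_circles <- function(edges, dim_hw, r_range_px, bin_px = 2,
                           min_score = 0.45) {
  if (nrow(edges) == 0) return(NULL)
  h <- dim_hw[1]; w <- dim_hw[2]
  nbr <- ceiling(h / bin_px); nbc <- ceiling(w / bin_px)
  radii <- seq(r_range_px[1], r_range_px[2], by = bin_px)
  eu <- edges[, 2]; ev <- edges[, 1]
  found <- list()
  for (r in radii) {
    nang <- max(16, ceiling(2 * pi * r / bin_px))
    ang <- seq(0, 2 * pi, length.out = nang + 1)[-1]
    cu <- rep(eu, times = nang) - rep(r * cos(ang), each = length(eu))
    cv <- rep(ev, times = nang) - rep(r * sin(ang), each = length(eu))
    ok <- cu >= 1 & cu <= w & cv >= 1 & cv <= h
    bu <- ceiling(cu[ok] / bin_px); bv <- ceiling(cv[ok] / bin_px)
    votes <- tabulate(bu + (bv - 1) * nbc, nbins = nbr * nbc)
    ## expected votes for a full circle of this radius ~ its edge count
    norm <- votes / (2 * pi * r)
    peaks <- which(norm >= min_score)
    if (length(peaks) > 0) {
      ord <- peaks[order(norm[peaks], decreasing = TRUE)]
      for (p in ord) {
        pu <- ((p - 1) %% nbc + 0.5) * bin_px
        pv <- ((p - 1) %/% nbc + 0.5) * bin_px
        found[[length(found) + 1]] <-
          data.frame(cx_px = pu, cy_px = pv, r_px = r, score = norm[p])
      }
    }
  }
  if (length(found) == 0) return(NULL)
  do.call(rbind, found)
}

#' Detect drawn circular targets
#'
#' Finds circular targets drawn on the board: the frame is thresholded
#' against the estimated board background, boundary pixels vote in a
#' circular Hough accumulator over a configurable radius range, and each
#' accepted peak is refined with an algebraic circle fit of the nearby
#' boundary pixels, in board coordinates. Duplicates (centre distance
#' below half a radius) are merged; circles are returned ordered by area,
#' largest first. An empty list — not an error — is returned when no
#' circle is found.
#'
#' @param frame `[H, W, 3]` RGB array.
#' @param map A `planar_map`.
#' @param r_range_mm Radius search range, mm (default 40-120).
#' @param bin_px Hough accumulator bin size, px.
#' @param min_score Minimum normalized vote fraction (1 = full outline
#'   present).
#' @param ink_thresh RGB distance from the board background counting as
#'   drawn ink.
#' @return List of [target_circle()]s in board mm.
#' @export
detect_targets <- function(frame, map, r_range_mm = c(40, 120), bin_px = 2,
                           min_score = 0.45, ink_thresh = 0.18) {
  mask <- .ink_mask(frame, ink_thresh)
  mask <- morph_clean(mask)
  edges <- .edge_pixels(mask)
  if (nrow(edges) == 0) return(list())
  s <- mm_per_pixel(map)
  cand <- .hough_circles(edges, dim(mask)[1:2], r_range_mm / s, bin_px,
                         min_score)
  if (is.null(cand)) return(list())

  ## greedy non-max suppression in pixel space
  cand <- cand[order(cand$score, decreasing = TRUE), ]
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    ci <- cand[i, ]
    dup <- any(vapply(kept, function(k)
      sqrt((k$cx_px - ci$cx_px)^2 + (k$cy_px - ci$cy_px)^2) <
        max(k$r_px, ci$r_px) / 2, logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- ci
  }

  ## refine each peak: circle fit in board mm on nearby edge pixels
  eu <- edges[, 2] - 0.5; ev <- edges[, 1] - 0.5
  out <- list()
  for (k in kept) {
    d <- sqrt((eu - k$cx_px)^2 + (ev - k$cy_px)^2)
    near <- abs(d - k$r_px) <= max(3, bin_px + 1)
    if (sum(near) < 6) next
    mm <- pixel_to_board(map, cbind(eu[near], ev[near]))
    fit <- .fit_circle(mm[, 1], mm[, 2])
    if (is.null(fit)) next
    out[[length(out) + 1]] <- target_circle(fit[1], fit[2], fit[3])
  }
  if (length(out) == 0) return(list())

  ## merge duplicates in mm, order by area descending
  merged <- list()
  for (tg in out) {
    dup <- FALSE
    for (m in merged) {
      if (sqrt((m$cx_mm - tg$cx_mm)^2 + (m$cy_mm - tg$cy_mm)^2) <
          max(m$r_mm, tg$r_mm) / 2) { dup <- TRUE; break }
    }
    if (!dup) merged[[length(merged) + 1]] <- tg
  }
  merged[order(vapply(merged, function(tg) tg$r_mm, numeric(1)),
               decreasing = TRUE)]
}

## Moore boundary tracing of one labelled component; returns (row, col)
## matrix of ordered boundary pixel centres (1-based, offset -0.5).
.trace_boundary <- function(lab, k) {
  oc <- EBImage::ocontour(EBImage::Image(lab == k))
  if (length(oc) == 0) return(NULL)
  b <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  ## EBImage images index [x, y]; here the matrix is [row, col] so
  ## ocontour's first coordinate is the row index (0-based)
  cbind(row = b[, 1] + 0.5, col = b[, 2] + 0.5)
}

## Ramer-Douglas-Peucker polyline simplification on a closed contour.
.rdp <- function(pts, eps) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack) > 0) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    seg <- (i + 1):(j - 1)
    d <- if (len < 1e-12) sqrt(rowSums(sweep(pts[seg, , drop = FALSE], 2, a)^2))
    else abs(ab[2] * (pts[seg, 1] - a[1]) - ab[1] * (pts[seg, 2] - a[2])) / len
    mx <- which.max(d)
    if (d[mx] > eps) {
      m <- seg[mx]
      keep[m] <- TRUE
      stack[[length(stack) + 1]] <- c(i, m)
      stack[[length(stack) + 1]] <- c(m, j)
    }
  }
  pts[keep, , drop = FALSE]
}

#' Detect drawn polygonal obstacles
#'
#' Finds drawn shapes that are not circles: connected components of the
#' ink mask are boundary-traced, simplified with the Ramer-Douglas-Peucker
#' algorithm (tolerance a fraction of the contour perimeter), and
#' components whose simplified outline has few vertices are returned as
#' polygons in board mm. Components classified as circles (many residual
#' vertices and a good circle fit) are left to [detect_targets()]. An
#' empty list is allowed.
#'
#' @param frame `[H, W, 3]` RGB array.
#' @param map A `planar_map`.
#' @param tol_frac RDP tolerance as a fraction of the contour perimeter
#'   (default 0.02).
#' @param max_vertices Simplified outlines with more vertices than this
#'   are treated as curved (circle-like) and skipped.
#' @param min_area_px Minimum component area.
#' @param ink_thresh As in [detect_targets()].
#' @return List of vertex matrices (columns x_mm, y_mm).
#' @export
detect_obstacles <- function(frame, map, tol_frac = 0.02, max_vertices = 8,
                             min_area_px = 200, ink_thresh = 0.18) {
  mask <- .ink_mask(frame, ink_thresh)
  ## no morphological opening here: it rounds polygon corners; speckle is
  ## rejected by the component area filter instead
  lab <- EBImage::bwlabel(mask)
  nk <- max(lab)
  if (nk == 0) return(list())
  areas <- tabulate(lab[lab > 0], nbins = nk)
  out <- list()
  for (k in which(areas >= min_area_px)) {
    b <- .trace_boundary(lab, k)
    if (is.null(b) || nrow(b) < 8) next
    ## near-circular outlines belong to detect_targets, not here
    cf <- .fit_circle(b[, 2], b[, 1])
    if (!is.null(cf)) {
      rad <- sqrt((b[, 2] - cf[1])^2 + (b[, 1] - cf[2])^2)
      if (stats::sd(rad) / cf[3] < 0.04) next
    }
    perim <- sum(sqrt(rowSums(diff(rbind(b, b[1, ]))^2)))
    ## close the contour for simplification by repeating the first point
    closed <- rbind(b, b[1, ])
    simp <- .rdp(closed, eps = tol_frac * perim)
    nv <- nrow(simp) - 1
    if (nv < 3 || nv > max_vertices) next    # curved outline: not a polygon
    ## drop collinear leftovers and convert (col, row) px -> mm
    verts_px <- cbind(simp[seq_len(nv), 2], simp[seq_len(nv), 1])
    mm <- pixel_to_board(map, verts_px)
    colnames(mm) <- c("x_mm", "y_mm")
    out[[length(out) + 1]] <- mm
  }
  out
}
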