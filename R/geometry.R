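#' Board geometry specification
#'
#' Describes the physical board and the camera image it is observed with.
#' The board frame has its origin at the board corner nearest the image
#' origin, x along the long side, y along the short side (y increases
#' downward in the registered view), units millimetres.
#'
#' @param width_mm Length of the long side in mm (default 914, a
#'   91.4 x 60.9 cm whiteboard).
#' @param height_mm Length of the short side in mm (default 609).
#' @param image_width_px,image_height_px Camera image size in pixels
#'   (default 640 x 480).
#' @return An object of class `board_spec`.
#' @examples
#' board_spec()
#' @export
board_spec <- function(width_mm = 914, height_mm = 609,
                       image_width_px = 640L, image_height_px = 480L) {
  stopifnot(width_mm > height_mm, height_mm > 0,
            image_width_px > 0, image_height_px > 0)
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px)),
            class = "board_spec")
}

#' @export
print.board_spec <- function(x, ...) {
  cat(sprintf("Board %g x %g mm imaged at %d x %d px (pixel pitch %.2f x %.2f mm)\n",
              x$width_mm, x$height_mm, x$image_width_px, x$image_height_px,
              x$width_mm / x$image_width_px, x$height_mm / x$image_height_px))
  invisible(x)
}

## Hartley-style normalization: centroid at origin, mean distance sqrt(2).
.normalize_points <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  t_mat <- rbind(c(s, 0, -s * ctr[1]),
                 c(0, s, -s * ctr[2]),
                 c(0, 0, 1))
  list(T = t_mat, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
}

#' Fit the pixel-to-board projective transform
#'
#' Estimates the 3x3 planar homography mapping image pixels to board
#' millimetres from matched point pairs, by normalized direct linear
#' transform solved as overdetermined least squares. The canonical
#' registration protocol uses five points: the four corners of the
#' rectangular field of view matched to the board corners, plus the crossing
#' of the diagonals matched to the board centre.
#'
#' @param image_points n x 2 matrix of pixel coordinates (n >= 4).
#' @param board_points n x 2 matrix of the corresponding board coordinates
#'   in mm.
#' @return An object of class `planar_map` with elements `matrix` (3x3,
#'   pixel to mm, normalized so that `matrix[3,3] == 1`), `inverse`,
#'   `residual_mm` (RMS reprojection error in mm) and the point pairs used.
#' @examples
#' img <- rbind(c(0, 0), c(640, 0), c(640, 480), c(0, 480), c(320, 240))
#' brd <- rbind(c(0, 0), c(914, 0), c(914, 609), c(0, 609), c(457, 304.5))
#' m <- fit_planar_map(img, brd)
#' pixel_to_board(m, c(320, 240))
#' @export
fit_planar_map <- function(image_points, board_points) {
  image_points <- as.matrix(image_points)
  board_points <- as.matrix(board_points)
  n <- nrow(image_points)
  if (n < 4 || nrow(board_points) != n || ncol(image_points) != 2 ||
      ncol(board_points) != 2)
    stop("need at least 4 matched point pairs, given as n x 2 matrices")
  if (anyDuplicated(round(image_points, 9)) ||
      anyDuplicated(round(board_points, 9)))
    stop("degenerate configuration: coincident points")

  ni <- .normalize_points(image_points)
  nb <- .normalize_points(board_points)
  u <- ni$p[, 1]; v <- ni$p[, 2]
  x <- nb$p[, 1]; y <- nb$p[, 2]
  a <- matrix(0, 2 * n, 9)
  a[seq(1, 2 * n, 2), ] <- cbind(u, v, 1, 0, 0, 0, -x * u, -x * v, -x)
  a[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, u, v, 1, -y * u, -y * v, -y)
  sv <- svd(a)
  ## Rank < 8 means the correspondences do not pin down the 8 DOF
  ## (e.g. collinear points).
  if (sv$d[8] < 1e-9 * sv$d[1])
    stop("degenerate configuration: points do not determine a projective map ",
         "(collinear or near-collinear)")
  h <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  h <- solve(nb$T) %*% h %*% ni$T
  if (abs(h[3, 3]) < 1e-12 * max(abs(h)))
    stop("degenerate configuration: ill-conditioned homography")
  h <- h / h[3, 3]

  map <- structure(list(matrix = h, inverse = solve(h),
                        image_points = image_points,
                        board_points = board_points,
                        residual_mm = NA_real_),
                   class = "planar_map")
  proj <- pixel_to_board(map, image_points)
  map$residual_mm <- sqrt(mean(rowSums((proj - board_points)^2)))
  map
}

#' @export
print.planar_map <- function(x, ...) {
  cat("Planar map (pixel -> mm), fitted from", nrow(x$image_points),
      "point pairs\n")
  print(round(x$matrix, 6))
  cat(sprintf("RMS reprojection residual: %.4g mm\n", x$residual_mm))
  invisible(x)
}

.apply_homography <- function(h, p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  q <- cbind(p, 1) %*% t(h)
  w <- q[, 3]
  if (any(abs(w) < 1e-12))
    stop("point maps to the plane at infinity (homogeneous w ~ 0)")
  out <- q[, 1:2, drop = FALSE] / w
  if (nrow(out) == 1) drop(out) else out
}

#' Map image pixels to board millimetres
#'
#' Applies the registered homography with perspective division. Accepts a
#' single point (length-2 vector) or an n x 2 matrix.
#'
#' @param map A `planar_map` from [fit_planar_map()].
#' @param p Pixel point(s).
#' @return Board point(s) in mm, same shape as the input.
#' @export
pixel_to_board <- function(map, p) {
  stopifnot(inherits(map, "planar_map"))
  .apply_homography(map$matrix, p)
}

#' Map board millimetres to image pixels
#'
#' Inverse of [pixel_to_board()]; the two compose to the identity.
#'
#' @inheritParams pixel_to_board
#' @param p Board point(s) in mm.
#' @return Pixel point(s).
#' @export
board_to_pixel <- function(map, p) {
  stopifnot(inherits(map, "planar_map"))
  .apply_homography(map$inverse, p)
}

#' Millimetres per pixel at a board location
#'
#' Local isotropic scale of the registered view, used to convert radius
#' search ranges between units. Computed from the Jacobian of the
#' pixel-to-mm map at the pixel projecting to `at_mm`.
#'
#' @param map A `planar_map`.
#' @param at_mm Board point at which to evaluate (default board centre of
#'   the registration points).
#' @return Scalar mm-per-pixel scale (geometric mean of the two axes).
#' @export
mm_per_pixel <- function(map, at_mm = colMeans(map$board_points)) {
  p0 <- board_to_pixel(map, at_mm)
  dx <- pixel_to_board(map, p0 + c(1, 0)) - at_mm
  dy <- pixel_to_board(map, p0 + c(0, 1)) - at_mm
  sqrt(sqrt(sum(dx^2)) * sqrt(sum(dy^2)))
}

#' Write / read a registration file
#'
#' Plain-text YAML storing the board specification, the matched point
#' pairs and the fitted 3x3 matrix (row-major). `read_registration`
#' refits the map from the stored point pairs and checks it against the
#' stored matrix.
#'
#' @param map A `planar_map`.
#' @param board A `board_spec`.
#' @param path File path.
#' @return `read_registration` returns a list with elements `map` and
#'   `board`.
#' @export
write_registration <- function(map, board, path) {
  stopifnot(inherits(map, "planar_map"), inherits(board, "board_spec"))
  obj <- list(
    board = list(width_mm = board$width_mm, height_mm = board$height_mm,
                 image_width_px = board$image_width_px,
                 image_height_px = board$image_height_px),
    image_points = apply(map$image_points, 1, as.numeric, simplify = FALSE),
    board_points = apply(map$board_points, 1, as.numeric, simplify = FALSE),
    matrix_row_major = as.numeric(t(map$matrix)))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_registration
#' @export
read_registration <- function(path) {
  if (!file.exists(path)) stop("registration file not found: ", path)
  obj <- yaml::read_yaml(path)
  board <- board_spec(obj$board$width_mm, obj$board$height_mm,
                      obj$board$image_width_px, obj$board$image_height_px)
  ip <- do.call(rbind, obj$image_points)
  bp <- do.call(rbind, obj$board_points)
  map <- fit_planar_map(ip, bp)
  stored <- matrix(as.numeric(obj$matrix_row_major), 3, 3, byrow = TRUE)
  if (max(abs(stored - map$matrix)) > 1e-6 * max(1, max(abs(stored))))
    warning("stored matrix differs from refit; using the refit")
  list(map = map, board = board)
}

#' Identity registration for a board viewed without perspective
#'
#' Convenience map in which the four image corners coincide with the four
#' board corners (pure anisotropic scaling), plus the centre point.
#'
#' @param board A `board_spec`.
#' @return A `planar_map`.
#' @export
axis_aligned_map <- function(board = board_spec()) {
  w <- board$image_width_px; h <- board$image_height_px
  img <- rbind(c(0, 0), c(w, 0), c(w, h), c(0, h), c(w / 2, h / 2))
  brd <- rbind(c(0, 0), c(board$width_mm, 0),
               c(board$width_mm, board$height_mm), c(0, board$height_mm),
               c(board$width_mm / 2, board$height_mm / 2))
  fit_planar_map(img, brd)
}
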