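#' Closed cell contour
#'
#' A closed polyline outlining one cell, vertices in micrometre, oriented
#' counter-clockwise (re-oriented on construction if needed). A duplicated
#' closing vertex is dropped; closure is implicit. The pixel size carries
#' the camera calibration used by the curvature smoothing rule and by the
#' tangent-correlation arc-length conversion.
#'
#' @param x,y Vertex coordinates, micrometre (>= 3 vertices).
#' @param pixel_size Camera pixel size, micrometre per pixel. Default 0.065.
#' @param meta Optional named list of metadata.
#' @return An object of class `cell_contour`.
#' @export
cell_contour <- function(x, y, pixel_size = 0.065, meta = list()) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)),
            is.numeric(pixel_size), pixel_size > 0)
  n <- length(x)
  if (n >= 3L && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
    if (length(meta$section) == n) meta$section <- meta$section[-n]
    n <- n - 1L
  }
  if (n < 3L) stop("cell_contour: need at least 3 distinct vertices")
  d <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  if (any(d == 0)) stop("cell_contour: repeated (degenerate) vertices")
  if (.polygon_signed_area(x, y) < 0) {     # enforce counter-clockwise
    x <- rev(x); y <- rev(y)
    if (length(meta$section) == n) meta$section <- rev(meta$section)
  }
  structure(list(x = x, y = y, pixel_size = pixel_size, meta = meta),
            class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf(
    "Cell contour: %d vertices, perimeter %.3f um, area %.3f um^2\n",
    length(x$x), contour_perimeter(x), contour_area(x)))
  invisible(x)
}

#' @export
plot.cell_contour <- function(x, ...) {
  graphics::plot(c(x$x, x$x[1]), c(x$y, x$y[1]), type = "l", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  invisible(x)
}

#' @export
as.data.frame.cell_contour <- function(x, ...) {
  data.frame(vertex_index = seq_along(x$x), x_um = x$x, y_um = x$y)
}

.polygon_signed_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @rdname cell_contour
#' @param contour A `cell_contour`.
#' @export
contour_area <- function(contour) {
  abs(.polygon_signed_area(contour$x, contour$y))
}

#' @rdname cell_contour
#' @export
contour_perimeter <- function(contour) {
  x <- contour$x; y <- contour$y
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# even-odd point-in-polygon test, vectorized over query points
.point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
  vapply(seq_along(px), function(k) {
    cross <- (y > py[k]) != (yj > py[k])
    xint <- (xj - x) * (py[k] - y) / (yj - y) + x
    sum(cross & (px[k] < xint)) %% 2L == 1L
  }, logical(1))
}

# distance from points to the closest polygon edge
.dist_to_boundary <- function(px, py, x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  ex <- x2 - x; ey <- y2 - y
  el2 <- ex^2 + ey^2
  vapply(seq_along(px), function(k) {
    t <- pmin(1, pmax(0, ((px[k] - x) * ex + (py[k] - y) * ey) / el2))
    min(sqrt((x + t * ex - px[k])^2 + (y + t * ey - py[k])^2))
  }, numeric(1))
}
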