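#' Signed sidewall curvature along a cell contour
#'
#' Per-vertex signed curvature computed from each triple of successive
#' contour points (the curvature of their circumscribed circle), then
#' boxcar-smoothed over an arc-length window of two pixels. The contour is
#' closed, so the triples and the smoothing window wrap around. Sign
#' convention: positive where the contour is locally convex outward (a
#' circle has uniformly positive curvature), negative at inward-curved
#' regions such as the neck of a budding cell.
#'
#' @param contour A [cell_contour()].
#' @param smooth_window Smoothing window as an arc length in micrometre;
#'   default `2 * contour$pixel_size` ("smoothed over two pixels"). Use 0
#'   to disable smoothing.
#' @return Numeric vector of per-vertex curvature, 1/micrometre.
#' @examples
#' circ <- generate_contour(contour_scenario("sphere", radius = 1))
#' summary(sidewall_curvature(circ))   # all ~1
#' @export
sidewall_curvature <- function(contour,
                               smooth_window = 2 * contour$pixel_size) {
  stopifnot(inherits(contour, "cell_contour"))
  x <- contour$x; y <- contour$y
  n <- length(x)
  xm <- c(x[n], x[-n]); ym <- c(y[n], y[-n])   # previous vertex
  xp <- c(x[-1], x[1]); yp <- c(y[-1], y[1])   # next vertex
  # signed curvature of the circumscribed circle of (prev, this, next):
  # kappa = 2 * cross / (|a| |b| |c|); collinear triples give 0
  ax <- x - xm; ay <- y - ym
  bx <- xp - x; by <- yp - y
  cx <- xp - xm; cy <- yp - ym
  cross <- ax * by - ay * bx
  denom <- sqrt(ax^2 + ay^2) * sqrt(bx^2 + by^2) * sqrt(cx^2 + cy^2)
  kappa <- ifelse(denom > 0, 2 * cross / denom, 0)
  if (smooth_window > 0) {
    edge <- sqrt(bx^2 + by^2)                  # edge i -> i+1
    half <- max(0L, floor(smooth_window / (2 * mean(edge))))
    if (half > 0L) {
      idx <- outer(seq_len(n), -half:half, function(i, k) ((i + k - 1L) %% n) + 1L)
      kappa <- rowMeans(matrix(kappa[idx], nrow = n))
    }
  }
  kappa
}

#' Midline and width profile of an elongated cell contour
#'
#' Discretizes an elongated contour into a midline with perpendicular width
#' segments (a "pill mesh"): stations are placed along the contour's
#' principal axis, the chord of the polygon perpendicular to the axis is
#' measured at each station, and the chord midpoints form the midline. The
#' cell width is the maximum segment width along the length. Contours whose
#' principal-axis aspect ratio does not exceed `round_threshold` are
#' flagged round: they have no midline, and the width is reported as the
#' maximum inscribed diameter instead.
#'
#' @param contour A [cell_contour()].
#' @param n_stations Number of stations along the long axis.
#' @param round_threshold Aspect-ratio threshold below which the cell is
#'   treated as round. Default 1.1.
#' @return An object of class `width_profile` with components `round`
#'   (logical), `midline` (data frame `x`, `y`, `angle_deg` or `NULL`),
#'   `segment_widths` (um), `cell_width` (um), `axis_angle_deg`.
#' @export
pill_mesh <- function(contour, n_stations = 50, round_threshold = 1.1) {
  stopifnot(inherits(contour, "cell_contour"))
  x <- contour$x; y <- contour$y
  cx <- mean(x); cy <- mean(y)
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)
  u <- ev$vectors[, 1]                    # long axis
  v <- ev$vectors[, 2]                    # transverse axis
  s <- (x - cx) * u[1] + (y - cy) * u[2]  # axial coordinate
  t <- (x - cx) * v[1] + (y - cy) * v[2]
  if (diff(range(t)) == 0 || diff(range(s)) == 0)
    stop("pill_mesh: degenerate (zero-width) contour")
  aspect <- diff(range(s)) / diff(range(t))
  axis_angle <- (atan2(u[2], u[1]) * 180 / pi) %% 180
  if (aspect <= round_threshold) {
    width <- 2 * .max_inscribed_radius(x, y)
    out <- list(round = TRUE, midline = NULL, segment_widths = numeric(0),
                cell_width = width, axis_angle_deg = axis_angle)
    class(out) <- "width_profile"
    return(out)
  }
  smin <- min(s); smax <- max(s)
  stations <- seq(smin, smax, length.out = n_stations + 2L)
  stations <- stations[-c(1L, n_stations + 2L)]  # chords at the tips degenerate
  n <- length(x)
  s2 <- c(s[-1], s[1]); t2 <- c(t[-1], t[1])
  mids <- widths <- rep(NA_real_, length(stations))
  for (k in seq_along(stations)) {
    s0 <- stations[k]
    crosses <- which((s < s0 & s2 >= s0) | (s >= s0 & s2 < s0))
    if (length(crosses) < 2L) next
    frac <- (s0 - s[crosses]) / (s2[crosses] - s[crosses])
    tc <- t[crosses] + frac * (t2[crosses] - t[crosses])
    widths[k] <- max(tc) - min(tc)
    mids[k] <- (max(tc) + min(tc)) / 2
  }
  ok <- !is.na(widths) & widths > 0
  stations <- stations[ok]; widths <- widths[ok]; mids <- mids[ok]
  mx <- cx + stations * u[1] + mids * v[1]
  my <- cy + stations * u[2] + mids * v[2]
  # midline tangent angle per station (axial, degrees in [0, 180))
  nst <- length(mx)
  dx <- c(mx[2] - mx[1], diff(mx))
  dy <- c(my[2] - my[1], diff(my))
  ang <- (atan2(dy, dx) * 180 / pi) %% 180
  out <- list(round = FALSE,
              midline = data.frame(x = mx, y = my, angle_deg = ang),
              segment_widths = widths,
              cell_width = max(widths),
              axis_angle_deg = axis_angle)
  class(out) <- "width_profile"
  out
}

#' @export
print.width_profile <- function(x, ...) {
  if (x$round) {
    cat(sprintf("Width profile: round cell, max inscribed diameter %.3f um\n",
                x$cell_width))
  } else {
    cat(sprintf(
      "Width profile: %d stations, cell width %.3f um, axis %.1f deg\n",
      nrow(x$midline), x$cell_width, x$axis_angle_deg))
  }
  invisible(x)
}

# maximum inscribed radius via a grid search over interior points
.max_inscribed_radius <- function(x, y, n_grid = 40) {
  gx <- seq(min(x), max(x), length.out = n_grid)
  gy <- seq(min(y), max(y), length.out = n_grid)
  g <- expand.grid(px = gx, py = gy)
  inside <- .point_in_polygon(g$px, g$py, x, y)
  if (!any(inside)) return(0)
  max(.dist_to_boundary(g$px[inside], g$py[inside], x, y))
}

#' Principal-curvature ratio of a cell contour
#'
#' Ratio of the in-plane sidewall curvature to the radial curvature
#' \eqn{\kappa_2 = 1/r_{cell}} derived from the cell width (assuming radial
#' symmetry), with \eqn{r_{cell}} half the cell width. The sidewall
#' curvature entering the ratio is the mean over the flank region (midline
#' stations excluding 10 percent of the axial length at each pole); for
#' round cells all vertices are used and the width is the maximum extent.
#' A ratio near 1 indicates the two principal curvatures are similar (the
#' cell is round); an ideal rod flank gives 0.
#'
#' @param contour A [cell_contour()].
#' @param flank_trim Fraction of the axial extent excluded at each pole
#'   when averaging sidewall curvature for elongated cells. Default 0.1.
#' @return An object of class `curvature_profile`: list with per-vertex
#'   `kappa1`, scalar `radial_curvature` (\eqn{\kappa_2}), `ratio`,
#'   `cell_width`, `round`.
#' @examples
#' principal_curvature_ratio(generate_contour(contour_scenario("sphere")))$ratio
#' @export
principal_curvature_ratio <- function(contour, flank_trim = 0.1) {
  stopifnot(inherits(contour, "cell_contour"))
  kappa <- sidewall_curvature(contour)
  mesh <- pill_mesh(contour)
  if (mesh$round) {
    # round cell: width is the maximum extent, all vertices are sidewall
    d <- as.matrix(stats::dist(cbind(contour$x, contour$y)))
    width <- max(d)
    flank_mean <- mean(kappa)
  } else {
    width <- mesh$cell_width
    # flank region: vertices whose axial coordinate avoids the polar caps
    cx <- mean(contour$x); cy <- mean(contour$y)
    th <- mesh$axis_angle_deg * pi / 180
    s <- (contour$x - cx) * cos(th) + (contour$y - cy) * sin(th)
    lo <- min(s) + flank_trim * diff(range(s))
    hi <- max(s) - flank_trim * diff(range(s))
    flank_mean <- mean(kappa[s >= lo & s <= hi])
  }
  if (width <= 0) stop("principal_curvature_ratio: zero cell width")
  k2 <- 1 / (width / 2)
  out <- list(kappa1 = kappa, radial_curvature = k2,
              ratio = flank_mean / k2, cell_width = width,
              round = mesh$round)
  class(out) <- "curvature_profile"
  out
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf(
    "Curvature profile: kappa2 = %.3f 1/um (width %.3f um), ratio kappa1/kappa2 = %.3f%s\n",
    x$radial_curvature, x$cell_width, x$ratio,
    if (x$round) " [round]" else ""))
  invisible(x)
}

#' Local sidewall curvature nearest to a point
#'
#' Mean of the sidewall curvature of the 3 nearest contour points on each
#' side of the contour relative to a query position (e.g. a track's mean
#' position): the two sides are the two arcs facing the point across the
#' cell, approximated by the 3 nearest vertices and the 3 nearest vertices
#' of the opposite half of the contour.
#'
#' @param contour A [cell_contour()].
#' @param px,py Query position, um.
#' @param k Number of nearest points per side. Default 3.
#' @return Mean local curvature, 1/um.
#' @export
local_sidewall_curvature <- function(contour, px, py, k = 3) {
  kappa <- sidewall_curvature(contour)
  d <- sqrt((contour$x - px)^2 + (contour$y - py)^2)
  near <- order(d)[seq_len(k)]
  # opposite side: reflect the query through the contour centroid
  qx <- 2 * mean(contour$x) - px; qy <- 2 * mean(contour$y) - py
  d2 <- sqrt((contour$x - qx)^2 + (contour$y - qy)^2)
  far <- order(d2)[seq_len(k)]
  mean(kappa[c(near, far)])
}

#' Tangent-angle correlation along a cell contour
#'
#' For each contour edge the tangent direction is computed with the
#' two-argument arctangent; the correlation
#' \eqn{G(l) = \frac{1}{N}\sum_i \cos(\theta_{i+n} - \theta_i)} is averaged
#' over all edges at vertex separation `n` (wrapping around the closed
#' contour) and the separation converted to arc length using the mean edge
#' length. A straight polyline has \eqn{G \equiv 1}; a circle of radius
#' \eqn{r} gives \eqn{G(l) = \cos(l/r)}.
#'
#' @param contour A [cell_contour()].
#' @param max_arc Largest arc-length separation, um; must be below half
#'   the perimeter. Default: half the perimeter.
#' @return Data frame with columns `l_um` and `G`.
#' @export
tangential_correlation <- function(contour, max_arc = NULL) {
  stopifnot(inherits(contour, "cell_contour"))
  x <- contour$x; y <- contour$y
  n <- length(x)
  per <- contour_perimeter(contour)
  if (is.null(max_arc)) max_arc <- per / 2
  if (max_arc >= per / 2 + 1e-9) max_arc <- per / 2
  theta <- atan2(c(y[-1], y[1]) - y, c(x[-1], x[1]) - x)
  step <- per / n                              # mean edge length
  nmax <- min(n - 1L, floor(max_arc / step))
  G <- vapply(0:nmax, function(lag) {
    shifted <- theta[((seq_len(n) - 1L + lag) %% n) + 1L]
    mean(cos(shifted - theta))
  }, numeric(1))
  data.frame(l_um = (0:nmax) * step, G = G)
}

#' Doubling time from a single-cell area time series
#'
#' Fits a line to log(area) versus time by least squares; the doubling
#' time is \eqn{\ln 2 / slope}. A non-positive slope is flagged as
#' non-growing (no doubling time).
#'
#' @param areas Cell areas, um^2 (all > 0, >= 3 points).
#' @param times Matching times, minutes.
#' @return List with `doubling_time` (minutes, `NA` if non-growing),
#'   `growth_rate` (1/min), `growing` (logical), `r_squared`.
#' @examples
#' doubling_time(c(1, 2, 4), c(0, 30, 60))$doubling_time  # 30
#' @export
doubling_time <- function(areas, times) {
  stopifnot(is.numeric(areas), is.numeric(times),
            length(areas) == length(times))
  if (length(areas) < 3L) stop("doubling_time: need at least 3 time points")
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("doubling_time: areas must be positive")
  fit <- stats::lm(log(areas) ~ times)
  slope <- unname(stats::coef(fit)[2])
  growing <- slope > 0
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(doubling_time = if (growing) log(2) / slope else NA_real_,
       growth_rate = slope, growing = growing, r_squared = r2)
}
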