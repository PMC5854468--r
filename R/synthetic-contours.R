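#' Synthetic cell-contour scenario
#'
#' Describes a synthetic cell outline to be generated by
#' [generate_contour()]: a rod (spherocylinder outline), a sphere (circle),
#' or a bulged sphere (a sphere with a smaller tangent bulge joined by an
#' inward-curved neck — the geometry of a round cell emitting a nascent
#' rod). All lengths in micrometre.
#'
#' @param kind One of `"rod"`, `"sphere"`, `"bulged_sphere"`.
#' @param width Rod width (diameter), um.
#' @param length Rod total length (including caps), um; must exceed
#'   `width`.
#' @param radius Sphere radius, um.
#' @param bulge_width Diameter of the bulge circle, um; must be smaller
#'   than the sphere diameter.
#' @param neck_depth Fillet radius of the inward-curved neck joining sphere
#'   and bulge, um.
#' @param n_vertices Number of contour vertices (>= 16).
#' @param vertex_jitter Radial Gaussian jitter applied to each vertex, um.
#' @param seed Integer seed (used only when `vertex_jitter > 0`).
#' @return An object of class `contour_scenario`.
#' @export
contour_scenario <- function(kind = c("rod", "sphere", "bulged_sphere"),
                             width = 0.9, length = 3, radius = 0.5,
                             bulge_width = 0.5, neck_depth = 0.2,
                             n_vertices = 128, vertex_jitter = 0, seed = 1L) {
  if (length(kind) != 1L || !kind %in% c("rod", "sphere", "bulged_sphere"))
    stop("contour_scenario: unknown contour kind '",
         paste(kind, collapse = "/"), "'")
  stopifnot(n_vertices >= 16, width > 0, length > 0, radius > 0,
            bulge_width > 0, neck_depth > 0, vertex_jitter >= 0)
  structure(list(kind = kind, width = width, length = length,
                 radius = radius, bulge_width = bulge_width,
                 neck_depth = neck_depth, n_vertices = as.integer(n_vertices),
                 vertex_jitter = vertex_jitter, seed = as.integer(seed)),
            class = "contour_scenario")
}

# points along a circular arc; direction +1 = counter-clockwise
.arc_points <- function(cx, cy, r, a0, a1, direction, n) {
  span <- (a1 - a0) %% (2 * pi)
  if (direction < 0) span <- span - 2 * pi
  if (span == 0) span <- direction * 2 * pi
  a <- a0 + span * seq(0, 1, length.out = n)
  cbind(cx + r * cos(a), cy + r * sin(a))
}

# spherocylinder outline, axis along x, centred at the origin
.rod_outline <- function(width, length, n_vertices) {
  if (length <= width)
    stop("generate_contour: rod length must exceed its width")
  r <- width / 2
  lf <- length - width                    # straight flank length
  half <- lf / 2
  per <- 2 * lf + 2 * pi * r
  # arc-length parameterization, counter-clockwise from (-half, -r)
  s <- seq(0, per, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  f <- function(si) {
    if (si < lf) {                               # bottom flank, left->right
      c(-half + si, -r, 1)                       # 1 = flank
    } else if (si < lf + pi * r) {               # right cap
      a <- -pi / 2 + (si - lf) / r
      c(half + r * cos(a), r * sin(a), 2)        # 2 = cap
    } else if (si < 2 * lf + pi * r) {           # top flank, right->left
      c(half - (si - lf - pi * r), r, 1)
    } else {                                     # left cap
      a <- pi / 2 + (si - 2 * lf - pi * r) / r
      c(-half + r * cos(a), r * sin(a), 2)
    }
  }
  m <- t(vapply(s, f, numeric(3)))
  list(x = m[, 1], y = m[, 2],
       section = c("flank", "cap")[m[, 3]])
}

# sphere with tangent bulge joined by concave fillet arcs
.bulged_outline <- function(radius, bulge_width, neck_depth, n_vertices) {
  R <- radius; rb <- bulge_width / 2; rf <- neck_depth
  if (bulge_width >= 2 * radius)
    stop("generate_contour: bulge_width must be smaller than the sphere diameter")
  d <- R + rb                               # externally tangent circles
  # fillet circle centres: distance R+rf from body, rb+rf from bulge
  xf <- (d^2 + (R + rf)^2 - (rb + rf)^2) / (2 * d)
  yf2 <- (R + rf)^2 - xf^2
  if (yf2 <= 0) stop("generate_contour: neck fillet does not fit; increase neck_depth")
  yf <- sqrt(yf2)
  Fu <- c(xf, yf); Fl <- c(xf, -yf)
  unitv <- function(v) v / sqrt(sum(v^2))
  T1u <- R * unitv(Fu); T1l <- R * unitv(Fl)          # tangency on body
  Cb <- c(d, 0)
  T2u <- Cb + rb * unitv(Fu - Cb); T2l <- Cb + rb * unitv(Fl - Cb)
  ang <- function(p, c0) atan2(p[2] - c0[2], p[1] - c0[1])
  segs <- list(
    list(c0 = c(0, 0), r = R, a0 = ang(T1u, c(0, 0)), a1 = ang(T1l, c(0, 0)),
         dir = 1, section = "body"),
    list(c0 = Fl, r = rf, a0 = ang(T1l, Fl), a1 = ang(T2l, Fl),
         dir = -1, section = "neck"),
    list(c0 = Cb, r = rb, a0 = ang(T2l, Cb), a1 = ang(T2u, Cb),
         dir = 1, section = "bulge"),
    list(c0 = Fu, r = rf, a0 = ang(T2u, Fu), a1 = ang(T1u, Fu),
         dir = -1, section = "neck"))
  span <- function(s) {
    sp <- (s$a1 - s$a0) %% (2 * pi)
    if (s$dir < 0) sp <- 2 * pi - sp
    sp * s$r
  }
  lens <- vapply(segs, span, numeric(1))
  nv <- pmax(3L, round(n_vertices * lens / sum(lens)))
  pts <- vector("list", length(segs))
  sect <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    p <- .arc_points(s$c0[1], s$c0[2], s$r, s$a0, s$a1, s$dir, nv[i] + 1L)
    pts[[i]] <- p[-nrow(p), , drop = FALSE]  # drop shared endpoint
    sect[[i]] <- rep(s$section, nv[i])
  }
  m <- do.call(rbind, pts)
  list(x = m[, 1], y = m[, 2], section = unlist(sect))
}

#' Generate a synthetic cell contour
#'
#' Builds the closed, counter-clockwise outline described by a
#' [contour_scenario()]: a circle for spheres, a spherocylinder outline
#' (two parallel flanks capped by semicircles) for rods, and a
#' sphere-with-bulge joined by concave neck fillets for `bulged_sphere`.
#' Vertices carry a `section` label in the contour metadata
#' (`"flank"`/`"cap"` for rods, `"body"`/`"neck"`/`"bulge"` for bulged
#' spheres) so tests and downstream analyses can address regions.
#'
#' @param scenario A [contour_scenario()].
#' @param pixel_size Pixel size recorded on the contour, um. Default 0.065.
#' @return A [cell_contour()].
#' @examples
#' rod <- generate_contour(contour_scenario("rod", width = 0.9, length = 3))
#' range(pill_mesh(rod)$segment_widths)
#' @export
generate_contour <- function(scenario, pixel_size = 0.065) {
  stopifnot(inherits(scenario, "contour_scenario"))
  out <- switch(scenario$kind,
    sphere = {
      a <- seq(0, 2 * pi, length.out = scenario$n_vertices + 1L)
      a <- a[-(scenario$n_vertices + 1L)]
      list(x = scenario$radius * cos(a), y = scenario$radius * sin(a),
           section = rep("body", scenario$n_vertices))
    },
    rod = .rod_outline(scenario$width, scenario$length, scenario$n_vertices),
    bulged_sphere = .bulged_outline(scenario$radius, scenario$bulge_width,
                                    scenario$neck_depth, scenario$n_vertices))
  if (scenario$vertex_jitter > 0) {
    set.seed(scenario$seed)
    # radial jitter about the centroid keeps the polyline simple for small
    # amplitudes
    cx <- mean(out$x); cy <- mean(out$y)
    th <- atan2(out$y - cy, out$x - cx)
    j <- stats::rnorm(length(out$x), 0, scenario$vertex_jitter)
    out$x <- out$x + j * cos(th)
    out$y <- out$y + j * sin(th)
  }
  cell_contour(out$x, out$y, pixel_size = pixel_size,
               meta = list(section = out$section, scenario = scenario))
}
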