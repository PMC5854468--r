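#' Surface geometry given by its two principal curvatures
#'
#' Describes the local geometry of the membrane surface a filament binds to,
#' by its two principal curvatures. The sign convention follows the inner
#' leaflet of a bacterial membrane: a curvature is *negative* when the
#' surface curves toward the filament side (the cell interior), so the inner
#' wall of a rod-shaped cell of radius \eqn{R} has \eqn{\kappa_1 = 0} along
#' the long axis and \eqn{\kappa_2 = -1/R} around the circumference; the
#' inside of a sphere has \eqn{\kappa_1 = \kappa_2 = -1/R}; a neck (saddle)
#' has curvatures of opposite sign.
#'
#' @param kappa1 Principal curvature along the reference direction
#'   (conventionally the cell long axis), in 1/micrometre.
#' @param kappa2 Principal curvature along the orthogonal direction
#'   (conventionally the circumference), in 1/micrometre.
#' @return An object of class `surface_geometry`.
#' @seealso [normal_curvature()], [cylinder_surface()], [sphere_surface()]
#' @examples
#' surface_geometry(0, -1 / 0.45)       # inner wall of a 0.45 um radius rod
#' sphere_surface(radius = 0.45)        # inside of a sphere
#' @export
surface_geometry <- function(kappa1, kappa2) {
  stopifnot(is.numeric(kappa1), is.numeric(kappa2),
            length(kappa1) == 1L, length(kappa2) == 1L,
            is.finite(kappa1), is.finite(kappa2))
  structure(list(kappa1 = kappa1, kappa2 = kappa2),
            class = "surface_geometry")
}

#' @rdname surface_geometry
#' @param radius Radius in micrometre.
#' @export
cylinder_surface <- function(radius) {
  stopifnot(radius > 0)
  surface_geometry(0, -1 / radius)
}

#' @rdname surface_geometry
#' @export
sphere_surface <- function(radius) {
  stopifnot(radius > 0)
  surface_geometry(-1 / radius, -1 / radius)
}

#' @export
print.surface_geometry <- function(x, ...) {
  cat(sprintf("Surface geometry: kappa1 = %g, kappa2 = %g (1/um)\n",
              x$kappa1, x$kappa2))
  invisible(x)
}

#' Normal curvature of a surface along a tangent direction
#'
#' Euler's curvature relation: the curvature of the surface along a tangent
#' direction at angle `theta` from the first principal direction is
#' \deqn{\kappa_n(\theta) = \kappa_1 \cos^2\theta + \kappa_2 \sin^2\theta.}
#' On the inner wall of a rod this is 0 along the long axis (theta = 0) and
#' \eqn{-1/R} around the circumference (theta = 90).
#'
#' @param surface A [surface_geometry()].
#' @param theta_deg Direction(s) in degrees, measured from the `kappa1`
#'   (long-axis) principal direction; any finite values are accepted
#'   (the relation has period 180 degrees).
#' @return Normal curvature(s) in 1/micrometre.
#' @examples
#' normal_curvature(cylinder_surface(0.45), c(0, 45, 90))
#' @export
normal_curvature <- function(surface, theta_deg) {
  stopifnot(inherits(surface, "surface_geometry"), is.numeric(theta_deg),
            all(is.finite(theta_deg)))
  th <- theta_deg * pi / 180
  surface$kappa1 * cos(th)^2 + surface$kappa2 * sin(th)^2
}
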