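#' Orthogonal line fit of a track
#'
#' Fits a line through a track's positions by orthogonal least squares
#' (principal component analysis), minimizing perpendicular distances. The
#' line angle is axial (degrees in \[0, 180)), the fit quality is the
#' fraction of positional variance explained by the first principal axis
#' (1 for a perfect line, ~0.5 for an isotropic cloud), and the
#' displacement is the end-to-end distance of the first and last positions
#' projected on the fitted axis.
#'
#' @param track A [track()] with at least 5 frames (not all positions
#'   identical).
#' @return List with `line_angle` (deg), `r2_orth`, `mean_x`, `mean_y`,
#'   `displacement` (um), `duration` (s).
#' @export
fit_track_line <- function(track) {
  stopifnot(inherits(track, "track"))
  n <- length(track$x)
  if (n < 5L && n != 2L)
    warning("fit_track_line: track ", track$track_id,
            " has fewer than 5 frames")
  xy <- cbind(track$x, track$y)
  cxy <- sweep(xy, 2, colMeans(xy))
  cv <- crossprod(cxy) / (n - 1)
  if (sum(diag(cv)) == 0)
    stop("fit_track_line: zero-variance track ", track$track_id)
  ev <- eigen(cv, symmetric = TRUE)
  u <- ev$vectors[, 1]
  proj <- cxy %*% u
  list(line_angle = (atan2(u[2], u[1]) * 180 / pi) %% 180,
       r2_orth = ev$values[1] / sum(ev$values),
       mean_x = mean(track$x), mean_y = mean(track$y),
       displacement = abs(proj[n] - proj[1]),
       duration = (track$frames[n] - track$frames[1]) * track$frame_interval)
}

#' Fold an axial angle difference into \[0, 90\] degrees
#'
#' Trajectories are axial quantities (a line at theta and theta + 180
#' degrees is the same line), so raw angle differences are first brought to
#' \[0, 180) and then reflected: differences above 90 map to 180 minus the
#' difference. The transform is idempotent.
#'
#' @param delta_deg Angle difference(s), degrees (any real values).
#' @return Folded difference(s) in \[0, 90\].
#' @examples
#' fold_angle_90(c(-30, 150, 91))  # 30 30 89
#' @export
fold_angle_90 <- function(delta_deg) {
  d <- delta_deg %% 180
  ifelse(d > 90, 180 - d, d)
}

#' Root-mean-square deviation of angles from 90 degrees
#'
#' The circumferential-alignment summary statistic
#' \eqn{\sigma_{90} = \sqrt{\sum_i (x_i - 90)^2 / N}} for a sample of
#' midline angles in degrees: 0 for perfectly circumferential motion,
#' \eqn{90/\sqrt{3} \approx 52} degrees for isotropic motion (angles
#' uniform on \[0, 180\]).
#'
#' @param angles_deg Non-empty numeric vector of angles, degrees.
#' @return \eqn{\sigma_{90}} in degrees.
#' @examples
#' sigma90(c(60, 120))  # 30
#' @export
sigma90 <- function(angles_deg) {
  if (length(angles_deg) == 0L) stop("sigma90: empty angle list")
  stopifnot(is.numeric(angles_deg), all(is.finite(angles_deg)))
  sqrt(mean((angles_deg - 90)^2))
}

#' Track angle relative to the cell midline
#'
#' Takes the midline angle at the station nearest the query position
#' (Euclidean distance, ties broken by lower station index), subtracts it
#' from the track's line angle, and folds the difference to \[0, 90\]
#' degrees: 0 = parallel to the midline, 90 = circumferential. Round cells
#' have no midline; the angle is reported as `NA`.
#'
#' @param line_angle_deg Track line angle(s), degrees (axial).
#' @param px,py Track mean position(s), um.
#' @param contour A [cell_contour()] or a precomputed [pill_mesh()].
#' @return Folded angle(s) to the midline in degrees, or `NA` for round
#'   cells.
#' @export
angle_to_midline <- function(line_angle_deg, px, py, contour) {
  mesh <- if (inherits(contour, "width_profile")) contour
          else pill_mesh(contour)
  if (mesh$round) {
    warning("angle_to_midline: round cell, no midline")
    return(rep(NA_real_, length(line_angle_deg)))
  }
  vapply(seq_along(line_angle_deg), function(i) {
    d <- (mesh$midline$x - px[i])^2 + (mesh$midline$y - py[i])^2
    mang <- mesh$midline$angle_deg[which.min(d)]
    fold_angle_90(line_angle_deg[i] - mang)
  }, numeric(1))
}

#' Local cell width nearest a position
#'
#' Mean of the widths of the `k` mesh stations nearest the query position
#' (default 10, matching the convention of averaging the 10 nearest
#' contour-point widths around a track).
#'
#' @param contour A [cell_contour()] or [pill_mesh()].
#' @param px,py Query position, um.
#' @param k Number of nearest stations averaged. Default 10.
#' @return Local width, um (`NA` for round cells).
#' @export
local_width <- function(contour, px, py, k = 10) {
  mesh <- if (inherits(contour, "width_profile")) contour
          else pill_mesh(contour)
  if (mesh$round) return(NA_real_)
  d <- (mesh$midline$x - px)^2 + (mesh$midline$y - py)^2
  near <- order(d)[seq_len(min(k, length(d)))]
  mean(mesh$segment_widths[near])
}
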