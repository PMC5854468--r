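#' Per-track summary table
#'
#' Runs the orthogonal line fit and the MSD motion fit on every track and
#' assembles the per-track summary used by the directional filters and the
#' pairwise statistics. When a track carries a recorded line-fit quality in
#' its metadata (as the random-angle null generator attaches), that value
#' is used for `r2_orth` so simulated tracks behave under the filters as
#' they were specified to.
#'
#' @param tracks A [track_set()] or list of [track()] objects.
#' @param model MSD model variant passed to [fit_msd()].
#' @return Data frame (one row per track): `track_id`, `n_frames`,
#'   `mean_x`, `mean_y`, `line_angle`, `r2_orth`, `displacement`,
#'   `velocity_msd`, `diffusion_D`, `alpha`, `r2_loglog`, `converged`.
#' @export
summarize_tracks <- function(tracks, model = "drift_diffusion") {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    lf <- fit_track_line(tr)
    mf <- fit_msd(tr, model = model)
    cf <- coef(mf)
    data.frame(
      track_id = tr$track_id, n_frames = length(tr$frames),
      mean_x = lf$mean_x, mean_y = lf$mean_y,
      line_angle = lf$line_angle,
      r2_orth = tr$meta$r2 %||% lf$r2_orth,
      displacement = lf$displacement,
      velocity_msd = cf[["V"]], diffusion_D = cf[["D"]],
      alpha = cf[["alpha"]], r2_loglog = mf$r2_loglog,
      converged = mf$converged)
  })
  do.call(rbind, rows)
}

#' Directional-track filter policy
#'
#' Thresholds for selecting linear, directionally moving tracks. The
#' default policy is the filament-trajectory filter: orthogonal-fit
#' \eqn{R^2 > 0.9}, displacement \eqn{> 0.2} um, velocity
#' \eqn{> 10^{-9}} um/s, log-log MSD fit \eqn{R^2 > 0.6}, and at least 5
#' frames. [single_molecule_policy()] is the single-molecule variant:
#' track length between 10 and 120 frames, log-log \eqn{R^2 > 0.95}, and
#' velocity \eqn{> 5\times10^{-5}} nm/s (5e-8 um/s), with no
#' line-fit/displacement requirement. All inequalities are strict.
#'
#' @param r2_orth_min Minimum orthogonal-regression fit quality.
#' @param displacement_min_um Minimum end-to-end displacement, um.
#' @param velocity_min_um_s Minimum MSD-fit velocity, um/s.
#' @param r2_loglog_min Minimum log MSD vs log t fit quality.
#' @param min_frames,max_frames Allowed track length range (inclusive).
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(r2_orth_min = 0.9, displacement_min_um = 0.2,
                          velocity_min_um_s = 1e-9, r2_loglog_min = 0.6,
                          min_frames = 5L, max_frames = Inf) {
  structure(list(r2_orth_min = r2_orth_min,
                 displacement_min_um = displacement_min_um,
                 velocity_min_um_s = velocity_min_um_s,
                 r2_loglog_min = r2_loglog_min,
                 min_frames = min_frames, max_frames = max_frames),
            class = "filter_policy")
}

#' @rdname filter_policy
#' @export
single_molecule_policy <- function() {
  filter_policy(r2_orth_min = -Inf, displacement_min_um = -Inf,
                velocity_min_um_s = 5e-8, r2_loglog_min = 0.95,
                min_frames = 10L, max_frames = 120L)
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("Track filter policy:\n")
  cat(sprintf("  frames in [%s, %s], R2_orth > %g, displacement > %g um\n",
              x$min_frames, x$max_frames, x$r2_orth_min,
              x$displacement_min_um))
  cat(sprintf("  velocity > %g um/s, log-log R2 > %g\n",
              x$velocity_min_um_s, x$r2_loglog_min))
  invisible(x)
}

#' Apply a directional filter policy to track summaries
#'
#' Retains tracks for which every policy predicate holds, and reports how
#' many tracks each predicate alone rejects (attrition). Non-converged MSD
#' fits are always dropped.
#'
#' @param summaries Data frame from [summarize_tracks()].
#' @param policy A [filter_policy()]. Default: the filament policy.
#' @return An object of class `filter_report`: list with `retained` (the
#'   surviving subset of `summaries`), `attrition` (named integer vector of
#'   per-predicate rejection counts), `n_in`, `n_out`.
#' @export
apply_filters <- function(summaries, policy = filter_policy()) {
  stopifnot(is.data.frame(summaries), inherits(policy, "filter_policy"))
  pred <- list(
    frames = summaries$n_frames >= policy$min_frames &
             summaries$n_frames <= policy$max_frames,
    r2_orth = summaries$r2_orth > policy$r2_orth_min,
    displacement = summaries$displacement > policy$displacement_min_um,
    velocity = summaries$velocity_msd > policy$velocity_min_um_s,
    r2_loglog = summaries$r2_loglog > policy$r2_loglog_min,
    converged = summaries$converged)
  pred <- lapply(pred, function(p) !is.na(p) & p)
  keep <- Reduce(`&`, pred)
  out <- list(retained = summaries[keep, , drop = FALSE],
              attrition = vapply(pred, function(p) sum(!p), integer(1)),
              n_in = nrow(summaries), n_out = sum(keep))
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Track filter: %d of %d tracks retained\n", x$n_out, x$n_in))
  att <- x$attrition[x$attrition > 0]
  if (length(att))
    cat("  rejected by:",
        paste(sprintf("%s (%d)", names(att), att), collapse = ", "), "\n")
  invisible(x)
}
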