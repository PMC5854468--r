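#' Pairwise angle and dot-product statistics of track populations
#'
#' For every pair of eligible tracks, computes the distance between mean
#' positions \eqn{d_{ij}}, the pairwise angle difference folded to
#' \[0, 90\] degrees, and the dot product \eqn{DP_{ij} =
#' \cos(\theta_i - \theta_j)} of the raw line angles (no folding or
#' absolute value is applied to the dot product). Only tracks with at
#' least `neighborhood_min` other tracks within `neighborhood_radius` are
#' eligible (this removes isolated, out-of-cell tracks). Pairs are binned
#' by distance up to `max_distance` (the average cell length); the key
#' alignment summary is the median folded angle difference of pairs closer
#' than `close_distance`: ~0 for aligned motion, 45 degrees for randomly
#' oriented motion.
#'
#' @param summaries Data frame from [summarize_tracks()] (typically after
#'   [apply_filters()]), needing columns `mean_x`, `mean_y`, `line_angle`.
#' @param neighborhood_radius Radius of the track-density eligibility
#'   test, um. Default 5.
#' @param neighborhood_min Minimum number of other tracks within the
#'   radius. Default 3.
#' @param bin_width Distance bin width, um. Default 0.5.
#' @param max_distance Maximum binned pair distance, um. Default 3.
#' @param close_distance Distance defining "close" pairs for the median
#'   angle difference, um. Default 1.
#' @return An object of class `pair_statistic`: list with `pairs` (data
#'   frame `d_um`, `delta_theta`, `dp`), `bins` (per-bin mean DP, median
#'   angle, count), `median_dtheta_close`, `mean_dp_close`, `n_eligible`.
#' @export
pairwise_statistics <- function(summaries, neighborhood_radius = 5,
                                neighborhood_min = 3, bin_width = 0.5,
                                max_distance = 3, close_distance = 1) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 2L)
  px <- summaries$mean_x; py <- summaries$mean_y
  th <- summaries$line_angle
  dm <- as.matrix(stats::dist(cbind(px, py)))
  eligible <- rowSums(dm <= neighborhood_radius) - 1L >= neighborhood_min
  idx <- which(eligible)
  if (length(idx) < 2L) {
    pairs <- data.frame(d_um = numeric(0), delta_theta = numeric(0),
                        dp = numeric(0))
  } else {
    cmb <- utils::combn(idx, 2L)
    i <- cmb[1, ]; j <- cmb[2, ]
    dth_raw <- th[i] - th[j]
    pairs <- data.frame(d_um = dm[cbind(i, j)],
                        delta_theta = fold_angle_90(dth_raw),
                        dp = cos(dth_raw * pi / 180))
  }
  edges <- seq(0, max_distance, by = bin_width)
  binned <- pairs[pairs$d_um > 0 & pairs$d_um <= max_distance, ]
  bin_id <- cut(binned$d_um, edges, include.lowest = FALSE)
  bins <- data.frame(
    d_lo = edges[-length(edges)], d_hi = edges[-1],
    mean_dp = as.numeric(tapply(binned$dp, bin_id, mean)),
    median_dtheta = as.numeric(tapply(binned$delta_theta, bin_id, stats::median)),
    n = as.integer(table(bin_id)))
  close <- pairs$d_um <= close_distance
  out <- list(pairs = pairs, bins = bins,
              median_dtheta_close =
                if (any(close)) stats::median(pairs$delta_theta[close])
                else NA_real_,
              mean_dp_close =
                if (any(close)) mean(pairs$dp[close]) else NA_real_,
              n_eligible = length(idx),
              close_distance = close_distance)
  class(out) <- "pair_statistic"
  out
}

#' @export
print.pair_statistic <- function(x, ...) {
  cat(sprintf("Pairwise track statistics: %d eligible tracks, %d pairs\n",
              x$n_eligible, nrow(x$pairs)))
  cat(sprintf("  median delta-theta (d <= %g um): %.2f deg\n",
              x$close_distance, x$median_dtheta_close))
  cat(sprintf("  mean DP (d <= %g um): %.3f\n", x$close_distance,
              x$mean_dp_close))
  invisible(x)
}

#' Median track angle binned by local cell width
#'
#' Bins per-track midline angles by the local cell width at each track and
#' reports the median folded angle per width bin. In narrow rods the
#' median sits near 90 degrees (circumferential); as cells widen and
#' become round the median decays toward the isotropic value (~45-50
#' degrees). Bins with fewer than `min_per_bin` tracks are suppressed.
#'
#' @param angle_deg Per-track angles to the midline, degrees in \[0, 90\].
#' @param width_um Per-track local cell widths, um (e.g. from
#'   [local_width()]).
#' @param bin_width Width bin size, um. Default 0.25.
#' @param min_per_bin Minimum tracks per reported bin. Default 5.
#' @return Data frame with `width_mid`, `median_angle`, `n`.
#' @export
angle_width_binning <- function(angle_deg, width_um, bin_width = 0.25,
                                min_per_bin = 5L) {
  stopifnot(length(angle_deg) == length(width_um))
  ok <- is.finite(angle_deg) & is.finite(width_um)
  angle_deg <- angle_deg[ok]; width_um <- width_um[ok]
  if (!length(angle_deg))
    return(data.frame(width_mid = numeric(0), median_angle = numeric(0),
                      n = integer(0)))
  edges <- seq(0, max(width_um) + bin_width, by = bin_width)
  bin_id <- cut(width_um, edges, include.lowest = TRUE)
  med <- tapply(angle_deg, bin_id, stats::median)
  n <- as.integer(table(bin_id))
  mids <- (edges[-length(edges)] + edges[-1]) / 2
  out <- data.frame(width_mid = mids, median_angle = as.numeric(med), n = n)
  out[out$n >= min_per_bin & !is.na(out$median_angle), , drop = FALSE]
}
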