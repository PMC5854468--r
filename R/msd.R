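#' Time-averaged mean squared displacement of a track
#'
#' \eqn{MSD(k\Delta t)} averaged over all position pairs separated by `k`
#' frames within one track.
#'
#' @param track A [track()].
#' @param max_lag Largest frame lag; default all available lags.
#' @return Data frame with `lag_frames`, `t_s`, `msd` (um^2), `n_pairs`.
#' @export
track_msd <- function(track, max_lag = NULL) {
  stopifnot(inherits(track, "track"))
  fr <- track$frames
  span <- fr[length(fr)] - fr[1]
  if (is.null(max_lag)) max_lag <- span
  lags <- seq_len(min(max_lag, span))
  res <- lapply(lags, function(k) {
    idx <- match(fr + k, fr)
    i <- which(!is.na(idx))
    if (!length(i)) return(NULL)
    j <- idx[i]
    data.frame(lag_frames = k, t_s = k * track$frame_interval,
               msd = mean((track$x[j] - track$x[i])^2 +
                          (track$y[j] - track$y[i])^2),
               n_pairs = length(i))
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

# exact non-negative least squares for a small design matrix by active-set
# enumeration (all 2^p sign patterns); returns coefficients >= 0
.nnls_small <- function(X, y) {
  p <- ncol(X)
  best <- NULL; best_rss <- Inf
  for (mask in 0:(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    beta <- numeric(p)
    if (length(free)) {
      fit <- tryCatch(stats::lm.fit(X[, free, drop = FALSE], y),
                      error = function(e) NULL)
      if (is.null(fit)) next
      b <- fit$coefficients
      b[is.na(b)] <- 0
      if (any(b < 0)) next
      beta[free] <- b
    }
    rss <- sum((y - X %*% beta)^2)
    if (rss < best_rss) { best_rss <- rss; best <- beta }
  }
  best
}

#' Fit a motion model to a track's mean squared displacement
#'
#' Classifies a track's motion by fitting its time-averaged MSD curve.
#' Three model variants are supported:
#' \describe{
#'   \item{`drift_diffusion`}{\eqn{MSD(t) = 4Dt + (Vt)^2}, fit over the
#'     first 80 percent of lags (later lags average fewer pairs and are
#'     noisier) — the standard variant for filament trajectories.}
#'   \item{`drift_diffusion_locnoise`}{\eqn{MSD(t) = 4Dt + (Vt)^2 +
#'     4\sigma^2} with a static localization-noise floor, fit over lags up
#'     to half the track length — the single-molecule variant.}
#'   \item{`powerlaw_locnoise`}{\eqn{MSD(t) = C t^\alpha + 4\sigma^2}, fit
#'     over lags up to half the track length.}
#' }
#' All parameters are constrained non-negative. Independently of the model,
#' the anomalous exponent `alpha` is estimated as the slope of a straight
#' line through log MSD versus log t over the same lags, with its own
#' goodness of fit (`r2_loglog`); `alpha` near 2 indicates directed motion,
#' near 1 diffusion, near 0 a stationary noise floor.
#'
#' @param track A [track()] with at least 5 frames.
#' @param model Model variant (see Details).
#' @param lag_fraction Fraction of available lags used by
#'   `drift_diffusion`. Default 0.8.
#' @param max_lag Cap on the number of MSD lags entering the fit; `NULL`
#'   (default) uses every available lag, appropriate for the short tracks
#'   the filters admit. For very long tracks a cap (e.g. 100) avoids the
#'   large-lag regime where a single track's time-averaged MSD carries
#'   almost no information.
#' @return An object of class `msd_fit` with `coef`, `print`, `predict`,
#'   `residuals` and `plot` methods. Coefficients: `D` (um^2/s), `V`
#'   (um/s), `sigma_loc` (um), `C`, `alpha`; plus `r2_loglog` and
#'   `converged`.
#' @examples
#' tr <- generate_msd_fixture("ballistic", list(speed = 0.025))
#' coef(fit_msd(tr))[["V"]]
#' @export
fit_msd <- function(track,
                    model = c("drift_diffusion", "drift_diffusion_locnoise",
                              "powerlaw_locnoise"),
                    lag_fraction = 0.8, max_lag = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(track, "track"))
  if (length(track$frames) < 5L)
    stop("fit_msd: track ", track$track_id, " has fewer than 5 frames")
  msd <- track_msd(track, max_lag = max_lag)
  nlag <- nrow(msd)
  use <- if (model == "drift_diffusion") {
    seq_len(max(3L, floor(lag_fraction * nlag)))
  } else {
    seq_len(max(3L, floor(nlag / 2)))
  }
  use <- use[use <= nlag]
  fitdat <- msd[use, ]
  t <- fitdat$t_s; y <- fitdat$msd
  cf <- c(D = NA_real_, V = NA_real_, sigma_loc = NA_real_,
          C = NA_real_, alpha = NA_real_)
  converged <- TRUE
  fitted_vals <- rep(NA_real_, length(t))
  if (model == "drift_diffusion") {
    beta <- .nnls_small(cbind(t, t^2), y)
    cf["D"] <- beta[1] / 4; cf["V"] <- sqrt(beta[2]); cf["sigma_loc"] <- 0
    fitted_vals <- beta[1] * t + beta[2] * t^2
  } else if (model == "drift_diffusion_locnoise") {
    beta <- .nnls_small(cbind(t, t^2, 1), y)
    cf["D"] <- beta[1] / 4; cf["V"] <- sqrt(beta[2])
    cf["sigma_loc"] <- sqrt(beta[3] / 4)
    fitted_vals <- beta[1] * t + beta[2] * t^2 + beta[3]
  } else {
    # start values from the log-log line; noise floor from the first lag
    pos <- y > 0
    if (sum(pos) >= 3) {
      ll <- suppressWarnings(stats::lm(log(y[pos]) ~ log(t[pos])))
      a0 <- min(max(unname(stats::coef(ll)[2]), 0.05), 3)
      c0 <- exp(unname(stats::coef(ll)[1]))
    } else {
      a0 <- 1; c0 <- max(y[1], 1e-6)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ C * t^alpha + 4 * s2,
                        start = list(C = c0, alpha = a0, s2 = 1e-6),
                        lower = c(0, 0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      converged <- FALSE
    } else {
      b <- stats::coef(fit)
      cf["C"] <- b[["C"]]; cf["alpha"] <- b[["alpha"]]
      cf["sigma_loc"] <- sqrt(b[["s2"]])
      fitted_vals <- stats::fitted(fit)
    }
  }
  # log-log slope over the same lags (alpha for the drift models; r2 for all)
  pos <- y > 0
  if (sum(pos) >= 3) {
    ll <- suppressWarnings(stats::lm(log(y[pos]) ~ log(t[pos])))
    alpha_ll <- unname(stats::coef(ll)[2])
    r2_ll <- suppressWarnings(summary(ll)$r.squared)
  } else {
    alpha_ll <- NA_real_; r2_ll <- NA_real_
  }
  if (model != "powerlaw_locnoise") cf["alpha"] <- alpha_ll
  out <- list(coefficients = cf, model = model, msd = msd,
              lags_used = use, fitted = fitted_vals,
              r2_loglog = r2_ll, alpha_loglog = alpha_ll,
              converged = converged, track_id = track$track_id,
              frame_interval = track$frame_interval)
  class(out) <- "msd_fit"
  out
}

#' @export
coef.msd_fit <- function(object, ...) object$coefficients

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD fit (%s) of track %s: %d lags, %d used\n",
              x$model, x$track_id, nrow(x$msd), length(x$lags_used)))
  cf <- x$coefficients[!is.na(x$coefficients)]
  cat("  ", paste(sprintf("%s = %.4g", names(cf), cf), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  log-log alpha = %.3g (R2 = %.3g)%s\n",
              x$alpha_loglog, x$r2_loglog,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
predict.msd_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$msd$t_s[object$lags_used]
  cf <- object$coefficients
  switch(object$model,
    drift_diffusion = 4 * cf[["D"]] * t + (cf[["V"]] * t)^2,
    drift_diffusion_locnoise =
      4 * cf[["D"]] * t + (cf[["V"]] * t)^2 + 4 * cf[["sigma_loc"]]^2,
    powerlaw_locnoise = cf[["C"]] * t^cf[["alpha"]] + 4 * cf[["sigma_loc"]]^2)
}

#' @export
residuals.msd_fit <- function(object, ...) {
  object$msd$msd[object$lags_used] - object$fitted
}

#' @export
plot.msd_fit <- function(x, ...) {
  graphics::plot(x$msd$t_s, x$msd$msd, xlab = "lag t (s)",
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  tt <- x$msd$t_s[x$lags_used]
  graphics::lines(tt, predict(x, tt), col = 2)
  invisible(x)
}
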