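#' Single-particle track
#'
#' A track is an ordered set of per-frame 2-D positions with a fixed frame
#' interval — the unit of trajectory analysis. Positions are in micrometre,
#' the frame interval in seconds. Tracks with at least five frames are
#' eligible for line and MSD fitting.
#'
#' @param track_id Identifier (coerced to character).
#' @param frames Strictly increasing integer frame indices.
#' @param x,y Positions per frame, micrometre.
#' @param frame_interval Time between successive frames, seconds.
#' @param meta Optional named list of metadata (e.g. a recorded fit quality
#'   for simulated tracks).
#' @return An object of class `track`.
#' @export
track <- function(track_id, frames, x, y, frame_interval, meta = list()) {
  frames <- as.integer(frames)
  stopifnot(length(frames) == length(x), length(x) == length(y),
            length(frames) >= 2L, is.numeric(x), is.numeric(y),
            all(is.finite(x)), all(is.finite(y)),
            is.numeric(frame_interval), frame_interval > 0)
  if (any(diff(frames) <= 0L))
    stop("track ", track_id, ": frames must be strictly increasing")
  structure(list(track_id = as.character(track_id), frames = frames,
                 x = as.numeric(x), y = as.numeric(y),
                 frame_interval = frame_interval, meta = meta),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("Track %s: %d frames, dt = %g s, start (%.3f, %.3f) um\n",
              x$track_id, length(x$frames), x$frame_interval, x$x[1], x$y[1]))
  invisible(x)
}

#' @rdname track
#' @param tracks A list of [track()] objects.
#' @export
track_set <- function(tracks) {
  stopifnot(is.list(tracks),
            all(vapply(tracks, inherits, logical(1), "track")))
  structure(tracks, class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  nf <- vapply(x, function(t) length(t$frames), integer(1))
  cat(sprintf("Track set: %d tracks, %d-%d frames each\n",
              length(x), if (length(nf)) min(nf) else 0L,
              if (length(nf)) max(nf) else 0L))
  invisible(x)
}

#' @export
as.data.frame.track <- function(x, ...) {
  data.frame(track_id = x$track_id, frame = x$frames,
             x_um = x$x, y_um = x$y)
}

#' @export
as.data.frame.track_set <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' @export
`[.track_set` <- function(x, i) track_set(unclass(x)[i])

# number of frames per track
track_lengths <- function(tracks) {
  vapply(tracks, function(t) length(t$frames), integer(1))
}
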