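#' Read tracks from a CSV table
#'
#' Two dialects are supported. The native dialect has columns
#' `track_id, frame, x_um, y_um` (positions in micrometre) and may carry
#' the frame interval in a header comment line
#' `# frame_interval_s: <seconds>`. The `trackmate_export` dialect is the
#' simplified spot-table export of common trackers, with columns
#' `TRACK_ID, FRAME, POSITION_X, POSITION_Y`; when `pixel_size` is given
#' the positions are taken to be in pixels and are converted to
#' micrometre.
#'
#' Tracks are sorted by id then frame. Non-monotone frames within a track
#' are an error naming the track. Tracks shorter than 5 frames are kept
#' but flagged with a warning — they are not eligible for line/MSD fits.
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"trackmate_export"`.
#' @param frame_interval Frame interval in seconds; overrides any header
#'   value. Required if the file carries none.
#' @param pixel_size Pixel size in um/pixel for pixel-based dialects.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, dialect = c("native", "trackmate_export"),
                        frame_interval = NULL, pixel_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_tracks: no such file: ", path)
  header <- readLines(path, n = 20L)
  hline <- grep("^#\\s*frame_interval_s\\s*[:=]", header, value = TRUE)
  if (is.null(frame_interval)) {
    if (length(hline)) {
      frame_interval <- as.numeric(sub("^#\\s*frame_interval_s\\s*[:=]\\s*",
                                       "", hline[1]))
    } else stop("read_tracks: frame_interval not given and not in header")
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cols <- switch(dialect,
    native = c(id = "track_id", frame = "frame", x = "x_um", y = "y_um"),
    trackmate_export = c(id = "TRACK_ID", frame = "FRAME",
                         x = "POSITION_X", y = "POSITION_Y"))
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("read_tracks: missing required column(s): ",
         paste(miss, collapse = ", "))
  scale <- if (dialect == "trackmate_export" && !is.null(pixel_size))
    pixel_size else 1
  df <- df[order(df[[cols["id"]]], df[[cols["frame"]]]), ]
  ids <- unique(df[[cols["id"]]])
  tracks <- lapply(ids, function(id) {
    sub <- df[df[[cols["id"]]] == id, ]
    fr <- sub[[cols["frame"]]]
    if (any(diff(fr) <= 0))
      stop("read_tracks: non-monotone frames in track ", id)
    if (nrow(sub) < 2L) return(NULL)
    track(id, fr, sub[[cols["x"]]] * scale, sub[[cols["y"]]] * scale,
          frame_interval)
  })
  drop <- vapply(tracks, is.null, logical(1))
  if (any(drop))
    warning("read_tracks: dropped ", sum(drop), " single-point track(s)")
  tracks <- tracks[!drop]
  short <- vapply(tracks, function(t) length(t$frames) < 5L, logical(1))
  if (any(short))
    warning("read_tracks: ", sum(short),
            " track(s) shorter than 5 frames are not fit-eligible")
  track_set(tracks)
}

#' Write tracks to the native CSV dialect
#'
#' @param tracks A [track_set()].
#' @param path Output CSV path; the frame interval is written as a header
#'   comment so [read_tracks()] round-trips.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"), length(tracks) >= 1L)
  df <- as.data.frame(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval_s: %.10g",
                     tracks[[1]]$frame_interval), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cell contours from CSV or JSON
#'
#' CSV dialect: columns `cell_id, vertex_index, x_um, y_um`. JSON
#' alternative (by file extension): an object mapping cell ids to objects
#' with `x` and `y` vertex arrays, optionally a top-level `pixel_size_um`.
#'
#' @param path File path (`.csv` or `.json`).
#' @param pixel_size Pixel size recorded on the contours, um. Default
#'   0.065 (overridden by a JSON `pixel_size_um` field).
#' @return Named list of [cell_contour()] objects.
#' @export
read_contours <- function(path, pixel_size = 0.065) {
  if (!file.exists(path)) stop("read_contours: no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(obj$pixel_size_um)) {
      pixel_size <- obj$pixel_size_um
      obj$pixel_size_um <- NULL
    }
    cells <- lapply(obj, function(c0)
      cell_contour(c0$x, c0$y, pixel_size = pixel_size))
    return(cells)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_id", "vertex_index", "x_um", "y_um"), names(df))
  if (length(miss))
    stop("read_contours: missing required column(s): ",
         paste(miss, collapse = ", "))
  df <- df[order(df$cell_id, df$vertex_index), ]
  out <- lapply(split(df, df$cell_id), function(sub)
    cell_contour(sub$x_um, sub$y_um, pixel_size = pixel_size))
  out
}

#' Write cell contours to the CSV dialect
#'
#' @param contours Named list of [cell_contour()] objects (or a single
#'   contour).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "cell_contour")) contours <- list(cell1 = contours)
  ids <- names(contours) %||% paste0("cell", seq_along(contours))
  df <- do.call(rbind, lapply(seq_along(contours), function(i) {
    cbind(cell_id = ids[i], as.data.frame(contours[[i]]))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# known configuration keys: flat key = value files, strict parsing
.config_keys <- function() {
  c("seed", "output_dir", "log_level",
    paste0("tracks.", setdiff(names(formals(trajectory_scenario)), "")),
    paste0("contour.", setdiff(names(formals(contour_scenario)), "")),
    paste0("filter.", names(formals(filter_policy))),
    paste0("mechanics.", names(formals(mechanics_params))),
    "io.frame_interval_s", "io.pixel_size_um")
}

#' Read a flat key-value run configuration
#'
#' Parses `key = value` lines (`#` comments and blank lines ignored).
#' Values that parse as numbers become numeric; `true`/`false` become
#' logical; comma-separated values become vectors. Unknown keys are
#' rejected — keys are namespaced as `tracks.*`, `contour.*`, `filter.*`,
#' `mechanics.*`, `io.*` plus `seed`, `output_dir`, `log_level`.
#'
#' @param path Config file path.
#' @return Named list of parsed values, class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad))
    stop("read_config: unparseable line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  unknown <- setdiff(keys, .config_keys())
  if (length(unknown))
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("read_config: duplicate key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) return(num)
    if (all(tolower(parts) %in% c("true", "false")))
      return(tolower(parts) == "true")
    if (length(parts) == 1L) parts else parts
  }
  out <- stats::setNames(lapply(vals, parse_val), keys)
  class(out) <- "run_config"
  out
}

#' Write the resolved configuration next to run outputs
#'
#' @param config A named list (e.g. a `run_config`).
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
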