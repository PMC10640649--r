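#' Construct a single particle track
#'
#' A track is one particle's time-ordered 2-D positions.  Positions are in
#' micrometres, frames are 0-based integers, and `dt` is the frame interval
#' in seconds, so elapsed time between frames `f1` and `f2` is `(f2 - f1) * dt`.
#' Frame gaps (non-consecutive frames, e.g. from gap-closing in the upstream
#' tracker) are allowed and preserved.
#'
#' @param track_id character scalar, unique identifier.
#' @param frames integer vector, strictly increasing, 0-based.
#' @param x,y numeric vectors of positions in micrometres.
#' @param dt frame interval in seconds (> 0).
#' @param cell_id character scalar, the cell the track belongs to.
#' @param condition character scalar, experimental condition label.
#' @return An object of class `"perox_track"`.
#' @export
track <- function(track_id, frames, x, y, dt, cell_id = "cell1",
                  condition = "default") {
  track_id <- as.character(track_id)
  frames <- as.integer(frames)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(frames) < 2L)
    stop("a track needs at least 2 positions", call. = FALSE)
  if (length(x) != length(frames) || length(y) != length(frames))
    stop("frames, x and y must have equal length", call. = FALSE)
  if (any(diff(frames) <= 0L))
    stop("frames must be strictly increasing", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar (seconds)", call. = FALSE)
  structure(
    list(track_id = track_id, frames = frames, x = x, y = y, dt = dt,
         cell_id = as.character(cell_id), condition = as.character(condition)),
    class = "perox_track")
}

#' Number of steps (displacements) of a track
#' @param tr a `perox_track`.
#' @return integer, `length(positions) - 1`.
#' @export
n_steps <- function(tr) length(tr$frames) - 1L

#' @export
print.perox_track <- function(x, ...) {
  cat(sprintf("<perox_track %s> %d positions (%d steps), dt = %g s, cell %s, condition %s\n",
              x$track_id, length(x$frames), n_steps(x), x$dt, x$cell_id,
              x$condition))
  invisible(x)
}

#' Bundle tracks into a track set
#'
#' @param tracks list of `perox_track` objects with unique ids.
#' @return An object of class `"perox_trackset"`: a list of tracks, indexable
#'   by track id.
#' @export
track_set <- function(tracks = list()) {
  stopifnot(is.list(tracks))
  for (tr in tracks)
    if (!inherits(tr, "perox_track")) stop("all elements must be perox_track")
  ids <- vapply(tracks, `[[`, "", "track_id")
  if (anyDuplicated(ids)) stop("duplicate track_id in track set", call. = FALSE)
  names(tracks) <- ids
  structure(tracks, class = "perox_trackset")
}

#' @export
print.perox_trackset <- function(x, ...) {
  conds <- vapply(unclass(x), `[[`, "", "condition")
  cells <- vapply(unclass(x), `[[`, "", "cell_id")
  cat(sprintf("<perox_trackset> %d tracks, %d cells, %d condition(s)\n",
              length(x), length(unique(cells)), length(unique(conds))))
  invisible(x)
}

#' @export
`[.perox_trackset` <- function(x, i) track_set(unclass(x)[i])

#' Condition -> cell -> track ids grouping of a track set
#' @param ts a `perox_trackset`.
#' @return nested named list `condition -> cell_id -> character vector of ids`.
#' @export
track_grouping <- function(ts) {
  out <- list()
  for (tr in unclass(ts))
    out[[tr$condition]][[tr$cell_id]] <-
      c(out[[tr$condition]][[tr$cell_id]], tr$track_id)
  out
}

#' Convert a track set to a long data frame
#' @param ts a `perox_trackset`.
#' @return data.frame with columns track_id, frame, x, y, cell_id, condition.
#' @export
tracks_to_df <- function(ts) {
  do.call(rbind, lapply(unclass(ts), function(tr)
    data.frame(track_id = tr$track_id, frame = tr$frames, x = tr$x, y = tr$y,
               cell_id = tr$cell_id, condition = tr$condition,
               stringsAsFactors = FALSE)))
}

#' Read tracks from a CSV table
#'
#' Expects a comma-separated file with header
#' `track_id,frame,x,y[,cell_id,condition]`; positions in micrometres.  Rows
#' may appear in any order; they are sorted by frame within each track.
#'
#' @param path file path.
#' @param dt frame interval in seconds.
#' @return a `perox_trackset`.
#' @export
read_tracks_csv <- function(path, dt) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("track CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df[c("track_id", "frame")]))
    stop("duplicate (track_id, frame) rows in ", path, call. = FALSE)
  stem <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(df$cell_id)) df$cell_id <- stem
  if (is.null(df$condition)) df$condition <- "default"
  tracks_from_df(df, dt)
}

#' Assemble a track set from a long data frame
#' @param df data.frame with columns track_id, frame, x, y and optionally
#'   cell_id, condition.
#' @param dt frame interval in seconds.
#' @return a `perox_trackset`.
#' @export
tracks_from_df <- function(df, dt) {
  if (is.null(df$cell_id)) df$cell_id <- "cell1"
  if (is.null(df$condition)) df$condition <- "default"
  pieces <- split(df, df$track_id)
  tracks <- lapply(pieces, function(p) {
    p <- p[order(p$frame), , drop = FALSE]
    track(p$track_id[1], p$frame, p$x, p$y, dt,
          cell_id = p$cell_id[1], condition = p$condition[1])
  })
  track_set(unname(tracks))
}

#' Write tracks to CSV
#' @param ts a `perox_trackset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(ts, path) {
  df <- tracks_to_df(ts)
  # 17 significant digits round-trip doubles exactly
  df$x <- format(df$x, digits = 17, trim = TRUE, scientific = FALSE)
  df$y <- format(df$y, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter tracks by minimum number of steps
#'
#' Retains tracks with at least `min_steps` displacements (positions minus
#' one).  The default of 50 steps corresponds to 5 s of tracking at 10
#' frames/s and suppresses the influence of very short tracks.
#'
#' @param ts a `perox_trackset`.
#' @param min_steps minimum number of steps (>= 1).
#' @return the filtered `perox_trackset` (possibly empty).
#' @export
filter_min_steps <- function(ts, min_steps = 50L) {
  stopifnot(min_steps >= 1L)
  keep <- vapply(unclass(ts), function(tr) n_steps(tr) >= min_steps, NA)
  track_set(unclass(ts)[keep])
}
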