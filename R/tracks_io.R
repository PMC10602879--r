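#' Single-particle trajectory
#'
#' A particle's time-ordered 2D positions at a fixed frame interval. Frames
#' are strictly consecutive: readers split tracks at gaps rather than bridge
#' them.
#'
#' @param track_id identifier
#' @param x,y numeric positions in micrometres, equal length
#' @param frame_interval frame interval in seconds (> 0)
#' @param frame0 frame number of the first position (default 0)
#' @return An object of class `Trajectory` with elements `track_id`, `x`,
#'   `y`, `frames`, `t` (seconds) and `frame_interval`.
#' @export
trajectory <- function(track_id, x, y, frame_interval, frame0 = 0L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("empty trajectory")
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive")
  }
  frames <- frame0 + seq_along(x) - 1L
  structure(
    list(track_id = track_id, x = x, y = y, frames = frames,
         t = frames * frame_interval, frame_interval = frame_interval),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %s: %d frames at dt = %g s (%.1f s)\n",
              as.character(x$track_id), length(x$x), x$frame_interval,
              (length(x$x) - 1) * x$frame_interval))
  invisible(x)
}

#' @export
length.Trajectory <- function(x) length(x$x)

#' Read a TrackMate-style track table into trajectories
#'
#' Expects a CSV with at least columns for the track id, frame and x/y
#' positions. Recognized column names (case-insensitive): `track_id`/
#' `TRACK_ID`/`track`, `frame`/`FRAME`, `x`/`x_um`/`POSITION_X`,
#' `y`/`y_um`/`POSITION_Y`. Positions may be in pixels; `scale_um_per_px`
#' converts them to micrometres at read time. Rows are grouped by track id
#' and sorted by frame; a gap in the frame numbering splits the track into
#' separate trajectories (no gap closing), with `-a`, `-b`, ... appended to
#' the id of the later fragments.
#'
#' @param path CSV file
#' @param frame_interval frame interval in seconds
#' @param scale_um_per_px multiplicative conversion applied to x and y
#'   (default 1, i.e. positions already in micrometres)
#' @return A list of [trajectory()] objects (possibly empty)
#' @export
read_tracks <- function(path, frame_interval, scale_um_per_px = 1) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pick <- function(aliases) {
    hit <- match(tolower(aliases), tolower(names(df)))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) stop("missing required column: one of ",
                                paste(aliases, collapse = "/"))
    names(df)[hit[1]]
  }
  if (nrow(df) == 0L) return(list())
  c_id <- pick(c("track_id", "track"))
  c_fr <- pick(c("frame"))
  c_x <- pick(c("x_um", "x", "position_x"))
  c_y <- pick(c("y_um", "y", "position_y"))
  if (anyDuplicated(df[, c(c_id, c_fr)])) {
    stop("duplicate (track, frame) rows in ", path)
  }
  out <- list()
  for (id in unique(df[[c_id]])) {
    sub <- df[df[[c_id]] == id, , drop = FALSE]
    sub <- sub[order(sub[[c_fr]]), , drop = FALSE]
    runs <- cumsum(c(1L, diff(sub[[c_fr]]) != 1L))
    for (r in unique(runs)) {
      seg <- sub[runs == r, , drop = FALSE]
      seg_id <- if (max(runs) > 1L) paste0(id, "-", letters[r]) else as.character(id)
      out[[length(out) + 1L]] <- trajectory(
        seg_id,
        seg[[c_x]] * scale_um_per_px,
        seg[[c_y]] * scale_um_per_px,
        frame_interval,
        frame0 = seg[[c_fr]][1]
      )
    }
  }
  out
}

#' Write trajectories to a track CSV
#'
#' Columns: `track_id, frame, t_s, x_um, y_um` -- the same layout
#' [read_tracks()] consumes, so write-then-read round-trips.
#'
#' @param trajectories list of [trajectory()] objects
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_tracks <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    data.frame(track_id = as.character(tr$track_id), frame = tr$frames,
               t_s = tr$t, x_um = tr$x, y_um = tr$y,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = character(), frame = integer(), t_s = numeric(),
               x_um = numeric(), y_um = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis summary as JSON
#'
#' @param summary a named list of scalars or simple vectors
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
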