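#' Construct a lysosome track
#'
#' A track is a uniformly sampled axial position series for one particle.
#' Positions are in micrometres with the soma at 0 and increasing away from
#' it; retrograde movement therefore decreases position.
#'
#' @param track_id identifier (coerced to character).
#' @param group group label (e.g. genotype).
#' @param positions numeric vector of axial positions (um), one per frame,
#'   all finite and >= 0, length >= 2.
#' @param frame_interval_s sampling interval in seconds (> 0).
#' @param pixel_size_um spatial calibration in um per pixel (> 0).
#' @return an object of class `track`.
#' @export
track <- function(track_id, group, positions, frame_interval_s = 0.5,
                  pixel_size_um = 0.1) {
  if (!is.numeric(positions) || length(positions) < 2L)
    abort("a track needs at least 2 position samples")
  if (any(!is.finite(positions)))
    abort("track positions must all be finite")
  if (any(positions < 0))
    abort("track positions must be >= 0 (soma at 0, increasing away)")
  assert_scalar_number(frame_interval_s, "frame_interval_s", 0, strict_lower = TRUE)
  assert_scalar_number(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  structure(list(track_id = as.character(track_id), group = as.character(group),
                 positions = as.numeric(positions),
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s> group=%s, %d frames @ %gs, pixel %g um\n",
              x$track_id, x$group, length(x$positions), x$frame_interval_s,
              x$pixel_size_um))
  invisible(x)
}

#' Traced duration of a track in seconds
#'
#' Duration spanned by the sampled frames, i.e. (n_frames - 1) times the
#' frame interval.
#'
#' @param x a `track`.
#' @return seconds.
#' @export
track_duration_s <- function(x) (length(x$positions) - 1L) * x$frame_interval_s

#' Convert a list of tracks to a long data frame
#'
#' @param tracks list of `track` objects.
#' @return data frame with columns track_id, group, frame (0-based), time_s,
#'   position_um.
#' @export
tracks_to_df <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr) {
    n <- length(tr$positions)
    data.frame(track_id = tr$track_id, group = tr$group, frame = seq_len(n) - 1L,
               time_s = (seq_len(n) - 1L) * tr$frame_interval_s,
               position_um = tr$positions, stringsAsFactors = FALSE)
  }))
}

#' Rebuild track objects from a long data frame
#'
#' @param df data frame as produced by [tracks_to_df()].
#' @param frame_interval_s,pixel_size_um calibration shared by all tracks.
#' @return list of `track` objects.
#' @export
df_to_tracks <- function(df, frame_interval_s = 0.5, pixel_size_um = 0.1) {
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    track(d$track_id[1], d$group[1], d$position_um,
          frame_interval_s = frame_interval_s, pixel_size_um = pixel_size_um)
  })
}

#' Write / read tracks as CSV
#'
#' @param tracks list of `track` objects.
#' @param file path.
#' @return `read_tracks_csv` returns a list of `track` objects.
#' @export
write_tracks_csv <- function(tracks, file) {
  utils::write.csv(tracks_to_df(tracks), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tracks_csv
#' @param frame_interval_s,pixel_size_um calibration (not stored in the CSV).
#' @export
read_tracks_csv <- function(file, frame_interval_s = 0.5, pixel_size_um = 0.1) {
  df_to_tracks(utils::read.csv(file, stringsAsFactors = FALSE),
               frame_interval_s = frame_interval_s, pixel_size_um = pixel_size_um)
}
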