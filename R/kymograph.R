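#' Render tracks into a kymograph raster
#'
#' Rows index time (row 0 = first frame) and columns index axial position with
#' column 0 on the soma side. Each particle increments the pixel its position
#' falls in at each frame; the per-track pixel paths are returned alongside so
#' tracing can be exercised without an image-analysis step.
#'
#' @param tracks list of [track()] objects sharing calibration.
#' @param width_px optional raster width in pixels; if the tracks need more
#'   columns an error reports the required width.
#' @return list with `image` (frames x width integer matrix of particle
#'   counts), `paths` (data frame track_id, group, row_px, col_px with 0-based
#'   pixel coordinates), `pixel_size_um`, `frame_interval_s`.
#' @export
render_kymograph <- function(tracks, width_px = NULL) {
  if (!length(tracks)) abort("no tracks to render")
  px <- unique(vapply(tracks, function(t) t$pixel_size_um, numeric(1)))
  dt <- unique(vapply(tracks, function(t) t$frame_interval_s, numeric(1)))
  if (length(px) != 1L || length(dt) != 1L)
    abort("all tracks must share pixel size and frame interval")
  cols <- lapply(tracks, function(t) as.integer(round(t$positions / px)))
  required <- max(unlist(cols)) + 1L
  if (is.null(width_px)) width_px <- required
  if (width_px < required)
    abort("raster width ", width_px, " px too small; tracks require ",
          required, " px")
  n_rows <- max(vapply(tracks, function(t) length(t$positions), integer(1)))
  img <- matrix(0L, nrow = n_rows, ncol = width_px)
  paths <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]; cc <- cols[[i]]
    rows <- seq_along(cc) - 1L
    img[cbind(rows + 1L, cc + 1L)] <- img[cbind(rows + 1L, cc + 1L)] + 1L
    paths[[i]] <- data.frame(track_id = tr$track_id, group = tr$group,
                             row_px = rows, col_px = cc,
                             stringsAsFactors = FALSE)
  }
  list(image = img, paths = do.call(rbind, paths), pixel_size_um = px,
       frame_interval_s = dt)
}

#' Convert a traced kymograph path to a track
#'
#' Replaces GUI kymograph tracing: a polyline in pixel coordinates (0-based;
#' rows = time, columns = axial position) is resampled at every integer frame
#' row by linear interpolation and converted to micrometres, placing the soma
#' at position 0 according to which side of the image it lies on.
#'
#' @param path data frame with columns `row_px` and `col_px`; vertex rows must
#'   be strictly increasing (a kymograph path cannot revisit a time row).
#' @param pixel_size_um,frame_interval_s calibration.
#' @param soma_side `"left"` (column 0 is the soma) or `"right"`.
#' @param width_px raster width; required when `soma_side = "right"`.
#' @param track_id,group labels for the resulting track.
#' @return a [track()].
#' @export
path_to_track <- function(path, pixel_size_um, frame_interval_s,
                          soma_side = c("left", "right"), width_px = NULL,
                          track_id = "traced", group = "unknown") {
  soma_side <- match.arg(soma_side)
  if (!all(c("row_px", "col_px") %in% names(path)))
    abort("path needs columns row_px and col_px")
  if (nrow(path) < 2L) abort("a path needs at least 2 vertices")
  if (any(diff(path$row_px) <= 0))
    abort("path rows must be strictly increasing: a kymograph path cannot revisit a time row")
  rows <- seq(ceiling(path$row_px[1]), floor(path$row_px[nrow(path)]))
  col <- stats::approx(path$row_px, path$col_px, xout = rows)$y
  pos <- if (soma_side == "left") col * pixel_size_um else {
    if (is.null(width_px))
      abort("width_px is required when soma_side = 'right'")
    (width_px - 1 - col) * pixel_size_um
  }
  track(track_id, group, pos, frame_interval_s = frame_interval_s,
        pixel_size_um = pixel_size_um)
}

#' Re-trace rendered kymograph paths into tracks
#'
#' Convenience wrapper applying [path_to_track()] to every per-track path
#' returned by [render_kymograph()].
#'
#' @param kymo result of [render_kymograph()].
#' @param soma_side side of the soma in the raster.
#' @return list of [track()] objects.
#' @export
trace_kymograph_paths <- function(kymo, soma_side = "left") {
  lapply(split(kymo$paths, kymo$paths$track_id), function(p) {
    p <- p[order(p$row_px), ]
    path_to_track(p, kymo$pixel_size_um, kymo$frame_interval_s,
                  soma_side = soma_side, width_px = ncol(kymo$image),
                  track_id = p$track_id[1], group = p$group[1])
  })
}

#' Write a kymograph raster as a plain-text PGM image
#'
#' @param kymo result of [render_kymograph()].
#' @param file output path (portable graymap, text encoding).
#' @export
write_kymograph_pgm <- function(kymo, file) {
  img <- kymo$image
  mx <- max(1L, max(img))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(mx)), con)
  write.table(img, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
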