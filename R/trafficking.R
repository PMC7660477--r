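#' Run segmentation parameters
#'
#' @param min_run_frames minimum frames a movement must last to count as a run
#'   (default 3, i.e. 1.5 s at 0.5 s per frame).
#' @param min_step_um per-frame displacement below which a step is treated as
#'   stationary; `NULL` (default) uses the track's pixel size, the tracing
#'   resolution bound.
#' @param min_trace_s minimum traced duration for a track to enter the
#'   retrograde metrics (default 60 s).
#' @param eligibility how `min_trace_s` is applied: `"total"` (total traced
#'   duration, default) or `"retrograde_time"` (cumulative time spent in
#'   retrograde runs).
#' @param speed_weighting per-track mean retrograde speed as unweighted mean of
#'   per-run speeds (`"run_mean"`, default) or duration-weighted
#'   (`"duration_weighted"`).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(min_run_frames = 3L, min_step_um = NULL,
                                min_trace_s = 60,
                                eligibility = c("total", "retrograde_time"),
                                speed_weighting = c("run_mean", "duration_weighted")) {
  min_run_frames <- assert_count(min_run_frames, "min_run_frames", min = 2L)
  if (!is.null(min_step_um))
    assert_scalar_number(min_step_um, "min_step_um", 0)
  assert_scalar_number(min_trace_s, "min_trace_s", 0)
  structure(list(min_run_frames = min_run_frames, min_step_um = min_step_um,
                 min_trace_s = min_trace_s,
                 eligibility = match.arg(eligibility),
                 speed_weighting = match.arg(speed_weighting)),
            class = "segmentation_params")
}

empty_runs <- function() {
  data.frame(track_id = character(), direction = character(),
             start_frame = integer(), end_frame = integer(),
             length_um = numeric(), duration_s = numeric(),
             speed_um_per_s = numeric(), stringsAsFactors = FALSE)
}

#' Segment a track into directional runs
#'
#' Each per-frame step is classified as anterograde (displacement >=
#' `min_step_um`), retrograde (<= -`min_step_um`) or stationary. A run is a
#' maximal block of consecutive steps of one moving sign spanning at least
#' `min_run_frames` frames; it ends at the first step of a different state
#' (that terminating frame is not part of the run). Frame indices are 0-based
#' and inclusive; run length is the net displacement over the block.
#'
#' @param track a [track()].
#' @param params a [segmentation_params()].
#' @return data frame of runs (possibly 0 rows): track_id, direction,
#'   start_frame, end_frame, length_um, duration_s, speed_um_per_s.
#' @export
segment_runs <- function(track, params = segmentation_params()) {
  if (!inherits(track, "track")) abort("segment_runs expects a track object")
  pos <- track$positions
  if (any(!is.finite(pos))) abort("track has non-finite positions")
  if (length(pos) < params$min_run_frames) return(empty_runs())
  min_step <- if (is.null(params$min_step_um)) track$pixel_size_um else
    params$min_step_um
  d <- diff(pos)
  sg <- integer(length(d))
  sg[d >= min_step] <- 1L
  sg[d <= -min_step] <- -1L
  min_steps <- params$min_run_frames - 1L
  # maximal same-sign blocks
  r <- rle(sg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= min_steps
  if (!any(keep)) return(empty_runs())
  s <- starts[keep]; e <- ends[keep]; v <- r$values[keep]
  dt <- track$frame_interval_s
  out <- data.frame(
    track_id = track$track_id,
    direction = ifelse(v > 0, "anterograde", "retrograde"),
    start_frame = s - 1L, end_frame = e,
    length_um = abs(pos[e + 1L] - pos[s]),
    duration_s = (e - s + 1L) * dt,
    stringsAsFactors = FALSE)
  out$speed_um_per_s <- out$length_um / out$duration_s
  out
}

#' Classify a track from its run list
#'
#' Immobile when there are no runs; anterograde or retrograde when all runs
#' share that direction; bidirectional when both occur.
#'
#' @param runs run data frame from [segment_runs()] (one track only).
#' @return one of `"anterograde"`, `"retrograde"`, `"bidirectional"`,
#'   `"immobile"`.
#' @export
classify_track <- function(runs) {
  if (nrow(runs) && length(unique(runs$track_id)) > 1L)
    abort("classify_track received runs from more than one track")
  has_a <- any(runs$direction == "anterograde")
  has_r <- any(runs$direction == "retrograde")
  if (!has_a && !has_r) "immobile"
  else if (has_a && has_r) "bidirectional"
  else if (has_a) "anterograde"
  else "retrograde"
}

movement_classes <- c("anterograde", "retrograde", "bidirectional", "immobile")

#' Per-track retrograde transport metrics
#'
#' A track is eligible when it was traced for at least `min_trace_s` (total
#' traced duration by default; cumulative retrograde run time under the
#' `"retrograde_time"` eligibility mode) and has at least one retrograde run.
#' Metrics are `NA` for ineligible tracks.
#'
#' @param track a [track()].
#' @param runs runs from [segment_runs()] on that track.
#' @param params a [segmentation_params()].
#' @return list: track_id, eligible, traced_s, n_retro_runs,
#'   mean_retro_speed_um_per_s, retro_run_lengths_um, total_retro_distance_um.
#' @export
retrograde_metrics <- function(track, runs, params = segmentation_params()) {
  retro <- runs[runs$direction == "retrograde", , drop = FALSE]
  traced <- switch(params$eligibility,
                   total = track_duration_s(track),
                   retrograde_time = sum(retro$duration_s))
  eligible <- traced >= params$min_trace_s && nrow(retro) > 0
  if (!eligible)
    return(list(track_id = track$track_id, eligible = FALSE, traced_s = traced,
                n_retro_runs = nrow(retro),
                mean_retro_speed_um_per_s = NA_real_,
                retro_run_lengths_um = numeric(0),
                total_retro_distance_um = NA_real_))
  speed <- switch(params$speed_weighting,
                  run_mean = mean(retro$speed_um_per_s),
                  duration_weighted = sum(retro$length_um) / sum(retro$duration_s))
  list(track_id = track$track_id, eligible = TRUE, traced_s = traced,
       n_retro_runs = nrow(retro),
       mean_retro_speed_um_per_s = speed,
       retro_run_lengths_um = retro$length_um,
       total_retro_distance_um = sum(retro$length_um))
}

#' Group-by-class movement contingency table
#'
#' @param classifications data frame with columns `track_id`, `group`,
#'   `class`.
#' @param groups group labels expected in the table (order of rows); labels in
#'   the data but not in `groups` raise an error.
#' @return integer matrix, groups x movement classes.
#' @export
movement_class_table <- function(classifications,
                                 groups = unique(classifications$group)) {
  unknown <- setdiff(unique(classifications$group), groups)
  if (length(unknown))
    abort("unknown group label(s): ", paste(unknown, collapse = ", "))
  bad <- setdiff(unique(classifications$class), movement_classes)
  if (length(bad))
    abort("unknown movement class(es): ", paste(bad, collapse = ", "))
  tab <- table(factor(classifications$group, levels = groups),
               factor(classifications$class, levels = movement_classes))
  m <- matrix(as.integer(tab), nrow = length(groups),
              dimnames = list(groups, movement_classes))
  m
}

#' Full trafficking comparison between two groups
#'
#' Segments and classifies every track, tabulates movement classes and runs
#' the study's comparisons: a chi-square test on class proportions, a
#' Mann-Whitney test on retrograde run lengths (pooled from eligible tracks by
#' default), and Mann-Whitney tests on per-track mean retrograde speed and
#' total retrograde distance over eligible tracks.
#'
#' @param tracks list of [track()] objects covering exactly two groups.
#' @param params a [segmentation_params()].
#' @param run_pool `"eligible"` (runs from min-trace-eligible tracks, default)
#'   or `"all"` (runs from every track).
#' @return list of class `trafficking_report`.
#' @export
compare_trafficking <- function(tracks, params = segmentation_params(),
                                run_pool = c("eligible", "all")) {
  run_pool <- match.arg(run_pool)
  groups <- unique(vapply(tracks, function(t) t$group, character(1)))
  if (length(groups) != 2L)
    abort("compare_trafficking needs exactly two groups, got ",
          length(groups))
  runs_by_track <- lapply(tracks, segment_runs, params = params)
  runs <- do.call(rbind, c(runs_by_track, list(empty_runs())))
  cls <- data.frame(
    track_id = vapply(tracks, function(t) t$track_id, character(1)),
    group = vapply(tracks, function(t) t$group, character(1)),
    class = vapply(runs_by_track, classify_track, character(1)),
    stringsAsFactors = FALSE)
  tab <- movement_class_table(cls, groups)
  occupied <- tab[, colSums(tab) > 0, drop = FALSE]
  chis <- if (ncol(occupied) >= 2L && all(rowSums(occupied) > 0)) {
    c(chi_square_independence(occupied), computable = TRUE)
  } else list(computable = FALSE, statistic = NA_real_, df = NA_real_,
              p_value = NA_real_,
              reason = "fewer than two occupied movement classes or an empty group")

  metrics <- Map(retrograde_metrics, tracks, runs_by_track,
                 MoreArgs = list(params = params))
  met_df <- data.frame(
    track_id = vapply(metrics, `[[`, character(1), "track_id"),
    group = cls$group,
    eligible = vapply(metrics, `[[`, logical(1), "eligible"),
    mean_retro_speed_um_per_s = vapply(metrics, `[[`, numeric(1),
                                       "mean_retro_speed_um_per_s"),
    total_retro_distance_um = vapply(metrics, `[[`, numeric(1),
                                     "total_retro_distance_um"),
    stringsAsFactors = FALSE)

  pool_ids <- if (run_pool == "eligible") met_df$track_id[met_df$eligible] else
    met_df$track_id
  retro_runs <- runs[runs$direction == "retrograde" &
                       runs$track_id %in% pool_ids, , drop = FALSE]
  retro_runs$group <- cls$group[match(retro_runs$track_id, cls$track_id)]

  g1 <- groups[1]; g2 <- groups[2]
  two_group <- function(x, y, what) {
    if (!length(x) || !length(y))
      return(list(test = what, computable = FALSE,
                  reason = "a group has no eligible observations"))
    res <- mann_whitney(x, y)
    res$test <- what; res$computable <- TRUE
    res
  }
  rl <- two_group(retro_runs$length_um[retro_runs$group == g1],
                  retro_runs$length_um[retro_runs$group == g2],
                  "retrograde run length (um)")
  elig <- met_df[met_df$eligible, , drop = FALSE]
  sp <- two_group(elig$mean_retro_speed_um_per_s[elig$group == g1],
                  elig$mean_retro_speed_um_per_s[elig$group == g2],
                  "mean retrograde speed (um/s)")
  td <- two_group(elig$total_retro_distance_um[elig$group == g1],
                  elig$total_retro_distance_um[elig$group == g2],
                  "total retrograde distance (um)")

  structure(list(
    groups = groups,
    n_tracks = nrow(cls),
    movement_table = tab,
    class_test = chis,
    runs = runs,
    run_pool = run_pool,
    n_runs = c(setNames(sum(retro_runs$group == g1), g1),
               setNames(sum(retro_runs$group == g2), g2)),
    n_eligible_tracks = c(setNames(sum(elig$group == g1), g1),
                          setNames(sum(elig$group == g2), g2)),
    run_length_medians = c(
      setNames(median(retro_runs$length_um[retro_runs$group == g1]), g1),
      setNames(median(retro_runs$length_um[retro_runs$group == g2]), g2)),
    run_length_test = rl,
    speed_test = sp,
    total_distance_test = td,
    track_metrics = met_df,
    classifications = cls), class = "trafficking_report")
}

#' @export
print.trafficking_report <- function(x, ...) {
  cat("Lysosome trafficking comparison:", paste(x$groups, collapse = " vs "), "\n")
  cat("  tracks classified:", x$n_tracks, "\n")
  print(x$movement_table)
  if (isTRUE(x$class_test$computable))
    cat(sprintf("  class chi-square: %.3f, df = %d, p = %.4f\n",
                x$class_test$statistic, x$class_test$df, x$class_test$p_value))
  if (isTRUE(x$run_length_test$computable))
    cat(sprintf("  retrograde run length (n = %d / %d runs): medians %.2f / %.2f um, Mann-Whitney p = %.4g\n",
                x$n_runs[1], x$n_runs[2], x$run_length_medians[1],
                x$run_length_medians[2], x$run_length_test$p_value))
  if (isTRUE(x$speed_test$computable))
    cat(sprintf("  mean retrograde speed (n = %d / %d tracks): Mann-Whitney p = %.4g\n",
                x$n_eligible_tracks[1], x$n_eligible_tracks[2],
                x$speed_test$p_value))
  if (isTRUE(x$total_distance_test$computable))
    cat(sprintf("  total retrograde distance: Mann-Whitney p = %.4g\n",
                x$total_distance_test$p_value))
  invisible(x)
}
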