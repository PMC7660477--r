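#' Configuration for the lysosome motion simulator
#'
#' Motion follows a continuous-time Markov chain over three states
#' (anterograde run, retrograde run, pause) with exponential dwell times and a
#' constant log-normal speed drawn per run episode; the continuous path is
#' sampled on the imaging grid and Gaussian localisation noise is added after
#' state sampling, so ground-truth run episodes stay exact.
#'
#' By default the retrograde exit rate of each group is calibrated with
#' [calibrate_retro_exit_rate()] so the ground-truth median retrograde run
#' length equals `target_retro_median_um` (2.52 um for controls, 1.91 um for
#' mutants).
#'
#' @param n_tracks_per_group tracks simulated per group.
#' @param groups group labels.
#' @param frame_interval_s imaging interval (s); default 0.5.
#' @param duration_s recording duration (s); default 180 (3 min).
#' @param target_retro_median_um named per-group target median ground-truth
#'   retrograde run length (um); used only when `state_rates` is NULL.
#' @param state_rates optional per-group named list of exit rates (per second)
#'   for states `anterograde`, `retrograde`, `pause`.
#' @param speed_dist list with elements `anterograde` and `retrograde`, each
#'   `c(meanlog, sdlog)` of the log-normal run speed (um/s).
#' @param reversal_matrix 3x3 row-stochastic matrix of state-transition
#'   probabilities on exit (rows/cols: anterograde, retrograde, pause).
#' @param initial_state_probs probabilities of the state occupied at t = 0.
#' @param start_range_um range of the uniform start position (um from soma).
#' @param immobile_fraction fraction of lysosomes belonging to a stationary
#'   subpopulation that never leaves the pause state (live-cell lysotracker
#'   recordings typically show a large immobile pool).
#' @param position_noise_um sd of Gaussian localisation noise (um).
#' @param pixel_size_um spatial calibration (um per pixel).
#' @param seed integer seed.
#' @return an object of class `track_sim_config`.
#' @export
track_sim_config <- function(n_tracks_per_group = 50,
                             groups = c("control", "mutant"),
                             frame_interval_s = 0.5,
                             duration_s = 180,
                             target_retro_median_um = c(control = 2.52, mutant = 1.91),
                             state_rates = NULL,
                             speed_dist = list(
                               anterograde = c(meanlog = log(0.8), sdlog = 0.3),
                               retrograde = c(meanlog = log(1.0), sdlog = 0.3)),
                             reversal_matrix = NULL,
                             initial_state_probs = c(anterograde = 0.25,
                                                     retrograde = 0.25, pause = 0.5),
                             start_range_um = c(30, 70),
                             immobile_fraction = 0.35,
                             position_noise_um = 0.02,
                             pixel_size_um = 0.1,
                             seed = 1L) {
  n_tracks_per_group <- assert_count(n_tracks_per_group, "n_tracks_per_group")
  assert_scalar_number(frame_interval_s, "frame_interval_s", 0, strict_lower = TRUE)
  assert_scalar_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  n_steps <- duration_s / frame_interval_s
  if (abs(n_steps - round(n_steps)) > 1e-9 || round(n_steps) < 2)
    config_error("duration_s",
                 "duration_s / frame_interval_s must be an integer frame count >= 3")
  assert_scalar_number(immobile_fraction, "immobile_fraction", 0, 1)
  assert_scalar_number(position_noise_um, "position_noise_um", 0)
  assert_scalar_number(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)

  states <- c("anterograde", "retrograde", "pause")
  if (is.null(reversal_matrix)) {
    reversal_matrix <- rbind(anterograde = c(0, 0.4, 0.6),
                             retrograde  = c(0.4, 0, 0.6),
                             pause       = c(0.5, 0.5, 0))
    colnames(reversal_matrix) <- states
  }
  if (!is.matrix(reversal_matrix) || !all(dim(reversal_matrix) == 3) ||
      any(reversal_matrix < 0) ||
      any(abs(rowSums(reversal_matrix) - 1) > 1e-9))
    config_error("reversal_matrix", "rows must be probability vectors summing to 1")
  dimnames(reversal_matrix) <- list(states, states)

  for (st in c("anterograde", "retrograde")) {
    sdl <- speed_dist[[st]]["sdlog"]
    if (is.na(sdl) || sdl < 0)
      config_error("speed_dist", paste0(st, " sdlog must be >= 0"))
  }

  if (is.null(state_rates)) {
    if (!all(groups %in% names(target_retro_median_um)))
      config_error("target_retro_median_um", "needs one entry per group")
    state_rates <- lapply(groups, function(g) {
      c(anterograde = 0.4,
        retrograde = calibrate_retro_exit_rate(
          target_retro_median_um[[g]],
          speed_dist$retrograde["meanlog"], speed_dist$retrograde["sdlog"]),
        pause = 0.25)
    })
    names(state_rates) <- groups
  }
  if (!all(groups %in% names(state_rates)))
    config_error("state_rates", "needs one entry per group")
  for (g in groups) {
    r <- state_rates[[g]]
    if (!all(states %in% names(r)) || any(!is.finite(unlist(r))) ||
        any(unlist(r) <= 0))
      config_error("state_rates",
                   paste0("group '", g, "' must give positive rates for all three states"))
  }

  structure(list(n_tracks_per_group = n_tracks_per_group, groups = groups,
                 frame_interval_s = frame_interval_s, duration_s = duration_s,
                 state_rates = state_rates, speed_dist = speed_dist,
                 reversal_matrix = reversal_matrix,
                 initial_state_probs = initial_state_probs[states],
                 start_range_um = start_range_um,
                 immobile_fraction = immobile_fraction,
                 position_noise_um = position_noise_um,
                 pixel_size_um = pixel_size_um, seed = seed),
            class = "track_sim_config")
}

#' Calibrate the retrograde exit rate to a target median run length
#'
#' A run length is the product of a log-normal speed and an exponential dwell
#' time. The median of that product is computed by Gaussian quadrature over
#' the speed distribution and the exit rate solved by root finding, so the
#' ground-truth median run length of the simulator equals the target.
#'
#' @param target_median_um target median run length (um).
#' @param speed_meanlog,speed_sdlog log-normal speed parameters (um/s).
#' @return exit rate (per second).
#' @export
calibrate_retro_exit_rate <- function(target_median_um, speed_meanlog,
                                      speed_sdlog) {
  assert_scalar_number(target_median_um, "target_median_um", 0, strict_lower = TRUE)
  z <- seq(-6, 6, length.out = 2001)
  w <- dnorm(z); w <- w / sum(w)
  speeds <- exp(speed_meanlog + speed_sdlog * z)
  f <- function(rate) sum(w * (1 - exp(-rate * target_median_um / speeds))) - 0.5
  uniroot(f, c(1e-6, 1e3), tol = 1e-10)$root
}

# simulate one CTMC path; returns episode table
sim_state_path <- function(duration_s, rates, rev, speed_dist, init_probs) {
  states <- c("anterograde", "retrograde", "pause")
  s <- sample(states, 1, prob = init_probs)
  segs_state <- character(64); segs_t0 <- numeric(64); segs_t1 <- numeric(64)
  segs_v <- numeric(64)
  t <- 0; i <- 0L
  while (t < duration_s) {
    dwell <- rexp(1, rates[[s]])
    v <- if (s == "pause") 0 else {
      sp <- rlnorm(1, speed_dist[[s]]["meanlog"], speed_dist[[s]]["sdlog"])
      if (s == "retrograde") -sp else sp
    }
    i <- i + 1L
    if (i > length(segs_state)) {
      segs_state <- c(segs_state, character(length(segs_state)))
      segs_t0 <- c(segs_t0, numeric(length(segs_t0)))
      segs_t1 <- c(segs_t1, numeric(length(segs_t1)))
      segs_v <- c(segs_v, numeric(length(segs_v)))
    }
    segs_state[i] <- s; segs_t0[i] <- t; segs_t1[i] <- min(t + dwell, duration_s)
    segs_v[i] <- v
    t <- t + dwell
    s <- sample(states, 1, prob = rev[s, ])
  }
  data.frame(state = segs_state[1:i], t0 = segs_t0[1:i], t1 = segs_t1[1:i],
             v = segs_v[1:i], stringsAsFactors = FALSE)
}

#' Simulate lysosome tracks with ground truth
#'
#' Generates one set of tracks per group under the configured state-switching
#' motion model, together with a ground-truth table of every simulated run
#' episode (direction, start/end time, displacement, speed, and the grid
#' frames fully contained in the episode).
#'
#' Identical configurations (including seed) give identical output; the global
#' RNG state is left untouched.
#'
#' @param config a [track_sim_config()].
#' @return list with elements `tracks` (list of [track()] objects) and `truth`
#'   (data frame of ground-truth runs).
#' @export
simulate_tracks <- function(config) {
  if (!inherits(config, "track_sim_config"))
    config_error("config", "must be a track_sim_config")
  dt <- config$frame_interval_s
  n_frames <- round(config$duration_s / dt) + 1L
  grid <- (seq_len(n_frames) - 1L) * dt

  with_seed(config$seed, {
    tracks <- list(); truth <- list()
    for (g in config$groups) {
      rates <- as.list(config$state_rates[[g]])
      for (k in seq_len(config$n_tracks_per_group)) {
        id <- sprintf("%s_%03d", g, k)
        segs <- if (runif(1) < config$immobile_fraction) {
          data.frame(state = "pause", t0 = 0, t1 = config$duration_s, v = 0,
                     stringsAsFactors = FALSE)
        } else {
          sim_state_path(config$duration_s, rates, config$reversal_matrix,
                         config$speed_dist, config$initial_state_probs)
        }
        # integrate the piecewise-constant velocity
        disp_end <- cumsum(segs$v * (segs$t1 - segs$t0))
        disp_start <- c(0, head(disp_end, -1))
        posf <- function(ti) {
          j <- findInterval(ti, segs$t0)
          disp_start[j] + segs$v[j] * (ti - segs$t0[j])
        }
        rel <- posf(grid)
        x0 <- runif(1, config$start_range_um[1], config$start_range_um[2])
        # shift the start so the whole path stays on the soma-positive side
        x0 <- x0 + max(0, 0.5 - (x0 + min(rel)))
        clean <- x0 + rel
        noisy <- clean + rnorm(n_frames, 0, config$position_noise_um)
        noisy <- pmax(noisy, 0)
        tracks[[id]] <- track(id, g, noisy, frame_interval_s = dt,
                              pixel_size_um = config$pixel_size_um)
        runs <- segs[segs$state != "pause" & segs$t1 > segs$t0, , drop = FALSE]
        if (nrow(runs)) {
          sf <- ceiling(runs$t0 / dt - 1e-9)
          ef <- floor(runs$t1 / dt + 1e-9)
          gd <- ifelse(ef > sf, clean[pmin(ef, n_frames - 1L) + 1L] -
                         clean[pmax(sf, 0L) + 1L], 0)
          truth[[id]] <- data.frame(
            track_id = id, group = g, direction = runs$state,
            start_s = runs$t0, end_s = runs$t1,
            duration_s = runs$t1 - runs$t0,
            displacement_um = runs$v * (runs$t1 - runs$t0),
            length_um = abs(runs$v) * (runs$t1 - runs$t0),
            speed_um_per_s = abs(runs$v),
            start_frame = sf, end_frame = ef,
            n_frames = pmax(0L, ef - sf + 1L),
            grid_displacement_um = gd,
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(track_id = character(), group = character(),
                 direction = character(), start_s = numeric(),
                 end_s = numeric(), duration_s = numeric(),
                 displacement_um = numeric(), length_um = numeric(),
                 speed_um_per_s = numeric(), start_frame = integer(),
                 end_frame = integer(), n_frames = integer(),
                 grid_displacement_um = numeric(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(tracks = tracks, truth = truth)
  })
}
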