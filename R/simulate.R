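#' Parameters for the switching-track simulator
#'
#' Defaults reproduce the validation setting: 100 tracks of 200 steps at
#' `dt` = 1 s, random migration as a discrete Ornstein-Uhlenbeck (OU)
#' velocity process with persistence `tau` = 1.5 s and diffusion coefficient
#' `D` = 5 um^2/s, directed migration at speeds drawn from normal(10, 1)
#' um/s along the previous direction with unit additive velocity noise, and
#' symmetric per-step switching `T12 = T21 = 0.1` from initial state
#' probabilities (0.5, 0.5).
#'
#' @param n_tracks number of tracks.
#' @param n_steps steps per track.
#' @param dt frame interval, seconds.
#' @param tau OU velocity persistence time, seconds.
#' @param D diffusion coefficient of the random mode, um^2/s.
#' @param v_dir_mean,v_dir_sd directed-mode speed distribution, um/s
#'   (negative draws are rejected and redrawn).
#' @param T12,T21 per-step switch probabilities.
#' @param pi0 initial-state probabilities.
#' @param dir_noise_sd per-component sd of the additive velocity noise in the
#'   directed mode (1 = the standard-normal noise of the generative model;
#'   0 turns directed segments into exactly straight runs, useful for
#'   geometric checks).
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(n_tracks = 100L, n_steps = 200L, dt = 1, tau = 1.5,
                       D = 5, v_dir_mean = 10, v_dir_sd = 1,
                       T12 = 0.1, T21 = 0.1, pi0 = c(0.5, 0.5),
                       dir_noise_sd = 1) {
  stopifnot(n_tracks >= 0, n_steps >= 1, dt > 0, tau > 0, D > 0,
            v_dir_mean > 0, v_dir_sd >= 0, dir_noise_sd >= 0,
            T12 >= 0, T12 <= 1, T21 >= 0, T21 <= 1,
            length(pi0) == 2L, all(pi0 >= 0), abs(sum(pi0) - 1) < 1e-8)
  structure(list(n_tracks = as.integer(n_tracks),
                 n_steps = as.integer(n_steps), dt = dt, tau = tau, D = D,
                 v_dir_mean = v_dir_mean, v_dir_sd = v_dir_sd,
                 T12 = T12, T21 = T21, pi0 = pi0,
                 dir_noise_sd = dir_noise_sd),
            class = "sim_params")
}

# stationary per-component velocity variance of the discrete OU update
# v' = a v + b eps with a = 1 - dt/tau, b = sqrt(dt) sqrt(2D)/tau
ou_stationary_var <- function(p) {
  a <- 1 - p$dt / p$tau
  b2 <- p$dt * 2 * p$D / p$tau^2
  b2 / (1 - a^2)
}

#' Simulate one switching-mode track with ground truth
#'
#' The hidden state chain starts from `pi0` and switches with `T12`/`T21`
#' each step.  Random-mode steps follow the discrete OU velocity update
#' `v' = (1 - dt/tau) v + sqrt(dt) (sqrt(2D)/tau) eps`; directed-mode steps
#' draw a speed from normal(`v_dir_mean`, `v_dir_sd`), keep the previous
#' direction, and add unit normal velocity noise per component.  Positions
#' advance by `dt * v'`.  The initial velocity is drawn from the OU
#' stationary distribution (or uniformly-directed at the directed speed when
#' starting directed); on entering directed mode from exactly zero velocity
#' the direction is drawn uniformly on the circle.
#'
#' Uses R's current RNG stream; seed via `set.seed()` or use
#' [simulate_dataset()] for per-track substreams.
#'
#' @param p a `sim_params`.
#' @param track_id,cell_id,condition labels for the generated track.
#' @return list of class `"labeled_track"`: `track` (a `perox_track`) and
#'   `truth` (integer states, one per step).
#' @export
simulate_track <- function(p, track_id = "sim1", cell_id = "simcell",
                           condition = "sim") {
  n <- p$n_steps
  s <- integer(n)
  s[1] <- 1L + (stats::runif(1) < p$pi0[2])
  if (n > 1L) for (t in seq_len(n - 1L)) {
    sw <- stats::runif(1) < if (s[t] == 1L) p$T12 else p$T21
    s[t + 1L] <- if (sw) 3L - s[t] else s[t]
  }

  a <- 1 - p$dt / p$tau
  b <- sqrt(p$dt) * sqrt(2 * p$D) / p$tau
  draw_speed <- function() {
    repeat {
      sp <- stats::rnorm(1, p$v_dir_mean, p$v_dir_sd)
      if (sp >= 0) return(sp)
    }
  }
  if (s[1] == 1L) {
    v <- stats::rnorm(2, 0, sqrt(ou_stationary_var(p)))
  } else {
    th <- stats::runif(1, 0, 2 * pi)
    v <- c(cos(th), sin(th)) * draw_speed()
  }

  x <- matrix(0, n + 1L, 2L)
  for (t in seq_len(n)) {
    if (s[t] == 1L) {
      v <- a * v + b * stats::rnorm(2)
    } else {
      nv <- sqrt(sum(v^2))
      dir <- if (nv > 0) v / nv else {
        th <- stats::runif(1, 0, 2 * pi); c(cos(th), sin(th))
      }
      v <- dir * draw_speed() + p$dir_noise_sd * stats::rnorm(2)
    }
    x[t + 1L, ] <- x[t, ] + p$dt * v
  }
  structure(list(track = track(track_id, 0:n, x[, 1], x[, 2], p$dt,
                               cell_id = cell_id, condition = condition),
                 truth = s),
            class = "labeled_track")
}

#' Simulate a dataset of labelled tracks
#'
#' Generates `n_tracks` independent tracks, each from its own seeded
#' substream derived from the root seed, so any single track can be replayed
#' exactly.
#'
#' @param p a `sim_params`.
#' @param seed root seed (integer) for reproducibility; `NULL` uses the
#'   current RNG state to draw the substream seeds.
#' @param cell_id,condition labels applied to all tracks.
#' @return list with `tracks` (a `perox_trackset`), `truth` (named list of
#'   integer state vectors), and `track_seeds` (the per-track substream
#'   seeds, for replay).
#' @export
simulate_dataset <- function(p, seed = NULL, cell_id = "simcell",
                             condition = "sim") {
  if (!is.null(seed)) set.seed(seed)
  if (p$n_tracks == 0L)
    return(list(tracks = track_set(), truth = list(),
                track_seeds = integer(0)))
  track_seeds <- sample.int(.Machine$integer.max - 1L, p$n_tracks)
  labs <- lapply(seq_len(p$n_tracks), function(i) {
    set.seed(track_seeds[i])
    simulate_track(p, track_id = sprintf("sim%03d", i),
                   cell_id = cell_id, condition = condition)
  })
  tracks <- track_set(lapply(labs, `[[`, "track"))
  truth <- lapply(labs, `[[`, "truth")
  names(truth) <- vapply(labs, function(l) l$track$track_id, "")
  list(tracks = tracks, truth = truth, track_seeds = track_seeds)
}

#' Write simulation ground truth as CSV
#' @param truth named list of integer state vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  df <- do.call(rbind, lapply(names(truth), function(id)
    data.frame(track_id = id, step = seq_along(truth[[id]]),
               state = truth[[id]], stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
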