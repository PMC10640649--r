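#' Convert a track to HMM observables
#'
#' For each displacement (step) of the track, computes the dimensionless
#' instantaneous speed `iota` — speed in micrometres/second divided by the
#' reference 1 um/s, so the natural logarithm is well defined — and, at each
#' interior vertex, the relative turning angle `alpha` in degrees: the signed
#' angle between the displacement arriving at the vertex and the one leaving
#' it, in (-180, 180].  Step `t` carries the turning angle at vertex `t`, so
#' the first step has no angle.
#'
#' Speeds across a frame gap use the true elapsed time (frame difference
#' times `dt`).  Zero-length displacements get `iota` floored at `eps`
#' (keeping the log-normal density finite) and the adjacent angles are marked
#' absent, as are, by default, angles touching a gap-closed step.
#'
#' @param tr a `perox_track` (>= 2 positions; >= 3 for any angle to exist).
#' @param gap_angles if `FALSE` (default) the two angles touching a frame gap
#'   are marked absent; if `TRUE` they are kept.
#' @param eps floor for zero displacement speeds.
#' @return An object of class `"perox_obs"`: list with `iota` (length =
#'   number of steps), `alpha` (same length; `NA` where absent, always at
#'   step 1), `dt`, `track_id`.
#' @export
compute_observables <- function(tr, gap_angles = FALSE, eps = 1e-9) {
  stopifnot(inherits(tr, "perox_track"))
  n <- n_steps(tr)
  if (n < 1L) stop("track has fewer than 2 positions", call. = FALSE)
  dx <- diff(tr$x)
  dy <- diff(tr$y)
  dframe <- diff(tr$frames)
  d <- sqrt(dx^2 + dy^2)
  iota <- d / (dframe * tr$dt)          # um/s over 1 um/s
  zero <- d == 0
  iota[zero] <- eps

  alpha <- rep(NA_real_, n)
  if (n >= 2L) {
    i <- seq_len(n - 1L)                # vertex between step i and i+1
    cross <- dx[i] * dy[i + 1L] - dy[i] * dx[i + 1L]
    dot <- dx[i] * dx[i + 1L] + dy[i] * dy[i + 1L]
    a <- atan2(cross, dot) * 180 / pi   # (-180, 180]
    a[a <= -180] <- 180
    bad <- zero[i] | zero[i + 1L]
    if (!gap_angles) bad <- bad | dframe[i] > 1L | dframe[i + 1L] > 1L
    a[bad] <- NA_real_
    alpha[i + 1L] <- a
  }
  structure(list(iota = iota, alpha = alpha, dt = tr$dt,
                 track_id = tr$track_id),
            class = "perox_obs")
}

#' @export
print.perox_obs <- function(x, ...) {
  cat(sprintf("<perox_obs %s> %d steps, %d angles, dt = %g s\n",
              x$track_id, length(x$iota), sum(!is.na(x$alpha)), x$dt))
  invisible(x)
}

#' Observables for every track of a set
#' @param ts a `perox_trackset`.
#' @param ... passed to [compute_observables()].
#' @return named list of `perox_obs`, one per track.
#' @export
observables_set <- function(ts, ...) {
  lapply(unclass(ts), compute_observables, ...)
}

#' Export observables as a data frame
#' @param obs a `perox_obs` or list of them.
#' @return data.frame with columns track_id, step, iota, alpha.
#' @export
observables_to_df <- function(obs) {
  if (inherits(obs, "perox_obs")) obs <- list(obs)
  do.call(rbind, lapply(obs, function(o)
    data.frame(track_id = o$track_id, step = seq_along(o$iota),
               iota = o$iota, alpha = o$alpha, stringsAsFactors = FALSE)))
}

#' Downsample a track in time
#'
#' Keeps positions at indices 1, 1+k, 1+2k, ... and multiplies the frame
#' interval by `k`, emulating acquisition at a k-fold lower frame rate.  The
#' apparent mean speed of a non-straight track decreases with `k` (triangle
#' inequality), which is why speed estimates depend on the acquisition rate.
#'
#' @param tr a `perox_track`.
#' @param k positive integer downsampling factor.
#' @return a `perox_track` with `dt` multiplied by `k`.
#' @export
downsample <- function(tr, k) {
  stopifnot(inherits(tr, "perox_track"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be an integer >= 1", call. = FALSE)
  k <- as.integer(k)
  if (k == 1L) return(tr)
  idx <- seq(1L, length(tr$frames), by = k)
  if (length(idx) < 2L)
    stop("downsampling leaves fewer than 2 positions", call. = FALSE)
  f <- tr$frames[idx]
  if (any(diff(tr$frames) != 1L)) {
    warning("downsampling a gapped track: gap timing rounded to the new dt")
    f <- (f - f[1L]) %/% k
  } else {
    f <- (f - f[1L]) %/% k
  }
  track(tr$track_id, f, tr$x[idx], tr$y[idx], tr$dt * k,
        cell_id = tr$cell_id, condition = tr$condition)
}
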