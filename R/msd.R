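#' Ensemble mean squared displacement of a group of tracks
#'
#' Computes the from-origin (ensemble) MSD: at each lag `t` (multiples of
#' `dt` up to `max_lag`), the average over tracks of the squared displacement
#' from the track's own starting position,
#' `MSD(t) = (1/N) sum_i |x_i(t) - x_i(0)|^2`.  Tracks contribute to every
#' lag they reach; the per-lag track count is recorded.  A time-averaged
#' variant (averaging over all start points within each track) is available
#' behind `time_averaged`, off by default.
#'
#' @param ts a `perox_trackset` (typically one cell, already filtered with
#'   [filter_min_steps()]); all tracks must share one `dt`.
#' @param max_lag largest lag in seconds.
#' @param time_averaged use the time-averaged MSD instead of the ensemble
#'   from-origin form.
#' @return object of class `"perox_msd"`: list with `lags` (seconds,
#'   starting at 0), `msd` (um^2), `n_tracks` (per lag), `dt`, `cell_id`.
#' @export
msd_curve <- function(ts, max_lag = 20, time_averaged = FALSE) {
  trs <- unclass(ts)
  if (!length(trs)) stop("no tracks for MSD", call. = FALSE)
  stopifnot(max_lag > 0)
  dts <- unique(vapply(trs, `[[`, 0, "dt"))
  if (length(dts) != 1L) stop("tracks differ in dt", call. = FALSE)
  dt <- dts
  M <- floor(max_lag / dt + 1e-9)
  if (M < 1L) stop("max_lag smaller than dt", call. = FALSE)
  sums <- numeric(M)
  counts <- integer(M)
  for (tr in trs) {
    f <- tr$frames - tr$frames[1L]
    if (time_averaged) {
      pos <- match(0:max(f), f)        # index by frame offset; NA at gaps
      for (m in seq_len(min(M, max(f)))) {
        i0 <- pos[seq_len(max(f) - m + 1L)]
        i1 <- pos[seq_len(max(f) - m + 1L) + m]
        ok <- !is.na(i0) & !is.na(i1)
        if (any(ok)) {
          d2 <- (tr$x[i1[ok]] - tr$x[i0[ok]])^2 +
                (tr$y[i1[ok]] - tr$y[i0[ok]])^2
          sums[m] <- sums[m] + mean(d2)
          counts[m] <- counts[m] + 1L
        }
      }
    } else {
      hit <- f >= 1L & f <= M
      m <- f[hit]
      d2 <- (tr$x[hit] - tr$x[1L])^2 + (tr$y[hit] - tr$y[1L])^2
      sums[m] <- sums[m] + d2
      counts[m] <- counts[m] + 1L
    }
  }
  if (all(counts == 0L)) stop("no track reaches any requested lag",
                              call. = FALSE)
  msd <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  structure(list(lags = c(0, seq_len(M) * dt), msd = c(0, msd),
                 n_tracks = c(length(trs), counts), dt = dt,
                 cell_id = trs[[1L]]$cell_id),
            class = "perox_msd")
}

#' @export
print.perox_msd <- function(x, ...) {
  cat(sprintf("<perox_msd %s> %d lags up to %g s, max MSD %.3g um^2\n",
              x$cell_id, length(x$lags) - 1L, max(x$lags),
              max(x$msd, na.rm = TRUE)))
  invisible(x)
}

#' Fit the anomalous-diffusion exponent of an MSD curve
#'
#' Least-squares slope of `log(MSD)` against `log(t)` over the fit range —
#' the exponent `alpha` in `MSD(t) ~ t^alpha` (alpha < 1 subdiffusive,
#' alpha = 1 Brownian, alpha > 1 superdiffusive).  Lag 0 is always excluded.
#'
#' @param m a `perox_msd`.
#' @param fit_range numeric length 2, `(t_min, t_max)` in seconds.
#' @param weighted weight lags by the per-lag track count.
#' @return the fitted exponent (numeric scalar).
#' @export
fit_alpha <- function(m, fit_range = c(0.1, 20), weighted = FALSE) {
  sel <- m$lags >= fit_range[1] & m$lags <= fit_range[2] & m$lags > 0 &
    !is.na(m$msd) & m$msd > 0
  if (sum(sel) < 2L)
    stop("need at least 2 positive MSD points inside the fit range",
         call. = FALSE)
  w <- if (weighted) m$n_tracks[sel] else NULL
  unname(stats::coef(stats::lm(log(m$msd[sel]) ~ log(m$lags[sel]),
                               weights = w))[2])
}

#' Per-cell MSD summary of a track set
#'
#' Applies the minimum-steps filter, groups tracks by cell, and returns the
#' MSD curve and fitted exponent per cell.
#'
#' @param ts a `perox_trackset`.
#' @param max_lag largest lag in seconds.
#' @param min_steps minimum track length filter.
#' @param fit_range passed to [fit_alpha()].
#' @return list with `curves` (named list of `perox_msd`) and `summary`
#'   (data.frame cell_id, condition, alpha_msd, n_tracks).
#' @export
msd_by_cell <- function(ts, max_lag = 20, min_steps = 50L,
                        fit_range = c(0.1, 20)) {
  ts <- filter_min_steps(ts, min_steps)
  if (!length(ts)) stop("no track passes the minimum-steps filter",
                        call. = FALSE)
  cells <- vapply(unclass(ts), `[[`, "", "cell_id")
  conds <- vapply(unclass(ts), `[[`, "", "condition")
  curves <- list()
  rows <- list()
  for (cid in unique(cells)) {
    sub <- ts[cells == cid]
    m <- msd_curve(sub, max_lag = max_lag)
    a <- tryCatch(fit_alpha(m, fit_range), error = function(e) NA_real_)
    curves[[cid]] <- m
    rows[[cid]] <- data.frame(cell_id = cid,
                              condition = conds[cells == cid][1],
                              alpha_msd = a, n_tracks = length(sub),
                              stringsAsFactors = FALSE)
  }
  list(curves = curves, summary = do.call(rbind, unname(rows)))
}
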