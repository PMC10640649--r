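#' Fit the two-state migration HMM to tracks
#'
#' The central fitting function.  Tracks are converted to observables
#' (dimensionless speed, relative turning angle) and the two-state hidden
#' Markov model — state 1 random migration, state 2 directed migration — is
#' estimated by scaled Baum-Welch.  Two sharing modes are supported:
#' \describe{
#'   \item{`"per_track"` (default)}{each track gets its own fit; the
#'     object's headline parameters are the element-wise across-track means
#'     (averaging row-stochastic matrices preserves row sums).}
#'   \item{`"pooled"`}{all tracks are treated as independent sequences
#'     sharing one parameter set, fitted jointly.}
#' }
#' Freezing `mu_iota`, `sigma_iota` and `sigma_alpha2` at values from a
#' previous fit while leaving `pi` and `T` free gives the two-stage protocol
#' used for scanning whole datasets: emissions are learned once from
#' mixed-mode tracks, then occupancy and switching are estimated per track.
#'
#' @param x a `perox_trackset`, a single `perox_track`, a `perox_obs`, or a
#'   list of `perox_obs`.
#' @param params0 optional starting/frozen `hmm_params`.
#' @param frozen character vector of parameter groups to hold fixed
#'   (subset of `mu_iota`, `sigma_iota`, `sigma_alpha2`, `pi`, `T`).
#' @param share `"per_track"` or `"pooled"`.
#' @param tol,max_iter,pi_update passed to [baum_welch()].
#' @param gap_angles passed to [compute_observables()].
#' @return An object of class `"track_hmm"` with components `params`
#'   (headline `hmm_params`), `fits` (named list of per-track `hmm_fit`, or
#'   length-1 for pooled), `per_track` (data.frame of per-track parameter
#'   estimates), `obs` (named list of `perox_obs`), `share`, `call`.
#' @seealso [predict.track_hmm()], [simulate.track_hmm()], [viterbi()]
#' @export
track_hmm <- function(x, params0 = NULL, frozen = character(),
                      share = c("per_track", "pooled"),
                      tol = 1e-6, max_iter = 500L,
                      pi_update = c("occupancy", "initial"),
                      gap_angles = FALSE) {
  share <- match.arg(share)
  pi_update <- match.arg(pi_update)
  obs <- as_obs_list(x, gap_angles = gap_angles)
  if (!length(obs)) stop("no observation sequences to fit", call. = FALSE)

  if (share == "pooled") {
    fit <- baum_welch(obs, params0 = params0, frozen = frozen, tol = tol,
                      max_iter = max_iter, pi_update = pi_update)
    fits <- list(pooled = fit)
    params <- fit$params
  } else {
    fits <- lapply(obs, function(o)
      baum_welch(o, params0 = params0, frozen = frozen, tol = tol,
                 max_iter = max_iter, pi_update = pi_update))
    params <- average_params(lapply(fits, `[[`, "params"))
  }
  per_track <- do.call(rbind, lapply(names(fits), function(id) {
    p <- fits[[id]]$params
    data.frame(track_id = id, mu1 = p$mu_iota[1], mu2 = p$mu_iota[2],
               sigma1 = p$sigma_iota[1], sigma2 = p$sigma_iota[2],
               sigma_alpha2 = p$sigma_alpha2, pi1 = p$pi[1], pi2 = p$pi[2],
               T11 = p$T[1, 1], T12 = p$T[1, 2], T21 = p$T[2, 1],
               T22 = p$T[2, 2],
               loglik = fits[[id]]$loglik_trace[length(fits[[id]]$loglik_trace)],
               n_iter = fits[[id]]$n_iter, converged = fits[[id]]$converged,
               stringsAsFactors = FALSE)
  }))
  rownames(per_track) <- NULL
  structure(list(params = params, fits = fits, per_track = per_track,
                 obs = obs, share = share, frozen = frozen,
                 pi_update = pi_update, call = match.call()),
            class = "track_hmm")
}

# coerce the accepted input types to a named list of perox_obs
as_obs_list <- function(x, gap_angles = FALSE) {
  if (inherits(x, "perox_obs")) return(stats::setNames(list(x), x$track_id))
  if (inherits(x, "perox_track"))
    return(stats::setNames(list(compute_observables(x, gap_angles = gap_angles)),
                           x$track_id))
  if (inherits(x, "perox_trackset"))
    return(observables_set(x, gap_angles = gap_angles))
  if (is.list(x) && all(vapply(x, inherits, NA, "perox_obs")))
    return(stats::setNames(x, vapply(x, `[[`, "", "track_id")))
  stop("cannot interpret 'x' as tracks or observation sequences",
       call. = FALSE)
}

# element-wise mean of a list of hmm_params
average_params <- function(plist) {
  m <- function(f) Reduce(`+`, lapply(plist, f)) / length(plist)
  hmm_params(m(function(p) p$mu_iota), m(function(p) p$sigma_iota),
             m(function(p) p$sigma_alpha2), m(function(p) p$pi),
             m(function(p) p$T))
}

#' @export
print.track_hmm <- function(x, ...) {
  cat(sprintf("Two-state migration HMM (%s fit, %d track%s)\n", x$share,
              length(x$obs), if (length(x$obs) == 1) "" else "s"))
  print(x$params)
  invisible(x)
}

#' @export
summary.track_hmm <- function(object, ...) {
  p <- object$params
  out <- list(
    params = p,
    expected_speed_um_s = expected_speed(p$mu_iota, p$sigma_iota),
    n_tracks = length(object$obs),
    n_steps = sum(vapply(object$obs, function(o) length(o$iota), 0L)),
    share = object$share, frozen = object$frozen,
    loglik = sum(object$per_track$loglik),
    converged = all(object$per_track$converged))
  class(out) <- "summary.track_hmm"
  out
}

#' @export
print.summary.track_hmm <- function(x, ...) {
  cat(sprintf("Two-state migration HMM: %d tracks, %d steps (%s fit)\n",
              x$n_tracks, x$n_steps, x$share))
  if (length(x$frozen))
    cat("  frozen groups:", paste(x$frozen, collapse = ", "), "\n")
  print(x$params)
  cat(sprintf("  expected speeds: %.2f um/s (random), %.2f um/s (directed)\n",
              x$expected_speed_um_s[1], x$expected_speed_um_s[2]))
  cat(sprintf("  total log-likelihood: %.2f (%s)\n", x$loglik,
              if (x$converged) "all fits converged" else "some fits did not converge"))
  invisible(x)
}

#' @export
coef.track_hmm <- function(object, ...) {
  p <- object$params
  c(mu_iota1 = p$mu_iota[1], mu_iota2 = p$mu_iota[2],
    sigma_iota1 = p$sigma_iota[1], sigma_iota2 = p$sigma_iota[2],
    sigma_alpha2 = p$sigma_alpha2, pi1 = p$pi[1], pi2 = p$pi[2],
    T11 = p$T[1, 1], T12 = p$T[1, 2], T21 = p$T[2, 1], T22 = p$T[2, 2])
}

#' @export
logLik.track_hmm <- function(object, ...) {
  groups <- c(mu_iota = 2, sigma_iota = 2, sigma_alpha2 = 1, pi = 1, T = 2)
  free <- sum(groups[setdiff(names(groups), object$frozen)])
  if (object$share == "per_track") free <- free * length(object$fits)
  structure(sum(object$per_track$loglik), df = free,
            nobs = sum(vapply(object$obs, function(o) length(o$iota), 0L)),
            class = "logLik")
}

#' Decode states or posteriors from a fitted track HMM
#'
#' @param object a `track_hmm`.
#' @param newdata optional tracks/observations to decode; default: the
#'   training data.
#' @param type `"viterbi"` for the most probable state path, `"posterior"`
#'   for per-step state-2 probabilities.
#' @param per_track use each track's own fitted parameters where available
#'   (default for per-track fits on training data); otherwise the headline
#'   parameters are used.
#' @param ... unused.
#' @return data.frame with columns `track_id`, `step`, and `state` (integer)
#'   or `gamma2` (probability).
#' @export
predict.track_hmm <- function(object, newdata = NULL,
                              type = c("viterbi", "posterior"),
                              per_track = NULL, ...) {
  type <- match.arg(type)
  obs <- if (is.null(newdata)) object$obs else as_obs_list(newdata)
  if (is.null(per_track))
    per_track <- is.null(newdata) && object$share == "per_track"
  out <- lapply(names(obs), function(id) {
    p <- if (per_track && !is.null(object$fits[[id]]))
      object$fits[[id]]$params else object$params
    o <- obs[[id]]
    if (type == "viterbi") {
      data.frame(track_id = id, step = seq_along(o$iota),
                 state = viterbi(o, p), stringsAsFactors = FALSE)
    } else {
      data.frame(track_id = id, step = seq_along(o$iota),
                 gamma2 = forward_backward(o, p)$gamma[, 2],
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Simulate observation sequences from a fitted track HMM
#'
#' Draws hidden state chains from the fitted `pi`/`T` and observables from
#' the fitted emission densities (log-normal speeds; uniform or truncated
#' normal angles).  This samples from the probabilistic model itself; for
#' physically generated switching tracks with ground truth see
#' [simulate_dataset()].
#'
#' @param object a `track_hmm`.
#' @param nsim number of sequences.
#' @param seed optional seed (an integer) for reproducibility.
#' @param n_steps steps per sequence.
#' @param ... unused.
#' @return list of `perox_obs` with a `"states"` attribute each.
#' @export
simulate.track_hmm <- function(object, nsim = 1, seed = NULL,
                               n_steps = 200L, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  lapply(seq_len(nsim), function(k) {
    s <- integer(n_steps)
    s[1] <- 1L + (stats::runif(1) < p$pi[2])
    for (t in seq_len(n_steps - 1L))
      s[t + 1L] <- 1L + (stats::runif(1) < p$T[s[t], 2])
    iota <- stats::rlnorm(n_steps, p$mu_iota[s], p$sigma_iota[s])
    alpha <- ifelse(s == 1L, stats::runif(n_steps, -180, 180),
                    truncnorm_draw(n_steps, p$sigma_alpha2))
    alpha[1] <- NA_real_
    structure(list(iota = iota, alpha = alpha, dt = NA_real_,
                   track_id = sprintf("sim%d", k)),
              class = "perox_obs", states = s)
  })
}

# zero-mean normal(sd) truncated to (-180, 180] by inverse-cdf sampling
truncnorm_draw <- function(n, sd) {
  z <- stats::pnorm(180, 0, sd) - stats::pnorm(-180, 0, sd)
  u <- stats::runif(n, stats::pnorm(-180, 0, sd), stats::pnorm(180, 0, sd))
  stats::qnorm(u, 0, sd)
}

#' Plot a fitted track HMM
#'
#' Two base-graphics panels: the EM log-likelihood trace(s) and the fitted
#' speed emission densities on the log scale with the pooled observed
#' log-speed histogram.
#'
#' @param x a `track_hmm`.
#' @param which subset of `1:2`.
#' @param ... unused.
#' @export
plot.track_hmm <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    tr <- x$fits[[1]]$loglik_trace
    plot(seq_along(tr), tr, type = "l", xlab = "EM iteration",
         ylab = "log-likelihood", main = "Baum-Welch trace")
  }
  if (2 %in% which) {
    li <- log(unlist(lapply(x$obs, `[[`, "iota")))
    graphics::hist(li, breaks = 50, freq = FALSE, xlab = "log speed",
                   main = "speed emissions", col = "grey90", border = "grey70")
    xs <- seq(min(li), max(li), length.out = 300)
    p <- x$params
    graphics::lines(xs, p$pi[1] * stats::dnorm(xs, p$mu_iota[1],
                                               p$sigma_iota[1]), col = 2)
    graphics::lines(xs, p$pi[2] * stats::dnorm(xs, p$mu_iota[2],
                                               p$sigma_iota[2]), col = 4)
    graphics::legend("topright", c("random", "directed"), col = c(2, 4),
                     lty = 1, bty = "n")
  }
  invisible(x)
}
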