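#' Construct two-state HMM parameters
#'
#' State 1 is the random-migration mode (slow, isotropic turning), state 2
#' the microtubule-directed mode (fast, persistent).  Speeds are modelled in
#' both states by a log-normal on the dimensionless speed `iota`, with
#' location `mu_iota[i]` and scale `sigma_iota[i]` (mean and sd of
#' `log(iota)`).  Turning angles are uniform on (-180, 180] degrees in state
#' 1 and zero-mean normal with sd `sigma_alpha2` degrees (truncated to the
#' support and renormalised) in state 2.  `pi` is the state prior —
#' interpreted as the overall proportion of steps spent in each state — and
#' `T` the per-step transition matrix.
#'
#' @param mu_iota length-2 numeric, log-normal locations.
#' @param sigma_iota length-2 positive numeric, log-normal scales.
#' @param sigma_alpha2 positive scalar, directed-state turning-angle sd in
#'   degrees.
#' @param pi length-2 probability vector summing to 1.
#' @param T 2x2 row-stochastic transition matrix.
#' @return an object of class `"hmm_params"`.
#' @export
hmm_params <- function(mu_iota, sigma_iota, sigma_alpha2,
                       pi = c(0.5, 0.5),
                       T = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)) {
  mu_iota <- as.numeric(mu_iota)
  sigma_iota <- as.numeric(sigma_iota)
  pi <- as.numeric(pi)
  T <- matrix(as.numeric(T), 2, 2)
  stopifnot(length(mu_iota) == 2L, length(sigma_iota) == 2L,
            length(pi) == 2L)
  if (any(sigma_iota <= 0)) stop("sigma_iota must be positive", call. = FALSE)
  if (!is.numeric(sigma_alpha2) || sigma_alpha2 <= 0)
    stop("sigma_alpha2 must be positive", call. = FALSE)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a probability vector summing to 1", call. = FALSE)
  if (any(T < 0) || any(abs(rowSums(T) - 1) > 1e-8))
    stop("T must be row-stochastic", call. = FALSE)
  structure(list(mu_iota = mu_iota, sigma_iota = sigma_iota,
                 sigma_alpha2 = as.numeric(sigma_alpha2),
                 pi = pi / sum(pi), T = T / rowSums(T)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params>\n")
  cat(sprintf("  mu_iota:      [%.4f, %.4f]\n", x$mu_iota[1], x$mu_iota[2]))
  cat(sprintf("  sigma_iota:   [%.4f, %.4f]\n", x$sigma_iota[1],
              x$sigma_iota[2]))
  cat(sprintf("  sigma_alpha2: %.3f deg\n", x$sigma_alpha2))
  cat(sprintf("  pi:           [%.4f, %.4f]\n", x$pi[1], x$pi[2]))
  cat(sprintf("  T:            [[%.4f, %.4f], [%.4f, %.4f]]\n",
              x$T[1, 1], x$T[1, 2], x$T[2, 1], x$T[2, 2]))
  invisible(x)
}

#' Serialize / deserialize HMM parameters as JSON
#' @param params an `hmm_params`.
#' @param path file path; for `params_to_json`, `NULL` returns the JSON string.
#' @return `params_from_json` returns an `hmm_params`.
#' @export
params_to_json <- function(params, path = NULL) {
  x <- list(mu_iota = params$mu_iota, sigma_iota = params$sigma_iota,
            sigma_alpha2_deg = params$sigma_alpha2, pi = params$pi,
            T = params$T)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  hmm_params(x$mu_iota, x$sigma_iota, x$sigma_alpha2_deg, x$pi,
             matrix(unlist(x$T), 2, 2))
}

#' Log density of the dimensionless speed under one state
#'
#' Log-normal density, integrating to 1 over (0, Inf).
#'
#' @param iota positive dimensionless speed(s).
#' @param state 1 (random) or 2 (directed).
#' @param params an `hmm_params`.
#' @return log density value(s).
#' @export
speed_logpdf <- function(iota, state, params) {
  if (any(iota <= 0)) stop("iota must be positive", call. = FALSE)
  stats::dlnorm(iota, params$mu_iota[state], params$sigma_iota[state],
                log = TRUE)
}

#' Log density of the turning angle under one state
#'
#' Per-degree densities on (-180, 180]: uniform (1/360) in state 1; zero-mean
#' normal with sd `sigma_alpha2`, truncated to the support and renormalised,
#' in state 2.  Absent angles (`NA`, e.g. the first step of a track)
#' contribute a likelihood factor of 1, i.e. log density 0, in both states.
#'
#' @param alpha angle(s) in degrees in (-180, 180], or `NA` for absent.
#' @inheritParams speed_logpdf
#' @return log density value(s).
#' @export
angle_logpdf <- function(alpha, state, params) {
  out <- numeric(length(alpha))
  ok <- !is.na(alpha)
  if (any(ok)) {
    if (state == 1L) {
      out[ok] <- -log(360)
    } else {
      s <- params$sigma_alpha2
      z <- stats::pnorm(180, 0, s) - stats::pnorm(-180, 0, s)
      out[ok] <- stats::dnorm(alpha[ok], 0, s, log = TRUE) - log(z)
    }
  }
  out
}

#' Joint emission log density of one observation
#'
#' Speed and angle are conditionally independent given the state, so the
#' joint log density is the sum of [speed_logpdf()] and [angle_logpdf()].
#'
#' @inheritParams speed_logpdf
#' @inheritParams angle_logpdf
#' @return log density value(s).
#' @export
emission_logpdf <- function(iota, alpha, state, params) {
  speed_logpdf(iota, state, params) + angle_logpdf(alpha, state, params)
}

#' Single-observation state posterior (Bayes' theorem)
#'
#' @inheritParams emission_logpdf
#' @return length-2 probability vector `p(state | observation)`.
#' @export
posterior_state <- function(iota, alpha, params) {
  lp <- c(emission_logpdf(iota, alpha, 1L, params) + log(params$pi[1]),
          emission_logpdf(iota, alpha, 2L, params) + log(params$pi[2]))
  m <- max(lp)
  if (!is.finite(m)) stop("both states have zero density at this observation",
                          call. = FALSE)
  w <- exp(lp - m)
  w / sum(w)
}

#' Expected speed of a log-normal state
#'
#' The mean of a log-normal with parameters `mu` and `sigma` is
#' `exp(mu + sigma^2 / 2)`; via the 1 um/s nondimensionalisation this is the
#' expected instantaneous speed in um/s.
#'
#' @param mu log-normal location.
#' @param sigma log-normal scale (>= 0).
#' @return expected speed in um/s.
#' @export
expected_speed <- function(mu, sigma) {
  stopifnot(all(sigma >= 0))
  exp(mu + sigma^2 / 2)
}
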