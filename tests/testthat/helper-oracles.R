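# Brute-force HMM oracles (path enumeration) and small fixture builders.
# These deliberately avoid the package's forward-backward / Viterbi code
# paths: likelihoods are summed over explicitly enumerated state paths.

make_obs <- function(iota, alpha = NULL, track_id = "t1", dt = 0.1) {
  if (is.null(alpha)) alpha <- c(NA_real_, rep(0, length(iota) - 1L))
  structure(list(iota = iota, alpha = alpha, dt = dt, track_id = track_id),
            class = "perox_obs")
}

random_obs <- function(n) {
  make_obs(iota = exp(stats::rnorm(n, 0.5, 1)),
           alpha = c(NA_real_, stats::runif(n - 1L, -180, 180)))
}

random_params <- function() {
  mu <- sort(stats::rnorm(2, 0.5, 1))
  T12 <- stats::runif(1, 0.02, 0.5)
  T21 <- stats::runif(1, 0.02, 0.5)
  p1 <- stats::runif(1, 0.1, 0.9)
  hmm_params(mu_iota = mu,
             sigma_iota = stats::runif(2, 0.2, 1.5),
             sigma_alpha2 = stats::runif(1, 5, 60),
             pi = c(p1, 1 - p1),
             T = matrix(c(1 - T12, T12, T21, 1 - T21), 2, byrow = TRUE))
}

# log of the total likelihood, summing over all 2^n state paths
brute_loglik <- function(obs, params) {
  n <- length(obs$iota)
  lb <- cbind(emission_logpdf(obs$iota, obs$alpha, 1L, params),
              emission_logpdf(obs$iota, obs$alpha, 2L, params))
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  lp <- apply(paths, 1L, function(s) {
    v <- log(params$pi[s[1L]]) + lb[1L, s[1L]]
    if (n > 1L) for (t in 2L:n)
      v <- v + log(params$T[s[t - 1L], s[t]]) + lb[t, s[t]]
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# exhaustive most-probable path (ties: lexicographically smallest, i.e.
# state 1 preferred)
brute_viterbi <- function(obs, params) {
  n <- length(obs$iota)
  lb <- cbind(emission_logpdf(obs$iota, obs$alpha, 1L, params),
              emission_logpdf(obs$iota, obs$alpha, 2L, params))
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  paths <- paths[do.call(order, as.data.frame(paths)), , drop = FALSE]
  lp <- apply(paths, 1L, function(s) {
    v <- log(params$pi[s[1L]]) + lb[1L, s[1L]]
    if (n > 1L) for (t in 2L:n)
      v <- v + log(params$T[s[t - 1L], s[t]]) + lb[t, s[t]]
    v
  })
  unname(paths[which.max(lp), ])
}

straight_track <- function(n = 5L, step = 1, dt = 0.1, id = "straight") {
  track(id, 0:(n - 1L), step * (0:(n - 1L)), rep(0, n), dt)
}

zigzag_track <- function(n = 21L, dt = 0.1, id = "zigzag") {
  # unit steps alternating between +x and +y: maximally non-straight
  dx <- rep(c(1, 0), length.out = n - 1L)
  dy <- rep(c(0, 1), length.out = n - 1L)
  track(id, 0:(n - 1L), cumsum(c(0, dx)), cumsum(c(0, dy)), dt)
}
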