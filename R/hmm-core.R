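# Scaled forward-backward, Viterbi and Baum-Welch for the two-state track HMM.
# Observation sequences enter as perox_obs objects (iota + alpha vectors).

# n x 2 matrix of emission log densities
emission_logmat <- function(obs, params) {
  cbind(emission_logpdf(obs$iota, obs$alpha, 1L, params),
        emission_logpdf(obs$iota, obs$alpha, 2L, params))
}

#' Scaled forward-backward recursion
#'
#' Computes per-step state posteriors (`gamma`), per-step transition
#' posteriors (`xi`) and the exact log-likelihood of the observation
#' sequence, using per-step normalisation of the forward variables so that
#' underflow cannot occur for any sequence length.
#'
#' @param obs a `perox_obs`.
#' @param params an `hmm_params`; `pi` is used as the initial distribution.
#' @return list with `gamma` (n x 2, rows sum to 1), `xi` ((n-1) x 2 x 2
#'   array, `xi[t, i, j] = p(state_t = i, state_{t+1} = j | obs)`), and
#'   `loglik`.
#' @export
forward_backward <- function(obs, params) {
  lb <- emission_logmat(obs, params)
  n <- nrow(lb)
  if (n < 1L) stop("empty observation sequence", call. = FALSE)
  # lift emissions to linear scale with a per-step offset (kept in loglik)
  off <- apply(lb, 1L, max)
  if (any(!is.finite(off)))
    stop("zero emission density in both states", call. = FALSE)
  b <- exp(lb - off)
  Tm <- params$T

  af <- matrix(0, n, 2)                 # scaled forward
  cs <- numeric(n)                      # per-step scale factors
  a <- params$pi * b[1L, ]
  cs[1L] <- sum(a)
  if (cs[1L] <= 0) stop("zero total likelihood at step 1", call. = FALSE)
  af[1L, ] <- a / cs[1L]
  if (n > 1L) for (t in 2L:n) {
    a <- (af[t - 1L, ] %*% Tm) * b[t, ]
    cs[t] <- sum(a)
    if (cs[t] <= 0) stop("zero total likelihood at step ", t, call. = FALSE)
    af[t, ] <- a / cs[t]
  }

  bw <- matrix(0, n, 2)                 # scaled backward
  bw[n, ] <- 1
  if (n > 1L) for (t in (n - 1L):1L) {
    bw[t, ] <- (Tm %*% (b[t + 1L, ] * bw[t + 1L, ])) / cs[t + 1L]
  }

  gamma <- af * bw
  gamma <- gamma / rowSums(gamma)
  xi <- array(0, c(max(n - 1L, 0L), 2L, 2L))
  if (n > 1L) for (t in seq_len(n - 1L)) {
    m <- (af[t, ] %o% (b[t + 1L, ] * bw[t + 1L, ])) * Tm / cs[t + 1L]
    xi[t, , ] <- m / sum(m)
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cs)) + sum(off))
}

#' Viterbi decoding
#'
#' Returns the most probable hidden state path given the observations,
#' computed in log space.  Exact ties are broken towards state 1.
#'
#' @inheritParams forward_backward
#' @return integer vector of states (1 = random, 2 = directed), one per step.
#' @export
viterbi <- function(obs, params) {
  lb <- emission_logmat(obs, params)
  n <- nrow(lb)
  if (n < 1L) stop("empty observation sequence", call. = FALSE)
  lT <- log(params$T)
  delta <- matrix(-Inf, n, 2)
  psi <- matrix(1L, n, 2)
  delta[1L, ] <- log(params$pi) + lb[1L, ]
  if (n > 1L) for (t in 2L:n) {
    for (j in 1:2) {
      cand <- delta[t - 1L, ] + lT[, j]
      psi[t, j] <- which.max(cand)      # first index wins ties -> state 1
      delta[t, j] <- cand[psi[t, j]] + lb[t, j]
    }
  }
  states <- integer(n)
  states[n] <- which.max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  states
}

# deterministic initial parameters from pooled log speeds
init_hmm_params <- function(obs_list) {
  li <- log(unlist(lapply(obs_list, `[[`, "iota")))
  q <- stats::quantile(li, c(0.25, 0.75), names = FALSE)
  if (q[2] - q[1] < 1e-6) q <- q + c(-0.5, 0.5)
  s <- max(stats::sd(li), 1e-3)
  hmm_params(mu_iota = q, sigma_iota = c(s, s), sigma_alpha2 = 30,
             pi = c(0.5, 0.5),
             T = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
}

#' Baum-Welch (EM) parameter estimation with freezable groups
#'
#' Fits the two-state HMM to one or several observation sequences (several
#' sequences are treated as independent realisations sharing one parameter
#' set).  Any subset of the parameter groups `mu_iota`, `sigma_iota`,
#' `sigma_alpha2`, `pi`, `T` can be frozen at its initial value; the
#' remaining groups are re-estimated each M-step:
#' \itemize{
#'   \item `mu_iota[i]` = responsibility-weighted mean of `log(iota)`;
#'   \item `sigma_iota[i]` = responsibility-weighted sd of `log(iota)`
#'     (floored at 1e-3);
#'   \item `sigma_alpha2` = sqrt of the state-2-weighted mean squared angle
#'     over steps with an angle (floored at 0.5 degrees);
#'   \item `T[i, j]` = expected transition counts, row-normalised;
#'   \item the chain's initial distribution = mean initial-step
#'     responsibility (the textbook update, which preserves the EM guarantee
#'     that the log-likelihood never decreases).
#' }
#' The reported `pi` follows its defined meaning — the overall proportion of
#' steps spent in each state: with `pi_update = "occupancy"` (default) the
#' returned `params$pi` is the time-averaged occupancy
#' `sum_t gamma_t(i) / n_steps` at convergence, which is what the
#' single-observation Bayes prior and downstream per-cell summaries use.
#' `pi_update = "initial"` instead reports the fitted initial-step
#' responsibility itself (degenerate towards 0/1 for a single long
#' sequence).
#'
#' After a fit with free `mu_iota`, states are relabelled if needed so that
#' state 1 is the slower one (`mu_iota[1] < mu_iota[2]`).
#'
#' @param obs a `perox_obs` or a list of them.
#' @param params0 starting `hmm_params`; `NULL` for a deterministic
#'   data-driven initialisation.
#' @param frozen character vector of parameter-group names to hold fixed.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum number of EM iterations.
#' @param pi_update `"occupancy"` (default) or `"initial"`.
#' @return list of class `"hmm_fit"`: `params`, `loglik_trace`, `n_iter`,
#'   `converged`.
#' @export
baum_welch <- function(obs, params0 = NULL, frozen = character(),
                       tol = 1e-6, max_iter = 500L,
                       pi_update = c("occupancy", "initial")) {
  pi_update <- match.arg(pi_update)
  if (inherits(obs, "perox_obs")) obs <- list(obs)
  groups <- c("mu_iota", "sigma_iota", "sigma_alpha2", "pi", "T")
  if (!all(frozen %in% groups))
    stop("unknown frozen group(s): ",
         paste(setdiff(frozen, groups), collapse = ", "), call. = FALSE)
  params <- if (is.null(params0)) init_hmm_params(obs) else params0

  if (all(groups %in% frozen)) {
    ll <- sum(vapply(obs, function(o) forward_backward(o, params)$loglik, 0))
    return(structure(list(params = params, loglik_trace = ll, n_iter = 0L,
                          converged = TRUE), class = "hmm_fit"))
  }

  li <- lapply(obs, function(o) log(o$iota))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  ll_prev <- -Inf
  repeat {
    fbs <- lapply(obs, forward_backward, params = params)
    ll <- sum(vapply(fbs, `[[`, 0, "loglik"))
    trace <- c(trace, ll)
    if (abs(ll - ll_prev) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_prev <- ll
    iter <- iter + 1L

    # accumulate sufficient statistics over sequences
    g_sum <- c(0, 0); gl_sum <- c(0, 0)
    g1 <- c(0, 0)
    xi_sum <- matrix(0, 2, 2); grow_sum <- c(0, 0)
    a2_sum <- 0; ga_sum <- 0
    for (k in seq_along(obs)) {
      g <- fbs[[k]]$gamma
      g_sum <- g_sum + colSums(g)
      gl_sum <- gl_sum + colSums(g * li[[k]])
      g1 <- g1 + g[1L, ]
      if (nrow(g) > 1L) {
        xi_sum <- xi_sum + apply(fbs[[k]]$xi, c(2, 3), sum)
        grow_sum <- grow_sum + colSums(g[-nrow(g), , drop = FALSE])
      }
      ok <- !is.na(obs[[k]]$alpha)
      if (any(ok)) {
        a2_sum <- a2_sum + sum(g[ok, 2L] * obs[[k]]$alpha[ok]^2)
        ga_sum <- ga_sum + sum(g[ok, 2L])
      }
    }

    mu <- params$mu_iota; sg <- params$sigma_iota
    if (!("mu_iota" %in% frozen) || !("sigma_iota" %in% frozen)) {
      if (any(g_sum < 1e-10)) {
        warning("a state received (near-)zero responsibility mass; ",
                "its speed parameters kept at previous values")
      }
      safe <- g_sum >= 1e-10
      mu_new <- ifelse(safe, gl_sum / pmax(g_sum, 1e-300), mu)
      if (!("mu_iota" %in% frozen)) mu <- mu_new
      if (!("sigma_iota" %in% frozen)) {
        v <- c(0, 0)
        for (k in seq_along(obs)) {
          g <- fbs[[k]]$gamma
          d2 <- cbind((li[[k]] - mu[1])^2, (li[[k]] - mu[2])^2)
          v <- v + colSums(g * d2)
        }
        sg <- ifelse(safe, pmax(sqrt(v / pmax(g_sum, 1e-300)), 1e-3), sg)
      }
    }
    sa <- params$sigma_alpha2
    if (!("sigma_alpha2" %in% frozen) && ga_sum > 1e-10)
      sa <- max(sqrt(a2_sum / ga_sum), 0.5)
    Tm <- params$T
    if (!("T" %in% frozen) && any(grow_sum > 0)) {
      Tm <- xi_sum / pmax(rowSums(xi_sum), 1e-300)
      zero <- rowSums(xi_sum) < 1e-300
      Tm[zero, ] <- params$T[zero, ]
    }
    pv <- params$pi
    if (!("pi" %in% frozen)) {
      pv <- g1 / length(obs)
      pv <- pmin(pmax(pv, 0), 1)
      pv <- pv / sum(pv)
    }
    params <- hmm_params(mu, sg, sa, pv, Tm)
  }

  if (!("pi" %in% frozen) && pi_update == "occupancy") {
    # report pi with its Eq.-interpretation: proportion of steps per state,
    # from the responsibilities at convergence
    occ <- Reduce(`+`, lapply(fbs, function(f) colSums(f$gamma)))
    params <- hmm_params(params$mu_iota, params$sigma_iota,
                         params$sigma_alpha2, occ / sum(occ), params$T)
  }
  if (!("mu_iota" %in% frozen) && params$mu_iota[1] > params$mu_iota[2])
    params <- relabel_states(params)
  structure(list(params = params, loglik_trace = trace, n_iter = iter,
                 converged = converged), class = "hmm_fit")
}

# swap state labels (1 <-> 2) in every parameter group; sigma_alpha2 stays
# attached to the directed state by construction
relabel_states <- function(params) {
  hmm_params(rev(params$mu_iota), rev(params$sigma_iota), params$sigma_alpha2,
             rev(params$pi), params$T[2:1, 2:1])
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> %d EM iterations, loglik %.4f, %s\n", x$n_iter,
              x$loglik_trace[length(x$loglik_trace)],
              if (x$converged) "converged" else "not converged"))
  print(x$params)
  invisible(x)
}
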