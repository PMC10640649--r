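sim_obs <- function(n_tracks, n_steps = 150L, seed = 1L, ...) {
  ds <- simulate_dataset(sim_params(n_tracks = n_tracks, n_steps = n_steps,
                                    ...), seed = seed)
  list(obs = observables_set(ds$tracks), truth = ds$truth, tracks = ds$tracks)
}

test_that("with every group frozen the fit is a no-op likelihood evaluation", {
  set.seed(31)
  obs <- random_obs(30)
  p0 <- random_params()
  fit <- baum_welch(obs, p0,
                    frozen = c("mu_iota", "sigma_iota", "sigma_alpha2",
                               "pi", "T"))
  expect_identical(fit$n_iter, 0L)
  expect_equal(fit$params$mu_iota, p0$mu_iota)
  expect_equal(fit$params$T, p0$T)
  expect_equal(fit$loglik_trace, forward_backward(obs, p0)$loglik)
})

test_that("EM log-likelihood never decreases, from arbitrary starts", {
  set.seed(32)
  d <- sim_obs(3, n_steps = 120L, seed = 91L)
  for (o in d$obs) {
    p0 <- random_params()
    fit <- baum_welch(o, p0, max_iter = 60L)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
  # and for a pooled multi-sequence fit
  fit_all <- baum_welch(d$obs, max_iter = 60L)
  expect_true(all(diff(fit_all$loglik_trace) >= -1e-8))
})

test_that("every M-step output is a valid parameter set", {
  set.seed(33)
  o <- sim_obs(1, n_steps = 100L, seed = 7L)$obs[[1]]
  fit <- baum_welch(o, max_iter = 50L)
  p <- fit$params
  expect_equal(sum(p$pi), 1, tolerance = 1e-12)
  expect_equal(rowSums(p$T), c(1, 1), tolerance = 1e-12)
  expect_true(all(p$sigma_iota >= 1e-3) && p$sigma_alpha2 >= 0.5)
})

test_that("frozen emission groups pass through the fit unchanged", {
  d <- sim_obs(2, n_steps = 150L, seed = 15L)
  em <- hmm_params(c(0.9, 2.3), c(0.7, 0.12), 6)
  for (o in d$obs) {
    fit <- baum_welch(o, em, frozen = c("mu_iota", "sigma_iota",
                                        "sigma_alpha2"))
    expect_identical(fit$params$mu_iota, em$mu_iota)
    expect_identical(fit$params$sigma_iota, em$sigma_iota)
    expect_identical(fit$params$sigma_alpha2, em$sigma_alpha2)
    expect_false(isTRUE(all.equal(fit$params$T, em$T)))  # T was free
  }
})

test_that("states are relabelled so state 1 is the slower one", {
  d <- sim_obs(1, n_steps = 200L, seed = 23L)
  o <- d$obs[[1]]
  flipped <- hmm_params(c(2.5, 0.8), c(0.2, 0.8), 30)
  fit <- baum_welch(o, flipped, max_iter = 100L)
  expect_lt(fit$params$mu_iota[1], fit$params$mu_iota[2])
})

test_that("fitted speed locations recover the generative ln-speed means", {
  d <- sim_obs(20, n_steps = 200L, seed = 41L)
  # moment oracle: ln-speed means of the two generative modes, from truth
  li <- lapply(d$obs, function(o) log(o$iota))
  m_true <- sapply(1:2, function(s)
    mean(unlist(Map(function(l, tr) l[tr == s], li, d$truth[names(li)]))))
  fits <- lapply(d$obs, baum_welch)
  mu <- rowMeans(sapply(fits, function(f) f$params$mu_iota))
  expect_equal(mu[1], m_true[1], tolerance = 0.1)
  expect_equal(mu[2], m_true[2], tolerance = 0.05)
  # directed-mode location: ln(10) minus the delta-method correction
  expect_equal(mu[2], log(10) - 1 / (2 * 100), tolerance = 0.05)
})

test_that("reported pi is the state occupancy of the sequence", {
  d <- sim_obs(4, n_steps = 200L, seed = 55L)
  for (id in names(d$obs)) {
    fit <- baum_welch(d$obs[[id]])
    occ_true <- mean(d$truth[[id]] == 2L)
    expect_equal(fit$params$pi[2], occ_true, tolerance = 0.06)
    fb <- forward_backward(d$obs[[id]], fit$params)
    expect_equal(fit$params$pi[2], mean(fb$gamma[, 2]), tolerance = 0.02)
  }
})

test_that("per-track switching estimates recover the generative rates", {
  d <- sim_obs(30, n_steps = 200L, seed = 77L)
  fits <- lapply(d$obs, baum_welch)
  T12 <- sapply(fits, function(f) f$params$T[1, 2])
  T21 <- sapply(fits, function(f) f$params$T[2, 1])
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(T12) - 0.1), 3 * se(T12) + 0.01)
  expect_lt(abs(mean(T21) - 0.1), 3 * se(T21) + 0.01)
})
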