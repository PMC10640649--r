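ref_params <- hmm_params(mu_iota = c(-0.93, 0.06), sigma_iota = c(0.72, 0.50),
                         sigma_alpha2 = 26)

test_that("speed log density matches the log-normal closed form and normalises", {
  p <- hmm_params(c(0, 1), c(1, 1), 26)
  expect_equal(speed_logpdf(1, 1L, p), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  # at the median of state 1 of the fitted parameters
  expect_equal(speed_logpdf(exp(-0.93), 1L, ref_params),
               log(1 / (exp(-0.93) * 0.72 * sqrt(2 * pi))),
               tolerance = 1e-12)
  expect_error(speed_logpdf(0, 1L, p), "positive")
  q <- stats::integrate(function(x) exp(speed_logpdf(x, 1L, ref_params)),
                        0, 50, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)
})

test_that("angle log density: uniform state, truncated normal state, absent angles", {
  expect_equal(angle_logpdf(37, 1L, ref_params), log(1 / 360))
  expect_equal(angle_logpdf(-170, 1L, ref_params), log(1 / 360))
  # truncation correction at sigma = 26 degrees is < 1e-10
  expect_equal(angle_logpdf(0, 2L, ref_params),
               log(1 / (26 * sqrt(2 * pi))), tolerance = 1e-9)
  # one-sigma point of a Gaussian sits exactly 1/2 below the mode
  expect_equal(angle_logpdf(26, 2L, ref_params),
               angle_logpdf(0, 2L, ref_params) - 0.5, tolerance = 1e-12)
  expect_identical(angle_logpdf(NA_real_, 1L, ref_params), 0)
  expect_identical(angle_logpdf(NA_real_, 2L, ref_params), 0)
  # truncated density renormalises even when sigma is wide
  wide <- hmm_params(c(0, 1), c(1, 1), 200)
  q <- stats::integrate(function(a) exp(angle_logpdf(a, 2L, wide)),
                        -180, 180, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-8)
})

test_that("joint emission factorises and integrates to 1 over both observables", {
  expect_equal(emission_logpdf(1.3, NA_real_, 2L, ref_params),
               speed_logpdf(1.3, 2L, ref_params))
  p <- hmm_params(c(0, 1), c(1, 1), 26)
  expect_equal(emission_logpdf(1, 45, 1L, p),
               log(1 / sqrt(2 * pi)) + log(1 / 360), tolerance = 1e-12)
  qi <- stats::integrate(function(x) exp(speed_logpdf(x, 2L, ref_params)),
                         0, 100, rel.tol = 1e-10)$value
  qa <- stats::integrate(function(a) exp(angle_logpdf(a, 2L, ref_params)),
                         -180, 180, rel.tol = 1e-10)$value
  expect_equal(qi * qa, 1, tolerance = 1e-6)
})

test_that("single-observation posterior follows Bayes' theorem", {
  p <- hmm_params(c(0, 1), c(1, 1), 26, pi = c(0.5, 0.5))
  # symmetric emissions (absent angle, iota at equal density point)
  iota_eq <- exp(0.5)   # equidistant in log space from mu = 0 and mu = 1
  expect_equal(posterior_state(iota_eq, NA_real_, p), c(0.5, 0.5),
               tolerance = 1e-12)
  p10 <- hmm_params(c(0, 1), c(1, 1), 26, pi = c(1, 0))
  expect_equal(posterior_state(2, 30, p10), c(1, 0))
  # emission ratio 1:4 with prior [0.8, 0.2] balances out
  pr <- hmm_params(c(0, 0), c(1, 0.25), 26, pi = c(0.8, 0.2))
  expect_equal(posterior_state(1, NA_real_, pr), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("expected speeds reproduce the log-normal mean identity", {
  expect_equal(round(expected_speed(-0.93, 0.72), 1), 0.5)
  expect_equal(round(expected_speed(0.06, 0.50), 1), 1.2)
  expect_equal(expected_speed(0, 0), 1)
  expect_equal(expected_speed(2, 0.3), exp(2 + 0.045), tolerance = 1e-12)
})

test_that("parameter container validates and serialises to JSON round-trip", {
  expect_error(hmm_params(c(0, 1), c(1, -1), 26), "sigma_iota")
  expect_error(hmm_params(c(0, 1), c(1, 1), 26, pi = c(0.7, 0.7)), "pi")
  expect_error(hmm_params(c(0, 1), c(1, 1), 26,
                          T = matrix(c(0.5, 0.6, 0.1, 0.9), 2, byrow = TRUE)),
               "stochastic")
  f <- withr::local_tempfile(fileext = ".json")
  params_to_json(ref_params, f)
  back <- params_from_json(f)
  expect_equal(back$mu_iota, ref_params$mu_iota)
  expect_equal(back$T, ref_params$T)
  expect_equal(back$sigma_alpha2, ref_params$sigma_alpha2)
})
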