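test_that("classification metrics match hand-counted confusion tables", {
  truth <- c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)
  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1_standard, 1)
  expect_equal(perfect$per_track_accuracy, 1)

  # TP=3, FP=1, FN=2, TN=4
  tr <- c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)
  pr <- c(2L, 2L, 2L, 1L, 1L, 2L, 1L, 1L, 1L, 1L)
  m <- classification_metrics(tr, pr)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3L, 1L, 2L, 4L))
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1_standard, 2 * 0.45 / 1.35, tolerance = 1e-12)
  expect_equal(m$f1_as_printed, 0.45 / 1.35, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.7)

  all1 <- classification_metrics(tr, rep(1L, 10))
  expect_equal(all1$recall, 0)
  expect_equal(all1$precision, 0)
  expect_true("precision" %in% all1$undefined)
  expect_error(classification_metrics(1:4, 1:5), "mismatch")
})

test_that("run-ratio curves count consecutive directed steps with CIs", {
  one <- list(c(1L, 2L, 2L, 2L, 1L))
  rr <- run_ratio_curve(one, k_max = 5, n_boot = 50)
  expect_equal(rr$ratio, c(1, 1, 1, 0, 0))

  three <- list(rep(1L, 6), rep(1L, 4), c(2L))
  rr3 <- run_ratio_curve(three, k_max = 3, n_boot = 200)
  expect_equal(rr3$ratio[1], 1 / 3)
  expect_equal(rr3$ratio[2], 0)

  set.seed(81)
  rand <- lapply(1:20, function(i) sample(1:2, 30, replace = TRUE))
  rrr <- run_ratio_curve(rand, k_max = 8, n_boot = 300)
  expect_true(all(diff(rrr$ratio) <= 0))
  expect_true(all(rrr$ci_low <= rrr$ratio + 1e-12))
  expect_true(all(rrr$ci_high >= rrr$ratio - 1e-12))
  expect_error(run_ratio_curve(list(), 5), "no state")
})

test_that("per-cell aggregation takes element-wise means preserving row sums", {
  pt <- data.frame(cell_id = c("c1", "c2", "c2"),
                   pi1 = c(0.9, 0.8, 0.6), pi2 = c(0.1, 0.2, 0.4),
                   T11 = c(0.95, 0.9, 0.8), T12 = c(0.05, 0.1, 0.2),
                   T21 = c(0.3, 0.2, 0.4), T22 = c(0.7, 0.8, 0.6))
  agg <- aggregate_per_cell(pt)
  expect_equal(agg$pi2[agg$cell_id == "c1"], 0.1)   # single track: identity
  expect_equal(agg$pi2[agg$cell_id == "c2"], 0.3)   # mean of 0.2, 0.4
  expect_equal(agg$pi1 + agg$pi2, rep(1, 2))
  expect_equal(agg$T11 + agg$T12, rep(1, 2))
  expect_equal(agg$T21 + agg$T22, rep(1, 2))
  expect_equal(agg$n_tracks, c(1L, 2L))
})

test_that("condition comparison reproduces the textbook t statistic", {
  cc <- compare_conditions(c(1, 2, 3), c(4, 5, 6), var_equal = TRUE)
  # pooled sd = 1, t = -3 / sqrt(2/3), df = 4
  expect_equal(cc$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(cc$p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-10)
  expect_equal(cc$p, 0.0213, tolerance = 1e-2)

  same <- compare_conditions(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  cc3 <- compare_conditions(c(1, 2, 3), c(4, 5, 6), m = 3, var_equal = TRUE)
  expect_equal(cc3$q, min(1, 3 * cc3$p))
  expect_gte(cc3$q, cc3$p)
  cc1 <- compare_conditions(rnorm(5), rnorm(5), m = 1)
  expect_equal(cc1$q, cc1$p)
})

test_that("zero speed-parameter noise reproduces the unperturbed F1 exactly", {
  ds <- simulate_dataset(sim_params(n_tracks = 6L, n_steps = 120L),
                         seed = 83L)
  model <- track_hmm(ds$tracks)
  pred <- predict(model, type = "viterbi")
  base <- classification_metrics(ds$truth,
                                 split(pred$state, pred$track_id)[names(ds$truth)])
  set.seed(84)
  tab <- perturbation_experiment(model, ds$truth, sigma_levels = c(0, 10),
                                 n_reps = 3L)
  expect_equal(tab$mean_f1[tab$sigma == 0], base$f1_standard)
  expect_equal(tab$sd_f1[tab$sigma == 0], 0)
  # enormous noise destroys the emission ordering
  expect_lt(tab$mean_f1[tab$sigma == 10], base$f1_standard)
})
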