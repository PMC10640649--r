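#' End-to-end validation run on simulated tracks
#'
#' Simulates a labelled switching-track dataset, fits the full HMM to each
#' track (all parameter groups free), decodes states with Viterbi, and
#' scores the decoding against the generative ground truth; optionally runs
#' the speed-parameter perturbation experiment.
#'
#' @param sim a `sim_params` (defaults reproduce the validation setting).
#' @param seed root seed for simulation and perturbation noise.
#' @param sigma_levels,n_reps perturbation settings; `sigma_levels = NULL`
#'   skips the experiment.
#' @param out_dir optional directory; when given, tracks, truth, decoded
#'   states, the report and run metadata (seed, parameters) are written
#'   there as CSV/JSON.
#' @return list with `report` (a `validation_report`), `accuracy_per_track`,
#'   `mean_accuracy`, `model` (the `track_hmm`), `decoded` (named list of
#'   state vectors), `truth`, `perturbation` (data.frame or `NULL`), `sim`,
#'   `seed`.
#' @export
run_validation <- function(sim = sim_params(), seed = 1L,
                           sigma_levels = c(0, 0.1, 0.2, 0.3, 0.5),
                           n_reps = 20L, out_dir = NULL) {
  ds <- simulate_dataset(sim, seed = seed)
  if (!length(ds$truth)) stop("empty simulated dataset", call. = FALSE)
  model <- track_hmm(ds$tracks, share = "per_track")
  pred_df <- predict(model, type = "viterbi")
  decoded <- split(pred_df$state, pred_df$track_id)[names(ds$truth)]
  report <- classification_metrics(ds$truth, decoded)
  acc <- vapply(names(ds$truth),
                function(id) mean(ds$truth[[id]] == decoded[[id]]), 0)
  perturbation <- NULL
  if (!is.null(sigma_levels)) {
    set.seed(seed + 1L)
    perturbation <- perturbation_experiment(model, ds$truth,
                                            sigma_levels = sigma_levels,
                                            n_reps = n_reps)
  }
  out <- list(report = report, accuracy_per_track = acc,
              mean_accuracy = mean(acc), model = model, decoded = decoded,
              truth = ds$truth, perturbation = perturbation, sim = sim,
              seed = seed)
  if (!is.null(out_dir)) write_validation_outputs(out, ds, out_dir)
  out
}

write_validation_outputs <- function(out, ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks_csv(ds$tracks, file.path(out_dir, "tracks.csv"))
  write_truth_csv(ds$truth, file.path(out_dir, "truth.csv"))
  write_truth_csv(out$decoded, file.path(out_dir, "decoded_states.csv"))
  rep <- out$report
  utils::write.csv(data.frame(
    metric = c("tp", "fp", "tn", "fn", "recall", "precision", "f1_standard",
               "f1_as_printed", "accuracy", "mean_per_track_accuracy"),
    value = c(rep$tp, rep$fp, rep$tn, rep$fn, rep$recall, rep$precision,
              rep$f1_standard, rep$f1_as_printed, rep$accuracy,
              out$mean_accuracy)),
    file.path(out_dir, "validation_report.csv"), row.names = FALSE)
  if (!is.null(out$perturbation))
    utils::write.csv(out$perturbation,
                     file.path(out_dir, "perturbation.csv"),
                     row.names = FALSE)
  meta <- list(seed = out$seed, sim = unclass(out$sim),
               config_hash = config_hash(list(seed = out$seed,
                                              sim = unclass(out$sim))))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
}

# stable short hash of a configuration list (no external digest dependency)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Two-stage analysis of a track dataset
#'
#' The full analysis workflow for real or simulated track data:
#' \enumerate{
#'   \item Stage 1 — emission parameters (`mu_iota`, `sigma_iota`,
#'     `sigma_alpha2`) are taken from `emission_params`, or fitted (all
#'     groups free) on the tracks named in `stage1_ids` — a user-curated set
#'     of mixed-mode tracks — and averaged across them.
#'   \item Stage 2 — emissions are frozen and `pi` and `T` are fitted per
#'     track; states are Viterbi-decoded with each track's own parameters.
#'   \item Per-cell averages of `pi`/`T`, consecutive-directed-run ratio
#'     curves per condition with bootstrap CIs, per-cell MSD exponents, and
#'     pairwise condition comparisons (Bonferroni-corrected over all
#'     pairs x metrics) are derived from the per-track fits.
#' }
#'
#' @param ts a `perox_trackset` (cells/conditions taken from the tracks).
#' @param emission_params optional `hmm_params` carrying stage-1 emissions.
#' @param stage1_ids track ids used to fit emissions when `emission_params`
#'   is `NULL`.
#' @param min_steps minimum track length filter applied before stage 2.
#' @param k_max,n_boot run-ratio curve settings.
#' @param msd_max_lag,msd_fit_range MSD settings.
#' @param compare_metrics per-cell columns compared between conditions.
#' @param seed seed for the bootstrap.
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @return list with `emissions` (`hmm_params`), `stage2` (the `track_hmm`),
#'   `per_track` (data.frame incl. cell/condition), `per_cell`, `decoded`,
#'   `run_ratios` (named list per condition), `msd`, `comparisons`
#'   (data.frame), `seed`.
#' @export
run_study <- function(ts, emission_params = NULL, stage1_ids = NULL,
                      min_steps = 50L, k_max = 10L, n_boot = 1000L,
                      msd_max_lag = 20, msd_fit_range = c(0.1, 20),
                      compare_metrics = c("pi2", "T12", "T21"),
                      seed = 1L, out_dir = NULL) {
  ts <- filter_min_steps(ts, min_steps)
  if (!length(ts)) stop("no track passes the minimum-steps filter",
                        call. = FALSE)
  if (is.null(emission_params)) {
    if (is.null(stage1_ids))
      stop("supply emission_params or stage1_ids", call. = FALSE)
    missing <- setdiff(stage1_ids, names(unclass(ts)))
    if (length(missing))
      stop("stage1_ids not in track set: ", paste(missing, collapse = ", "),
           call. = FALSE)
    stage1 <- track_hmm(ts[stage1_ids], share = "per_track")
    emission_params <- stage1$params
  }
  stage2 <- track_hmm(ts, params0 = emission_params,
                      frozen = c("mu_iota", "sigma_iota", "sigma_alpha2"),
                      share = "per_track")
  pred_df <- predict(stage2, type = "viterbi")
  decoded <- split(pred_df$state, pred_df$track_id)

  per_track <- stage2$per_track
  trs <- unclass(ts)[per_track$track_id]
  per_track$cell_id <- vapply(trs, `[[`, "", "cell_id")
  per_track$condition <- vapply(trs, `[[`, "", "condition")
  per_cell <- aggregate_per_cell(per_track)

  set.seed(seed)
  conds <- unique(per_track$condition)
  run_ratios <- lapply(conds, function(cd) {
    ids <- per_track$track_id[per_track$condition == cd]
    run_ratio_curve(decoded[ids], k_max = k_max, n_boot = n_boot)
  })
  names(run_ratios) <- conds

  msd <- msd_by_cell(ts, max_lag = msd_max_lag, min_steps = min_steps,
                     fit_range = msd_fit_range)

  comparisons <- NULL
  if (length(conds) >= 2L) {
    pairs <- utils::combn(conds, 2L, simplify = FALSE)
    m <- length(pairs) * length(compare_metrics)
    rows <- list()
    for (pr in pairs) for (met in compare_metrics) {
      x <- per_cell[[met]][per_cell$condition == pr[1]]
      y <- per_cell[[met]][per_cell$condition == pr[2]]
      if (length(x) < 2L || length(y) < 2L) next
      cc <- compare_conditions(x, y, m = m)
      rows[[length(rows) + 1L]] <-
        data.frame(condition_a = pr[1], condition_b = pr[2], metric = met,
                   t = cc$statistic, df = cc$df, p = cc$p, q = cc$q, m = m,
                   stringsAsFactors = FALSE)
    }
    comparisons <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  out <- list(emissions = emission_params, stage2 = stage2,
              per_track = per_track, per_cell = per_cell, decoded = decoded,
              run_ratios = run_ratios, msd = msd,
              comparisons = comparisons, seed = seed)
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

write_study_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params_to_json(out$emissions, file.path(out_dir, "emission_params.json"))
  utils::write.csv(out$per_track, file.path(out_dir, "per_track.csv"),
                   row.names = FALSE)
  utils::write.csv(out$per_cell, file.path(out_dir, "per_cell.csv"),
                   row.names = FALSE)
  write_truth_csv(out$decoded, file.path(out_dir, "decoded_states.csv"))
  for (cd in names(out$run_ratios))
    utils::write.csv(out$run_ratios[[cd]],
                     file.path(out_dir, sprintf("run_ratio_%s.csv", cd)),
                     row.names = FALSE)
  utils::write.csv(out$msd$summary, file.path(out_dir, "msd_summary.csv"),
                   row.names = FALSE)
  if (!is.null(out$comparisons))
    utils::write.csv(out$comparisons,
                     file.path(out_dir, "condition_comparisons.csv"),
                     row.names = FALSE)
  meta <- list(seed = out$seed,
               config_hash = config_hash(list(seed = out$seed)))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
}
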