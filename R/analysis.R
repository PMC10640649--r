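#' Classification metrics for decoded state sequences
#'
#' Compares predicted to ground-truth state sequences with the directed
#' state (2) as the positive class.  Reports recall = TP/(TP+FN),
#' precision = TP/(TP+FP), the conventional F1 = 2PR/(P+R)
#' (`f1_standard`) and the variant without the factor 2
#' (`f1_as_printed`), plus overall and per-track accuracy.  Ratios with a
#' zero denominator are reported as 0 and flagged.
#'
#' @param truth,pred integer vectors in \{1, 2\}, or lists of such vectors
#'   (one per track); lengths must match element-wise.
#' @return list of class `"validation_report"`: counts `tp`, `fp`, `tn`,
#'   `fn`; `recall`, `precision`, `f1_standard`, `f1_as_printed`,
#'   `accuracy`, `per_track_accuracy` (mean over tracks), `undefined`
#'   (character vector of flagged metrics).
#' @export
classification_metrics <- function(truth, pred) {
  if (!is.list(truth)) truth <- list(truth)
  if (!is.list(pred)) pred <- list(pred)
  if (length(truth) != length(pred))
    stop("truth and pred must have the same number of sequences",
         call. = FALSE)
  tp <- fp <- tn <- fn <- 0L
  acc <- numeric(length(truth))
  for (k in seq_along(truth)) {
    tr <- truth[[k]]; pr <- pred[[k]]
    if (length(tr) != length(pr))
      stop("sequence length mismatch at index ", k, call. = FALSE)
    tp <- tp + sum(tr == 2L & pr == 2L)
    fp <- fp + sum(tr == 1L & pr == 2L)
    tn <- tn + sum(tr == 1L & pr == 1L)
    fn <- fn + sum(tr == 2L & pr == 1L)
    acc[k] <- mean(tr == pr)
  }
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  recall <- ratio(tp, tp + fn, "recall")
  precision <- ratio(tp, tp + fp, "precision")
  f1s <- ratio(2 * precision * recall, precision + recall, "f1")
  f1p <- ratio(precision * recall, precision + recall, "f1")
  undefined <- unique(undefined)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 recall = recall, precision = precision,
                 f1_standard = f1s, f1_as_printed = f1p,
                 accuracy = (tp + tn) / (tp + fp + tn + fn),
                 per_track_accuracy = mean(acc),
                 undefined = undefined),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  recall %.4f  precision %.4f  F1 %.4f (as-printed %.4f)\n",
              x$recall, x$precision, x$f1_standard, x$f1_as_printed))
  cat(sprintf("  accuracy %.4f  mean per-track accuracy %.4f\n",
              x$accuracy, x$per_track_accuracy))
  if (length(x$undefined))
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Sensitivity of state inference to speed-parameter noise
#'
#' For each noise level `sigma`, repeatedly perturbs both entries of the
#' fitted `mu_iota` with independent normal(0, sigma) noise, re-runs Viterbi
#' decoding with the perturbed parameters, and records the F1 score against
#' ground truth (pooled over tracks).  At `sigma = 0` this reproduces the
#' unperturbed F1 exactly.
#'
#' @param model a `track_hmm` fitted to the tracks being evaluated.
#' @param truth named list of ground-truth state vectors (names = track ids).
#' @param sigma_levels noise standard deviations to scan.
#' @param n_reps perturbation replicates per level.
#' @param f1 which F1 convention to report.
#' @return data.frame with columns `sigma`, `mean_f1`, `sd_f1`.
#' @export
perturbation_experiment <- function(model, truth,
                                    sigma_levels = c(0, 0.1, 0.2, 0.3, 0.5),
                                    n_reps = 20L,
                                    f1 = c("f1_standard", "f1_as_printed")) {
  f1 <- match.arg(f1)
  ids <- names(model$obs)
  stopifnot(all(ids %in% names(truth)))
  params_of <- function(id)
    if (model$share == "per_track") model$fits[[id]]$params else model$params
  rows <- lapply(sigma_levels, function(sg) {
    f1s <- vapply(seq_len(n_reps), function(r) {
      preds <- lapply(ids, function(id) {
        p <- params_of(id)
        noise <- stats::rnorm(2, 0, sg)
        pp <- hmm_params(p$mu_iota + noise, p$sigma_iota, p$sigma_alpha2,
                         p$pi, p$T)
        viterbi(model$obs[[id]], pp)
      })
      classification_metrics(truth[ids], preds)[[f1]]
    }, 0)
    data.frame(sigma = sg, mean_f1 = mean(f1s), sd_f1 = stats::sd(f1s))
  })
  do.call(rbind, rows)
}

# length of the longest run of the directed state in one sequence
longest_directed_run <- function(states) {
  r <- rle(states == 2L)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

#' Ratio of tracks with at least k consecutive directed steps
#'
#' For k = 1..`k_max`, the fraction of tracks whose decoded state sequence
#' contains a run of at least k consecutive directed (state 2) steps, with a
#' percentile bootstrap confidence interval obtained by resampling tracks
#' with replacement.  The curve is non-increasing in k by construction.
#'
#' @param states list of integer state vectors (one per track).
#' @param k_max largest run length considered.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @return data.frame with columns `k`, `ratio`, `ci_low`, `ci_high`.
#' @export
run_ratio_curve <- function(states, k_max = 10L, n_boot = 1000L,
                            conf = 0.95) {
  if (!length(states)) stop("no state sequences", call. = FALSE)
  stopifnot(n_boot >= 1L)
  runs <- vapply(states, longest_directed_run, 0L)
  ks <- seq_len(k_max)
  ratio <- vapply(ks, function(k) mean(runs >= k), 0)
  boot <- matrix(0, n_boot, k_max)
  for (b in seq_len(n_boot)) {
    rs <- runs[sample.int(length(runs), replace = TRUE)]
    boot[b, ] <- vapply(ks, function(k) mean(rs >= k), 0)
  }
  a <- (1 - conf) / 2
  ci <- apply(boot, 2L, stats::quantile, probs = c(a, 1 - a))
  data.frame(k = ks, ratio = ratio, ci_low = ci[1, ], ci_high = ci[2, ])
}

#' Per-cell averages of per-track occupancy and transition estimates
#'
#' Element-wise means of `pi` and `T` entries over the tracks of each cell.
#' Plain means preserve row-stochasticity, so no renormalisation is applied
#' unless requested.
#'
#' @param per_track data.frame with columns `cell_id`, `pi1`, `pi2`, `T11`,
#'   `T12`, `T21`, `T22` (one row per track), e.g. the `per_track` component
#'   of a `track_hmm` joined with cell ids.
#' @param renormalize re-normalise `pi` and the rows of `T` after averaging.
#' @return data.frame with one row per cell.
#' @export
aggregate_per_cell <- function(per_track, renormalize = FALSE) {
  stopifnot(is.data.frame(per_track), "cell_id" %in% names(per_track))
  cols <- c("pi1", "pi2", "T11", "T12", "T21", "T22")
  stopifnot(all(cols %in% names(per_track)))
  agg <- stats::aggregate(per_track[cols], by = list(cell_id = per_track$cell_id),
                          FUN = mean)
  if ("condition" %in% names(per_track)) {
    cond <- per_track$condition[match(agg$cell_id, per_track$cell_id)]
    agg <- cbind(agg[1], condition = cond, agg[-1])
  }
  agg$n_tracks <- as.integer(table(per_track$cell_id)[agg$cell_id])
  if (renormalize) {
    s <- agg$pi1 + agg$pi2
    agg$pi1 <- agg$pi1 / s; agg$pi2 <- agg$pi2 / s
    s1 <- agg$T11 + agg$T12; s2 <- agg$T21 + agg$T22
    agg$T11 <- agg$T11 / s1; agg$T12 <- agg$T12 / s1
    agg$T21 <- agg$T21 / s2; agg$T22 <- agg$T22 / s2
  }
  agg
}

#' Compare a per-cell quantity between two conditions
#'
#' Two-sided two-sample t-test (Welch by default; classical equal-variance
#' Student test via `var_equal = TRUE`) with Bonferroni correction
#' `q = min(1, m p)` for `m` simultaneous comparisons.
#'
#' @param x,y numeric vectors of per-cell values for the two conditions
#'   (length >= 2 each).
#' @param m number of comparisons for the Bonferroni correction.
#' @param var_equal assume equal variances.
#' @return list of class `"condition_comparison"`: `statistic`, `p`, `q`,
#'   `m`, `df`, `method`.
#' @export
compare_conditions <- function(x, y, m = 1L, var_equal = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L, m >= 1L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    out <- list(statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                p = if (eq) 1 else 0,
                df = length(x) + length(y) - 2,
                method = "degenerate (zero variance in both groups)")
  } else {
    tt <- stats::t.test(x, y, var.equal = var_equal,
                        alternative = "two.sided")
    out <- list(statistic = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter), method = tt$method)
  }
  out$q <- min(1, m * out$p)
  out$m <- as.integer(m)
  structure(out, class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> t = %.4f (df %.2f), p = %.4g, q = %.4g (m = %d)\n",
              x$statistic, x$df, x$p, x$q, x$m))
  invisible(x)
}
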