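#' Paired comparison of per-trial period statistics
#'
#' Two-sided paired test on per-trial values of a statistic in two periods
#' (trials are paired by construction: same seed, topology and noise).
#' Default is the paired t test; a Wilcoxon signed-rank test is available.
#' If every difference is exactly zero the comparison is degenerate and
#' `p = 1` is returned; if the differences are constant but non-zero the
#' t statistic is infinite and `p = 0`.
#'
#' @param a,b numeric vectors of equal length `n >= 3`, per-trial values.
#' @param method `"ttest"` or `"wilcoxon"`.
#' @return list with `statistic`, `p`, `method`, `n`, `mean_difference`.
#' @examples
#' compare_periods(c(2, 3, 4), c(1, 1, 1))$statistic  # 3.4641
#' @export
compare_periods <- function(a, b, method = c("ttest", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 3) stop("need at least 3 paired values")
  d <- a - b
  if (all(d == 0))
    return(list(statistic = 0, p = 1, method = method, n = n,
                mean_difference = 0))
  if (sd(d) == 0 && method == "ttest")
    return(list(statistic = sign(mean(d)) * Inf, p = 0, method = method,
                n = n, mean_difference = mean(d)))
  if (method == "ttest") {
    ht <- t.test(d)
    list(statistic = unname(ht$statistic), p = ht$p.value, method = method,
         n = n, mean_difference = mean(d))
  } else {
    ht <- suppressWarnings(wilcox.test(d, exact = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value, method = method,
         n = n, mean_difference = mean(d))
  }
}

#' Read-out spike counts per period
#'
#' @param recording a [run_trial()] recording (or its `spikes` data.frame).
#' @param periods a [default_periods()] period set.
#' @return named integer vector of read-out spike counts.
#' @export
readout_spike_counts <- function(recording, periods = default_periods()) {
  sp <- if (inherits(recording, "trial_recording")) recording$spikes
        else recording
  t_ro <- sp$t_ms[sp$class == "readout"]
  vapply(periods, function(per) sum(in_period(t_ro, per)), numeric(1))
}

#' Locate the return of the population rate to background
#'
#' Measures, on the trial-averaged excitatory PSTH of an
#' [run_condition()] result, when the rate first comes back to the
#' pre-stimulus background level after stimulus onset.
#'
#' The background band is `mean +/- 2 SD` where mean and SD are taken
#' across trials of the per-trial Pre-adp mean rate. Reported are:
#' \describe{
#'   \item{t_return}{left edge (ms) of the first post-onset window whose
#'     trial-averaged rate lies inside the band (0 if the rate never left
#'     it).}
#'   \item{t_rise}{left edge of the first post-onset window above the band
#'     (`NA` if the rate never rises above it).}
#'   \item{adaptation_length}{`t_return_after_rise - t_rise`: time from the
#'     rate rise to the first subsequent window back inside the band.}
#' }
#'
#' @param result an `experiment_result` (any condition).
#' @param window analysis window in ms; must be a multiple of the stored
#'   20-ms PSTH bin.
#' @param pre_period the background reference period.
#' @return list with the fields above plus `pre_mean`, `band`, and the
#'   windowed trial-averaged PSTH (`t`, `rate`).
#' @export
adaptation_timing <- function(result, window = 100,
                              pre_period = default_periods()$`Pre-adp`) {
  stopifnot(inherits(result, "experiment_result"))
  fold <- window / result$psth_e_bin
  if (abs(fold - round(fold)) > 1e-8)
    stop("window must be a multiple of the stored PSTH bin")
  fold <- round(fold)
  nb <- ncol(result$psth_e) %/% fold
  g <- rep(seq_len(nb), each = fold)
  m <- t(apply(result$psth_e[, seq_len(nb * fold), drop = FALSE], 1,
               function(row) tapply(row, g, mean)))
  edges <- result$t_range[1] + (seq_len(nb) - 1) * window

  pre_idx <- edges >= pre_period[1] & edges + window <= pre_period[2]
  pre_trial <- rowMeans(m[, pre_idx, drop = FALSE])
  pre_mean <- mean(pre_trial)
  band <- 2 * sd(pre_trial)

  avg <- colMeans(m)
  post <- which(edges >= 0)
  inside <- abs(avg[post] - pre_mean) <= band
  above <- avg[post] > pre_mean + band

  t_return <- if (any(inside)) edges[post[which(inside)[1]]] else NA_real_
  t_rise <- if (any(above)) edges[post[which(above)[1]]] else NA_real_
  t_ret_after <- NA_real_
  if (!is.na(t_rise)) {
    later <- post[edges[post] > t_rise]
    ins2 <- abs(avg[later] - pre_mean) <= band
    if (any(ins2)) t_ret_after <- edges[later[which(ins2)[1]]]
  }
  list(t_return = if (is.na(t_rise)) 0 else t_return,
       t_rise = t_rise,
       t_return_after_rise = t_ret_after,
       adaptation_length = if (!is.na(t_rise) && !is.na(t_ret_after))
         t_ret_after - t_rise else NA_real_,
       pre_mean = pre_mean, band = band,
       psth = data.frame(t = edges, rate = avg))
}

#' Significance report over a set of conditions
#'
#' Runs the paired period comparisons the protocol is built around: for
#' every condition, the correlation statistic (mean pairwise covariance;
#' its shuffled version for the `shuffled-analysis` condition) in Adp vs
#' Pre-adp and Adp vs Post-adp; for conditions with dynamic synapses also
#' the mean efficacy `ux`; and for the default condition the read-out
#' spike counts. Significance is assessed at `alpha` with no
#' multiple-comparison correction (each comparison is reported raw).
#'
#' @param results list of [run_condition()] results.
#' @param alpha significance threshold.
#' @param method test passed to [compare_periods()].
#' @return an object of class `significance_report`: a data.frame with one
#'   row per comparison (`condition`, `statistic`, `comparison`, `test`,
#'   `statistic_value`, `p`, `significant`, `n_trials`,
#'   `mean_difference`).
#' @export
build_report <- function(results, alpha = 0.05,
                         method = c("ttest", "wilcoxon")) {
  method <- match.arg(method)
  if (!length(results)) stop("need at least one condition result")
  if (inherits(results, "experiment_result")) results <- list(results)
  rows <- list()
  add <- function(cond, stat_name, comp_name, a, b, n) {
    ct <- compare_periods(a, b, method)
    rows[[length(rows) + 1]] <<- data.frame(
      condition = cond, statistic = stat_name, comparison = comp_name,
      test = ct$method, statistic_value = ct$statistic, p = ct$p,
      significant = ct$p < alpha, n_trials = n,
      mean_difference = ct$mean_difference, stringsAsFactors = FALSE)
  }
  for (res in results) {
    stopifnot(inherits(res, "experiment_result"))
    cn <- res$condition$name
    for (other in c("Pre-adp", "Post-adp")) {
      add(cn, "correlation", paste0("Adp vs ", other),
          correlation_statistic(res, "Adp"),
          correlation_statistic(res, other), res$n_trials)
      if (!res$condition$static_synapses && !res$condition$use_shuffled)
        add(cn, "ux", paste0("Adp vs ", other),
            period_statistic(res, "ux", "Adp"),
            period_statistic(res, "ux", other), res$n_trials)
      if (cn == "default")
        add(cn, "readout_count", paste0("Adp vs ", other),
            period_statistic(res, "readout_count", "Adp"),
            period_statistic(res, "readout_count", other), res$n_trials)
    }
  }
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("significance_report", "data.frame"))
}

#' @export
print.significance_report <- function(x, ...) {
  y <- as.data.frame(x)
  y$p <- signif(y$p, 3)
  y$statistic_value <- signif(y$statistic_value, 4)
  y$mean_difference <- signif(y$mean_difference, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Serialize a report or experiment summary to JSON / TSV
#'
#' @param report a [build_report()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write spikes in the exchange TSV layout
#'
#' Columns `trial`, `neuron_id`, `class`, `t_ms` (3-decimal fixed times,
#' relative to stimulus onset).
#'
#' @param recordings a `trial_recording` or list of them.
#' @param path output file.
#' @export
write_spikes_tsv <- function(recordings, path) {
  if (inherits(recordings, "trial_recording")) recordings <- list(recordings)
  tabs <- lapply(seq_along(recordings), function(k) {
    sp <- recordings[[k]]$spikes
    data.frame(trial = k, neuron_id = sp$neuron_id, class = sp$class,
               t_ms = sprintf("%.3f", sp$t_ms), stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
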