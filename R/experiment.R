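#' Bin a trace matrix over one period
#'
#' Restricts a (time x neuron) trace matrix to a period and averages
#' consecutive samples into bins of `bin` ms. This is the preprocessing
#' applied to the input currents `s_i` before every covariance estimate
#' (bin width `t_w` = 5 ms by default, the same bin the shuffling control
#' uses).
#'
#' @param trace matrix, time frames (rows) by neurons (columns).
#' @param times frame midpoints (ms), as in `run_trial(...)$time`.
#' @param period `c(start, end)` ms, half-open.
#' @param bin bin width in ms; must be a multiple of the frame interval and
#'   divide the period length.
#' @return matrix, bins (rows) by neurons (columns).
#' @export
period_bin_means <- function(trace, times, period, bin = 5) {
  keep <- times >= period[1] & times < period[2]
  m <- trace[keep, , drop = FALSE]
  dt <- if (sum(keep) > 1) diff(times[keep][1:2]) else 1
  per_bin <- bin / dt
  if (abs(per_bin - round(per_bin)) > 1e-8)
    stop("bin must be a multiple of the trace sampling interval")
  per_bin <- round(per_bin)
  nb <- nrow(m) / per_bin
  if (abs(nb - round(nb)) > 1e-8)
    stop("bin must divide the period length (no partial bins)")
  g <- rep(seq_len(round(nb)), each = per_bin)
  out <- rowsum(m, g, reorder = FALSE) / per_bin
  rownames(out) <- NULL
  out
}

#' Shuffle a current trace in small bins
#'
#' Cuts a trace into contiguous, non-overlapping bins of `bin` ms and
#' permutes their order uniformly at random; for a matrix each column
#' (neuron) is permuted independently. The multiset of bin contents, hence
#' every per-neuron time mean, is preserved exactly, while the temporal
#' structure (and any cross-neuron alignment) is destroyed. This is the
#' control analysis showing that the correlation increase during adaptation
#' is carried by the temporal structure of the currents, not by their
#' means.
#'
#' @param trace numeric vector or (time x neuron) matrix sampled on a
#'   regular grid.
#' @param bin bin size in ms.
#' @param seed integer seed (caller's RNG state preserved).
#' @param dt sampling interval of `trace` in ms.
#' @return an object of the same shape as `trace`.
#' @export
shuffle_current_bins <- function(trace, bin = 5, seed, dt = 1) {
  per_bin <- bin / dt
  if (abs(per_bin - round(per_bin)) > 1e-8)
    stop("bin must be a multiple of dt")
  per_bin <- round(per_bin)
  vec <- is.null(dim(trace))
  m <- if (vec) matrix(trace, ncol = 1) else trace
  nb <- nrow(m) / per_bin
  if (abs(nb - round(nb)) > 1e-8)
    stop("trace length must be an integer number of bins (no partial bins)")
  nb <- round(nb)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- m
  for (j in seq_len(ncol(m))) {
    perm <- sample.int(nb)
    idx <- rep((perm - 1) * per_bin, each = per_bin) + seq_len(per_bin)
    out[, j] <- m[idx, j]
  }
  if (vec) out[, 1] else out
}

#' Network-mean synaptic efficacy trace
#'
#' The instantaneous strength of an E-to-E synapse is `u * x` (release
#' probability times available fraction); both variables live on the
#' presynaptic neuron and are shared by all of its outgoing synapses, so
#' the network mean over synapses equals the mean over excitatory neurons.
#'
#' @param recording a [run_trial()] recording.
#' @return data.frame with `t` (ms) and `ux`.
#' @export
mean_synaptic_efficacy_trace <- function(recording) {
  stopifnot(inherits(recording, "trial_recording"))
  if (recording$static_synapses)
    stop("the static-synapse model has no plasticity state")
  data.frame(t = recording$time, ux = recording$ux)
}

#' Tsodyks-Markram steady state at a constant rate
#'
#' Mean-field fixed point of the facilitation/depression variables under
#' Poisson firing at `rate` Hz: `u* = U r tau_f / (1 + U r tau_f)` (with
#' `r` in 1/ms) and `x* = 1 / (1 + u+ r tau_d)` where `u+ = u* + U(1-u*)`
#' is the post-facilitation value that gates release. Used as an analytic
#' anchor for the baseline efficacy.
#'
#' @param rate firing rate in Hz.
#' @param params a [network_params()] object.
#' @return list with `u`, `x` and `ux = u+ x*` (the mean transmitted
#'   efficacy per spike) and `ux_rest = u* x*` (the resting product).
#' @export
stp_steady_state <- function(rate, params) {
  r <- rate / 1000
  u_star <- params$U * r * params$tau_f / (1 + params$U * r * params$tau_f)
  u_plus <- u_star + params$U * (1 - u_star)
  x_star <- 1 / (1 + u_plus * r * params$tau_d)
  list(u = u_star, x = x_star, ux = u_plus * x_star,
       ux_rest = u_star * x_star)
}

#' Experimental conditions
#'
#' Builds a condition descriptor for [run_condition()]:
#' \describe{
#'   \item{default}{dynamic synapses, sustained stimulus \[0, 1500) ms.}
#'   \item{transient}{stimulus only \[0, 20) ms; no adaptation develops.}
#'   \item{static}{no plasticity; every E-to-E spike transmits the constant
#'     efficacy `j_s`.}
#'   \item{stp_variant}{dynamic synapses with one of the alternative
#'     `(tau_d, tau_f, U)` triples from [stp_variants()].}
#'   \item{shuffled-analysis}{identical simulations to `default`; the
#'     correlation statistics are taken from bin-shuffled currents. A
#'     post-hoc analysis switch, not a new simulation.}
#' }
#'
#' @param name condition name.
#' @param variant for `stp_variant`, an index into [stp_variants()] or a
#'   named list with `tau_d`, `tau_f`, `U`.
#' @return an object of class `condition`.
#' @export
condition <- function(name = c("default", "transient", "static",
                               "stp_variant", "shuffled-analysis"),
                      variant = NULL) {
  name <- match.arg(name)
  cond <- list(name = name, stimulus_window = c(0, 1500),
               static_synapses = FALSE, overrides = list(),
               use_shuffled = FALSE)
  if (name == "transient") cond$stimulus_window <- c(0, 20)
  if (name == "static") cond$static_synapses <- TRUE
  if (name == "shuffled-analysis") cond$use_shuffled <- TRUE
  if (name == "stp_variant") {
    if (is.null(variant)) stop("stp_variant requires a 'variant'")
    if (is.numeric(variant)) variant <- stp_variants()[[variant]]
    stopifnot(all(c("tau_d", "tau_f", "U") %in% names(variant)))
    cond$overrides <- variant[c("tau_d", "tau_f", "U")]
    cond$variant <- variant
  } else if (!is.null(variant)) {
    stop("'variant' only applies to the stp_variant condition")
  }
  structure(cond, class = "condition")
}

#' @rdname condition
#' @return `stp_variants()` returns the three alternative plasticity
#'   parameter triples studied alongside the defaults: a slow-facilitation
#'   variant (`tau_f` = 1000 ms), a symmetric variant (`tau_f` = 400 ms)
#'   and a fast-facilitation variant (`tau_f` = 50 ms), each with
#'   `tau_d` = 400 ms and with `U` rescaled so that firing rates still
#'   adapt during the stimulus.
#' @export
stp_variants <- function() {
  list(slow_stf = list(tau_d = 400, tau_f = 1000, U = 0.0018),
       mid_stf = list(tau_d = 400, tau_f = 400, U = 0.00425),
       fast_stf = list(tau_d = 400, tau_f = 50, U = 0.02))
}

#' Run a batch of trials under one condition
#'
#' Simulates `n_trials` trials with seeds `base_seed + 0 ...
#' base_seed + n_trials - 1` and reduces each trial to its per-period
#' statistics. Because trial `i` of every condition uses the same seed, the
#' same topology and the same noise realization, conditions can be compared
#' with paired tests.
#'
#' Per trial and period the result records: the mean pairwise covariance of
#' the 5-ms binned input currents `s_i` (`mpc`, the estimate of
#' `sigma_s^2 alpha`), the same quantity after the bin-shuffling control
#' (`mpc_shuffled`), the mean per-neuron current SD (`sigma_s`) and mean
#' (`mu_s`), the mean synaptic efficacy (`ux`), the excitatory population
#' rate (`e_rate`, Hz), the read-out spike count (`readout_count`) and the
#' synchrony fractions in `t_w` bins (in `$fractions`).
#'
#' @param cond a [condition()] object (or a condition name).
#' @param n_trials number of trials (>= 1).
#' @param base_seed integer; trial `i` uses seed `base_seed + i - 1`.
#' @param params base [network_params()]; condition overrides are applied on
#'   top.
#' @param periods a [default_periods()] period set.
#' @param progress print one line per trial?
#' @return an object of class `experiment_result` with fields `stats`
#'   (data.frame), `fractions` (list: trial, then period), `psth_e`
#'   (trials x 20-ms bins matrix of E rates), `psth_readout` (trials x
#'   100-ms bins), `condition`, `params`, `periods`, `seeds`.
#' @export
run_condition <- function(cond, n_trials, base_seed, params = network_params(),
                          periods = default_periods(), progress = FALSE) {
  if (is.character(cond)) cond <- condition(cond)
  stopifnot(inherits(cond, "condition"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (length(cond$overrides))
    params <- do.call(network_params,
                      utils::modifyList(as.list(unclass(params)),
                                        cond$overrides))
  seeds <- base_seed + seq_len(n_trials) - 1L

  t_range <- c(-params$t_total / 2, params$t_total / 2)
  e_bins <- (t_range[2] - t_range[1]) %/% 20
  ro_bins <- (t_range[2] - t_range[1]) %/% 100
  psth_e <- matrix(0, n_trials, e_bins)
  psth_ro <- matrix(0, n_trials, ro_bins)
  fractions <- vector("list", n_trials)
  rows <- vector("list", n_trials)

  for (k in seq_len(n_trials)) {
    tr <- run_trial(params, stimulus_window = cond$stimulus_window,
                    seed = seeds[k], static_synapses = cond$static_synapses)
    sp <- tr$spikes
    psth_e[k, ] <- population_rate_trace(sp, 20, "E", params$n_e,
                                         t_range)$rate
    psth_ro[k, ] <- population_rate_trace(sp, 100, "readout", 1,
                                          t_range)$rate
    frac_k <- list()
    stat_k <- list()
    for (pn in names(periods)) {
      per <- periods[[pn]]
      bm <- period_bin_means(tr$s, tr$time, per, bin = params$t_w)
      bm_sh <- shuffle_current_bins(bm, bin = params$t_w, seed = seeds[k] + 33331L,
                                    dt = params$t_w)
      frac <- population_rate_fractions(sp, per, params$t_w, params$n_e)
      len_s <- (per[2] - per[1]) / 1000
      stat_k[[pn]] <- data.frame(
        trial = k, seed = seeds[k], period = pn,
        mpc = mean_pairwise_covariance(bm),
        mpc_shuffled = mean_pairwise_covariance(bm_sh),
        sigma_s = estimate_sigma_s(bm),
        mu_s = mean(bm),
        ux = if (cond$static_synapses) NA_real_
             else mean(tr$ux[in_period(tr$time, per)]),
        e_rate = sum(sp$class == "E" & in_period(sp$t_ms, per)) /
          params$n_e / len_s,
        readout_count = sum(sp$class == "readout" & in_period(sp$t_ms, per)),
        drive_mean = mean(tr$drive[in_period(tr$time, per)]),
        drive_sd = sd(tr$drive[in_period(tr$time, per)]),
        stringsAsFactors = FALSE)
      frac_k[[pn]] <- frac
    }
    fractions[[k]] <- frac_k
    rows[[k]] <- do.call(rbind, stat_k)
    if (progress)
      message(sprintf("trial %d/%d (seed %d) done", k, n_trials, seeds[k]))
  }

  structure(list(
    stats = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    fractions = fractions,
    psth_e = psth_e,
    psth_readout = psth_ro,
    psth_e_bin = 20, psth_readout_bin = 100, t_range = t_range,
    condition = cond, params = params, periods = periods,
    n_trials = n_trials, seeds = seeds), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> condition '%s', %d trials (seeds %d..%d)\n",
              x$condition$name, x$n_trials, min(x$seeds), max(x$seeds)))
  agg <- stats::aggregate(cbind(mpc, sigma_s, e_rate, readout_count) ~ period,
                          x$stats, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Extract a per-trial period statistic
#'
#' @param result an [run_condition()] result.
#' @param statistic column of `result$stats`.
#' @param period period label.
#' @return numeric vector, one value per trial (in trial order).
#' @export
period_statistic <- function(result, statistic, period) {
  stopifnot(inherits(result, "experiment_result"))
  st <- result$stats
  if (!statistic %in% names(st)) stop("unknown statistic: ", statistic)
  if (!period %in% st$period) stop("unknown period: ", period)
  st <- st[st$period == period, ]
  st[[statistic]][order(st$trial)]
}

#' Reinterpret a default-condition result as the shuffled-analysis control
#'
#' The shuffled-analysis condition is a post-hoc manipulation of the
#' default-condition recordings, not a new simulation: this converts a
#' default [run_condition()] result so that its correlation statistic is
#' read from the bin-shuffled currents.
#'
#' @param result a default-condition `experiment_result`.
#' @return the same result tagged as condition `shuffled-analysis`.
#' @export
shuffled_analysis <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  if (result$condition$name != "default")
    stop("shuffled-analysis reuses default-condition recordings")
  result$condition <- condition("shuffled-analysis")
  result
}

#' The correlation statistic a condition is judged by
#'
#' `mpc` for simulated conditions, `mpc_shuffled` for the post-hoc
#' `shuffled-analysis` condition.
#'
#' @inheritParams period_statistic
#' @export
correlation_statistic <- function(result, period) {
  stat <- if (isTRUE(result$condition$use_shuffled)) "mpc_shuffled" else "mpc"
  period_statistic(result, stat, period)
}
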