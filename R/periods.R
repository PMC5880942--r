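#' Analysis periods of a trial
#'
#' Returns the three labeled half-open analysis windows used throughout the
#' protocol (ms, relative to stimulus onset): `Pre-adp` = \[-900, -100),
#' before the stimulus; `Adp` = \[500, 1300), late in the stimulus when
#' firing rates have adapted; `Post-adp` = \[1600, 2400), after stimulus
#' offset. All three are 800 ms long and pairwise disjoint.
#'
#' @return an object of class `period_set`: a named list of `c(start, end)`
#'   vectors.
#' @examples
#' default_periods()$`Pre-adp`
#' @export
default_periods <- function() {
  structure(list(`Pre-adp` = c(-900, -100),
                 `Adp` = c(500, 1300),
                 `Post-adp` = c(1600, 2400)),
            class = "period_set")
}

#' @export
print.period_set <- function(x, ...) {
  cat("<period_set>\n")
  for (nm in names(x))
    cat(sprintf("  %-8s [%g, %g) ms\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

period_names <- function(periods) names(periods)

in_period <- function(t, period) t >= period[1] & t < period[2]

#' Binned population firing-rate trace
#'
#' Counts spikes of one class in consecutive windows of length `window`
#' (default `t_f` = 100 ms) and converts to Hz per neuron.
#'
#' @param spikes a spike data.frame (`neuron_id`, `class`, `t_ms`), e.g.
#'   `run_trial(...)$spikes`.
#' @param window bin width in ms.
#' @param class `"E"` or `"I"`.
#' @param n_neurons number of neurons in the class (defaults to the Table
#'   sizes 2000/500 cannot be guessed from spikes alone, so pass it).
#' @param t_range `c(start, end)` of the trace in ms.
#' @return a data.frame with `t` (left bin edge, ms) and `rate` (Hz per
#'   neuron).
#' @examples
#' sp <- data.frame(neuron_id = 1:5, class = "E", t_ms = rep(50, 5))
#' population_rate_trace(sp, 100, "E", n_neurons = 5, t_range = c(0, 100))
#' @export
population_rate_trace <- function(spikes, window, class, n_neurons,
                                  t_range) {
  if (window <= 0) stop("window must be > 0")
  if (n_neurons <= 0) stop("empty neuron class")
  edges <- seq(t_range[1], t_range[2], by = window)
  if (length(edges) < 2) stop("t_range shorter than one window")
  t <- spikes$t_ms[spikes$class == class]
  t <- t[t >= t_range[1] & t < edges[length(edges)]]
  counts <- tabulate(findInterval(t, edges), nbins = length(edges) - 1)
  data.frame(t = edges[-length(edges)],
             rate = counts / n_neurons / (window / 1000))
}

#' Population synchrony fractions
#'
#' Splits a period into bins of `t_w` ms (default 5 ms) and returns, for
#' each bin, the fraction of distinct excitatory neurons that fired at
#' least once in the bin. These fractions are the data fitted by the
#' dichotomized Gaussian population model.
#'
#' @inheritParams population_rate_trace
#' @param period `c(start, end)` in ms; `t_w` must divide its length.
#' @param t_w bin size in ms.
#' @param n_e number of excitatory neurons.
#' @return numeric vector of fractions in \[0, 1\], one per bin.
#' @export
population_rate_fractions <- function(spikes, period, t_w, n_e) {
  len <- period[2] - period[1]
  nb <- len / t_w
  if (abs(nb - round(nb)) > 1e-8)
    stop("t_w must divide the period length")
  nb <- round(nb)
  keep <- spikes$class == "E" & in_period(spikes$t_ms, period)
  if (!any(keep)) return(numeric(nb))
  bin <- floor((spikes$t_ms[keep] - period[1]) / t_w) + 1
  id <- spikes$neuron_id[keep]
  distinct <- tapply(id, factor(bin, levels = seq_len(nb)),
                     function(v) length(unique(v)))
  distinct[is.na(distinct)] <- 0
  as.numeric(distinct) / n_e
}

#' Trial-averaged peri-stimulus time histogram
#'
#' Averages spike counts per bin over trials and converts to a rate. For a
#' population PSTH pass `per_neuron = n_class` to get Hz per neuron; for the
#' read-out neuron leave `per_neuron = 1` to get absolute Hz.
#'
#' @param spike_list list of spike data.frames, one per trial.
#' @param bin bin width in ms.
#' @param class spike class to count.
#' @param per_neuron divisor for per-neuron rates.
#' @param t_range `c(start, end)` in ms.
#' @return data.frame with `t` (left edge), `rate` (trial-averaged Hz) and
#'   `rate_sd` (SD across trials).
#' @export
psth <- function(spike_list, bin, class, per_neuron = 1,
                 t_range = c(-2500, 2500)) {
  if (bin <= 0) stop("bin must be > 0")
  mats <- vapply(spike_list, function(sp)
    population_rate_trace(sp, bin, class, per_neuron, t_range)$rate,
    numeric((t_range[2] - t_range[1]) %/% bin))
  edges <- seq(t_range[1], t_range[2] - bin, by = bin)
  data.frame(t = edges,
             rate = rowMeans(mats),
             rate_sd = apply(mats, 1, sd))
}
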