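#' Dichotomized Gaussian population model
#'
#' The synchrony analysis models the input current of neuron `i` in a
#' stationary period as a Gaussian with a common latent factor,
#' `s_i = mu_s + sigma_s * (sqrt(1 - alpha) * nu_i + sqrt(alpha) * eps)`,
#' where `nu_i` are independent standard normals private to each neuron and
#' `eps` is a standard normal shared by the whole population. The shared
#' factor induces the pairwise covariance `cov(s_i, s_j) = sigma_s^2 *
#' alpha`, the quantity used to measure pairwise correlation. A neuron
#' "fires" in a bin when its current exceeds a threshold `h`, and the
#' population rate `r` of a bin is the fraction of neurons above threshold.
#'
#' @param mu_s mean input current (uA).
#' @param sigma_s SD of the input current (uA), > 0.
#' @param alpha shared-variance fraction in \[0, 1).
#' @param h firing threshold (uA).
#' @return an object of class `dg_params`.
#' @examples
#' dp <- dg_params(mu_s = 0, sigma_s = 1, alpha = 0.1, h = 1.5)
#' mean(dg_sample(dp, n_neurons = 500, n_bins = 200, seed = 1))
#' pnorm((dp$mu_s - dp$h) / dp$sigma_s)  # expected rate
#' @export
dg_params <- function(mu_s, sigma_s, alpha, h) {
  if (!is.finite(sigma_s) || sigma_s <= 0) stop("sigma_s must be > 0")
  if (!is.finite(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  structure(list(mu_s = mu_s, sigma_s = sigma_s, alpha = alpha, h = h),
            class = "dg_params")
}

#' @export
print.dg_params <- function(x, ...) {
  cat(sprintf("<dg_params> mu_s = %g, sigma_s = %g, alpha = %g, h = %g (cov = %g)\n",
              x$mu_s, x$sigma_s, x$alpha, x$h, x$sigma_s^2 * x$alpha))
  invisible(x)
}

#' Mean per-neuron input SD
#'
#' Estimates `sigma_s` as the mean over neurons of the per-neuron sample SD
#' of the binned input current, the population counterpart of the
#' per-neuron current fluctuation in the dichotomized Gaussian model.
#'
#' @param traces numeric matrix, samples (rows) by neurons (columns).
#' @return scalar estimate of `sigma_s`.
#' @export
estimate_sigma_s <- function(traces) {
  traces <- as.matrix(traces)
  if (nrow(traces) < 2)
    stop("need at least 2 samples per neuron to estimate sigma_s")
  mean(apply(traces, 2, sd))
}

#' Mean pairwise covariance of input currents
#'
#' Averages the sample covariance over all unordered neuron pairs; under
#' the dichotomized Gaussian model its expectation is `sigma_s^2 * alpha`.
#' Computed in O(N T) with the variance-of-sum identity
#' `mean_ij cov(s_i, s_j) = (Var(sum_i s_i) - sum_i Var(s_i)) / (N (N-1))`;
#' [mean_pairwise_covariance_pairs()] is the explicit O(N^2) pair loop kept
#' as a cross-check for small populations.
#'
#' @inheritParams estimate_sigma_s
#' @return scalar mean pairwise covariance (uA^2).
#' @export
mean_pairwise_covariance <- function(traces) {
  traces <- as.matrix(traces)
  n <- ncol(traces)
  if (n < 2) stop("need at least 2 neurons")
  (var(rowSums(traces)) - sum(apply(traces, 2, var))) / (n * (n - 1))
}

#' @rdname mean_pairwise_covariance
#' @export
mean_pairwise_covariance_pairs <- function(traces) {
  traces <- as.matrix(traces)
  n <- ncol(traces)
  if (n < 2) stop("need at least 2 neurons")
  cm <- cov(traces)
  mean(cm[upper.tri(cm)])
}

#' Monte Carlo sampler of population rates
#'
#' The brute-force sampling oracle of the model: per bin, one shared draw
#' `eps` and `n_neurons` private draws are thresholded and the fraction of
#' neurons above `h` is returned. Used to validate the closed-form density
#' [dg_rate_density()].
#'
#' @param params a [dg_params()] object.
#' @param n_neurons population size per bin.
#' @param n_bins number of bins (independent population samples).
#' @param seed integer seed (caller's RNG state is preserved).
#' @return numeric vector of `n_bins` fractions in \[0, 1\].
#' @export
dg_sample <- function(params, n_neurons, n_bins, seed) {
  stopifnot(inherits(params, "dg_params"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- numeric(n_bins)
  chunk <- max(1, floor(2e6 / max(n_neurons, 1)))
  done <- 0
  while (done < n_bins) {
    nb <- min(chunk, n_bins - done)
    eps <- rnorm(nb)
    nu <- matrix(rnorm(nb * n_neurons), n_neurons, nb)
    s <- params$mu_s + params$sigma_s *
      (sqrt(1 - params$alpha) * nu +
       matrix(sqrt(params$alpha) * eps, n_neurons, nb, byrow = TRUE))
    out[done + seq_len(nb)] <- colMeans(s >= params$h)
    done <- done + nb
  }
  out
}

#' Closed-form population-rate density
#'
#' Large-population density of the fraction `r` of neurons above threshold,
#' obtained by the change of variables from the shared factor `eps`: given
#' `eps`, the conditional firing probability is
#' `q(eps) = Phi((mu_s + sigma_s sqrt(alpha) eps - h) / (sigma_s sqrt(1 - alpha)))`
#' and as the population grows the fraction converges to `q(eps)`, so
#' `p(r) = phi(eps) / q'(eps)` at `eps = q^{-1}(r)`. The transformation is
#' exact, monotone and integrates to one; [dg_rate_density_norm()] reports
#' the quadrature check. `alpha = 0` is degenerate (all mass at the mean
#' rate) and is rejected.
#'
#' @inheritParams dg_sample
#' @param r rate value(s) strictly inside (0, 1).
#' @return density value(s).
#' @export
dg_rate_density <- function(params, r) {
  stopifnot(inherits(params, "dg_params"))
  if (params$alpha <= 0)
    stop("the density is degenerate at alpha = 0; use dg_sample()")
  if (any(r <= 0 | r >= 1)) stop("r must lie strictly inside (0, 1)")
  sa <- params$sigma_s * sqrt(params$alpha)
  s1 <- params$sigma_s * sqrt(1 - params$alpha)
  z <- qnorm(r)                      # q(eps) = r  <=>  z = Phi^-1(r)
  eps <- (s1 * z + params$h - params$mu_s) / sa
  # q'(eps) = phi(z) * sa / s1
  dnorm(eps) / (dnorm(z) * sa / s1)
}

#' @rdname dg_rate_density
#' @return `dg_rate_density_norm()` returns the numerical integral of the
#'   density over (0, 1); equal to 1 up to quadrature error.
#' @export
dg_rate_density_norm <- function(params) {
  integrate(function(r) dg_rate_density(params, r), 0, 1,
            rel.tol = 1e-9, subdivisions = 500L)$value
}

#' Finite-population synchrony distribution
#'
#' Exact distribution of the fraction `k / n_neurons` of neurons above
#' threshold in a population of `n_neurons`: conditional on the shared
#' factor `eps` the count is Binomial(`n_neurons`, `q(eps)`), so
#' `P(K = k) = integral phi(eps) dbinom(k, n, q(eps)) d eps` (computed on a
#' dense quadrature grid). This is the finite-population correction of
#' [dg_rate_density()] -- the large-population density smeared by binomial
#' sampling -- and converges to it as `n_neurons` grows.
#'
#' @inheritParams dg_sample
#' @param grid_n number of quadrature nodes over the shared factor.
#' @return data.frame with columns `k`, `r` (the fraction `k/n_neurons`)
#'   and probability `p` (sums to 1).
#' @export
dg_rate_pmf <- function(params, n_neurons, grid_n = 2001) {
  stopifnot(inherits(params, "dg_params"))
  eps <- seq(-8, 8, length.out = grid_n)
  w <- dnorm(eps)
  w <- w / sum(w)
  q <- pnorm((params$mu_s + params$sigma_s * sqrt(params$alpha) * eps -
              params$h) / (params$sigma_s * sqrt(1 - params$alpha)))
  k <- 0:n_neurons
  p <- numeric(n_neurons + 1)
  for (i in seq_along(eps))
    if (w[i] > 1e-14)
      p <- p + w[i] * stats::dbinom(k, n_neurons, q[i])
  data.frame(k = k, r = k / n_neurons, p = p / sum(p))
}

#' Total-variation distance between the model and its sampling oracle
#'
#' Draws `n_bins` population fractions with [dg_sample()] and compares the
#' empirical count distribution with the exact finite-population
#' distribution [dg_rate_pmf()] in total variation. Used to validate the
#' closed-form machinery against brute force. Counts are aggregated into
#' `n_hist` histogram cells whose width adapts to the central 99% of the
#' exact distribution (identically for both sides of the comparison), so
#' the statistic measures shape mismatch rather than per-count Monte Carlo
#' noise.
#'
#' @inheritParams dg_sample
#' @param n_hist target number of histogram cells across the distribution.
#' @return scalar TV distance in \[0, 1\].
#' @export
dg_tv_distance <- function(params, n_neurons, n_bins, seed, n_hist = 30) {
  r <- dg_sample(params, n_neurons, n_bins, seed)
  counts <- round(r * n_neurons)
  pmf <- dg_rate_pmf(params, n_neurons)
  cdf <- cumsum(pmf$p)
  lo <- pmf$k[which(cdf >= 0.005)[1]]
  hi <- pmf$k[which(cdf >= 0.995)[1]]
  w <- max(1, ceiling((hi - lo + 1) / n_hist))
  cell <- function(k) pmin(k %/% w, n_neurons %/% w) + 1
  n_cell <- n_neurons %/% w + 1
  emp <- tabulate(cell(counts), nbins = n_cell) / length(counts)
  exact <- vapply(split(pmf$p, cell(pmf$k)), sum, numeric(1))
  ex <- numeric(n_cell)
  ex[as.integer(names(exact))] <- exact
  sum(abs(emp - ex)) / 2
}

#' Threshold matching a mean population rate
#'
#' Solves `E[r] = Phi((mu_s - h) / sigma_s)` for the threshold:
#' `h = mu_s - sigma_s * Phi^{-1}(mean_rate)`. This is how the model is
#' anchored to data: `mu_s`, `sigma_s` and `alpha` come from the
#' current-trace estimates and only `h` is fitted, to the observed mean
#' synchrony fraction.
#'
#' @param mean_rate observed mean fraction of neurons firing per bin,
#'   strictly inside (0, 1).
#' @param mu_s,sigma_s current-trace estimates.
#' @return threshold `h` (uA).
#' @export
fit_threshold <- function(mean_rate, mu_s, sigma_s) {
  if (any(mean_rate <= 0 | mean_rate >= 1))
    stop("mean_rate must lie strictly inside (0, 1)")
  mu_s - sigma_s * qnorm(mean_rate)
}

#' Survival function of the synchrony distribution
#'
#' Right-tail cumulative probability `P(rate >= r)` of a synchrony
#' histogram, used to compare the probability of large synchronized events
#' across periods.
#'
#' @param fractions observed population fractions (e.g. from
#'   [population_rate_fractions()] or [dg_sample()]).
#' @param r_grid rate values at which to evaluate the survival function.
#' @return data.frame with `r` and `survival`.
#' @export
survival_curve <- function(fractions, r_grid = seq(0, 1, by = 0.005)) {
  n <- length(fractions)
  surv <- vapply(r_grid, function(r) sum(fractions >= r) / n, numeric(1))
  data.frame(r = r_grid, survival = surv)
}

#' Fit the dichotomized Gaussian model to one period of one trial
#'
#' Convenience wrapper assembling [dg_params()] from data: `mu_s` and
#' `sigma_s` from the binned current traces, `alpha` from the mean pairwise
#' covariance (`alpha = mpc / sigma_s^2`), and `h` from the observed mean
#' synchrony fraction via [fit_threshold()].
#'
#' @param bin_means binned current traces (bins x neurons).
#' @param fractions observed synchrony fractions for the same period.
#' @return a `dg_params` object with attribute `"mpc"` (the covariance
#'   estimate).
#' @export
fit_dg <- function(bin_means, fractions) {
  sigma_s <- estimate_sigma_s(bin_means)
  mpc <- mean_pairwise_covariance(bin_means)
  alpha <- max(0, min(mpc / sigma_s^2, 1 - 1e-12))
  mean_rate <- mean(fractions)
  mean_rate <- min(max(mean_rate, 1e-12), 1 - 1e-12)
  p <- dg_params(mu_s = mean(bin_means), sigma_s = sigma_s,
                 alpha = alpha, h = fit_threshold(mean_rate, mean(bin_means),
                                                  sigma_s))
  attr(p, "mpc") <- mpc
  p
}
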