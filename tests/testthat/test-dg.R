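test_that("sigma_s estimation recovers the per-neuron SD", {
  expect_equal(estimate_sigma_s(matrix(2.5, 50, 4)), 0)
  set.seed(14)
  m <- matrix(rnorm(5000 * 50, sd = 2), 5000, 50)
  est <- estimate_sigma_s(m)
  expect_lt(abs(est - 2), 3 * 2 / sqrt(2 * 5000))   # SE of an SD, averaged
  expect_equal(estimate_sigma_s(3 * m), 3 * est)    # homogeneity
  expect_error(estimate_sigma_s(m[1, , drop = FALSE]), "at least 2")
})

test_that("mean pairwise covariance: identity form equals the explicit pair loop", {
  set.seed(15)
  for (n in c(5, 20, 50)) {
    m <- matrix(rnorm(40 * n), 40, n) +
      matrix(rnorm(40), 40, n) * 0.3        # inject a common component
    expect_equal(mean_pairwise_covariance(m),
                 mean_pairwise_covariance_pairs(m), tolerance = 1e-12)
  }
  # identical traces -> the common variance; independent -> near zero
  v <- rnorm(100)
  expect_equal(mean_pairwise_covariance(cbind(v, v, v)), var(v))
  set.seed(16)
  ind <- matrix(rnorm(2000 * 100), 2000, 100)
  se <- 1 / sqrt(2000)                       # per-pair covariance SE ~ 1/sqrt(T)
  expect_lt(abs(mean_pairwise_covariance(ind)), 4 * se / sqrt(99))
})

test_that("the latent-factor model round-trips through the estimators", {
  # s_i = mu + sigma (sqrt(1-a) nu_i + sqrt(a) eps): recover sigma and
  # sigma^2 alpha from simulated traces
  set.seed(17)
  n_t <- 1e4; n_n <- 200; sigma <- 1; alpha <- 0.1
  eps <- rnorm(n_t)
  s <- sigma * (sqrt(1 - alpha) * matrix(rnorm(n_t * n_n), n_t, n_n) +
                sqrt(alpha) * eps)
  expect_lt(abs(estimate_sigma_s(s) - sigma), 0.03)
  mpc <- mean_pairwise_covariance(s)
  expect_gt(mpc, 0.08)
  expect_lt(mpc, 0.12)
})

test_that("the sampler obeys the degenerate and mean laws", {
  dp_all <- dg_params(0, 1, 0.2, h = -Inf)
  expect_true(all(dg_sample(dp_all, 50, 100, seed = 1) == 1))
  dp <- dg_params(0.3, 1.4, 0.25, h = 1.0)
  r <- dg_sample(dp, 400, 3000, seed = 2)
  target <- pnorm((dp$mu_s - dp$h) / dp$sigma_s)
  expect_lt(abs(mean(r) - target), 4 * sd(r) / sqrt(length(r)))
  # strong common noise pushes bins toward all-or-none firing
  dp1 <- dg_params(0, 1, 0.99, h = 0.6)
  r1 <- dg_sample(dp1, 400, 4000, seed = 3)
  expect_gt(mean(r1 < 0.05 | r1 > 0.95), 0.8)
  p_high <- pnorm((dp1$mu_s - dp1$h) / dp1$sigma_s)
  expect_lt(abs(mean(r1 > 0.5) - p_high), 4 * sqrt(p_high / 4000))
})

test_that("the closed-form density is normalized and matches the sampler", {
  for (al in c(0.05, 0.3)) {
    dp <- dg_params(0.1, 1.2, al, h = 1.3)
    expect_equal(dg_rate_density_norm(dp), 1, tolerance = 1e-6)
  }
  # vanishing shared variance concentrates the density at the mean rate
  dp0 <- dg_params(0, 1, 0.005, h = 0.5)
  center <- pnorm(-0.5)
  mass <- integrate(function(r) dg_rate_density(dp0, r),
                    center - 0.05, center + 0.05)$value
  expect_gt(mass, 0.9)
  expect_error(dg_rate_density(dp0, 0), "strictly inside")
  expect_error(dg_rate_density(dg_params(0, 1, 0, 1), 0.5), "degenerate")
  # moderate case: sampler histogram close to the finite-N distribution
  dp <- dg_params(0, 1, 0.1, h = fit_threshold(0.15, 0, 1))
  expect_lt(dg_tv_distance(dp, 500, 2e4, seed = 4), 0.05)
})

test_that("threshold fitting matches the observed mean rate", {
  expect_equal(fit_threshold(0.5, mu_s = 2.2, sigma_s = 3), 2.2)
  rates <- seq(0.05, 0.95, by = 0.1)
  hs <- fit_threshold(rates, 0, 1)
  expect_true(all(diff(hs) < 0))            # strictly decreasing
  # round trip: sampling at the fitted threshold reproduces the rate
  dp <- dg_params(0.4, 2, 0.15, h = fit_threshold(0.07, 0.4, 2))
  r <- dg_sample(dp, 300, 4000, seed = 5)
  expect_lt(abs(mean(r) - 0.07), 4 * sd(r) / sqrt(4000))
})

test_that("survival curves start at one and never increase", {
  fr <- c(0, 0.01, 0.02, 0.02, 0.5, 0.9)
  sc <- survival_curve(fr)
  expect_equal(sc$survival[sc$r == 0], 1)
  expect_true(all(diff(sc$survival) <= 0))
  expect_equal(sc$survival[length(sc$survival)], 0)  # beyond the maximum
})

test_that("fit_dg anchors the model to trace and synchrony estimates", {
  set.seed(18)
  n_t <- 5000; n_n <- 100; sigma <- 2; alpha <- 0.2; mu <- 1
  eps <- rnorm(n_t)
  s <- mu + sigma * (sqrt(1 - alpha) * matrix(rnorm(n_t * n_n), n_t, n_n) +
                     sqrt(alpha) * eps)
  frac <- rowMeans(s >= 3)
  dp <- fit_dg(s, frac)
  expect_lt(abs(dp$sigma_s - sigma), 0.1)
  expect_lt(abs(dp$alpha - alpha), 0.05)
  expect_lt(abs(dp$h - 3), 0.15)
  expect_lt(abs(attr(dp, "mpc") - sigma^2 * alpha), 0.1)
})
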