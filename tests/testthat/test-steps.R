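p0 <- network_params()

test_that("external current reproduces the stimulus and background means", {
  p <- network_params(sigma_ext = 0)
  expect_equal(external_current("E", TRUE, p, noise_draw = 0), 0.65)
  expect_equal(external_current("E", FALSE, p, noise_draw = 0), 0.45)
  expect_equal(external_current("I", TRUE, p, noise_draw = 0), 0.45)
  # additive stimulus mode stacks stimulus on background
  pa <- network_params(sigma_ext = 0, stimulus_mode = "add")
  expect_equal(external_current("E", TRUE, pa, noise_draw = 0), 1.1)
  # empirical mean of many draws matches mu within 4 standard errors
  set.seed(11)
  z <- rnorm(1e5)
  draws <- external_current("E", FALSE, p0, dt = 0.1, noise_draw = z)
  se <- p0$sigma_ext * sqrt(1000 / 0.1) / sqrt(1e5)
  expect_lt(abs(mean(draws) - 0.45), 4 * se)
})

test_that("plasticity relaxation follows the closed-form exponentials", {
  d <- stp_decay(0, 1, dt = 123, params = p0)
  expect_equal(d, list(u = 0, x = 1))                       # fixed point
  expect_equal(stp_decay(0.5, 1, dt = p0$tau_f, p0)$u, 0.5 / exp(1))
  # x recovers monotonically toward 1 from depletion
  xs <- Reduce(function(x, .) stp_decay(0, x, 50, p0)$x, 1:60,
               accumulate = TRUE, init = 0)
  expect_true(all(diff(xs) > 0))
  expect_gt(xs[61], 0.94)
  expect_error(stp_decay(1.5, 0.5, 1, p0), "corrupted")
})

test_that("spike-triggered plasticity updates facilitate, transmit, then deplete", {
  s <- stp_on_spike(0, 1, U = 1, p0)
  expect_equal(s, list(u = 1, x = 0, transmitted = 1))      # saturating case
  s <- stp_on_spike(0, 1, U = 0.00525, p0)
  expect_equal(s$u, 0.00525)
  expect_equal(s$transmitted, 0.00525)
  expect_equal(s$x, 1 - 0.00525)
  # strict ODE convention scales the jumps by the time constants
  ps <- network_params(delta_convention = "jump-equals-coefficient-over-tau")
  s2 <- stp_on_spike(0, 1, U = 0.00525, ps)
  expect_equal(s2$u, 0.00525 / ps$tau_f)
  expect_equal(s2$x, 1 - s2$u / ps$tau_d)
})

test_that("adaptation current decays, tracks depolarization and jumps on spikes", {
  # pure exponential decay at rest
  i1 <- adaptation_step(2, p0$e_l, FALSE, dt = 0.5, p0)
  expect_equal(i1, 2 * (1 - 0.5 / p0$tau_a))
  # clamped depolarization: fixed point A_p * (V - E_L) = 0.1 * 10 = 1 uA
  i <- 0
  for (k in 1:20000) i <- adaptation_step(i, p0$e_l + 10, FALSE, 0.5, p0)
  expect_equal(i, 1.0, tolerance = 1e-6)
  # spike adds A_s = 1 uA instantaneously
  expect_equal(adaptation_step(0, p0$e_l, TRUE, 0.1, p0) -
               adaptation_step(0, p0$e_l, FALSE, 0.1, p0), 1.0)
})

test_that("recurrent currents decay exponentially and superpose drives linearly", {
  expect_equal(recurrent_current_step(3, 0, dt = p0$tau_s, p0), 3 / exp(1))
  # one E->E spike with transmitted fraction q jumps by J_EE * q
  q <- 0.0123
  expect_equal(recurrent_current_step(0, p0$j_ee * q, 0.1, p0) -
               recurrent_current_step(0, 0, 0.1, p0), p0$j_ee * q)
  # two simultaneous spikes = sum of individual jumps
  expect_equal(recurrent_current_step(1, 0.4 + 0.7, 0.1, p0),
               recurrent_current_step(1, 0, 0.1, p0) + 0.4 + 0.7)
})

test_that("membrane dynamics match the closed-form charging curve with O(dt) error", {
  expect_equal(membrane_step(p0$e_l, 0, 0, 0.1, p0, "E")$V, p0$e_l)
  analytic <- function(t, I) p0$e_l + p0$r_m * I * (1 - exp(-t / p0$tau_m))
  run_euler <- function(dt, I, t_end) {
    v <- p0$e_l
    ts <- seq(dt, t_end, by = dt)
    out <- numeric(length(ts))
    for (k in seq_along(ts)) {
      v <- membrane_step(v, I, 0, dt, p0, "E")$V
      out[k] <- v
    }
    max(abs(out - analytic(ts, I)))
  }
  e1 <- run_euler(0.2, 5, 60)   # subthreshold: 5 mV < 10 mV gap
  e2 <- run_euler(0.1, 5, 60)
  expect_gt(e1 / e2, 1.6)       # halving dt roughly halves the error
  expect_lt(e1 / e2, 2.6)
})

test_that("the rheobase separates spiking from silent constant drives", {
  run_const <- function(I) {
    v <- p0$e_l
    for (k in 1:5000) {
      st <- membrane_step(v, I, 0, 0.1, p0, "E")
      if (st$spiked) return(TRUE)
      v <- st$V
    }
    FALSE
  }
  expect_true(run_const(10.5))   # R_m * I = 10.5 mV > 10 mV gap
  expect_false(run_const(9.5))
})

test_that("a synchronous volley drives the read-out along the double-exponential response", {
  m <- 50; dt <- 0.01
  st <- list(V_O = p0$e_l, I_E = 0, I_I = 0)
  st <- readout_step(st, m, 0, dt, p0)$state   # volley enters the filter
  ts <- seq(dt, 60, by = dt)
  v <- numeric(length(ts))
  for (k in seq_along(ts)) {
    out <- readout_step(st, 0, 0, dt, p0)
    st <- out$state
    v[k] <- st$V_O
  }
  a <- 1 / p0$tau_s - 1 / p0$tau_o
  analytic <- p0$e_l + (p0$r_m * p0$j_eo * m / p0$tau_o) *
    (exp(-ts / p0$tau_s) - exp(-ts / p0$tau_o)) / (-a)
  expect_lt(max(abs(v - analytic)), 0.05)      # mV, O(dt) Euler error
  expect_lt(max(v), p0$v_th_e)                 # stays subthreshold
  # with no input the read-out relaxes monotonically to rest
  st <- list(V_O = -58, I_E = 0, I_I = 0)
  vs <- numeric(300)
  for (k in 1:300) { st <- readout_step(st, 0, 0, 1, p0)$state; vs[k] <- st$V_O }
  expect_true(all(diff(vs) < 0))
  expect_equal(vs[300], p0$e_l, tolerance = 1e-4)
})

test_that("balanced Poisson populations leave the read-out drive at zero mean", {
  # J_EO N_E r_E = J_IO N_I r_I when r_I = 2 r_E and N_E = 4 N_I
  set.seed(5)
  n_steps <- 10000; dt <- 1
  e_counts <- rpois(n_steps, p0$n_e * 5 / 1000 * dt)
  i_counts <- rpois(n_steps, p0$n_i * 10 / 1000 * dt)
  st <- list(V_O = p0$e_l, I_E = 0, I_I = 0)
  drv <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    out <- readout_step(st, e_counts[k], i_counts[k], dt, p0)
    st <- out$state
    drv[k] <- out$drive
  }
  drv <- drv[-(1:100)]
  tol <- 4 * sd(drv) * sqrt(2 * p0$tau_s / length(drv))
  expect_lt(abs(mean(drv)), tol)
})
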