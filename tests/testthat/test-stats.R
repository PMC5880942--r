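test_that("paired comparisons reproduce the textbook t statistic", {
  ct <- compare_periods(c(2, 3, 4), c(1, 1, 1))
  # differences (1,2,3): t = mean / (SD/sqrt(3)) = 2 sqrt(3)
  expect_equal(ct$statistic, 2 * sqrt(3), tolerance = 1e-7)
  expect_equal(ct$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(ct$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-10)
  expect_equal(round(ct$p, 4), 0.0742)
  # degenerate cases
  expect_equal(compare_periods(1:5, 1:5)$p, 1)
  expect_equal(compare_periods(2:6, 1:5)$p, 0)
  expect_error(compare_periods(1:2, 2:3), "at least 3")
  expect_error(compare_periods(1:4, 1:3), "equal length")
  # a 5-SD shift over 30 pairs is overwhelming
  set.seed(19)
  a <- rnorm(30) + 5
  expect_lt(compare_periods(a, rnorm(30))$p, 1e-6)
  # the rank-based alternative agrees qualitatively
  expect_lt(compare_periods(a, rnorm(30), method = "wilcoxon")$p, 1e-4)
})

test_that("read-out spike counts land in the right periods", {
  sp <- data.frame(neuron_id = 1,
                   class = c("readout", "readout", "readout", "E"),
                   t_ms = c(-500, 700, 1299.9, 600))
  expect_equal(readout_spike_counts(sp),
               c(`Pre-adp` = 1, Adp = 2, `Post-adp` = 0))
  empty <- data.frame(neuron_id = 1, class = "E", t_ms = 0)
  expect_equal(unname(readout_spike_counts(empty)), c(0, 0, 0))
})

test_that("adaptation timing finds rise and return on a constructed PSTH", {
  n_tr <- 30
  bins <- 250                 # 20-ms bins over [-2500, 2500)
  edges <- seq(-2500, 2480, by = 20)
  set.seed(20)
  base <- matrix(5 + rnorm(n_tr * bins, sd = 0.02), n_tr, bins)
  bump <- edges >= 0 & edges < 200
  base[, bump] <- base[, bump] + 3
  fake <- structure(list(psth_e = base, psth_e_bin = 20,
                         t_range = c(-2500, 2500)),
                    class = "experiment_result")
  at <- adaptation_timing(fake, window = 100)
  expect_equal(at$t_rise, 0)
  expect_equal(at$t_return, 200)
  expect_equal(at$adaptation_length, 200)
  at20 <- adaptation_timing(fake, window = 20)
  expect_equal(at20$t_return, 200)
  # a flat PSTH never leaves the band: return time 0, no rise
  flat <- structure(list(psth_e = matrix(5 + rnorm(n_tr * bins, sd = 0.02),
                                         n_tr, bins),
                         psth_e_bin = 20, t_range = c(-2500, 2500)),
                    class = "experiment_result")
  atf <- adaptation_timing(flat, window = 100)
  expect_equal(atf$t_return, 0)
  expect_true(is.na(atf$t_rise))
})

make_fake_result <- function(name, mpc_adp_shift = 0, n_trials = 12,
                             seed = 1) {
  set.seed(seed)
  periods <- c("Pre-adp", "Adp", "Post-adp")
  st <- expand.grid(trial = seq_len(n_trials), period = periods,
                    stringsAsFactors = FALSE)
  st$seed <- st$trial
  st$mpc <- rnorm(nrow(st), sd = 0.01)
  st$mpc[st$period == "Adp"] <- st$mpc[st$period == "Adp"] + mpc_adp_shift
  st$mpc_shuffled <- rnorm(nrow(st), sd = 0.01)
  st$sigma_s <- 17; st$mu_s <- 0
  st$ux <- 0.012; st$e_rate <- 7
  st$readout_count <- rpois(nrow(st), 1)
  cond <- condition(name)
  structure(list(stats = st, condition = cond, n_trials = n_trials,
                 periods = default_periods()),
            class = "experiment_result")
}

test_that("reports flag exactly the injected effects and enumerate all comparisons", {
  strong <- make_fake_result("default", mpc_adp_shift = 0.1)
  null_res <- make_fake_result("static", mpc_adp_shift = 0, seed = 2)
  rep <- build_report(list(strong, null_res))
  # default rows: correlation, ux, readout x 2 comparisons; static: correlation x 2
  expect_equal(sum(rep$condition == "default"), 6)
  expect_equal(sum(rep$condition == "static"), 2)
  cor_rows <- rep$statistic == "correlation"
  expect_true(all(rep$significant[cor_rows & rep$condition == "default"]))
  expect_false(any(rep$significant[cor_rows & rep$condition == "static"]))
  expect_true(all(rep$p >= 0 & rep$p <= 1))
  expect_equal(rep$significant, rep$p < 0.05)
  # identical periods everywhere -> nothing flagged
  flat <- make_fake_result("static", 0, seed = 3)
  flat$stats$mpc <- 0.5
  rep2 <- build_report(list(flat))
  expect_false(any(rep2$significant))
  expect_true(all(rep2$p == 1))
})

test_that("reports are a pure function of their inputs", {
  res <- make_fake_result("default", 0.05)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report_json(build_report(list(res)), f1)
  write_report_json(build_report(list(res)), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("spike TSV export uses the exchange layout", {
  p <- tiny_params()
  tr <- run_trial(p, seed = 2, record_s = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_spikes_tsv(tr, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("trial", "neuron_id", "class", "t_ms"))
  expect_equal(nrow(tab), nrow(tr$spikes))
  expect_true(all(tab$trial == 1))
  unlink(f)
})
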