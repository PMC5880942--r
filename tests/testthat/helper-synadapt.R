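# small configurations and shared fixtures for the test suite

tiny_params <- function(...) {
  network_params(n_e = 40, n_i = 10, t_total = 2000, ...)
}

# short analysis periods fitting inside a 2000 ms trial (stimulus onset 0)
tiny_periods <- function() {
  structure(list(`Pre-adp` = c(-800, -300), `Adp` = c(200, 700)),
            class = "period_set")
}

make_periods <- function(...) {
  structure(list(...), class = "period_set")
}

# lazily computed full-size condition batches shared across test files.
# base seeds are fixed so the whole suite is reproducible.
.batch_cache <- new.env(parent = emptyenv())

acc_batch <- function(name) {
  if (!is.null(.batch_cache[[name]])) return(.batch_cache[[name]])
  res <- switch(name,
    default10 = run_condition("default", 10, base_seed = 101L),
    default30 = run_condition("default", 30, base_seed = 201L),
    static30 = run_condition("static", 30, base_seed = 201L),
    transient30 = run_condition("transient", 30, base_seed = 201L),
    variant_slow = run_condition(condition("stp_variant", 1), 30,
                                 base_seed = 201L),
    variant_mid = run_condition(condition("stp_variant", 2), 30,
                                base_seed = 201L),
    variant_fast = run_condition(condition("stp_variant", 3), 30,
                                 base_seed = 201L),
    stop("unknown batch: ", name))
  .batch_cache[[name]] <- res
  res
}

# mid-size default batch for plasticity-trace tests (500 E neurons keep the
# ux estimator precise at a fraction of the full-network cost)
mid_batch <- function() {
  if (is.null(.batch_cache$mid)) {
    p <- network_params(n_e = 500, n_i = 125)
    .batch_cache$mid <- run_condition("default", 10, base_seed = 301L,
                                      params = p)
  }
  .batch_cache$mid
}
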