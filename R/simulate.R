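#' Run one seeded trial of the network
#'
#' Integrates the sensory network and the read-out neuron over one trial.
#' Time runs from `-t_total/2` to `+t_total/2` ms (5000 ms by default), with
#' stimulus onset at t = 0: the first half of the trial is a warm-up under
#' background input during which the network relaxes into its stochastic
#' stationary state, so the response to the stimulus does not depend on the
#' (deterministic) initial state `V = E_L`, `u = 0`, `x = 1`.
#'
#' Seeding uses two child streams derived from `seed`: the connectivity
#' graph is drawn from R's RNG with `set.seed(seed)` (the caller's RNG state
#' is restored afterwards) and the membrane noise comes from the simulator's
#' internal Gaussian stream seeded with `seed + 1000003`. Conditions that
#' share a `seed` therefore share both the topology and the external-noise
#' realization, which makes control conditions pairable trial by trial. Two
#' calls with identical `(params, seed)` return bit-identical recordings.
#'
#' @param params a [network_params()] object.
#' @param stimulus_window numeric `c(on, off)` in ms; default `c(0, 1500)`.
#' @param seed integer master seed for the trial.
#' @param graph optional pre-built [build_connectivity()] graph; by default
#'   it is drawn from the trial's connectivity stream.
#' @param static_synapses logical; if `TRUE` every E-to-E spike transmits
#'   the constant efficacy `j_s` instead of `j_ee * u * x`, and the
#'   plasticity state is not meaningful (the `ux` trace is set to `NA`).
#' @param record_s logical; record the per-excitatory-neuron input current
#'   `s_i = I_syn,i - I_adp,i`? (~40 MB per default-size trial; required for
#'   the correlation analysis.)
#' @param noise optional `(n_steps x (n_e + n_i))` matrix of standard normal
#'   draws, used by the verification tests to drive the compiled and the
#'   pure-R integrator with identical noise.
#'
#' @return an object of class `trial_recording`:
#' \describe{
#'   \item{spikes}{data.frame `neuron_id`, `class` (`"E"`, `"I"`,
#'     `"readout"`), `t_ms`, sorted by time.}
#'   \item{s}{matrix (time frames x `n_e`) of input currents `s_i`, averaged
#'     over `trace_dt` frames (uA), or `NULL` if `record_s = FALSE`.}
#'   \item{ux}{population mean of `u * x` over excitatory neurons per frame.}
#'   \item{vo}{read-out membrane potential per frame (mV).}
#'   \item{drive}{balanced read-out drive `R_m (J_EO I_E - J_IO I_I)` per
#'     frame (mV).}
#'   \item{time}{frame midpoints (ms, stimulus onset at 0).}
#'   \item{seed, params, stimulus_window, graph_seed}{provenance.}
#' }
#' @examples
#' p <- network_params(n_e = 40, n_i = 10, t_total = 400)
#' tr <- run_trial(p, seed = 1)
#' head(tr$spikes)
#' @export
run_trial <- function(params, stimulus_window = c(0, 1500), seed,
                      graph = NULL, static_synapses = FALSE,
                      record_s = TRUE, noise = NULL) {
  stopifnot(inherits(params, "network_params"))
  params <- validate_params(params)
  if (length(stimulus_window) != 2 || stimulus_window[2] < stimulus_window[1])
    stop("stimulus_window must be c(on, off) with off >= on")
  seed <- as.integer(seed)
  r <- params$trace_dt / params$dt
  if (abs(r - round(r)) > 1e-8)
    stop("configuration error: dt must divide the trace sampling interval")

  if (is.null(graph)) {
    graph <- build_connectivity(params$n_e, params$n_i, params$p, seed = seed)
  } else {
    stopifnot(inherits(graph, "connectivity_graph"))
    if (graph$n_e != params$n_e || graph$n_i != params$n_i)
      stop("graph size does not match params")
  }

  t_start <- -params$t_total / 2
  t_end <- params$t_total / 2

  raw <- .sim_network_cpp(unclass(params),
                          graph$ee$ptr, graph$ee$idx,
                          graph$ei$ptr, graph$ei$idx,
                          graph$ie$ptr, graph$ie$idx,
                          t_start, t_end,
                          stimulus_window[1], stimulus_window[2],
                          noise, seed + 1000003L, static_synapses, record_s)

  cls <- c("E", "I", "readout")[raw$spike_class + 1L]
  spikes <- data.frame(neuron_id = raw$spike_id, class = cls,
                       t_ms = raw$spike_t, stringsAsFactors = FALSE)

  structure(list(
    spikes = spikes,
    s = if (record_s) raw$s else NULL,
    ux = if (static_synapses) rep(NA_real_, length(raw$ux)) else raw$ux,
    vo = raw$vo,
    drive = raw$drive,
    time = raw$time,
    seed = seed,
    graph_seed = graph$seed,
    stimulus_window = stimulus_window,
    static_synapses = static_synapses,
    params = params), class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  n_sp <- table(factor(x$spikes$class, levels = c("E", "I", "readout")))
  cat("<trial_recording> seed", x$seed, "\n")
  cat(sprintf("  t in [%g, %g] ms, stimulus [%g, %g) ms%s\n",
              min(x$time) - x$params$trace_dt / 2,
              max(x$time) + x$params$trace_dt / 2,
              x$stimulus_window[1], x$stimulus_window[2],
              if (x$static_synapses) ", static synapses" else ""))
  cat(sprintf("  spikes: %d E, %d I, %d read-out\n",
              n_sp[["E"]], n_sp[["I"]], n_sp[["readout"]]))
  invisible(x)
}

#' Pure-R reference integrator
#'
#' A direct (slow) R transcription of the compiled simulator, stepping the
#' same update order with the same conventions. Intended for small networks
#' and short horizons only; used to verify the compiled path on identical
#' noise.
#'
#' @inheritParams run_trial
#' @param graph a [build_connectivity()] graph.
#' @param noise `(n_steps x (n_e + n_i))` matrix of standard normal draws.
#' @return a list with `s`, `ux`, `vo`, `drive`, `time` traces and a
#'   `spikes` data.frame, in the layout of [run_trial()].
#' @keywords internal
#' @export
run_trial_reference <- function(params, stimulus_window, graph, noise,
                                static_synapses = FALSE) {
  p <- validate_params(params)
  n_e <- p$n_e; n_i <- p$n_i; n <- n_e + n_i
  dt <- p$dt
  t_start <- -p$t_total / 2; t_end <- p$t_total / 2
  n_steps <- round((t_end - t_start) / dt)
  stopifnot(nrow(noise) == n_steps, ncol(noise) == n)
  frame_len <- round(p$trace_dt / dt)
  n_frames <- n_steps %/% frame_len

  tgt_ee <- split_targets(graph$ee, n_e)
  tgt_ei <- split_targets(graph$ei, n_e)
  tgt_ie <- split_targets(graph$ie, n_i)

  V <- rep(p$e_l, n); I_rec <- numeric(n)
  I_adp <- numeric(n_e); u <- numeric(n_e); x <- rep(1, n_e)
  ro <- list(V_O = p$e_l, I_E = 0, I_I = 0)
  rec_jump <- delta_scale(p, p$tau_s)

  s_tr <- matrix(0, n_frames, n_e); ux_tr <- vo_tr <- dr_tr <- tm <- numeric(n_frames)
  s_acc <- numeric(n_e); ux_acc <- vo_acc <- dr_acc <- 0
  sp_t <- sp_id <- sp_cl <- list()

  for (step in seq_len(n_steps)) {
    t0 <- t_start + (step - 1) * dt
    in_stim <- t0 >= stimulus_window[1] && t0 < stimulus_window[2]
    z <- noise[step, ]
    i_ext <- c(external_current("E", in_stim, p, dt, z[seq_len(n_e)]),
               external_current("I", FALSE, p, dt, z[n_e + seq_len(n_i)]))
    i_syn <- i_ext + I_rec
    s_now <- i_syn[seq_len(n_e)] - I_adp

    v_old <- V
    me <- membrane_step(v_old[seq_len(n_e)], i_syn[seq_len(n_e)], I_adp,
                        dt, p, "E")
    mi <- membrane_step(v_old[n_e + seq_len(n_i)], i_syn[n_e + seq_len(n_i)],
                        0, dt, p, "I")
    I_adp <- I_adp + dt / p$tau_a *
      (-I_adp + p$a_p * (v_old[seq_len(n_e)] - p$e_l))
    V <- c(me$V, mi$V)

    dec <- stp_decay(u, x, dt, p)
    u <- dec$u; x <- dec$x

    buf <- numeric(n)
    e_sp <- which(me$spiked); i_sp <- which(mi$spiked)
    I_adp[e_sp] <- I_adp[e_sp] + p$a_s * delta_scale(p, p$tau_a)
    for (i in e_sp) {
      if (static_synapses) {
        q_drive <- p$j_s
      } else {
        sp <- stp_on_spike(u[i], x[i], p$U, p)
        u[i] <- sp$u; x[i] <- sp$x
        q_drive <- p$j_ee * sp$transmitted
      }
      for (j in tgt_ee[[i]]) buf[j] <- buf[j] + q_drive
      for (j in tgt_ei[[i]]) buf[n_e + j] <- buf[n_e + j] + p$j_ei
    }
    for (i in i_sp)
      for (j in tgt_ie[[i]]) buf[j] <- buf[j] - p$j_ie
    I_rec <- I_rec * exp(-dt / p$tau_s) + rec_jump * buf

    rs <- readout_step(ro, length(e_sp), length(i_sp), dt, p)
    ro <- rs$state

    t_spk <- t0 + dt
    ids <- c(e_sp, i_sp, if (rs$spiked) 1L)
    if (length(ids)) {
      sp_t[[length(sp_t) + 1]] <- rep(t_spk, length(ids))
      sp_id[[length(sp_id) + 1]] <- ids
      sp_cl[[length(sp_cl) + 1]] <- c(rep("E", length(e_sp)),
                                      rep("I", length(i_sp)),
                                      if (rs$spiked) "readout")
    }

    s_acc <- s_acc + s_now
    ux_acc <- ux_acc + mean(u * x)
    vo_acc <- vo_acc + ro$V_O
    dr_acc <- dr_acc + rs$drive
    if (step %% frame_len == 0) {
      fr <- step %/% frame_len
      tm[fr] <- t0 + dt - p$trace_dt / 2
      s_tr[fr, ] <- s_acc / frame_len
      ux_tr[fr] <- ux_acc / frame_len
      vo_tr[fr] <- vo_acc / frame_len
      dr_tr[fr] <- dr_acc / frame_len
      s_acc <- numeric(n_e); ux_acc <- vo_acc <- dr_acc <- 0
    }
  }

  list(spikes = data.frame(
         neuron_id = unlist(sp_id) %||% integer(0),
         class = unlist(sp_cl) %||% character(0),
         t_ms = unlist(sp_t) %||% numeric(0), stringsAsFactors = FALSE),
       s = s_tr, ux = ux_tr, vo = vo_tr, drive = dr_tr, time = tm)
}

# adjacency list (targets per source) from a CSR class
split_targets <- function(csr, n_src) {
  lapply(seq_len(n_src), function(s) {
    if (csr$ptr[s + 1] > csr$ptr[s])
      csr$idx[(csr$ptr[s] + 1):csr$ptr[s + 1]]
    else integer(0)
  })
}
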