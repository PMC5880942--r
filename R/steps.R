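#' Single-step state updates of the network model
#'
#' These functions expose one Euler step (or one spike event) of every state
#' variable of the model, exactly as the compiled simulator applies them.
#' They are vectorized over neurons and are used both directly (unit
#' analysis, tests) and as the reference implementation against which the
#' compiled path is verified.
#'
#' Between spikes every auxiliary variable relaxes exponentially and the
#' relaxation is applied with exact exponential factors (unconditionally
#' stable); only the membrane potential uses a plain Euler update.
#'
#' @name step_functions
NULL

#' @describeIn step_functions external current `mu + sigma_ext * eta` for one
#'   step; `mu` is `mu_ext` for an excitatory neuron inside the stimulus
#'   window (under `stimulus_mode = "replace"`) and `mu_b` otherwise.
#' @param class `"E"` or `"I"`.
#' @param in_stimulus logical; is the time inside the stimulus window?
#' @param params a [network_params()] object.
#' @param dt step length (ms).
#' @param noise_draw standard normal draw(s).
#' @export
external_current <- function(class = c("E", "I"), in_stimulus, params,
                             dt = params$dt, noise_draw = 0) {
  class <- match.arg(class)
  if (dt <= 0) stop("dt must be > 0")
  stim <- class == "E" & in_stimulus
  mu <- ifelse(stim,
               if (params$stimulus_mode == "add") params$mu_b + params$mu_ext
               else params$mu_ext,
               params$mu_b)
  scale <- if (params$noise_delta_unit == "s") sqrt(1000 / dt) else sqrt(1 / dt)
  mu + params$sigma_ext * scale * noise_draw
}

#' @describeIn step_functions exact exponential relaxation of the
#'   facilitation variable `u` (toward 0, time constant `tau_f`) and the
#'   depression variable `x` (toward 1, time constant `tau_d`) over `dt` ms
#'   with no intervening spike.
#' @param u,x release probability and available fraction, each in \[0, 1\].
#' @export
stp_decay <- function(u, x, dt, params) {
  if (any(u < 0 | u > 1 | x < 0 | x > 1))
    stop("corrupted STP state: u and x must lie in [0, 1]")
  list(u = u * exp(-dt / params$tau_f),
       x = 1 - (1 - x) * exp(-dt / params$tau_d))
}

#' @describeIn step_functions spike-triggered synapse update: facilitation is
#'   applied first (`u' = u + U(1-u)`), the transmitted fraction is `u' * x`,
#'   and depression follows (`x' = x(1 - u')`). Under the strict ODE
#'   convention the jump coefficients are divided by their time constants.
#' @param U facilitation increment (defaults to `params$U`).
#' @return `stp_on_spike()` returns `list(u, x, transmitted)`.
#' @export
stp_on_spike <- function(u, x, U = params$U, params = network_params()) {
  stopifnot(all(u >= 0 & u <= 1), all(x >= 0 & x <= 1),
            all(U >= 0 & U <= 1))
  u_jump <- if (params$delta_convention == "jump-equals-coefficient")
    U else U / params$tau_f
  u_new <- u + u_jump * (1 - u)
  q <- u_new * x
  x_rel <- if (params$delta_convention == "jump-equals-coefficient")
    1 else 1 / params$tau_d
  list(u = u_new, x = x - x_rel * q, transmitted = q)
}

#' @describeIn step_functions Euler relaxation of the adaptation current of
#'   an excitatory neuron, `I_adp <- I_adp + (dt/tau_a)(-I_adp + A_p (V - E_L))`,
#'   plus the spike-triggered jump `A_s` where `spiked` is `TRUE`.
#' @param I_adp adaptation current (uA).
#' @param V membrane potential (mV) at the start of the step.
#' @param spiked logical; did the neuron spike this step?
#' @export
adaptation_step <- function(I_adp, V, spiked, dt, params) {
  out <- I_adp + dt / params$tau_a * (-I_adp + params$a_p * (V - params$e_l))
  jump <- params$a_s * delta_scale(params, params$tau_a)
  out + ifelse(spiked, jump, 0)
}

#' @describeIn step_functions recurrent current update: exact exponential
#'   decay (time constant `tau_s`) plus the summed weighted drive of this
#'   step's presynaptic spikes (`J_EE * transmitted` per E-to-E spike,
#'   `J_EI` per E-to-I spike, `-J_IE` per I-to-E spike; linear superposition
#'   over simultaneous spikes).
#' @param I_rec recurrent current (uA).
#' @param incoming_drive summed weighted drive arriving this step (uA).
#' @export
recurrent_current_step <- function(I_rec, incoming_drive = 0, dt, params) {
  I_rec * exp(-dt / params$tau_s) +
    delta_scale(params, params$tau_s) * incoming_drive
}

#' @describeIn step_functions leaky integrate-and-fire membrane update with
#'   threshold test after the Euler step; a spiking neuron is reset to
#'   `E_L`. There is no refractory period. `I_adp` must be 0 for inhibitory
#'   neurons.
#' @param I_syn synaptic current `I_ext + I_rec` (uA).
#' @return `membrane_step()` returns `list(V, spiked)`.
#' @export
membrane_step <- function(V, I_syn, I_adp = 0, dt, params,
                          class = c("E", "I")) {
  class <- match.arg(class)
  v_th <- if (class == "E") params$v_th_e else params$v_th_i
  v_new <- V + dt / params$tau_m *
    (-(V - params$e_l) + params$r_m * (I_syn - I_adp))
  if (any(!is.finite(v_new)))
    stop("membrane potential diverged in membrane_step()")
  spiked <- v_new >= v_th
  v_new[spiked] <- params$e_l
  list(V = v_new, spiked = spiked)
}

#' @describeIn step_functions read-out neuron update. The excitatory and
#'   inhibitory population spike counts drive exponentially filtered traces
#'   `I_E`, `I_I` (time constant `tau_s`, unit jump per spike); the membrane
#'   follows `tau_o dV_O/dt = -(V_O - E_L) + R_m (J_EO I_E - J_IO I_I)` with
#'   threshold `v_th_e` and reset to `E_L`. The membrane update uses the
#'   start-of-step filter values; this step's spikes enter the filters
#'   afterwards.
#' @param state `list(V_O, I_E, I_I)`.
#' @param e_spikes,i_spikes numbers of sensory E and I spikes this step.
#' @return `readout_step()` returns `list(state, spiked, drive)`.
#' @export
readout_step <- function(state, e_spikes, i_spikes, dt, params) {
  drive <- params$r_m * (params$j_eo * state$I_E - params$j_io * state$I_I)
  v_new <- state$V_O + dt / params$tau_o * (-(state$V_O - params$e_l) + drive)
  es <- exp(-dt / params$tau_s)
  if (params$readout_drive == "filtered") {
    I_E <- state$I_E * es + e_spikes
    I_I <- state$I_I * es + i_spikes
  } else {
    I_E <- state$I_E * es
    I_I <- state$I_I * es
    v_new <- v_new + params$r_m * (params$j_eo * e_spikes -
                                   params$j_io * i_spikes)
  }
  spiked <- v_new >= params$v_th_e
  if (spiked) v_new <- params$e_l
  list(state = list(V_O = v_new, I_E = I_E, I_I = I_I),
       spiked = spiked, drive = drive)
}
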