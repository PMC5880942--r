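#' Network and integration parameters
#'
#' Builds the full parameter set of the sensory network, the read-out neuron
#' and the integrator. Internal units are mV, ms, uA and kOhm throughout, so
#' that `R_m * I` is in mV. The two inhibitory coupling strengths are commonly
#' quoted in nA; they are stored converted to uA (`j_ei = 0.005`,
#' `j_ie = 0.004`).
#'
#' Defaults describe a sparse random network of `n_e = 2000` excitatory and
#' `n_i = 500` inhibitory leaky integrate-and-fire neurons (connection
#' probability `p = 0.1`). Excitatory neurons carry a spike-frequency
#' adaptation current (subthreshold gain `a_p`, per-spike jump `a_s`, time
#' constant `tau_a`) and their outgoing synapses are subject to
#' Tsodyks-Markram short-term plasticity with facilitation increment `U`,
#' facilitation time constant `tau_f` and depression time constant `tau_d`.
#' All sensory neurons project to one downstream read-out neuron with
#' weights `j_eo` (excitatory) and `j_io` (inhibitory), chosen so that the
#' mean drive to the read-out cancels when inhibitory neurons fire at twice
#' the excitatory rate.
#'
#' @param ... named overrides of any default listed below.
#'
#' @section Fields:
#' \describe{
#'   \item{v_th_e, v_th_i, e_l}{spike thresholds (E: -55 mV, I: -57 mV) and
#'     resting/reset potential (-65 mV).}
#'   \item{tau_m, tau_a, tau_s, tau_f, tau_d, tau_o}{membrane, adaptation,
#'     synaptic-current, facilitation, depression and read-out membrane time
#'     constants (ms).}
#'   \item{r_m}{membrane resistance (kOhm), shared by all neurons.}
#'   \item{a_s, a_p}{spike-triggered adaptation jump (uA) and subthreshold
#'     adaptation gain (1/kOhm).}
#'   \item{j_ee, j_ei, j_ie, j_s, j_eo, j_io}{synaptic efficacies (uA). The
#'     instantaneous E-to-E efficacy is `j_ee * u * x`; `j_s` is the constant
#'     E-to-E efficacy of the static-synapse model.}
#'   \item{U}{facilitation increment of the release probability per
#'     presynaptic spike (dimensionless, in \[0, 1\]).}
#'   \item{n_e, n_i, p}{population sizes and connection probability.}
#'   \item{mu_ext, mu_b, sigma_ext}{mean stimulus drive, mean background
#'     drive, and white-noise SD of the external current (uA).}
#'   \item{t_total, t_f, t_w}{trial length (ms), population-rate window (ms)
#'     and synchrony bin (ms).}
#'   \item{dt, trace_dt}{Euler step and trace sampling interval (ms);
#'     `trace_dt` must be an integer multiple of `dt`.}
#'   \item{delta_convention}{how the delta terms of the state equations are
#'     realized: `"jump-equals-coefficient"` (standard Tsodyks-Markram
#'     bookkeeping; per-spike jumps equal the equation coefficients) or
#'     `"jump-equals-coefficient-over-tau"` (strict ODE reading; jumps are
#'     divided by the corresponding time constant).}
#'   \item{noise_delta_unit}{time unit of the white-noise delta correlation:
#'     `"s"` (default; per-step SD `sigma_ext * sqrt(1000 / dt)`) or `"ms"`
#'     (per-step SD `sigma_ext / sqrt(dt)`). See the methods vignette for why
#'     the per-second normalization is the default.}
#'   \item{stimulus_mode}{`"replace"` (stimulus mean replaces the background
#'     mean for excitatory neurons inside the window) or `"add"`.}
#'   \item{readout_drive}{`"filtered"` (population spike counts filtered with
#'     time constant `tau_s`, unit jump per spike) or `"raw"` (per-spike
#'     voltage kicks `r_m * j_eo` / `-r_m * j_io` on the read-out membrane).}
#' }
#'
#' @return an object of class `network_params` (a validated named list).
#' @examples
#' p <- network_params()
#' p$j_ei                      # 5 nA stored as uA
#' network_params(tau_f = 50, U = 0.02)$tau_f
#' @export
network_params <- function(...) {
  defaults <- list(
    # single-neuron
    v_th_e = -55, v_th_i = -57, e_l = -65,
    tau_m = 20, tau_a = 250, a_s = 1.0, a_p = 0.1, tau_o = 20, r_m = 1.0,
    # synaptic
    j_ee = 6, j_ei = 5e-3, j_ie = 4e-3, tau_s = 5,
    U = 0.00525, tau_f = 400, tau_d = 1000, j_s = 0.129,
    # network / protocol
    t_total = 5000, t_f = 100, t_w = 5, p = 0.1, n_e = 2000, n_i = 500,
    mu_ext = 0.65, mu_b = 0.45, sigma_ext = 1.2, j_eo = 1, j_io = 2,
    # integration & conventions
    dt = 0.1, trace_dt = 1,
    delta_convention = "jump-equals-coefficient",
    noise_delta_unit = "s",
    stimulus_mode = "replace",
    readout_drive = "filtered"
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all overrides must be named")
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    defaults[names(over)] <- over
  }
  validate_params(structure(defaults, class = "network_params"))
}

#' @rdname network_params
#' @param params an object to validate.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "network_params"))
  num_pos <- c("tau_m", "tau_a", "tau_s", "tau_f", "tau_d", "tau_o",
               "r_m", "dt", "trace_dt", "t_total", "t_f", "t_w")
  for (f in num_pos)
    if (!is.numeric(params[[f]]) || length(params[[f]]) != 1 ||
        !is.finite(params[[f]]) || params[[f]] <= 0)
      stop("parameter '", f, "' must be a positive finite scalar")
  if (params$p < 0 || params$p > 1) stop("p must lie in [0, 1]")
  if (params$U < 0 || params$U > 1) stop("U must lie in [0, 1]")
  if (params$n_e < 0 || params$n_i < 0) stop("population sizes must be >= 0")
  if (params$n_e != round(params$n_e) || params$n_i != round(params$n_i))
    stop("population sizes must be integers")
  if (params$sigma_ext < 0) stop("sigma_ext must be >= 0")
  if (params$dt > params$tau_s / 10)
    warning("dt = ", params$dt, " ms is coarse relative to tau_s = ",
            params$tau_s, " ms; expect visible integration error")
  r <- params$trace_dt / params$dt
  if (abs(r - round(r)) > 1e-8)
    stop("trace_dt must be an integer multiple of dt")
  params$delta_convention <- match.arg(params$delta_convention,
    c("jump-equals-coefficient", "jump-equals-coefficient-over-tau"))
  params$noise_delta_unit <- match.arg(params$noise_delta_unit, c("s", "ms"))
  params$stimulus_mode <- match.arg(params$stimulus_mode, c("replace", "add"))
  params$readout_drive <- match.arg(params$readout_drive, c("filtered", "raw"))
  params
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params>\n")
  cat(sprintf("  %d E + %d I neurons, p = %g, dt = %g ms\n",
              x$n_e, x$n_i, x$p, x$dt))
  cat(sprintf("  STP: U = %g, tau_f = %g ms, tau_d = %g ms (%s)\n",
              x$U, x$tau_f, x$tau_d, x$delta_convention))
  cat(sprintf("  adaptation: tau_a = %g ms, A_s = %g uA, A_p = %g /kOhm\n",
              x$tau_a, x$a_s, x$a_p))
  cat(sprintf("  drive: mu_ext = %g, mu_b = %g, sigma_ext = %g uA (noise delta per %s)\n",
              x$mu_ext, x$mu_b, x$sigma_ext, x$noise_delta_unit))
  invisible(x)
}

# per-spike jump scaling for the delta terms (1 under the standard
# Tsodyks-Markram convention, 1/tau under the strict ODE reading)
delta_scale <- function(params, tau) {
  if (params$delta_convention == "jump-equals-coefficient") 1 else 1 / tau
}

# per-step standard normal multiplier realizing the white-noise correlation
noise_scale <- function(params) {
  if (params$noise_delta_unit == "s") sqrt(1000 / params$dt)
  else sqrt(1 / params$dt)
}

#' Read or write a parameter configuration file
#'
#' Configurations are flat YAML or JSON documents whose keys match the field
#' names of [network_params()]. For convenience the inhibitory couplings may
#' be given in nA via the keys `j_ei_nA` / `j_ie_nA`; they are converted to
#' uA on load.
#'
#' @param path file path; format is chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_params()` returns a `network_params` object;
#'   `write_params()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_params(network_params(tau_f = 50), f)
#' read_params(f)$tau_f
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext))
  if (!is.null(raw$j_ei_nA)) { raw$j_ei <- raw$j_ei_nA / 1000; raw$j_ei_nA <- NULL }
  if (!is.null(raw$j_ie_nA)) { raw$j_ie <- raw$j_ie_nA / 1000; raw$j_ie_nA <- NULL }
  do.call(network_params, raw)
}

#' @rdname read_params
#' @param params a `network_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "network_params"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config extension: ", ext))
  invisible(path)
}
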