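# Cell-model registry.
#
# A cell model is a named ODE system dV/dt = -(sum of ionic currents +
# I_stim)/C_m plus Hodgkin-Huxley gate equations.  The registry maps channel
# identifiers to the parameter holding that current's maximal conductance, so
# drug block becomes a multiplicative conductance scaling.

.model_registry <- new.env(parent = emptyenv())

# --- six-current demonstration model ---------------------------------------
# A compact 9-state ventricular-like cell: V plus 8 gates.  Fixed Nernst
# potentials, no intracellular ion dynamics.  Gate steady states are
# Boltzmann sigmoids 1/(1 + exp(-(V - Vhalf)/k)); a negative k makes the gate
# an inactivation gate.  All constants below are the frozen, tuned values;
# regression tests pin the resulting AP morphology.
.sixcurrent_parameters <- function() {
  c(
    # maximal conductances (mS/uF)
    g_Na = 11, g_CaL = 0.12, g_Kr = 0.042, g_Ks = 0.012, g_K1 = 0.5,
    g_to = 0.12,
    # reversal potentials (mV) and membrane capacitance (uF/cm^2, normalised)
    E_Na = 65, E_Ca = 60, E_K = -88, C_m = 1,
    # I_Na activation m (fast) and inactivation h
    m_Vhalf = -33, m_k = 5.5, m_tau = 0.15,
    h_Vhalf = -67, h_k = -5.5,
    h_tau_base = 0.35, h_tau_amp = 12, h_tau_Vmid = -60, h_tau_k = 6,
    # I_CaL activation d and inactivation f
    d_Vhalf = -10, d_k = 6.5, d_tau = 1.8,
    f_Vhalf = -28, f_k = -6, f_tau = 200,
    # I_Kr activation x_r (delayed)
    xr_Vhalf = -21, xr_k = 7, xr_tau = 180,
    # I_Ks activation x_s (slow, squared)
    xs_Vhalf = -5, xs_k = 13, xs_tau = 500,
    # I_to activation r and inactivation s
    r_Vhalf = 8, r_k = 9, r_tau = 3.5,
    s_Vhalf = -42, s_k = -5, s_tau = 25,
    # instantaneous I_K1 rectification gate
    k1_Vhalf = -72, k1_k = -9
  )
}

# resting state, frozen from the unstimulated equilibrium of the tuned model
# (1-D root of the summed steady-state currents; gates at their V-infinity).
.sixcurrent_initial_state <- function() {
  c(V = -87.99974488, m = 4.539997448e-05, h = 0.9785035252,
    d = 6.144415762e-06, f = 0.9999546002, xr = 6.968943588e-05,
    xs = 0.001684508097, r = 2.330921856e-05, s = 0.9998989657)
}

.sixcurrent_definition <- function(name, ito_is_total) {
  structure(list(
    name = name,
    native = "sixcurrent",
    state_names = c("V", "m", "h", "d", "f", "xr", "xs", "r", "s"),
    state_units = c("mV", rep("dimensionless", 8)),
    default_initial_state = .sixcurrent_initial_state(),
    default_parameters = .sixcurrent_parameters(),
    conductance_keys = c(IKr = "g_Kr", ICaL = "g_CaL", INa = "g_Na",
                         IKs = "g_Ks", IK1 = "g_K1", Ito = "g_to"),
    ito_is_total = ito_is_total,
    # square pulse; amplitude in uA/uF, 1.5x the measured threshold
    stimulus_defaults = list(amplitude = 40, duration = 2, offset = 10)
  ), class = "ap_cell_model")
}

.register_builtin_models <- function() {
  assign("sixcurrent_demo",
         function() .sixcurrent_definition("sixcurrent_demo", FALSE),
         envir = .model_registry)
  # same equations, flagged as carrying a single total I_to conductance, so
  # an Ito screen is applied to the total current
  assign("sixcurrent_demo_totalito",
         function() .sixcurrent_definition("sixcurrent_demo_totalito", TRUE),
         envir = .model_registry)
}

#' List available cell models
#'
#' @return Character vector of registered model names.
#' @export
list_models <- function() {
  sort(ls(.model_registry))
}

#' Retrieve a cell model by name
#'
#' Returns a fresh definition with pristine default parameters; repeated calls
#' never share state.
#'
#' @param name Model name; see [list_models()].
#' @return An object of class \code{ap_cell_model}: state layout, default
#'   initial state and parameters, the channel-to-conductance mapping, and
#'   stimulus defaults.
#' @export
#' @examples
#' m <- get_model("sixcurrent_demo")
#' m$conductance_keys
get_model <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    stop("model name must be a single string", call. = FALSE)
  if (!exists(name, envir = .model_registry, inherits = FALSE))
    stop("unknown model '", name, "'; available models: ",
         paste(list_models(), collapse = ", "), call. = FALSE)
  get(name, envir = .model_registry)()
}

#' @export
print.ap_cell_model <- function(x, ...) {
  cat("Cell model:", x$name, "\n")
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  cat("  blockable channels:",
      paste(names(x$conductance_keys), collapse = ", "), "\n")
  if (isTRUE(x$ito_is_total))
    cat("  (Ito block applied to the total I_to conductance)\n")
  invisible(x)
}

#' Apply conductance block to model parameters
#'
#' Multiplies each mapped channel's maximal conductance by its fraction
#' remaining.  Channels the model cannot represent (absent from
#' \code{conductance_keys}) with a factor other than 1 are reported with a
#' warning rather than silently dropped.  For a model carrying only a total
#' transient-outward current, the \code{Ito} factor scales that total
#' conductance.
#'
#' @param model An [get_model()] definition.
#' @param params Named parameter vector (defaults:
#'   \code{model$default_parameters}).
#' @param factors A [block_factors()] vector.
#' @return A modified copy of \code{params}; the input is not changed.
#' @export
#' @examples
#' m <- get_model("sixcurrent_demo")
#' f <- block_factors(compound_spec("x", channel_block("hERG", pic50 = 6)), 1)
#' apply_block(m, m$default_parameters, f)[["g_Kr"]]
apply_block <- function(model, params = model$default_parameters, factors) {
  stopifnot(inherits(model, "ap_cell_model"))
  if (!inherits(factors, "ap_block_factors"))
    stop("factors must come from block_factors()", call. = FALSE)
  if (any(unclass(factors) < 0 | unclass(factors) > 1))
    stop("block factors must lie in [0, 1]", call. = FALSE)
  out <- params
  unmapped <- character(0)
  for (ch in channel_ids()) {
    key <- if (ch %in% names(model$conductance_keys))
      model$conductance_keys[[ch]] else NA_character_
    if (is.na(key)) {
      if (factors[[ch]] != 1) unmapped <- c(unmapped, ch)
      next
    }
    out[[key]] <- out[[key]] * factors[[ch]]
  }
  if (length(unmapped) > 0L)
    warning("model '", model$name, "' has no conductance for channel(s) ",
            paste(unmapped, collapse = ", "),
            "; the requested block was not applied", call. = FALSE)
  out
}

#' Evaluate a model's right-hand side
#'
#' Computes the state derivatives at one time point, including the stimulus
#' term (a positive stimulus amplitude depolarises the cell).
#'
#' @param model An [get_model()] definition.
#' @param t Time in ms.
#' @param state Numeric state vector (first entry is V in mV).
#' @param params Named parameter vector.
#' @param stim Stimulus amplitude in uA/uF (0 when unstimulated).
#' @return Numeric vector of derivatives, same length as \code{state}.
#' @export
evaluate_rhs <- function(model, t, state, params = model$default_parameters,
                         stim = 0) {
  stopifnot(inherits(model, "ap_cell_model"))
  state <- as.numeric(state)
  bad <- which(!is.finite(state))
  if (length(bad) > 0L)
    stop("non-finite state value at index ", bad[1],
         " (", model$state_names[bad[1]], ")", call. = FALSE)
  .cpp_rhs(model$native, t, state, .canonical_params(model, params), stim)
}

# order a user-facing named parameter vector into the native canonical order
.canonical_params <- function(model, params) {
  nm <- switch(model$native,
               sixcurrent = .cpp_six_param_names(),
               stop("no native parameter layout for ", model$native))
  missing <- setdiff(nm, names(params))
  if (length(missing) > 0L)
    stop("missing model parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- as.numeric(params[nm])
  gk <- intersect(unname(model$conductance_keys), nm)
  if (any(params[gk] < 0))
    stop("maximal conductances must be >= 0", call. = FALSE)
  p
}
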