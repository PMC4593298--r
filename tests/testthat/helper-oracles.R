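# Independent oracles and shared fixtures for the test suite.

# Resting equilibrium of the six-current demo model, found by 1-D
# root-finding on the summed steady-state currents (gates eliminated at
# their voltage-dependent steady states).  Independent of the package's
# compiled right-hand side.
sig_oracle <- function(V, Vh, k) 1 / (1 + exp(-(V - Vh) / k))

six_rest_current_oracle <- function(V, p) {
  m3h <- sig_oracle(V, p[["m_Vhalf"]], p[["m_k"]])^3 *
    sig_oracle(V, p[["h_Vhalf"]], p[["h_k"]])
  p[["g_Na"]] * m3h * (V - p[["E_Na"]]) +
    p[["g_CaL"]] * sig_oracle(V, p[["d_Vhalf"]], p[["d_k"]]) *
      sig_oracle(V, p[["f_Vhalf"]], p[["f_k"]]) * (V - p[["E_Ca"]]) +
    p[["g_Kr"]] * sig_oracle(V, p[["xr_Vhalf"]], p[["xr_k"]]) *
      (V - p[["E_K"]]) +
    p[["g_Ks"]] * sig_oracle(V, p[["xs_Vhalf"]], p[["xs_k"]])^2 *
      (V - p[["E_K"]]) +
    p[["g_K1"]] * sig_oracle(V, p[["k1_Vhalf"]], p[["k1_k"]]) *
      (V - p[["E_K"]]) +
    p[["g_to"]] * sig_oracle(V, p[["r_Vhalf"]], p[["r_k"]]) *
      sig_oracle(V, p[["s_Vhalf"]], p[["s_k"]]) * (V - p[["E_K"]])
}

six_equilibrium_oracle <- function(p) {
  V <- stats::uniroot(six_rest_current_oracle, c(-95, -60), p = p,
                      tol = 1e-13)$root
  c(V = V,
    m = sig_oracle(V, p[["m_Vhalf"]], p[["m_k"]]),
    h = sig_oracle(V, p[["h_Vhalf"]], p[["h_k"]]),
    d = sig_oracle(V, p[["d_Vhalf"]], p[["d_k"]]),
    f = sig_oracle(V, p[["f_Vhalf"]], p[["f_k"]]),
    xr = sig_oracle(V, p[["xr_Vhalf"]], p[["xr_k"]]),
    xs = sig_oracle(V, p[["xs_Vhalf"]], p[["xs_k"]]),
    r = sig_oracle(V, p[["r_Vhalf"]], p[["r_k"]]),
    s = sig_oracle(V, p[["s_Vhalf"]], p[["s_k"]]))
}

# synthetic traces with closed-form biomarkers
square_trace <- function(rest = -85, peak = 15, t_on = 10, t_off = 210,
                         t_end = 400, dt = 0.1) {
  tm <- seq(0, t_end, by = dt)
  list(times = tm, voltages = ifelse(tm >= t_on & tm < t_off, peak, rest))
}

ramp_trace <- function(rest = -85, peak = 15, t_on = 10, ramp_ms = 300,
                       t_end = 500, dt = 0.1) {
  tm <- seq(0, t_end, by = dt)
  v <- ifelse(tm < t_on, rest,
              pmax(rest, peak - (tm - t_on) * (peak - rest) / ramp_ms))
  list(times = tm, voltages = v)
}

# the 1 Hz default-protocol control steady state is used by several files;
# compute it once per session
.fixture_cache <- new.env(parent = emptyenv())
demo_control_steady <- function() {
  if (is.null(.fixture_cache$control)) {
    m <- get_model("sixcurrent_demo")
    .fixture_cache$control <- pace_to_steady(
      m, protocol = pacing_protocol(frequency = 1))
  }
  .fixture_cache$control
}
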