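// Six-current demonstration ventricular cell model.
//
// States (9): V [mV], then Hodgkin-Huxley gates m, h, d, f, xr, xs, r, s.
// dV/dt = -(I_Na + I_CaL + I_Kr + I_Ks + I_K1 + I_to + I_stim)/C_m with the
// stimulus entering as an inward (negative) current, so a positive
// stim amplitude depolarises the cell.
//
// Every kinetic constant is an entry of the parameter vector so that studies
// can override them; the canonical order is fixed here and exposed to R via
// six_param_names().

#include "apsweep.h"
#include <cmath>

static const char* SIX_PARAMS[] = {
  "g_Na", "g_CaL", "g_Kr", "g_Ks", "g_K1", "g_to",
  "E_Na", "E_Ca", "E_K", "C_m",
  "m_Vhalf", "m_k", "m_tau",
  "h_Vhalf", "h_k", "h_tau_base", "h_tau_amp", "h_tau_Vmid", "h_tau_k",
  "d_Vhalf", "d_k", "d_tau",
  "f_Vhalf", "f_k", "f_tau",
  "xr_Vhalf", "xr_k", "xr_tau",
  "xs_Vhalf", "xs_k", "xs_tau",
  "r_Vhalf", "r_k", "r_tau",
  "s_Vhalf", "s_k", "s_tau",
  "k1_Vhalf", "k1_k"
};

int six_n_state() { return 9; }
int six_n_param() { return 39; }

std::vector<std::string> six_param_names() {
  return std::vector<std::string>(SIX_PARAMS, SIX_PARAMS + 39);
}

// Boltzmann sigmoid; the sign of k sets the direction (k < 0: inactivation).
static inline double sig(double V, double Vh, double k) {
  return 1.0 / (1.0 + std::exp(-(V - Vh) / k));
}

void six_rhs(double t, const double* y, const double* p, double stim,
             double* dy) {
  (void)t; // autonomous within a stimulus segment
  const double V = y[0], m = y[1], h = y[2], d = y[3], f = y[4];
  const double xr = y[5], xs = y[6], r = y[7], s = y[8];

  const double INa  = p[0] * m * m * m * h * (V - p[6]);
  const double ICaL = p[1] * d * f * (V - p[7]);
  const double IKr  = p[2] * xr * (V - p[8]);
  const double IKs  = p[3] * xs * xs * (V - p[8]);
  const double IK1  = p[4] * sig(V, p[37], p[38]) * (V - p[8]);
  const double Ito  = p[5] * r * s * (V - p[8]);
  const double Istim = -stim; // inward current convention

  dy[0] = -(INa + ICaL + IKr + IKs + IK1 + Ito + Istim) / p[9];
  dy[1] = (sig(V, p[10], p[11]) - m) / p[12];
  const double tau_h = p[15] + p[16] / (1.0 + std::exp((V - p[17]) / p[18]));
  dy[2] = (sig(V, p[13], p[14]) - h) / tau_h;
  dy[3] = (sig(V, p[19], p[20]) - d) / p[21];
  dy[4] = (sig(V, p[22], p[23]) - f) / p[24];
  dy[5] = (sig(V, p[25], p[26]) - xr) / p[27];
  dy[6] = (sig(V, p[28], p[29]) - xs) / p[30];
  dy[7] = (sig(V, p[31], p[32]) - r) / p[33];
  dy[8] = (sig(V, p[34], p[35]) - s) / p[36];
}
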