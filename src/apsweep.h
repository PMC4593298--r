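#ifndef APSWEEP_H
#define APSWEEP_H

#include <string>
#include <vector>

// six-current demonstration model (sixcurrent.cpp)
int six_n_state();
int six_n_param();
std::vector<std::string> six_param_names();
void six_rhs(double t, const double* y, const double* p, double stim,
             double* dy);

#endif
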