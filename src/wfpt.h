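#ifndef RLDDM_WFPT_H
#define RLDDM_WFPT_H

// scalar defective first-passage density at clock time rt for boundary
// (+1 upper / -1 lower), drift v, separation a, non-decision time ndt,
// relative start w; defined in wfpt.cpp
double wfpt_density_scalar(double rt, int boundary, double v, double a,
                           double ndt, double w);

#endif
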