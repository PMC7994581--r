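#ifndef RETRIEVALMIX_WIENER_H
#define RETRIEVALMIX_WIENER_H

double dwiener_raw(double rt, double a, double v, double tau, double w,
                   int upper, double err);
double wiener_p_upper_raw(double a, double v, double w);

#endif
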