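# Anharmonic variant of water_harmonic.cfg: the harmonic bonds are replaced
# by Morse bonds with the same curvature at the minimum (2 D a^2 = kr),
# redshifting the stretching fundamentals; the bend stays harmonic.
# Synthetic parametrization (see water_harmonic.cfg). Atomic units.
kind = triatomic_water_anharmonic
D = 0.18748
a = 1.14679
r0 = 1.808846
ktheta = 0.1477
theta0 = 1.8242182
masses_amu = 15.9994, 1.00794, 1.00794
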