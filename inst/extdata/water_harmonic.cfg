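# Single gas-phase water molecule with harmonic bonds and a harmonic bend,
# emulating the one-molecule model of Witt, Ivanov, Shiga, Forbert and Marx,
# J. Chem. Phys. 130, 194510 (2009). The original force constants are not
# reproduced here; this synthetic re-parametrization is calibrated to the
# harmonic frequencies 1595 / 3680 / 3734 cm^-1 (gas-phase-like bend and
# stretches). Atomic units; r0 = 0.9572 A, theta0 = 104.52 deg.
kind = triatomic_water_harmonic
kr = 0.493
r0 = 1.808846
ktheta = 0.1477
theta0 = 1.8242182
masses_amu = 15.9994, 1.00794, 1.00794
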