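# OH radical as a 1D Morse oscillator.
# Parameters follow the OH Morse model used by Rossi, Ceriotti and
# Manolopoulos, J. Chem. Phys. 140, 234116 (2014) (harmonic frequency
# ~3751 cm^-1, fundamental ~3580 cm^-1). Atomic units.
kind = morse_diatomic
D = 0.18748
a = 1.1605
r0 = 1.8324
masses_amu = 15.9994, 1.00794
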