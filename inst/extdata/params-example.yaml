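# Example multicomponent-membrane parameter set (energies in kBT).
kA: 2.0        # bending rigidity, component A (ordered phase)
kB: 1.0        # bending rigidity, component B
kbarA: -0.5    # Gaussian rigidity, component A
kbarB: -0.2    # Gaussian rigidity, component B
sigmaA: 1.0    # tension, component A
sigmaB: 0.8    # tension, component B
lambda: 2.0    # double-well coupling
mu: 1.0        # gradient coefficient
P: 0.0         # transmembrane pressure difference
ternary:
  alpha: -1.0
  beta: 1.0
  gamma: 0.25
  kappa: 1.0
temperature:
  lambda0: 2.0
  Tc: 330.0
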