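# Default material table for the pCT simulator.
#
# density ............ g/cm^3
# eta_e .............. electron density relative to water (the reconstructed RSP)
# mean_excitation_I .. mean excitation energy, eV
# radiation_length ... X0 in g/cm^2 (drives the Highland scattering model)
#
# eta_e = density * (Z/A) / (1.0 * 0.55509); Z/A, I and X0 are standard
# reference values (ICRU compositions).  Bone is cortical bone; adipose and
# air densities follow the phantom specification.
water:
  density: 1.0
  eta_e: 1.0
  mean_excitation_I: 75.0
  radiation_length: 36.08
a150:
  density: 1.127
  eta_e: 1.11468
  mean_excitation_I: 65.1
  radiation_length: 41.77
silicon:
  density: 2.33
  eta_e: 2.09234
  mean_excitation_I: 173.0
  radiation_length: 21.82
bone:
  density: 1.85
  eta_e: 1.71563
  mean_excitation_I: 106.4
  radiation_length: 25.61
adipose:
  density: 0.92
  eta_e: 0.92726
  mean_excitation_I: 63.2
  radiation_length: 44.80
air:
  density: 0.0012
  eta_e: 0.0010792
  mean_excitation_I: 85.7
  radiation_length: 36.62
csi:
  density: 4.51
  eta_e: 3.37742
  mean_excitation_I: 553.1
  radiation_length: 8.39
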