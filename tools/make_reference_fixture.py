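"""Generate the synthetic reference stopping-power fixture.

Computes proton stopping powers for water and A150 tissue-equivalent plastic
from the standard full Bethe formula (PDG constants, no shell or density
corrections):

    S/rho = 0.307075 * (Z/A) / beta^2 * [ln(2 m_e c^2 beta^2 gamma^2 / I) - beta^2]

This parameterization is independent of the package's water-normalised
(K = 0.17 MeV/cm, eta_e) formulation and serves as its cross-check fixture.
"""
import numpy as np

MP, ME = 938.272, 0.510998928
MATS = {  # Z/A, I (eV), density (g/cm^3)
    "water": (0.55509, 75.0, 1.0),
    "a150": (0.5490221, 65.1, 1.127),
}

def s_mass(E, za, I):
    b2 = 1 - (MP / (E + MP)) ** 2
    g2 = 1 / (1 - b2)
    return 0.307075 * za / b2 * (np.log(2 * ME * 1e6 * b2 * g2 / I) - b2)

E = np.array([10, 15, 20, 30, 40, 50, 70, 100, 130, 160, 200, 250], float)
with open("inst/extdata/stopping_reference_synthetic.csv", "w") as f:
    f.write("# Synthetic reference stopping-power table (computed, not measured).\n")
    f.write("# Full Bethe formula, 0.307075*(Z/A) MeV cm^2/g prefactor, no shell or\n")
    f.write("# density corrections; see tools/make_reference_fixture.py.\n")
    f.write("material,E_MeV,S_MeV_per_cm\n")
    for m, (za, I, rho) in MATS.items():
        for e, s in zip(E, s_mass(E, za, I) * rho):
            f.write(f"{m},{e:g},{s:.6g}\n")
print(open("inst/extdata/stopping_reference_synthetic.csv").read())
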