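{
  "schema": "thermogate-model/1",
  "description": "ILLUSTRATIVE (synthetic) parameter set for the two-sensor allosteric gating model. Not an experimentally fitted parameterization: values were chosen once so that the model displays the qualitative phenomenology of Na+- and capsaicin-modulated heat gating (low-temperature rise, intermediate plateau whose level falls with external Na+, steep high-temperature rise, near-full activation in saturating capsaicin).",
  "units": {
    "enthalpy": "kcal/mol",
    "entropy": "kcal/(mol K)",
    "temperature": "K",
    "association_constants": "1/M"
  },
  "parameters": {
    "L": 0.005,
    "J1": { "dH0_kcal_mol": 40, "dS0_kcal_mol_K": 0.148148 },
    "J2": { "dH0_kcal_mol": 100, "dS0_kcal_mol_K": 0.317460 },
    "D": 50,
    "E": 600,
    "K1_per_M": 500,
    "F": 0.1,
    "G": 0.01,
    "H": 0.5,
    "K2_per_M": 20000000,
    "caps_couplings": { "c_L": 5000, "c_J1": 2, "c_J2": 2, "c_Na": 1 },
    "coop_exponent": 1.5
  }
}
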