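# Physical-chemistry constants used by the free-energy engine.
#
# Sources (standard compilations, values at 25 degC unless noted):
#   - Formation values (dGf, dHf, kJ/mol): NBS tables (Wagman et al. 1982)
#     supplemented with the aqueous-gas and sulfur-species values tabulated
#     by Amend & Shock (2001).
#   - Debye-Hueckel A, B: standard limiting-law coefficients for water at
#     0 and 25 degC (A in kg^1/2 mol^-1/2, B in kg^1/2 mol^-1/2 Angstrom^-1);
#     linear interpolation is used between tabulated temperatures.
#   - Ion-size parameters a0 (Angstrom): Kielland (1937); species without an
#     entry use default_a0.
#   - Henry constants (mol L^-1 bar^-1 at 0 degC): within the range of
#     compiled 0 degC constants (e.g. van't Hoff extrapolation of the Sander
#     compilation's 25 degC values); the O2 value reproduces air-saturated
#     cold-water solubility of ~14 mg/L at 1 bar.
#   - pKa1 of H2S at 0 degC: van't Hoff from pKa 6.98 (25 degC), dH 22 kJ/mol.
gas_constant_kj: 8.3145e-3   # kJ mol^-1 K^-1
reference_temperature_K: 298.15
debye_huckel:
  temperatures_C: [0.0, 25.0]
  A: [0.4913, 0.5092]
  B: [0.3247, 0.3283]
  default_a0: 4.0
setchenow:
  default_ks: 0.1            # L/mol, salting-out coefficient for all gases
atmosphere:
  total_pressure_bar: 1.0
  water_vapor_pressure_bar: 0.00611   # at 0 degC, 1 bar total
  mole_fraction: {O2: 0.21, N2: 0.78, CO2: 3.9e-4}
henry_0C:                     # mol L^-1 bar^-1
  O2: 2.10e-3
  N2: 1.04e-3
  CO2: 7.6e-2
molar_mass:                   # g/mol
  O2: 31.998
  N2: 28.014
  CO2: 44.009
  S: 32.066
  HCO3: 61.016
  CaCO3: 100.087
  C: 12.011
pKa1_H2S_0C: 7.33
below_detection_floor: 1.0e-12   # mol/L
species:
  "H+":        {charge: 1,  a0: 9.0, phase: aqueous, elements: {H: 1},            dGf: 0.0,     dHf: 0.0}
  "OH-":       {charge: -1, a0: 3.5, phase: aqueous, elements: {O: 1, H: 1},      dGf: -157.30, dHf: -230.02}
  "H2O":       {charge: 0,           phase: water,   elements: {H: 2, O: 1},      dGf: -237.18, dHf: -285.83}
  "O2(aq)":    {charge: 0,           phase: gas,     elements: {O: 2},            dGf: 16.54,   dHf: -11.70,  gas: O2}
  "N2(aq)":    {charge: 0,           phase: gas,     elements: {N: 2},            dGf: 18.18,   dHf: -10.40,  gas: N2}
  "CO2(aq)":   {charge: 0,           phase: gas,     elements: {C: 1, O: 2},      dGf: -385.98, dHf: -413.80, gas: CO2}
  "HCO3-":     {charge: -1, a0: 4.25, phase: aqueous, elements: {C: 1, O: 3, H: 1}, dGf: -586.85, dHf: -691.99}
  "SO4--":     {charge: -2, a0: 4.0, phase: aqueous, elements: {S: 1, O: 4},      dGf: -744.00, dHf: -909.60}
  "HS-":       {charge: -1, a0: 3.5, phase: aqueous, elements: {S: 1, H: 1},      dGf: 12.05,   dHf: -16.30}
  "H2S(aq)":   {charge: 0,           phase: aqueous, elements: {S: 1, H: 2},      dGf: -27.87,  dHf: -39.75}
  "S2O3--":    {charge: -2, a0: 4.0, phase: aqueous, elements: {S: 2, O: 3},      dGf: -522.50, dHf: -652.30}
  "SO3--":     {charge: -2, a0: 4.5, phase: aqueous, elements: {S: 1, O: 3},      dGf: -486.60, dHf: -635.50}
  "S0":        {charge: 0,           phase: solid,   elements: {S: 1},            dGf: 0.0,     dHf: 0.0}
  "NH4+":      {charge: 1,  a0: 2.5, phase: aqueous, elements: {N: 1, H: 4},      dGf: -79.37,  dHf: -133.26}
  "NO3-":      {charge: -1, a0: 3.0, phase: aqueous, elements: {N: 1, O: 3},      dGf: -110.83, dHf: -206.85}
  "NO2-":      {charge: -1, a0: 3.0, phase: aqueous, elements: {N: 1, O: 2},      dGf: -32.22,  dHf: -104.60}
  "Fe++":      {charge: 2,  a0: 6.0, phase: aqueous, elements: {Fe: 1},           dGf: -78.87,  dHf: -89.10}
  "Fe(OH)3":   {charge: 0,           phase: solid,   elements: {Fe: 1, O: 3, H: 3}, dGf: -699.0, dHf: -823.0}
  "Mn++":      {charge: 2,  a0: 6.0, phase: aqueous, elements: {Mn: 1},           dGf: -228.10, dHf: -220.75}
  "MnO2":      {charge: 0,           phase: solid,   elements: {Mn: 1, O: 2},     dGf: -465.14, dHf: -520.03}
  "H3AsO3":    {charge: 0,           phase: aqueous, elements: {As: 1, O: 3, H: 3}, dGf: -639.80, dHf: -742.20}
  "H2AsO4-":   {charge: -1, a0: 4.0, phase: aqueous, elements: {As: 1, O: 4, H: 2}, dGf: -753.17, dHf: -909.56}
  "HAsO4--":   {charge: -2, a0: 4.0, phase: aqueous, elements: {As: 1, O: 4, H: 1}, dGf: -714.60, dHf: -906.34}
  "Acetate-":  {charge: -1, a0: 4.5, phase: aqueous, elements: {C: 2, H: 3, O: 2}, dGf: -369.31, dHf: -486.01}
  "Na+":       {charge: 1,  a0: 4.0, phase: aqueous, elements: {Na: 1},           dGf: -261.91, dHf: -240.12}
  "K+":        {charge: 1,  a0: 3.0, phase: aqueous, elements: {K: 1},            dGf: -283.27, dHf: -252.38}
  "Mg++":      {charge: 2,  a0: 8.0, phase: aqueous, elements: {Mg: 1},           dGf: -454.80, dHf: -466.85}
  "Ca++":      {charge: 2,  a0: 6.0, phase: aqueous, elements: {Ca: 1},           dGf: -553.58, dHf: -542.83}
  "Cl-":       {charge: -1, a0: 3.0, phase: aqueous, elements: {Cl: 1},           dGf: -131.23, dHf: -167.16}
  "F-":        {charge: -1, a0: 3.5, phase: aqueous, elements: {F: 1},            dGf: -278.79, dHf: -332.63}
  "Br-":       {charge: -1, a0: 3.0, phase: aqueous, elements: {Br: 1},           dGf: -103.96, dHf: -121.55}
  "PO4---":    {charge: -3, a0: 4.0, phase: aqueous, elements: {P: 1, O: 4},      dGf: -1018.70, dHf: -1277.40}
  "H4SiO4":    {charge: 0,           phase: aqueous, elements: {Si: 1, O: 4, H: 4}, dGf: -1316.60, dHf: -1468.60}
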