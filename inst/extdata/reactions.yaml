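# Default catabolic reaction set for a sub-aerial elemental-sulfur deposit.
#
# Covers the reaction classes relevant to cold sulfur-spring deposits:
# aerobic oxidation of the reduced sulfur species (sulfide, elemental sulfur,
# thiosulfate, sulfite), aerobic oxidation of organic carbon (as acetate),
# anammox, the two nitrification steps, aerobic iron / manganese / arsenite
# oxidation, sulfur disproportionation, and nitrate-coupled sulfur oxidation.
# Every entry is user-replaceable; stoichiometry is parsed from the equation
# string and checked for charge and element balance at load time.
#
# electrons = moles of electrons transferred per formula unit of reaction.
reactions:
  - id: hs_o2
    name: aerobic sulfide oxidation
    equation: "HS- + 2 O2(aq) -> SO4-- + H+"
    electrons: 8
  - id: s0_o2
    name: aerobic elemental-sulfur oxidation
    equation: "S0 + 1.5 O2(aq) + H2O -> SO4-- + 2 H+"
    electrons: 6
  - id: s2o3_o2
    name: aerobic thiosulfate oxidation
    equation: "S2O3-- + 2 O2(aq) + H2O -> 2 SO4-- + 2 H+"
    electrons: 8
  - id: so3_o2
    name: aerobic sulfite oxidation
    equation: "SO3-- + 0.5 O2(aq) -> SO4--"
    electrons: 2
  - id: acetate_o2
    name: aerobic acetate oxidation
    equation: "Acetate- + 2 O2(aq) -> 2 HCO3- + H+"
    electrons: 8
  - id: anammox
    name: anaerobic ammonium oxidation by nitrite
    equation: "NH4+ + NO2- -> N2(aq) + 2 H2O"
    electrons: 3
  - id: nh4_o2
    name: aerobic ammonium oxidation to nitrite
    equation: "NH4+ + 1.5 O2(aq) -> NO2- + H2O + 2 H+"
    electrons: 6
  - id: no2_o2
    name: aerobic nitrite oxidation to nitrate
    equation: "NO2- + 0.5 O2(aq) -> NO3-"
    electrons: 2
  - id: fe2_o2
    name: aerobic ferrous-iron oxidation
    equation: "Fe++ + 0.25 O2(aq) + 2.5 H2O -> Fe(OH)3 + 2 H+"
    electrons: 1
  - id: mn2_o2
    name: aerobic manganese(II) oxidation
    equation: "Mn++ + 0.5 O2(aq) + H2O -> MnO2 + 2 H+"
    electrons: 2
  - id: as3_o2
    name: aerobic arsenite oxidation
    equation: "H3AsO3 + 0.5 O2(aq) -> H2AsO4- + H+"
    electrons: 2
  - id: s0_disp
    name: elemental-sulfur disproportionation
    equation: "4 S0 + 4 H2O -> SO4-- + 3 HS- + 5 H+"
    electrons: 6
  - id: s2o3_disp
    name: thiosulfate disproportionation
    equation: "S2O3-- + H2O -> SO4-- + HS- + H+"
    electrons: 4
  - id: s0_no3
    name: nitrate-coupled elemental-sulfur oxidation
    equation: "S0 + 1.2 NO3- + 0.4 H2O -> SO4-- + 0.6 N2(aq) + 0.8 H+"
    electrons: 6
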