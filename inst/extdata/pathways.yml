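# Default carbon / nitrogen / sulfur water-column reaction definitions.
# Marker gene sets follow the METABOLIC-style HMM naming convention and are
# configuration, not code: edit or replace this file for other marker sets.
# logic: AND of OR-groups; a genome has the reaction iff every group has at
# least one hit meeting its model cutoff (one copy per gene suffices).
default_cutoff: 50
cutoffs:
  mcrA: 60
  mcrB: 60
  mcrG: 60
  pmoA: 80
  mmoX: 80
  amoA: 80
  amoB: 80
  nifH: 70
  nifD: 70
  nifK: 70
  dsrA: 60
  dsrB: 60
  nxrA: 75
  nxrB: 75
reactions:
  - id: organic_carbon_oxidation
    cycle: carbon
    label: organic carbon oxidation
    substrate: organic C (0)
    product: CO2 (+IV)
    logic:
      - [glk, pfk, gapA]
  - id: fermentation
    cycle: carbon
    label: fermentation
    substrate: organic C (0)
    product: organic acids / ethanol
    logic:
      - [ldh, adhE, ackA]
  - id: hydrogen_generation
    cycle: carbon
    label: hydrogen generation
    substrate: H+ (+I)
    product: H2 (0)
    logic:
      - [hydA, echE, hndD]
  - id: hydrogen_oxidation
    cycle: carbon
    label: hydrogen oxidation
    substrate: H2 (0)
    product: H+ (+I)
    logic:
      - [hyaB, hybC, hoxH]
  - id: methanogenesis
    cycle: carbon
    label: methanogenesis
    substrate: CO2/acetate (+IV/0)
    product: CH4 (-IV)
    logic:
      - [mcrA]
      - [mcrB]
      - [mcrG]
  - id: methanotrophy
    cycle: carbon
    label: methanotrophy
    substrate: CH4 (-IV)
    product: CO2 (+IV)
    logic:
      - [pmoA, mmoX]
  - id: co2_fixation
    cycle: carbon
    label: CO2 fixation
    substrate: CO2 (+IV)
    product: organic C (0)
    logic:
      - [rbcL, aclB, cooS]
  - id: nitrogen_fixation
    cycle: nitrogen
    label: nitrogen fixation
    substrate: N2 (0)
    product: NH3 (-III)
    logic:
      - [nifH]
      - [nifD]
      - [nifK]
  - id: ammonia_oxidation
    cycle: nitrogen
    label: ammonia oxidation
    substrate: NH3 (-III)
    product: NO2- (+III)
    logic:
      - [amoA]
      - [amoB]
  - id: nitrite_oxidation
    cycle: nitrogen
    label: nitrite oxidation
    substrate: NO2- (+III)
    product: NO3- (+V)
    logic:
      - [nxrA]
      - [nxrB]
  - id: comammox
    cycle: nitrogen
    label: complete ammonia oxidation (comammox)
    substrate: NH3 (-III)
    product: NO3- (+V)
    logic:
      - [amoA]
      - [amoB]
      - [nxrA]
      - [nxrB]
  - id: nitrate_reduction
    cycle: nitrogen
    label: nitrate reduction
    substrate: NO3- (+V)
    product: NO2- (+III)
    logic:
      - [narG, napA]
      - [narH, napB]
  - id: nitrite_reduction
    cycle: nitrogen
    label: nitrite reduction
    substrate: NO2- (+III)
    product: NO (+II)
    logic:
      - [nirK, nirS]
  - id: nitric_oxide_reduction
    cycle: nitrogen
    label: nitric oxide reduction
    substrate: NO (+II)
    product: N2O (+I)
    logic:
      - [norB]
      - [norC]
  - id: nitrous_oxide_reduction
    cycle: nitrogen
    label: nitrous oxide reduction
    substrate: N2O (+I)
    product: N2 (0)
    logic:
      - [nosZ]
  - id: dnra
    cycle: nitrogen
    label: nitrate/nitrite ammonification (DNRA)
    substrate: NO2- (+III)
    product: NH4+ (-III)
    logic:
      - [nrfA, nirB]
  - id: anammox
    cycle: nitrogen
    label: anaerobic ammonium oxidation (anammox)
    substrate: NH4+ + NO2- (-III/+III)
    product: N2 (0)
    logic:
      - [hzsA]
      - [hzsB]
      - [hzo]
  - id: sulfide_oxidation
    cycle: sulfur
    label: sulfide oxidation
    substrate: H2S (-II)
    product: S0 (0)
    logic:
      - [sqr, fccB]
  - id: sulfur_oxidation
    cycle: sulfur
    label: sulfur oxidation
    substrate: S0 (0)
    product: SO3 2- (+IV)
    logic:
      - [soxB, sor]
  - id: sulfite_oxidation
    cycle: sulfur
    label: sulfite oxidation
    substrate: SO3 2- (+IV)
    product: SO4 2- (+VI)
    logic:
      - [soeA, sorA]
  - id: thiosulfate_oxidation
    cycle: sulfur
    label: thiosulfate oxidation
    substrate: S2O3 2- (+II)
    product: SO4 2- (+VI)
    logic:
      - [soxX]
      - [soxB]
  - id: sulfate_reduction
    cycle: sulfur
    label: sulfate reduction
    substrate: SO4 2- (+VI)
    product: SO3 2- (+IV)
    logic:
      - [sat]
      - [aprA]
      - [dsrA]
  - id: sulfite_reduction
    cycle: sulfur
    label: sulfite reduction
    substrate: SO3 2- (+IV)
    product: H2S (-II)
    logic:
      - [dsrA]
      - [dsrB]
  - id: sulfur_reduction
    cycle: sulfur
    label: sulfur reduction
    substrate: S0 (0)
    product: H2S (-II)
    logic:
      - [sreA, psrA]
  - id: thiosulfate_disproportionation
    cycle: sulfur
    label: thiosulfate disproportionation
    substrate: S2O3 2- (+II)
    product: H2S + SO3 2- (-II/+IV)
    logic:
      - [phsA]
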