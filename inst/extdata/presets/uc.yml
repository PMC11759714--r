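# Upland tundra core (UC) preset.
# Values marked [anchor] are tied to printed observations of the column
# experiment; all others are free calibration choices (see the methods
# vignette for rationale).
schema: 1
name: UC
description: Upland tundra soil column, historically unsaturated and oxic
geometry:
  diameter: 0.075        # m [anchor: 7.5 cm PVC tube]
  soil_depth: 0.50       # m [anchor: 60 cm tube minus 10 cm basal sand]
  n_cells: 50
phases:                  # [anchor: 32/21/28 d drain-saturate-drain]
  - {kind: drain, duration: 32}
  - {kind: saturate, duration: 21}
  - {kind: drain, duration: 28}
water_addition_hours: 2  # [anchor: water added over two hours]
headspace:
  volume_L: 0.5          # free (not printed); quasi-steady inversion is V-insensitive
  flow_mL_min: 5.0       # [anchor: constant flow of 5 mL/min of air]
layers:
  - name: organic        # [anchor: organic soil properties 0-15 cm]
    z_top: 0.00
    z_bot: 0.15
    porosity: 0.85       # free; high-porosity organic peat
    bulk_density: 0.25   # g/cm^3, free
    init_pH: 6.4         # [anchor: initial porewater pH 6.4 at 2 cm]
    buffer_mol_L: 0.030  # organic weak-acid buffer pool, free
    vg:                  # retention free; K_sat calibrated so early-drain
                         # outflow is ~4x the TC preset and the first drain
                         # approaches completion within about a month
      alpha: 5.0         # 1/m
      n_vg: 1.7
      S_r: 0.35
      K_sat: 1.6e-7      # m/s, free calibration
    init_pools:          # mol per g dry soil, free (order of magnitude from
                         # 48% C organic horizon and 10^2 umol/g extractable Fe)
      POC: 0.035
      MAOC: 0.004
      FeIII_oxide: 5.0e-5
      FeIII_OM: 1.2e-4
      C_per_Fe_OM: 2.0
    init_aqueous:        # mol/L; DOM split gives initial DOC near 110 mg/L
                         # [anchor: initial UC DOC 95-131 mg/L]
      DOM_L: 3.0e-3
      DOM_A: 6.0e-3
      acetate: 1.0e-4
      Fe2: 2.0e-5
      Fe3aq: 2.0e-5
      DIC: 2.0e-3
      O2aq: 1.0e-5
      CH4aq: 1.0e-6
      H2: 1.0e-8
    guild_factors:       # dimensionless multipliers; aerobe > 1 and tiny
                         # methanogen factors encode the oxic-history
                         # community (memory effect)
      aerobe: 1.5
      fermenter: 1.0
      Fe_reducer: 1.0
      Fe_oxidizer: 1.0
      ac_methanogen: 0.005
      h2_methanogen: 0.005
  - name: mineral        # [anchor: mineral soil properties 15-50 cm]
    z_top: 0.15
    z_bot: 0.50
    porosity: 0.65
    bulk_density: 0.80
    init_pH: 6.3         # [anchor: initial porewater pH 6.3 at 12 cm,
                         # extended to the mineral layer]
    buffer_mol_L: 0.020
    vg:
      alpha: 3.0
      n_vg: 1.5
      S_r: 0.55
      K_sat: 2.8e-8      # m/s, free calibration (drainage-limiting layer)
    init_pools:
      POC: 0.010
      MAOC: 0.003
      FeIII_oxide: 1.0e-4
      FeIII_OM: 6.0e-5
      C_per_Fe_OM: 2.0
    init_aqueous:
      DOM_L: 1.5e-3
      DOM_A: 4.0e-3
      acetate: 5.0e-5
      Fe2: 4.0e-5
      Fe3aq: 2.0e-5
      DIC: 2.5e-3
      O2aq: 5.0e-6
      CH4aq: 2.0e-6
      H2: 1.0e-8
    guild_factors:
      aerobe: 1.5
      fermenter: 1.0
      Fe_reducer: 1.0
      Fe_oxidizer: 1.0
      ac_methanogen: 0.005
      h2_methanogen: 0.005
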