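# Thermokarst channel core (TC) preset.
# Values marked [anchor] are tied to printed observations; all others are
# free calibration choices (methods vignette).
schema: 1
name: TC
description: Thermokarst channel soil column, historically saturated and reduced
geometry:
  diameter: 0.075        # m [anchor]
  soil_depth: 0.50       # m [anchor]
  n_cells: 50
phases:                  # [anchor: 37/19/35 d drain-saturate-drain]
  - {kind: drain, duration: 37}
  - {kind: saturate, duration: 19}
  - {kind: drain, duration: 35}
water_addition_hours: 2
headspace:
  volume_L: 0.5
  flow_mL_min: 5.0
layers:
  - name: organic
    z_top: 0.00
    z_bot: 0.15
    porosity: 0.80
    bulk_density: 0.30
    init_pH: 7.2         # [anchor: initial porewater pH 7.2 at 2 cm]
    buffer_mol_L: 0.045  # higher buffering mutes thermokarst pH shifts
    vg:                  # K_sat 1/4 of the UC layer values [anchor: UC
                         # early-drain outflow approx 4x TC]
      alpha: 4.0
      n_vg: 1.6
      S_r: 0.45
      K_sat: 4.0e-8
    init_pools:
      POC: 0.022
      MAOC: 0.004
      FeIII_oxide: 3.0e-5
      FeIII_OM: 8.0e-5
      C_per_Fe_OM: 2.0
    init_aqueous:        # reduced starting condition: high Fe2, high DIC,
                         # high CH4; Fe2/(Fe2+Fe3aq) = 0.95 initially
      DOM_L: 1.5e-3
      DOM_A: 5.0e-3
      acetate: 1.5e-4
      Fe2: 4.0e-4
      Fe3aq: 2.0e-5
      DIC: 4.0e-3
      O2aq: 1.0e-6
      CH4aq: 1.0e-4
      H2: 2.0e-8
    guild_factors:       # anoxia-adapted community: methanogen factors two
                         # orders of magnitude above the UC preset
      aerobe: 1.0
      fermenter: 1.0
      Fe_reducer: 1.0
      Fe_oxidizer: 1.0
      ac_methanogen: 1.0
      h2_methanogen: 1.0
  - name: mineral
    z_top: 0.15
    z_bot: 0.50
    porosity: 0.60
    bulk_density: 0.90
    init_pH: 6.7         # [anchor: initial porewater pH 6.7 at 12 cm,
                         # extended to the mineral layer]
    buffer_mol_L: 0.035
    vg:
      alpha: 2.5
      n_vg: 1.45
      S_r: 0.55
      K_sat: 7.0e-9
    init_pools:
      POC: 0.012
      MAOC: 0.004
      FeIII_oxide: 5.0e-5
      FeIII_OM: 5.0e-5
      C_per_Fe_OM: 2.0
    init_aqueous:
      DOM_L: 1.0e-3
      DOM_A: 4.0e-3
      acetate: 1.0e-4
      Fe2: 3.0e-4
      Fe3aq: 1.5e-5
      DIC: 4.5e-3
      O2aq: 1.0e-6
      CH4aq: 1.5e-4
      H2: 2.0e-8
    guild_factors:
      aerobe: 1.0
      fermenter: 1.0
      Fe_reducer: 1.0
      Fe_oxidizer: 1.0
      ac_methanogen: 1.0
      h2_methanogen: 1.0
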