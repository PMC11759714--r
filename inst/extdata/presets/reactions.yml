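# Reaction network kinetics and transport constants shared by both presets.
# All kinetic constants are free calibration values chosen to reproduce the
# qualitative column behaviour (redox ladder, oxygen drawdown within hours of
# re-saturation, saturation-phase DOC excursion in the upland column); the
# methods vignette documents each choice.
schema: 1
kinetics:
  Vmax_R3: 3.0e-8     # aerobic respiration, mol/L/s per unit guild factor
  Vmax_R4: 1.5e-8     # fermentation
  Vmax_R5: 5.0e-11    # Fe(III)-oxide reduction (acetate units)
  Vmax_R6: 5.0e-11    # organic-complexed Fe(III) reduction (acetate units)
  Vmax_R8: 2.0e-9     # acetoclastic methanogenesis
  Vmax_R9: 2.0e-9     # hydrogenotrophic methanogenesis (CH4 units)
  K_DOM: 1.0e-4       # mol/L
  K_O2: 1.0e-5        # mol/L
  K_ac: 1.0e-4        # mol/L
  K_H2: 1.0e-4        # mol/L
  K_DIC: 1.0e-4       # mol/L
  K_FeIII: 5.0e-6     # mol/g-dwt (solid-phase half saturation)
  K_I: 1.0e-6         # mol/L, O2 inhibition constant
  k_hyd: 2.0e-9       # 1/s, particulate C hydrolysis
  k_att: 1.0e-8       # 1/s, DOM_L attachment to mineral surfaces
  k_det: 1.0e-12      # 1/s, MAOC detachment
  k_ox: 3.0e-4        # L/mol/s, Fe(II) + O2 oxidation (slow at pH < 7, 4 degC)
  r_CFe: 2.0          # mol C released to DOM per mol Fe reduced from FeIII_OM
  f_L: 0.6            # labile fraction of DOM released by R6
  f_aq: 0.1           # fraction of oxidised Fe(III) staying aqueous (complexed)
transport:
  D_w0: 1.0e-9        # m^2/s, free-water diffusivity, all aqueous solutes
  D_a0: 1.6e-5        # m^2/s, free-air diffusivity, all gases
  henry:              # dimensionless K_cc = C_aq/C_gas at 4 degC
    O2: 0.047
    CO2: 1.30
    CH4: 0.053
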