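---
title: "A coupled hydrology–redox model of Arctic soil columns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled hydrology–redox model of Arctic soil columns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`redoxcolumn` reconstructs, at desk scale, a laboratory experiment in which
two Arctic soil cores — an upland tundra core (UC, historically drained and
oxic) and a thermokarst channel core (TC, historically inundated and
reduced) — are packed into 7.5 cm × 50 cm columns at 4 °C and cycled through
drain → saturate → drain phases while headspace gases, sensors and porewater
are monitored. This vignette is the package's account of the science inside
it: the model structure and its assumptions, the parameters that matter and
why they hold their default values, what the synthetic-observation generator
does and does not emulate, the numerical choices, and the known limitations.

## 1. Water flow: a sharp-interface drainage model

Flow is the backbone: water saturation gates oxygen, and oxygen gates the
redox chemistry. We deliberately do not solve the Richards equation.
Instead the column carries a single water-table depth `z_wt`; cells below it
are saturated, and cells above it hold the hydrostatic van Genuchten profile
anchored at the table, `S_e(z) = [1 + (α (z_wt − z))^n]^{−(1−1/n)}`.
Gravity drainage removes water at a Darcy rate equal to the harmonic-mean
saturated conductivity of the flow path from the table to the column base
(unit-gradient free drainage through the basal sand, which is treated as a
boundary rather than gridded). The new table position is found by inverting
the storage function by bisection, so **water balance is exact by
construction** — the mass ledgers in `run_experiment()` close to round-off,
not to a solver tolerance. The same machinery serves the prescribed-outflow
mode, where the cumulative outflow record is the boundary condition and the
table is placed to match it, mirroring how the experiment's own drainage
data can drive the water level.

What this buys: unconditional stability, exact conservation, and strict
monotonicity in `K_sat` (a faster-draining column is drier at every time, a
property the sensitivity analysis relies on). What it costs: no transient
disequilibrium between the unsaturated profile and the table — the
column is always in hydrostatic equilibrium above `z_wt` — and no
hysteresis, evaporation, or frozen-soil physics. For a 50-cm column drained
over weeks, vertical equilibration of the unsaturated zone is fast relative
to the table's motion, which is the regime where the approximation is
honest.

Per-interface water volumes are exported from each flow step so that solute
advection (first-order upwind, effluent accumulated at the base) and gas
displacement (replacement air cascading down during drainage; displaced
soil gas venting to the headspace during refill) follow the same water to
machine precision.

### Hydraulic parameters

The retention parameters and `K_sat` are free calibration choices,
documented in the preset files. Two observations pin them: the upland
column's early-drain outflow rate is about four times the thermokarst
column's, and volumetric water content stays above 50% at every sensor.
Both presets therefore use fairly fine-textured retention (α = 5/1.7 m⁻¹,
n = 1.7/1.5 organic/mineral for UC; α = 4/2.5 m⁻¹ for TC) with high residual
saturations, and `K_sat` values (UC 1.6 × 10⁻⁷ / 2.8 × 10⁻⁸ m/s organic /
mineral; TC exactly one quarter of each) whose 4:1 ratio is inherited by the
early-drain outflow because the mineral layer limits the path conductivity
in both columns. The upland column approaches its drained state in roughly
three weeks; the thermokarst column is still draining when its first phase
ends, which is the behaviour that motivated the experiment's longer TC
schedule.

## 2. Transport and phase exchange

Both phases diffuse with Millington–Quirk effective diffusivities
`D_eff = D₀ θ^{10/3}/n²`, one free-water diffusivity (10⁻⁹ m²/s) for all
solutes and one free-air diffusivity (1.6 × 10⁻⁵ m²/s) for all gases —
matching the single aqueous and gas diffusion coefficients manipulated in
the sensitivity scenarios. Diffusion is fully implicit — one factored
tridiagonal operator per phase per flow step, applied to every species of
that phase — conservative, and positivity-preserving. Gas-phase advection is neglected; a saturated cell
has zero gas-phase transport because `θ_a = 0` annihilates `D_eff`.

Volatiles partition instantaneously to Henry equilibrium with dimensionless
`K_cc = C_aq/C_gas` at 4 °C: CO2 1.30, O2 0.047, CH4 0.053
(literature-typical values; replaceable constants in the parameter file).
Only the dissolved-CO2 fraction of DIC exchanges, evaluated at the cell's
cached diagnostic pH — a standard operator-splitting approximation.
H2 is kept aqueous-only: it exists to couple fermentation to
hydrogenotrophic methanogenesis, and giving it a gas phase would add a
volatile the observations never constrain.

The soil–headspace interface uses a half-cell gradient: gas-side
`D_a,eff (C_top − C_hs)/(dz/2)` when the top cell is unsaturated, an
aqueous-film form when saturated (about four orders of magnitude slower,
which is why saturation throttles outgassing). Because the coupling is
stiff relative to the 600 s step when the surface is dry, the top-cell pool
is relaxed exponentially toward the (frozen) headspace concentration and
the transferred moles define the mean surface flux handed to the CSTR —
stable for any step size.

## 3. The reaction network

Nine reactions (R1–R9, listed in `?rate_vector`) connect four solid pools
(particulate and mineral-associated organic carbon, iron-oxide and
organically complexed Fe(III)) to nine aqueous species. Rates are Monod in
their substrates, all anaerobic pathways are suppressed by
`I(O2) = K_I/(K_I + [O2])` with `K_I = 10⁻⁶` M, and each reaction is scaled
by a static guild factor — aerobes, fermenters, iron reducers, iron
oxidisers, acetoclastic and hydrogenotrophic methanogens. Guilds do not
grow or die: over a 90-day experiment the community-composition data show
strong persistence of each core's starting community ("memory"), and static
multipliers encode exactly that. The UC preset carries methanogen factors
of 0.005 against the TC's 1.0 (the observed abundance contrast spans orders
of magnitude) and a modestly higher aerobe factor of 1.5.

Stoichiometry conserves carbon and iron exactly, counting organically
complexed Fe(III) as carrying `r_CFe = 2` mol bound C per mol Fe: reducing
that pool releases its carbon to the dissolved pools, fraction `f_L = 0.6`
labile and the rest aromatic. The labile/aromatic split of DOM exists so
the specific-UV-absorbance proxy (a DOC-weighted mean absorptivity, 1.0 vs
4.5 L mg⁻¹ m⁻¹) rises when labile DOM is preferentially consumed — the
direction the porewater measurements show.

### Kinetic constants

All kinetic constants are free calibration values; none is a measured
quantity. The defaults were chosen once, against four qualitative
behaviours of the experiment, and are recorded in
`inst/extdata/presets/reactions.yml`:

* `Vmax` aerobic = 3 × 10⁻⁸ mol L⁻¹ s⁻¹ and `k_hyd` = 2 × 10⁻⁹ s⁻¹ jointly
  set the drain-phase respiration rate (hydrolysis-limited at steady state)
  and make dissolved oxygen collapse within hours of re-saturation.
* Fermentation `Vmax` = 1.5 × 10⁻⁸ drives the saturation-phase accumulation
  of acetate and CO2 that acidifies the surface porewater.
* Iron reduction `Vmax` = 5 × 10⁻¹¹ (each pathway) keeps millimolar-scale
  Fe(II) accumulation over a 20-day saturation. The 8:1 Fe:acetate
  stoichiometry gives this constant enormous leverage on the charge
  balance: an order of magnitude more iron reduction drives the diagnostic
  pH alkaline, the opposite of the observed acidification, which is the
  model's way of reproducing the inference that iron reduction was not the
  dominant pH control.
* Fe(II) oxidation `k_ox` = 3 × 10⁻⁴ L mol⁻¹ s⁻¹ — slow, as appropriate for
  pH < 7 porewater at 4 °C — so the thermokarst column's dissolved iron
  stays ≥ 75% reduced through both drain phases while the upland ratio
  responds visibly to saturation.

Methanogenesis constants (2 × 10⁻⁹) leave the thermokarst column
substrate-limited rather than kinetics-saturated, one of the two regimes
consistent with the low simulated TC methane.

## 4. Diagnostic pH

pH is never integrated; it is recomputed from the charge balance
`[H⁺] + 2[Fe²⁺] + Z − [OH⁻] − [HCO₃⁻] − 2[CO₃²⁻] − [Ac⁻] − [A⁻] = 0`
with 25 °C constants (pK₁ 6.35, pK₂ 10.33, acetate pKa 4.76, pKw 14; the
4–25 °C correction is under 0.2 pH units and ignored). `Z` is the
conservative net cation charge, calibrated per layer so the initial pH hits
the measured porewater anchors (UC 6.4, TC 7.2 at 2 cm). The `[A⁻]` term is
a static organic weak-acid buffer (pKa 5.5; 20–45 mM by layer) representing
the high pH-buffering capacity of these organic-rich soils; without it,
CO2 degassing during drains would swing the diagnostic pH far alkaline of
anything a humic porewater does. The buffer defaults to zero in the
standalone solver (`solve_ph()`), whose contract is the bare
carbonate–acetate–iron balance.

The solved pH behaves as the experiment's surface porewater does: it falls
during saturation (CO2 and acetate accumulation out-running Fe(II)
production) and the thermokarst shift is smaller than the upland shift
(stronger buffering, and methanogens consuming the acetate). The drained
baseline for that comparison is the late first drain, immediately before
saturation: acetate produced under saturation has no aerobic sink in this
network, so it persists into the second drain and keeps the late-run pH
depressed.

## 5. The synthetic observation generator

`generate_bundle()` produces the package's stand-in for the experiment's
data streams. It is anchor-exact by design: printed observations — initial
and end-of-saturation porewater pH per depth, DOC rises of 374/400/103/86
mg/L and the 556 mg/L maximum, the −51/+44 µmol g⁻¹ organic-bound iron
transfer, depth-profile endpoints, the 140.8/33.9 µmol s⁻¹ m⁻² drain-phase
CO2 means and 234/87 maxima — are imposed after shape synthesis, by
noise-free control points or by an affine rescaling of the flux profiles,
so the analysis operations recover them exactly and independently of the
seed. Truncated lognormal-style noise (σ = 2%, cut at 2.5σ) perturbs only
non-anchor points. The flux maximum is held as a 3-day plateau, far longer
than five headspace residence times (V/Q = 100 min), so the quasi-steady
inversion can recover it; headspace samples come from exact forward CSTR
integration on a 7.2-minute grid.

What the generator does *not* emulate: ebullition (the methane pulses are
imposed shapes at days 35 and 80, not a bubble-transport model — the
simulation side has no ebullition either), sensor drift or calibration
error, vial storage artifacts, and any microbiome data. Gas sampling uses a
fixed 2-day grid and porewater a 7-day grid, regularising the experiment's
1–4-day and weekly cadences. Passing tests against these fixtures therefore
demonstrates that the machinery recovers what was put in — not that the
coupled simulation reproduces the experiment's magnitudes, which only the
trend-level comparisons (`compare_sim_to_obs()`) address.

## 6. Numerics

* Operator split: flow, solute advection, gas displacement and reactions
  advance on the outer 600 s step; the transport chain — diffusion in both
  phases, Henry equilibration and headspace exchange — cycles together on a
  fixed 100 s step inside it. The split *between* those operators, not any
  one of them, is the leading temporal error: interleaving them on the
  shorter cycle is what makes the export fluxes converge. The diffusion
  operator is factored once per outer step (the water content is constant
  between flow steps) and each cycle is a single matrix product over all
  species. Outputs archive every 6 simulated hours.
* The reaction integrator is an adaptive Heun scheme with a
  positivity pre-limit (step bounded by 45% of the fastest depletion time;
  pools are never clipped) and step-doubling error control. The single-cell
  contract (`integrate_reactions()`) defaults to a 10⁻⁶ relative
  tolerance; the column loop runs at 5 × 10⁻³ per step, where the split
  transport error dominates anyway.
* The charge balance is solved by vectorised bisection (52 iterations) in
  the column loop and by Brent plus a residual polish (< 10⁻¹² mol/L) in
  the standalone solver. Halving both time resolutions moves the
  cumulative CO2 export by under 1%, and halving the grid spacing by under
  2%, measured over a window containing the strongly transport-limited
  early drainage.
* Saturation events fill the column over two hours in substeps small
  enough that the wetting front's upwind advection respects its Courant
  bound; added water carries no solutes; displaced soil gas vents to the
  headspace.
* Sensitivity sweeps run 100-day horizons with the preset's phase plan
  cycled to fit. The packaged analyses use a 1200 s step and 12 h archives
  for sweeps — the convergence checks above justify the coarser step —
  and "cumulative" scenario responses are 0–100 d time integrals of the
  column inventories, because the base and fast-draining columns converge
  to the same drained state and instantaneous day-100 stocks differ only
  by noise. Test problem sizes follow the same logic: conservation and
  direction properties run on full 81/91-day base runs; convergence checks
  use 4–6-day windows that contain the relevant transition.

## 7. Design decisions on genuinely open points

* **Flow solver.** A Picard-iterated implicit Richards solver was the
  obvious alternative; the sharp-interface model was chosen for exact
  conservation and monotonicity in `K_sat` (section 1). Both modes the
  study needs — gravity drainage and measured-outflow forcing — fall out
  of one storage-inversion mechanism.
* **Drain-phase averages** pool both drain phases, weighting each retained
  sample equally (sample-weighted, not time-weighted); a sample on a phase
  boundary belongs to the phase that ends there. The fixture generator
  enforces the same convention, so the printed means are recovered exactly.
* **"Free DOM"** is reported as the column-integrated dissolved labile +
  aromatic DOM (not sorbed, not acetate), and sweep responses are extracted
  as column integrals rather than at a single depth.
* **Which species share `D_w`**: all aqueous solutes, volatile or not.
* **Fermentation stoichiometry** follows the acetogenic glucose template
  (per 6 C: 2 acetate + 2 CO2 + 4 H2).
* **Aqueous ferric iron** exists only as an organically complexed pool fed
  by the `f_aq = 0.1` fraction of Fe(II) oxidation, so the measured
  Fe(II)/Fe_total ratio can sit below one; there is no ferric hydrolysis
  speciation.

## 8. Known limitations

* The thermokarst simulation accumulates a saturation-phase DOC rise of
  similar shape to the upland column's, because hydrolysis is not
  preset-specific; the experiment saw no TC rise. Differentiating the
  labile-carbon inventories of the two cores would require data the study
  does not print.
* Simulated CO2 fluxes are of order 1–3 µmol s⁻¹ m⁻² — physically ordinary
  for organic soils but two orders below the experiment's unusually large
  chamber values; only flux *trends* (drain vs saturation, UC vs TC,
  correlation with saturation) are meaningful comparisons, and the
  magnitude anchors are carried by the fixture path instead.
* No ebullition, no methanotrophy, no nitrogen or sulfur redox, no
  temperature dependence, no vegetation or lateral flow.
* The static-guild assumption means no community adaptation; runs much
  longer than the experiment's three months would leave its domain of
  validity.
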