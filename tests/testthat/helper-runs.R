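# Shared expensive simulation runs, computed once per test session.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

base_run <- function(preset) {
  cached_run(paste0("base_", preset), run_experiment(preset))
}

uc_bundle <- function(seed = 42) {
  cached_run(paste0("bundle_UC_", seed), generate_bundle("UC", seed = seed))
}

tc_bundle <- function(seed = 42) {
  cached_run(paste0("bundle_TC_", seed), generate_bundle("TC", seed = seed))
}

# A two-cell single-layer column variant for toy transport problems.
two_cell_column <- function(porosity = 0.6, S_l = 0.5) {
  preset <- load_preset("UC")
  preset$geometry$n_cells <- 2
  preset$geometry$soil_depth <- 0.02
  preset$layers[[1]]$z_bot <- 0.01
  preset$layers[[2]]$z_top <- 0.01
  preset$layers[[2]]$z_bot <- 0.02
  preset$layers[[1]]$porosity <- porosity
  preset$layers[[2]]$porosity <- porosity
  col <- build_column(preset)
  col$state$S_l <- rep(S_l, 2)
  col
}

# A single representative cell for reaction-network tests.
toy_cell <- function(guilds = c(aerobe = 1, fermenter = 1, Fe_reducer = 1,
                                Fe_oxidizer = 1, ac_methanogen = 1,
                                h2_methanogen = 1)) {
  list(
    aq = c(O2aq = 2e-4, DOM_L = 2e-3, DOM_A = 4e-3, acetate = 1e-4,
           H2 = 1e-8, Fe2 = 1e-4, Fe3aq = 1e-5, CH4aq = 1e-6, DIC = 2e-3),
    sol = c(POC = 0.02, MAOC = 0.004, FeIII_oxide = 3e-5, FeIII_OM = 8e-5),
    conv = 300,
    guilds = guilds)
}

# Total carbon and iron of a toy cell (aqueous mol/L + solids converted to
# the same units), for stoichiometric conservation checks.
cell_totals <- function(cell, r_CFe = 2) {
  aq <- cell$aq; sol <- cell$sol
  C <- aq[["DOM_L"]] + aq[["DOM_A"]] + 2 * aq[["acetate"]] + aq[["DIC"]] +
    aq[["CH4aq"]] +
    (sol[["POC"]] + sol[["MAOC"]] + r_CFe * sol[["FeIII_OM"]]) * cell$conv
  Fe <- aq[["Fe2"]] + aq[["Fe3aq"]] +
    (sol[["FeIII_oxide"]] + sol[["FeIII_OM"]]) * cell$conv
  c(C = C, Fe = Fe)
}
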