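# Full-column integration behaviour.  The 90-day base runs are shared
# through helper-runs.R; shorter horizons are used where the property only
# needs a drain or a transition.

test_that("a lifeless column moves water but no chemistry", {
  col <- build_column("UC")
  col$cells$guilds[] <- 0
  col$params$kinetics$k_hyd <- 0
  col$params$kinetics$k_att <- 0
  col$params$kinetics$k_det <- 0
  col$params$kinetics$k_ox <- 0
  ## uniform chemistry, no gradients: only water should change
  col$state$aq[] <- rep(colMeans(col$state$aq), each = 50)
  col$state$aq[, c("O2aq", "CH4aq", "DIC")] <- 0   # no volatiles to exchange
  res <- run_experiment(col, horizon_days = 2)
  prof <- tidyr::pivot_wider(res$profiles, names_from = "variable",
                             values_from = "value")
  expect_lt(max(abs(prof$Fe2 - prof$Fe2[1])), 1e-12)
  expect_lt(max(abs(prof$DOM_L - prof$DOM_L[1])), 1e-12)
  expect_gt(max(res$outflow$cumulative_outflow_mL), 0)
})

test_that("identical configuration and seed reproduce bit-identical results", {
  a <- run_experiment("UC", horizon_days = 1.5, seed = 4)
  b <- run_experiment("UC", horizon_days = 1.5, seed = 4)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$fluxes, b$fluxes)
  expect_identical(a$mass_balance, b$mass_balance)
})

test_that("full runs close carbon, iron and water ledgers within 0.5%", {
  for (preset in c("UC", "TC")) {
    mb <- base_run(preset)$mass_balance
    expect_lt(max(abs(mb$closure)), 0.005)
  }
})

test_that("drain-phase CO2 outgassing beats the saturated phase, UC beats TC", {
  drain_sat <- function(res) {
    co2 <- dplyr::filter(res$fluxes, .data$gas == "CO2")
    kind <- redoxcolumn:::phase_of(co2$time_days, res$plan)
    c(drain = mean(co2$flux_umol_per_s_per_m2[kind == "drain"]),
      sat = mean(co2$flux_umol_per_s_per_m2[kind == "saturate"]))
  }
  uc <- drain_sat(base_run("UC"))
  tc <- drain_sat(base_run("TC"))
  expect_gt(uc[["drain"]], uc[["sat"]])
  expect_gt(tc[["drain"]], tc[["sat"]])
  expect_gt(uc[["drain"]], tc[["drain"]])
})

test_that("oxygen collapses within hours of re-saturation, faster with aerobes", {
  expect_lte(o2_consumption_check(base_run("UC")), 12)
  ## an abiotic column never depletes
  col <- build_column("UC")
  col$cells$guilds[] <- 0
  res <- cached_run("abiotic_uc",
                    run_experiment(col, plan = list(
                      phases = tibble::tibble(
                        kind = c("drain", "saturate"),
                        duration_days = c(2, 2),
                        t_start = c(0, 2), t_end = c(2, 4)),
                      water_addition_hours = 2)))
  expect_equal(o2_consumption_check(res), Inf)
})

test_that("saturation lowers surface porewater pH below the drained baseline", {
  shift_2cm <- function(res) {
    ph <- dplyr::filter(res$profiles, .data$variable == "pH",
                        .data$depth_cm == 2.5)
    sat <- res$plan$phases[res$plan$phases$kind == "saturate", ][1, ]
    drained <- mean(ph$value[ph$time_days > sat$t_start - 5 &
                               ph$time_days <= sat$t_start])
    late_sat <- mean(ph$value[ph$time_days > sat$t_end - 5 &
                                ph$time_days <= sat$t_end])
    drained - late_sat
  }
  uc <- shift_2cm(base_run("UC"))
  tc <- shift_2cm(base_run("TC"))
  expect_gt(uc, 0)
  expect_gt(tc, 0)
  expect_lt(tc, uc)    # thermokarst responds more subtly
})

test_that("thermokarst porewater iron stays at least 75% reduced in simulation", {
  res <- base_run("TC")
  w <- tidyr::pivot_wider(
    dplyr::filter(res$profiles, .data$variable %in% c("Fe2", "Fe3aq")),
    names_from = "variable", values_from = "value")
  w <- dplyr::filter(w, .data$depth_cm %in% c(2.5, 12.5, 22.5, 32.5, 42.5))
  expect_gte(min(100 * w$Fe2 / (w$Fe2 + w$Fe3aq)), 75)
})

test_that("upland VWC stays above 50% at every sensor through the run", {
  v <- base_run("UC")$vwc
  expect_gt(min(v$vwc), 0.5)
})

test_that("scenario sweeps include the base case and a unit multiplier is a no-op", {
  sw <- cached_run("mini_sweep",
                   sensitivity_sweep("UC", "ksat10", horizon_days = 4,
                                     dt = 1200, archive_hours = 12))
  expect_setequal(unique(sw$responses$scenario), c("base", "ksat10"))
  ## a multiplier of one duplicates the base case bit-for-bit
  col_a <- build_column("UC")
  col_b <- redoxcolumn:::apply_scenario(build_column("UC"),
                                        list(name = "dup", m_Ksat = 1,
                                             porosity = NULL, m_Da = 1,
                                             m_Dw = 1))
  ra <- run_experiment(col_a, horizon_days = 1.5)
  rb <- run_experiment(col_b, horizon_days = 1.5)
  expect_identical(ra$profiles, rb$profiles)
})

test_that("faster-draining columns hold less water at every archive time", {
  sw <- cached_run("mini_sweep",
                   sensitivity_sweep("UC", "ksat10", horizon_days = 4,
                                     dt = 1200, archive_hours = 12))
  r <- sw$responses
  base <- dplyr::filter(r, .data$scenario == "base")
  k10 <- dplyr::filter(r, .data$scenario == "ksat10")
  expect_true(all(k10$liquid_saturation <= base$liquid_saturation + 1e-9))
})

test_that("doubling gas diffusivity increases cumulative oxygen invasion", {
  invasion <- function(sc) {
    col <- redoxcolumn:::apply_scenario(build_column("UC"), sc)
    res <- run_experiment(col, horizon_days = 4, dt = 1200,
                          archive_hours = 12)
    o2 <- dplyr::filter(res$profiles, .data$variable == "O2aq")
    sum(o2$value)
  }
  base <- invasion(list(name = "base", m_Ksat = 1, porosity = NULL,
                        m_Da = 1, m_Dw = 1))
  up <- invasion(list(name = "diff2", m_Ksat = 1, porosity = NULL,
                      m_Da = 2, m_Dw = 2))
  dn <- invasion(list(name = "diff05", m_Ksat = 1, porosity = NULL,
                      m_Da = 0.5, m_Dw = 0.5))
  expect_gt(up, base)
  expect_lt(dn, base)
})

test_that("halving the temporal resolution barely moves cumulative CO2 export", {
  ## both the outer step and the transport cycle halve together
  cum_co2 <- function(dt, tdt) {
    res <- run_experiment("UC", horizon_days = 6, dt = dt,
                          transport_dt = tdt)
    res$final_state$hs_export[["CO2"]] - res$final_state$hs_import[["CO2"]]
  }
  a <- cum_co2(600, 100)
  b <- cum_co2(300, 50)
  expect_lt(abs(a - b) / abs(b), 0.01)
})

test_that("halving the grid spacing barely moves cumulative CO2 export", {
  cum_co2_n <- function(n_cells) {
    p <- load_preset("UC")
    p$geometry$n_cells <- n_cells
    res <- run_experiment(build_column(p), horizon_days = 4)
    res$final_state$hs_export[["CO2"]] - res$final_state$hs_import[["CO2"]]
  }
  a <- cum_co2_n(50)
  b <- cum_co2_n(100)
  expect_lt(abs(a - b) / abs(b), 0.02)
})

test_that("prescribed-outflow runs honour the supplied drainage record", {
  os <- tibble::tibble(time_days = c(0, 1, 2, 40),
                       cumulative_outflow_mL = c(0, 60, 100, 100))
  res <- run_experiment("UC", flow_mode = "prescribed_outflow",
                        outflow_series = os, horizon_days = 2)
  got <- approx(res$outflow$time_days, res$outflow$cumulative_outflow_mL,
                xout = c(1, 2))$y
  expect_equal(got, c(60, 100), tolerance = 1e-6)
})

test_that("simulated CO2 flux tracks the fixture's trend", {
  res <- base_run("UC")
  cmp <- compare_sim_to_obs(res, uc_bundle())
  expect_gt(cmp$spearman_rho[cmp$variable == "co2_flux"], 0)
})

test_that("tidiers expose the result surfaces", {
  res <- cached_run("short_uc", run_experiment("UC", horizon_days = 2))
  td <- tidy(res)
  expect_true(all(c("time_days", "depth_cm", "variable", "value") %in%
                    names(td)))
  gl <- glance(res)
  expect_equal(gl$preset, "UC")
  expect_lt(gl$worst_closure, 0.005)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  sw <- cached_run("mini_sweep",
                   sensitivity_sweep("UC", "ksat10", horizon_days = 4,
                                     dt = 1200, archive_hours = 12))
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(plot_fluxes(res), "ggplot")
})
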