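test_that("porewater pH anchors are hit exactly", {
  uc <- uc_bundle()
  pw <- uc$porewater
  pt <- redoxcolumn:::porewater_times(uc$plan)
  at <- function(d, t) pw$pH[pw$depth_cm == d & pw$time_days == t]
  expect_identical(at(2, 0), 6.4)
  expect_identical(at(12, 0), 6.3)
  expect_identical(at(2, pt$last_sat), 4.6)
  expect_identical(at(12, pt$last_sat), 4.4)

  tc <- tc_bundle()
  ptc <- redoxcolumn:::porewater_times(tc$plan)
  atc <- function(d, t) tc$porewater$pH[tc$porewater$depth_cm == d &
                                          tc$porewater$time_days == t]
  expect_identical(atc(2, 0), 7.2)
  expect_identical(atc(12, 0), 6.7)
  expect_identical(atc(2, ptc$last_sat), 6.0)
  expect_identical(atc(12, ptc$last_sat), 5.85)
})

test_that("thermokarst porewater iron stays at least 75% reduced, any seed", {
  for (seed in c(1, 42, 77, 2024)) {
    b <- generate_bundle("TC", seed = seed)
    expect_gte(min(b$porewater$fe2_ratio), 0.75)
    expect_true(all(b$porewater$fe2_ratio <= 1))
  }
})

test_that("DOC anchors: rises, initial range, and the 556 mg/L maximum", {
  uc <- uc_bundle()
  plan <- uc$plan
  for (d in c(2, 12, 22, 32)) {
    rise <- doc_increase(uc$porewater, plan, d)
    expect_equal(rise, c(`2` = 374, `12` = 400, `22` = 103, `32` = 86)[[as.character(d)]])
  }
  expect_equal(max(uc$porewater$doc_mg_L), 556)
  init <- uc$porewater$doc_mg_L[uc$porewater$time_days == 0]
  expect_true(all(init >= 95 & init <= 131))

  tc <- tc_bundle()
  for (d in c(2, 12, 22, 32, 42)) {
    expect_lt(abs(doc_increase(tc$porewater, tc$plan, d)), 15)
  }
})

test_that("iron extraction tables encode the organic-bound transfer", {
  fe <- generate_fe_extractions("UC")
  d <- iron_redistribution(fe$pre, fe$post)$delta
  get <- function(l, p) d$delta_umol_fe_per_g[d$layer == l & d$pool == p]
  expect_identical(get("org", "organic_bound"), -51)
  expect_identical(get("min", "organic_bound"), 44)
  expect_true(all(d$delta_umol_fe_per_g[d$pool != "organic_bound"] == 0))
  fe_tc <- generate_fe_extractions("TC")
  d_tc <- iron_redistribution(fe_tc$pre, fe_tc$post)$delta
  expect_true(all(d_tc$delta_umol_fe_per_g == 0))
})

test_that("depth profiles hit the printed endpoints and iron contrast", {
  uc <- generate_depth_profiles("UC", seed = 42)
  tc <- generate_depth_profiles("TC", seed = 42)
  expect_equal(uc$theta_g[1], 5.37)
  expect_equal(uc$theta_g[nrow(uc)], 0.95)
  expect_equal(tc$theta_g[1], 7.67)
  expect_equal(tc$theta_g[nrow(tc)], 0.77)
  expect_equal(uc$pct_C[c(1, nrow(uc))], c(48, 15))
  expect_equal(tc$pct_C[c(1, nrow(tc))], c(32, 18))
  expect_equal(uc$CN[c(1, nrow(uc))], c(44, 24))
  top30 <- uc$depth_cm < 30
  ratio <- tc$fe2_KCl_umol_g[top30] / uc$fe2_KCl_umol_g[top30]
  expect_true(all(ratio >= 6 & ratio <= 10))
})

test_that("flux fixtures carry the drain-mean and maximum anchors exactly", {
  uc <- uc_bundle()
  co2 <- dplyr::filter(uc$true_flux, gas == "CO2")
  kind <- redoxcolumn:::phase_of(co2$time_days, uc$plan)
  expect_equal(mean(co2$flux_umol_per_s_per_m2[kind == "drain"]), 140.8,
               tolerance = 1e-10)
  expect_equal(max(co2$flux_umol_per_s_per_m2), 234, tolerance = 1e-10)
  expect_true(all(co2$flux_umol_per_s_per_m2 >= 0))
  ## saturation-phase fluxes sit well below the drain mean
  expect_lt(mean(co2$flux_umol_per_s_per_m2[kind == "saturate"]), 140.8 / 2)

  tc <- tc_bundle()
  co2t <- dplyr::filter(tc$true_flux, gas == "CO2")
  kindt <- redoxcolumn:::phase_of(co2t$time_days, tc$plan)
  expect_equal(mean(co2t$flux_umol_per_s_per_m2[kindt == "drain"]), 33.9,
               tolerance = 1e-10)
  expect_equal(max(co2t$flux_umol_per_s_per_m2), 87, tolerance = 1e-10)
})

test_that("thermokarst methane pulses sit near days 35 and 80", {
  tc <- tc_bundle()
  ch4 <- dplyr::filter(tc$true_flux, gas == "CH4")
  v <- ch4$flux_umol_per_s_per_m2
  peak1 <- ch4$time_days[which.max(v * (ch4$time_days < 60))]
  peak2 <- ch4$time_days[which.max(v * (ch4$time_days >= 60))]
  expect_lt(abs(peak1 - 35), 2.5)
  expect_lt(abs(peak2 - 80), 2.5)
  ## only trace methane from the upland column
  uc <- uc_bundle()
  ch4u <- dplyr::filter(uc$true_flux, gas == "CH4")
  expect_lt(max(ch4u$flux_umol_per_s_per_m2), 0.1)
})

test_that("a zero-flux profile leaves the headspace at inflow air", {
  hs <- new_headspace()
  plan <- phase_plan(load_preset("UC"))
  spec <- list(CO2 = list(
    controls = cbind(c(0, 81), c(0, 0)), plateau = NULL,
    drain_mean = NULL, run_max = NULL))
  out <- generate_flux_and_headspace(spec, hs, seq(0, 80, 2), plan, seed = 1)
  expect_equal(out$headspace_samples$concentration_ppmv,
               rep(hs$C_in[["CO2"]] / 43.96 * 1e6, 41), tolerance = 1e-10)
})

test_that("infeasible flux targets are rejected", {
  hs <- new_headspace()
  plan <- phase_plan(load_preset("UC"))
  spec <- list(CO2 = list(controls = cbind(c(0, 81), c(1, 1)), plateau = NULL,
                          drain_mean = 100, run_max = 50))
  expect_error(generate_flux_and_headspace(spec, hs, seq(0, 80, 2), plan, 1),
               "infeasible")
})

test_that("bundles are deterministic per seed and vary off-anchor", {
  a <- generate_bundle("UC", seed = 7)
  b <- generate_bundle("UC", seed = 7)
  expect_identical(a, b)
  c <- generate_bundle("UC", seed = 8)
  ## anchors shared, non-anchor points differ
  expect_false(identical(a$porewater$doc_mg_L, c$porewater$doc_mg_L))
  pt <- redoxcolumn:::porewater_times(a$plan)
  expect_identical(
    a$porewater$pH[a$porewater$time_days %in% c(0, pt$last_sat)],
    c$porewater$pH[c$porewater$time_days %in% c(0, pt$last_sat)])
})

test_that("bundle invariants: monotone outflow, fractions in range", {
  for (b in list(uc_bundle(), tc_bundle())) {
    expect_true(all(diff(b$outflow$cumulative_outflow_mL) >= 0))
    expect_true(all(b$porewater$fe2_ratio >= 0 & b$porewater$fe2_ratio <= 1))
    expect_true(all(b$vwc$vwc > 0 & b$vwc$vwc < 1))
    expect_true(all(b$o2$o2_pct >= 0 & b$o2$o2_pct <= 25))
  }
})
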