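test_that("the CSTR holds steady states and follows the exact exponential", {
  hs <- new_headspace()
  expect_equal(hs$V / hs$Q / 60, 100, tolerance = 1e-10)  # residence, min
  ## no flux at inflow composition: unchanged
  hs2 <- cstr_step(hs, c(CO2 = 0, CH4 = 0, O2 = 0), 3600)
  expect_equal(hs2$C, hs$C)
  ## constant flux: C converges to C_in + F A / Q
  F <- c(CO2 = 1e-5)
  hs3 <- hs
  for (i in 1:200) hs3 <- cstr_step(hs3, F, 600)   # ~20 residence times
  expect_equal(hs3$C[["CO2"]], hs$C_in[["CO2"]] + 1e-5 * hs$A / hs$Q,
               tolerance = 1e-6)
  ## one big exact step equals many small ones
  hs4 <- cstr_step(hs, F, 200 * 600)
  expect_equal(hs4$C[["CO2"]], hs3$C[["CO2"]], tolerance = 1e-12)
})

test_that("headspace mass balance closes for arbitrary flux profiles", {
  hs <- new_headspace()
  set.seed(3)
  dt <- 300
  flux_in <- 0; purge_out <- 0; purge_in <- 0
  stored0 <- hs$C[["CO2"]] * hs$V
  for (i in 1:500) {
    F <- c(CO2 = 1e-5 * abs(sin(i / 30)) + 1e-6 * stats::runif(1))
    C0 <- hs$C[["CO2"]]
    hs1 <- cstr_step(hs, F, dt)
    ## exact purge integral over the step for this linear ODE
    C_ss <- hs$C_in[["CO2"]] + F[["CO2"]] * hs$A / hs$Q
    int_C <- C_ss * dt + (C0 - C_ss) * hs$V / hs$Q *
      (1 - exp(-hs$Q * dt / hs$V))
    purge_out <- purge_out + hs$Q * int_C
    purge_in <- purge_in + hs$Q * hs$C_in[["CO2"]] * dt
    flux_in <- flux_in + F[["CO2"]] * hs$A * dt
    hs <- hs1
  }
  stored1 <- hs$C[["CO2"]] * hs$V
  expect_equal(stored1 - stored0, flux_in + purge_in - purge_out,
               tolerance = 1e-6 * max(1e-12, purge_out))
})

test_that("surface exchange is zero at equal concentrations and scales with D_a", {
  col <- build_column("UC")
  st <- col$state
  st$S_l <- rep(0.6, 50)
  st$pH <- rep(6.4, 50)
  ## equal concentrations: no flux
  st$gas[] <- rep(st$headspace$C, each = 50)
  f0 <- surface_exchange(col, st)
  expect_equal(unname(f0), c(0, 0, 0))
  ## contrast: flux linear in the gradient and in D_a
  st$gas[1, "CO2"] <- st$headspace$C[["CO2"]] + 1
  f1 <- surface_exchange(col, st)
  col2 <- col
  col2$params$transport$f_Da <- 2
  f2 <- surface_exchange(col2, st)
  expect_equal(f2[["CO2"]], 2 * f1[["CO2"]], tolerance = 1e-12)
  ## saturated top cell: aqueous film, at least 100x slower at a matched
  ## equivalent contrast
  stw <- st
  stw$S_l <- rep(1, 50)
  kcc <- col$params$transport$henry$CO2
  stw$aq[1, "DIC"] <- (st$headspace$C[["CO2"]] + 1) * kcc / 1000 /
    0.4418                             # approximate CO2* fraction at pH 6.4
  fw <- surface_exchange(col, stw)
  expect_lt(abs(fw[["CO2"]]), abs(f1[["CO2"]]) / 100)
})

test_that("quasi-steady inversion matches the direct arithmetic example", {
  hs <- new_headspace(Q = 8.3333e-8, A = 4.4179e-3)
  samples <- tibble::tibble(time_days = c(0, 2),
                            concentration = hs$C_in[[1]] + c(1, 1))
  fl <- invert_flux(samples, hs, gas = "O2")
  expect_equal(fl$flux_umol_per_s_per_m2,
               rep(18.86, 2), tolerance = 1e-3)
})

test_that("inversion of a forward CSTR run recovers a held flux", {
  hs <- new_headspace()
  F_true <- 2.5e-5                      # mol/m^2/s
  hs2 <- cstr_step(hs, c(CO2 = F_true), 10 * hs$V / hs$Q)  # 10 residences
  samples <- tibble::tibble(
    time_days = c(0, 10 * hs$V / hs$Q / 86400),
    concentration = c(hs$C[["CO2"]], hs2$C[["CO2"]]))
  fl <- invert_flux(samples, hs, gas = "CO2")
  expect_equal(fl$flux_umol_per_s_per_m2[2], F_true * 1e6,
               tolerance = 1e-3 * F_true * 1e6)
  ## transient mode nails a piecewise-constant profile even mid-transient
  t3 <- c(0, 1, 2, 3, 4) * 5 * hs$V / hs$Q / 86400
  hs3 <- hs
  conc <- hs$C[["CO2"]]
  for (i in 2:5) {
    hs3 <- cstr_step(hs3, c(CO2 = F_true), diff(t3 * 86400)[i - 1])
    conc <- c(conc, hs3$C[["CO2"]])
  }
  fl3 <- invert_flux(tibble::tibble(time_days = t3, concentration = conc),
                     hs, gas = "CO2", mode = "quasi_steady")
  expect_equal(fl3$flux_umol_per_s_per_m2[5], F_true * 1e6,
               tolerance = 0.01 * F_true * 1e6)
})

test_that("inversion validates its inputs", {
  hs <- new_headspace()
  expect_error(invert_flux(tibble::tibble(time_days = 1,
                                          concentration = 1), hs, gas = "CO2"),
               "two samples")
  expect_error(invert_flux(tibble::tibble(time_days = c(1, 1),
                                          concentration = c(1, 2)),
                           hs, gas = "CO2"),
               "strictly increasing")
})
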