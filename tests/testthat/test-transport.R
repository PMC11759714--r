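test_that("Millington-Quirk effective diffusivity follows the closed form", {
  expect_equal(effective_diffusivity(1e-9, 0, 0.6), 0)
  n <- 0.6
  expect_equal(effective_diffusivity(1e-9, n, n), 1e-9 * n^(4 / 3))
  expect_equal(effective_diffusivity(1e-9, 0.3, 0.6),
               1e-9 * 0.3^(10 / 3) / 0.36)
})

test_that("diffusion preserves uniform profiles and interior mass", {
  col <- build_column("UC")
  st <- col$state
  st$S_l <- rep(0.8, 50)
  st$aq[] <- rep(colMeans(st$aq), each = 50)   # uniform per species
  st2 <- diffuse(col, st, 3600, "aqueous")
  expect_equal(st2$aq, st$aq, tolerance = 1e-12)
  ## non-uniform: mass conserved
  st$aq[1:10, "Fe2"] <- 5e-4
  Vw <- col$cells$porosity * st$S_l
  m0 <- sum(st$aq[, "Fe2"] * Vw)
  st3 <- diffuse(col, st, 86400, "aqueous")
  expect_equal(sum(st3$aq[, "Fe2"] * Vw), m0, tolerance = 1e-12)
  expect_true(all(st3$aq >= 0))
  ## gradient relaxes toward uniform
  expect_lt(diff(range(st3$aq[, "Fe2"])), diff(range(st$aq[, "Fe2"])))
})

test_that("a saturated column supports no gas-phase transport", {
  col <- build_column("UC")
  st <- col$state                      # fully saturated
  st$gas[1:5, "CO2"] <- 1
  st2 <- diffuse(col, st, 86400, "gas")
  expect_equal(st2$gas, st$gas)
})

test_that("two-box diffusion matches the analytic exponential equilibration", {
  col <- two_cell_column(porosity = 0.6, S_l = 1)
  st <- col$state
  st$aq[, "Fe2"] <- c(1e-3, 0)
  dz <- col$geometry$dz
  theta <- col$cells$porosity * st$S_l
  Deff <- effective_diffusivity(col$params$transport$D_w0, theta[1],
                                col$cells$porosity[1])
  ## two equal boxes: theta dz dC1/dt = -Deff (C1 - C2) / dz, so the
  ## difference decays with rate constant lambda = 2 Deff / (theta dz^2)
  lambda <- 2 * Deff / (theta[1] * dz^2)
  t_end <- 5 / lambda
  n_steps <- 400
  for (i in 1:n_steps) st <- diffuse(col, st, t_end / n_steps, "aqueous")
  mean_c <- 5e-4
  exact <- mean_c + (1e-3 - mean_c) * exp(-lambda * t_end)
  expect_equal(unname(st$aq[1, "Fe2"]), exact, tolerance = 0.01)
  expect_equal(unname(st$aq[1, "Fe2"] + st$aq[2, "Fe2"]), 1e-3,
               tolerance = 1e-12)
})

test_that("upwind advection moves solute downward and conserves mass", {
  col <- build_column("UC")
  st <- col$state
  st$aq[] <- 0
  st$aq[1, "Fe2"] <- 1e-3
  theta_old <- col$cells$porosity * st$S_l
  cell_L <- col$geometry$dz * col$geometry$area * 1000
  total0 <- sum(st$aq[, "Fe2"] * theta_old * cell_L)
  ## steady through-flow: 10% of a cell's water per step at every
  ## interface; the top influx carries zero solutes
  fx <- rep(0.1 * theta_old[1] * col$geometry$dz * col$geometry$area, 51)
  centroid <- function(s) sum(seq_len(50) * s$aq[, "Fe2"]) / sum(s$aq[, "Fe2"])
  c0 <- centroid(st)
  for (i in 1:20) st <- advect(col, st, fx, theta_old)
  expect_gt(centroid(st), c0)
  total1 <- sum(st$aq[, "Fe2"] * theta_old * cell_L) +
    st$effluent[["Fe2"]]
  expect_equal(total1, total0, tolerance = 1e-10)
  ## zero flux: identity
  st2 <- advect(col, st, numeric(51), theta_old)
  expect_equal(st2$aq, st$aq)
  ## Courant violation is refused with a sub-step suggestion
  bad <- rep(2 * theta_old[1] * col$geometry$dz * col$geometry$area, 51)
  expect_error(advect(col, st, bad, theta_old), "Courant")
})

test_that("Henry equilibration conserves moles and hits the partition ratio", {
  col <- two_cell_column(porosity = 0.6, S_l = 0.5)
  col$params$transport$henry$CH4 <- 1.0
  st <- col$state
  st$aq[, "CH4aq"] <- 2e-4
  st$gas[, "CH4"] <- 0
  st$pH <- c(7, 7)
  theta_w <- col$cells$porosity * st$S_l
  theta_a <- col$cells$porosity * (1 - st$S_l)
  tot0 <- st$aq[1, "CH4aq"] * 1000 * theta_w[1] + st$gas[1, "CH4"] * theta_a[1]
  st2 <- equilibrate_phases(col, st)
  ## K_cc = 1 with equal phase volumes: equal concentrations, half the
  ## mass in each phase
  expect_equal(unname(st2$aq[1, "CH4aq"] * 1000),
               unname(st2$gas[1, "CH4"]))
  expect_equal(unname(st2$aq[1, "CH4aq"] * 1000 * theta_w[1]),
               unname(st2$gas[1, "CH4"] * theta_a[1]))
  tot1 <- st2$aq[1, "CH4aq"] * 1000 * theta_w[1] + st2$gas[1, "CH4"] * theta_a[1]
  expect_equal(tot1, tot0, tolerance = 1e-12)
  ## idempotent once at equilibrium
  st3 <- equilibrate_phases(col, st2)
  expect_equal(st3$aq[, "CH4aq"], st2$aq[, "CH4aq"], tolerance = 1e-12)
  ## saturated cell: all mass aqueous
  st$S_l <- c(1, 1)
  st$gas[, "CH4"] <- 0.5
  st4 <- equilibrate_phases(col, st)
  expect_equal(st4$gas[, "CH4"], c(0, 0))
})
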