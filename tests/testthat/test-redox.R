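k_params <- load_reaction_params()$kinetics

test_that("rates vanish without substrates and follow Monod algebra", {
  cell <- toy_cell()
  cell$aq["O2aq"] <- 0
  r <- rate_vector(cell, k_params)
  expect_equal(r[["R3"]], 0)
  expect_equal(r[["R7"]], 0)
  ## strong oxygen inhibits every anaerobic pathway
  cell$aq["O2aq"] <- 1
  r <- rate_vector(cell, k_params)
  for (rx in c("R4", "R5", "R6", "R8", "R9")) {
    expect_lt(r[[rx]], 1e-6 * k_params$Vmax_R4)
  }
  ## half-saturation product: R3 = Vmax * guild / 4
  cell <- toy_cell(guilds = c(aerobe = 2, fermenter = 0, Fe_reducer = 0,
                              Fe_oxidizer = 0, ac_methanogen = 0,
                              h2_methanogen = 0))
  cell$aq["DOM_L"] <- k_params$K_DOM
  cell$aq["O2aq"] <- k_params$K_O2
  r <- rate_vector(cell, k_params)
  expect_equal(r[["R3"]], k_params$Vmax_R3 * 2 / 4)
  expect_true(all(r >= 0 | names(r) == "R2"))
})

test_that("hydrolysis-only integration matches exponential decay", {
  k0 <- k_params
  for (nm in grep("^Vmax|^k_", names(k0), value = TRUE)) k0[[nm]] <- 0
  k0$k_hyd <- 1e-7
  cell <- toy_cell()
  out <- integrate_reactions(cell, dt = 1e5, params = k0)
  expect_equal(out$sol[["POC"]] / cell$sol[["POC"]], exp(-0.01),
               tolerance = 1e-8)
  ## released carbon lands in DOM_L, conserving total C
  expect_equal(cell_totals(out, k0$r_CFe), cell_totals(cell, k0$r_CFe),
               tolerance = 1e-12)
})

test_that("all-zero rates give the identity", {
  k0 <- k_params
  for (nm in grep("^Vmax|^k_", names(k0), value = TRUE)) k0[[nm]] <- 0
  cell <- toy_cell()
  out <- integrate_reactions(cell, dt = 1e6, params = k0)
  expect_equal(out$aq, cell$aq)
  expect_equal(out$sol, cell$sol)
})

test_that("stoichiometry conserves carbon and iron for random states", {
  set.seed(7)
  for (i in 1:25) {
    cell <- toy_cell()
    cell$aq <- cell$aq * stats::runif(9, 0.1, 10)
    cell$sol <- cell$sol * stats::runif(4, 0.1, 10)
    out <- integrate_reactions(cell, dt = 3600, params = k_params)
    expect_equal(cell_totals(out), cell_totals(cell), tolerance = 1e-9)
    expect_true(all(out$aq >= 0) && all(out$sol >= 0))
  }
})

test_that("adaptive integration agrees with a fine-step explicit oracle", {
  cell <- toy_cell()
  dt_big <- 600
  hours <- 12
  out <- cell
  for (i in seq_len(hours * 6)) {
    out <- integrate_reactions(out, dt = dt_big, params = k_params)
  }
  ## explicit Euler oracle at a 0.25 s step (independent of the Heun path)
  aq <- rbind(unname(cell$aq)); sol <- rbind(unname(cell$sol))
  h <- 0.25
  g <- rbind(unname(cell$guilds))
  for (i in seq_len(hours * 3600 / h)) {
    d <- redoxcolumn:::derivs_fast(aq, sol, cell$conv, g, k_params)
    aq <- aq + h * d$aq
    sol <- sol + h * d$sol
  }
  scale <- pmax(abs(aq), 1e-7)
  expect_lt(max(abs(out$aq - aq) / scale), 0.005)
  expect_lt(max(abs(out$sol - sol) / pmax(abs(sol), 1e-9)), 0.005)
})

test_that("the redox ladder unfolds: aerobic, then iron, then methane", {
  ## closed, saturated cell seeded with every substrate
  cell <- toy_cell()
  cell$aq["O2aq"] <- 4e-4
  days <- 40
  dt <- 3600 * 3
  n <- days * 8
  rates <- matrix(0, n, 9)
  tt <- numeric(n)
  for (i in 1:n) {
    rates[i, ] <- rate_vector(cell, k_params)
    cell <- integrate_reactions(cell, dt, params = k_params)
    tt[i] <- i * dt / 86400
  }
  colnames(rates) <- paste0("R", 1:9)
  t_o2_dead <- tt[min(which(rates[, "R3"] < 0.01 * max(rates[, "R3"])))]
  t_fe_peak <- tt[which.max(rates[, "R5"] + rates[, "R6"])]
  t_ch4_peak <- tt[which.max(rates[, "R8"] + rates[, "R9"])]
  expect_lt(t_o2_dead, t_fe_peak)
  expect_lt(t_fe_peak, t_ch4_peak)
})

test_that("iron-linked DOM release is a mechanistic switch", {
  run_dom <- function(r_CFe) {
    k <- k_params
    k$r_CFe <- r_CFe
    cell <- toy_cell()
    cell$aq["O2aq"] <- 0
    released <- numeric(0)
    extent <- numeric(0)
    fe0 <- cell$sol[["FeIII_OM"]]
    dom0 <- cell$aq[["DOM_L"]] + cell$aq[["DOM_A"]]
    for (i in 1:60) {
      cell <- integrate_reactions(cell, 43200, params = k)
      released <- c(released, cell$aq[["DOM_L"]] + cell$aq[["DOM_A"]] - dom0)
      extent <- c(extent, fe0 - cell$sol[["FeIII_OM"]])
    }
    list(released = released, extent = extent)
  }
  on <- run_dom(2)
  off <- run_dom(0)
  ## R6 extent and DOM release move together when the coupling is on
  expect_gt(cor(diff(on$released), diff(on$extent)), 0)
  expect_true(all(diff(on$extent) >= 0))
  ## switching r_CFe off removes the iron-linked share of the release
  expect_gt(tail(on$released, 1), tail(off$released, 1))
})

test_that("doubling the aerobe guild cannot slow oxygen drawdown", {
  drawdown <- function(mult) {
    cell <- toy_cell(guilds = c(aerobe = mult, fermenter = 1, Fe_reducer = 1,
                                Fe_oxidizer = 1, ac_methanogen = 1,
                                h2_methanogen = 1))
    cell$aq["O2aq"] <- 4e-4
    t <- 0
    while (cell$aq[["O2aq"]] > 0.01 * 4e-4 && t < 100 * 3600) {
      cell <- integrate_reactions(cell, 1800, params = k_params)
      t <- t + 1800
    }
    t
  }
  expect_lte(drawdown(3), drawdown(1.5))
})
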