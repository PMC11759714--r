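## runner: operator-split time loop (flow -> advect -> diffuse -> equilibrate
## -> exchange -> react), scenario sweeps over hydraulic parameters, and
## model-versus-observation comparison.

## Inventory of carbon, iron and water in column + headspace (mol, mol, m^3).
inventory <- function(column, state) {
  geom <- column$geometry; cells <- column$cells
  cell_vol <- geom$dz * geom$area
  Vw_L <- cells$porosity * state$S_l * cell_vol * 1000
  Vg <- cells$porosity * (1 - state$S_l) * cell_vol
  grams <- cells$bulk_density * 1e6 * cell_vol
  r_CFe <- cells$C_per_Fe_OM
  C_aq <- sum((state$aq[, "DOM_L"] + state$aq[, "DOM_A"] +
                 2 * state$aq[, "acetate"] + state$aq[, "DIC"] +
                 state$aq[, "CH4aq"]) * Vw_L)
  C_sol <- sum((state$sol[, "POC"] + state$sol[, "MAOC"] +
                  r_CFe * state$sol[, "FeIII_OM"]) * grams)
  C_gas <- sum((state$gas[, "CO2"] + state$gas[, "CH4"]) * Vg)
  C_hs <- (state$headspace$C[["CO2"]] + state$headspace$C[["CH4"]]) *
    state$headspace$V
  Fe_aq <- sum((state$aq[, "Fe2"] + state$aq[, "Fe3aq"]) * Vw_L)
  Fe_sol <- sum((state$sol[, "FeIII_oxide"] + state$sol[, "FeIII_OM"]) * grams)
  list(C = C_aq + C_sol + C_gas + C_hs,
       Fe = Fe_aq + Fe_sol,
       water = sum(cells$porosity * state$S_l) * cell_vol)
}

## Soil-headspace gas exchange over one step.  The top-cell pool relaxes
## exponentially toward equilibrium with the (frozen) headspace — the
## coupling is stiff relative to dt when the top cell is dry — and the
## transferred moles are converted to the mean surface flux handed to the
## CSTR.  Returns list(state, flux) with flux in mol/m^2/s positive upward.
exchange_step <- function(column, state, dt, n_sub = NULL) {
  ## the headspace turns over in ~V/Q (100 min), comparable to dt, so the
  ## frozen-headspace relaxation is sub-stepped internally
  n_sub <- n_sub %||% max(1L, ceiling(dt / 150))
  if (n_sub > 1) {
    h <- dt / n_sub
    tot <- setNames(numeric(3), .gas_species)
    for (i in seq_len(n_sub)) {
      ex <- exchange_step(column, state, h, n_sub = 1L)
      state <- ex$state
      tot <- tot + ex$flux
    }
    return(list(state = state, flux = tot / n_sub))
  }
  cells <- column$cells; tp <- column$params$transport
  geom <- column$geometry
  dz <- geom$dz; A <- geom$area
  hsC <- state$headspace$C
  theta_a <- cells$porosity[1] * (1 - state$S_l[1])
  theta_w <- cells$porosity[1] * state$S_l[1]
  flux <- setNames(numeric(3), .gas_species)
  if (theta_a > 1e-9) {
    ## half-cell film conductance: harmonic integral of D_eff over the top
    ## half cell using the hydrostatic air-content profile (Simpson on the
    ## resistance), which matters because theta_a falls steeply with depth
    zq <- c(1e-6, dz / 8, dz / 4, 3 * dz / 8, dz / 2)
    psi_q <- pmin(0, -(state$z_wt - zq))
    vg1 <- list(alpha = cells$alpha[1], n_vg = cells$n_vg[1])
    Se_q <- effective_saturation(psi_q, vg1)
    th_q <- cells$porosity[1] *
      (1 - (cells$S_r[1] + (1 - cells$S_r[1]) * Se_q))
    Dq <- effective_diffusivity(tp$D_a0 * (tp$f_Da %||% 1), pmax(th_q, 1e-12),
                                cells$porosity[1])
    w <- c(1, 4, 2, 4, 1) / 12 * (dz / 2)   # Simpson weights, 4 panels
    R_film <- sum(w / Dq)
    k <- 1 / R_film                          # m/s transfer coefficient
    tau <- theta_a * dz / k
    relax <- 1 - exp(-dt / tau)
    for (g in .gas_species) {
      dC <- (hsC[[g]] - state$gas[1, g]) * relax
      moles <- -dC * theta_a * dz * A       # moles leaving the soil
      state$gas[1, g] <- state$gas[1, g] + dC
      flux[g] <- moles / (A * dt)
    }
  } else {
    Dw <- effective_diffusivity(tp$D_w0 * (tp$f_Dw %||% 1), theta_w,
                                cells$porosity[1])
    k <- Dw / (dz / 2)
    pH1 <- (state$pH %||% column_ph(column, state))[1]
    h <- 10^(-pH1)
    K1 <- 10^(-.const$pK1); K2 <- 10^(-.const$pK2)
    f_co2 <- 1 / (1 + K1 / h + K1 * K2 / h^2)
    aq_of <- c(O2 = "O2aq", CO2 = "DIC", CH4 = "CH4aq")
    for (g in .gas_species) {
      Kcc <- tp$henry[[g]]
      Caq3 <- state$aq[1, aq_of[[g]]] * 1000
      exch <- if (g == "CO2") f_co2 * Caq3 else Caq3
      eq <- Kcc * hsC[[g]]
      tau <- theta_w * dz / k
      dC <- (eq - exch) * (1 - exp(-dt / tau))   # mol/m^3 water
      moles <- -dC * theta_w * dz * A
      state$aq[1, aq_of[[g]]] <- state$aq[1, aq_of[[g]]] + dC / 1000
      flux[g] <- moles / (A * dt)
    }
  }
  ## exact CSTR update and exact purge integrals for the mass ledger
  hs <- state$headspace
  C0 <- hs$C
  C_ss <- hs$C_in + flux * hs$A / hs$Q
  decay <- exp(-hs$Q * dt / hs$V)
  hs$C <- C_ss + (C0 - C_ss) * decay
  int_C <- C_ss * dt + (C0 - C_ss) * hs$V / hs$Q * (1 - decay)
  state$hs_export <- state$hs_export + hs$Q * int_C
  state$hs_import <- state$hs_import + hs$Q * hs$C_in * dt
  state$headspace <- hs
  list(state = state, flux = flux)
}

## Extend a phase plan cyclically to cover `horizon_days` (used by sweeps).
extend_plan <- function(plan, horizon_days) {
  ph <- plan$phases[, c("kind", "duration_days")]
  out <- ph[0, ]
  t <- 0; i <- 1
  while (t < horizon_days - 1e-9) {
    row <- ph[(i - 1) %% nrow(ph) + 1, ]
    row$duration_days <- min(row$duration_days, horizon_days - t)
    out <- rbind(out, row)
    t <- t + row$duration_days
    i <- i + 1
  }
  ends <- cumsum(out$duration_days)
  list(phases = tibble::tibble(kind = out$kind,
                               duration_days = out$duration_days,
                               t_start = c(0, head(ends, -1)),
                               t_end = ends),
       water_addition_hours = plan$water_addition_hours)
}

#' Run a full saturation-drainage column experiment
#'
#' Integrates the coupled model through the preset's drain/saturate schedule
#' with the operator split flow -> advection -> diffusion (aqueous, gas) ->
#' phase equilibration -> headspace exchange -> reactions, archiving depth
#' profiles, sensor series, surface gas fluxes and the outflow curve, and
#' closing a carbon/iron/water mass ledger.
#'
#' @param column A `column` from [build_column()], or a preset name.
#' @param flow_mode `"gravity"` (default) or `"prescribed_outflow"`.
#' @param outflow_series For prescribed mode: data frame `time_days`,
#'   `cumulative_outflow_m3` (or `cumulative_outflow_mL`).
#' @param plan Optional phase plan overriding the preset's (e.g. from
#'   [extend_plan()] internals via `horizon_days`).
#' @param horizon_days Optional horizon; the preset's plan is cycled or
#'   truncated to fit.
#' @param dt Outer time step (s, default 600): flow, reactions, archiving.
#' @param transport_dt Transport cycle step (s, default 100): diffusion in
#'   both phases, Henry partitioning and headspace exchange advance
#'   together on this shorter cycle.
#' @param archive_hours Archive interval (simulated hours), default 6.
#' @param reactions If `FALSE`, the biogeochemistry is frozen (transport-only
#'   run, used by conservation tests).
#' @param tol Relative tolerance of the reaction integrator.
#' @param seed Optional integer; the simulation itself is deterministic, the
#'   seed is only stored in the result manifest.
#' @param quiet Suppress per-phase progress lines.
#' @return A `simulation_result`: list with `preset_name`, `plan`,
#'   `profiles` (tibble `time_days`, `depth_cm`, `variable`, `value`),
#'   `fluxes` (tibble `time_days`, `gas`, `flux_umol_per_s_per_m2`),
#'   `outflow` (`time_days`, `cumulative_outflow_mL`), `vwc`
#'   (`time_days`, `depth_cm`, `vwc`), `headspace`
#'   (`time_days`, `gas`, `concentration_ppmv`), `mass_balance`,
#'   `final_state`, `manifest`.
#' @export
run_experiment <- function(column, flow_mode = c("gravity", "prescribed_outflow"),
                           outflow_series = NULL, plan = NULL,
                           horizon_days = NULL, dt = 600, transport_dt = 100,
                           archive_hours = 6,
                           reactions = TRUE, tol = 5e-3, seed = NULL,
                           quiet = TRUE) {
  flow_mode <- match.arg(flow_mode)
  if (is.character(column)) column <- build_column(column)
  if (!is.null(outflow_series) && "cumulative_outflow_mL" %in% names(outflow_series)) {
    outflow_series$cumulative_outflow_m3 <- outflow_series$cumulative_outflow_mL * 1e-6
  }
  plan <- plan %||% column$plan
  if (!is.null(horizon_days)) plan <- extend_plan(plan, horizon_days)
  geom <- column$geometry
  state <- column$state
  state$pH <- column_ph(column, state)
  inv0 <- inventory(column, state)
  arch <- list(); arch_i <- 0
  archive_s <- archive_hours * 3600
  next_archive <- 0
  rhiz_idx <- cell_at_depth(.sensor_depths$rhizon, geom)
  vwc_idx <- cell_at_depth(.sensor_depths$vwc, geom)
  take_archive <- function(state, flux) {
    state$pH <- column_ph(column, state)
    td <- state$time / 86400
    prof_vars <- c(.aq_species, "S_l", "pH")
    vals <- cbind(state$aq, S_l = state$S_l, pH = state$pH,
                  gas_O2 = state$gas[, "O2"], gas_CO2 = state$gas[, "CO2"],
                  gas_CH4 = state$gas[, "CH4"])
    arch_i <<- arch_i + 1
    arch[[arch_i]] <<- list(
      time_days = td,
      values = vals,
      flux = flux,
      hs = state$headspace$C,
      cum_outflow = state$cum_outflow,
      z_wt = state$z_wt,
      vwc = column$cells$porosity[vwc_idx] * state$S_l[vwc_idx])
    state
  }
  state <- take_archive(state, setNames(numeric(3), .gas_species))
  next_archive <- archive_s
  for (p in seq_len(nrow(plan$phases))) {
    ph <- plan$phases[p, ]
    if (!quiet) {
      message(sprintf("phase %d: %s %g d (t = %g d)", p, ph$kind,
                      ph$duration_days, ph$t_start))
    }
    phase_end_s <- ph$t_end * 86400
    if (ph$kind == "saturate" && p > 1) {
      ## water addition over the configured hours; each fill substep advects
      ## solutes with the wetting front and vents displaced soil gas
      add_h <- plan$water_addition_hours
      cellA <- geom$dz * geom$area
      deficit <- sum(column$cells$porosity * (1 - state$S_l)) * cellA
      min_w <- min(column$cells$porosity * state$S_l) * cellA
      ## keep each fill substep below ~40% of the driest cell's water so the
      ## upwind advection stays within its Courant bound
      n_sub <- max(2, ceiling(add_h * 3600 / dt),
                   ceiling(deficit / (0.4 * min_w)))
      ev <- saturate_event(column, state, duration_h = add_h, n_sub = n_sub)
      replay <- state                  # pre-event pools; S_l replayed below
      for (k in seq_along(ev$substeps)) {
        fx <- ev$substeps[[k]]
        theta_before <- column$cells$porosity * replay$S_l
        theta_a_before <- column$cells$porosity * (1 - replay$S_l)
        ## per-cell storage change = inflow - outflow through its interfaces
        dS <- (fx[-length(fx)] - fx[-1]) /
          (geom$dz * geom$area * column$cells$porosity)
        replay$S_l <- pmin(1, replay$S_l + dS)
        replay <- advect(column, replay, fx, theta_before)
        replay <- displace_gas(column, replay, theta_a_before)
      }
      replay$S_l <- ev$state$S_l
      replay$z_wt <- ev$state$z_wt
      replay$time <- ev$state$time
      replay$cum_added <- ev$state$cum_added
      state <- equilibrate_phases(column, replay)
      state$pH <- column_ph(column, state)
    }
    while (state$time < phase_end_s - 1e-6) {
      step <- min(dt, phase_end_s - state$time)
      theta_old <- column$cells$porosity * state$S_l
      theta_a_old <- column$cells$porosity * (1 - state$S_l)
      if (ph$kind == "drain") {
        fl <- step_flow(column, state, step, mode = flow_mode,
                        outflow_series = outflow_series)
        state <- fl$state
        if (fl$outflow_volume > 0) {
          state <- advect(column, state, fl$interface_flux, theta_old)
          state <- displace_gas(column, state, theta_a_old)
        }
      } else {
        state$time <- state$time + step
      }
      ## the transport chain (diffusion in both phases, Henry partitioning,
      ## headspace exchange) cycles together on a short fixed step: the
      ## first-order splitting error among these operators, not any one of
      ## them, controls volatile-transport accuracy
      m <- max(1L, ceiling(step / transport_dt))
      h <- step / m
      flux_acc <- setNames(numeric(3), .gas_species)
      unsat <- any(state$S_l < 1)
      ## theta is fixed between flow steps: factor the diffusion operators
      ## once and reuse them across the transport cycles
      fac_aq <- diffuse_factor(column, state, h, "aqueous")
      fac_gas <- if (unsat) diffuse_factor(column, state, h, "gas")
      for (j in seq_len(m)) {
        state$aq <- diffuse_solve(fac_aq, state$aq)
        if (unsat) state$gas <- diffuse_solve(fac_gas, state$gas)
        state <- equilibrate_phases(column, state)
        ex <- exchange_step(column, state, h)
        state <- ex$state
        flux_acc <- flux_acc + ex$flux
      }
      ex <- list(flux = flux_acc / m)
      if (reactions) state <- react_column(column, state, step, tol = tol)
      if (state$time >= next_archive - 1e-6) {
        state <- take_archive(state, ex$flux)
        next_archive <- next_archive + archive_s
      }
    }
  }
  inv1 <- inventory(column, state)
  mb <- tibble::tibble(
    quantity = c("carbon", "iron", "water"),
    initial = c(inv0$C, inv0$Fe, inv0$water),
    final = c(inv1$C, inv1$Fe, inv1$water),
    exported = c(
      sum(state$effluent[c("DOM_L", "DOM_A", "DIC", "CH4aq")]) +
        2 * state$effluent[["acetate"]] +
        (state$hs_export[["CO2"]] - state$hs_import[["CO2"]]) +
        (state$hs_export[["CH4"]] - state$hs_import[["CH4"]]),
      state$effluent[["Fe2"]] + state$effluent[["Fe3aq"]],
      state$cum_outflow - state$cum_added),
    closure = (.data$final + .data$exported - .data$initial) /
      pmax(abs(.data$initial), 1e-300))
  times <- vapply(arch, `[[`, 0, "time_days")
  depth_cm <- geom$z_centers * 100
  prof <- purrr::map_dfr(arch, function(a) {
    vals <- a$values
    tibble::tibble(
      time_days = a$time_days,
      depth_cm = rep(depth_cm, ncol(vals)),
      variable = rep(colnames(vals), each = nrow(vals)),
      value = as.vector(vals))
  })
  fluxes <- purrr::map_dfr(arch, function(a) {
    tibble::tibble(time_days = a$time_days, gas = .gas_species,
                   flux_umol_per_s_per_m2 = as.numeric(a$flux) * 1e6)
  })
  hs_series <- purrr::map_dfr(arch, function(a) {
    tibble::tibble(time_days = a$time_days, gas = .gas_species,
                   concentration_ppmv = as.numeric(a$hs) /
                     .const$air_molar_density * 1e6)
  })
  outflow <- tibble::tibble(
    time_days = times,
    cumulative_outflow_mL = vapply(arch, `[[`, 0, "cum_outflow") * 1e6)
  vwc <- purrr::map_dfr(arch, function(a) {
    tibble::tibble(time_days = a$time_days,
                   depth_cm = .sensor_depths$vwc * 100, vwc = a$vwc)
  })
  structure(list(preset_name = column$preset_name, plan = plan,
                 profiles = prof, fluxes = fluxes, headspace = hs_series,
                 outflow = outflow, vwc = vwc, mass_balance = mb,
                 final_state = state, initial_inventory = inv0,
                 manifest = list(schema = 1, preset = column$preset_name,
                                 flow_mode = flow_mode, dt = dt,
                                 transport_dt = transport_dt,
                                 archive_hours = archive_hours,
                                 seed = seed)),
            class = "simulation_result")
}

#' Built-in sensitivity scenarios
#'
#' `base`, `ksat10`/`ksat01` (saturated conductivity x10 / x0.1), `por09` /
#' `por01` (porosity overridden to 0.9 / 0.1 in both layers), `diff2` /
#' `diff05` (air and water diffusivities doubled / halved).
#'
#' @param names Scenario names to materialise.
#' @return Named list of scenario specs
#'   (`name`, `m_Ksat`, `porosity`, `m_Da`, `m_Dw`).
#' @export
scenario_specs <- function(names = c("base", "ksat10", "ksat01", "por09",
                                     "por01", "diff2", "diff05")) {
  all <- list(
    base = list(name = "base", m_Ksat = 1, porosity = NULL, m_Da = 1, m_Dw = 1),
    ksat10 = list(name = "ksat10", m_Ksat = 10, porosity = NULL, m_Da = 1, m_Dw = 1),
    ksat01 = list(name = "ksat01", m_Ksat = 0.1, porosity = NULL, m_Da = 1, m_Dw = 1),
    por09 = list(name = "por09", m_Ksat = 1, porosity = 0.9, m_Da = 1, m_Dw = 1),
    por01 = list(name = "por01", m_Ksat = 1, porosity = 0.1, m_Da = 1, m_Dw = 1),
    diff2 = list(name = "diff2", m_Ksat = 1, porosity = NULL, m_Da = 2, m_Dw = 2),
    diff05 = list(name = "diff05", m_Ksat = 1, porosity = NULL, m_Da = 0.5, m_Dw = 0.5))
  unknown <- setdiff(names, names(all))
  if (length(unknown)) {
    stop("unknown scenario(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(all), collapse = ", "), call. = FALSE)
  }
  all[names]
}

## Apply a scenario spec to a freshly built column.
apply_scenario <- function(column, sc) {
  stopifnot(sc$m_Ksat > 0, sc$m_Da > 0, sc$m_Dw > 0)
  column$cells$K_sat <- column$cells$K_sat * sc$m_Ksat
  if (!is.null(sc$porosity)) {
    stopifnot(sc$porosity > 0, sc$porosity < 1)
    column$cells$porosity <- rep(sc$porosity, column$geometry$n_cells)
  }
  column$params$transport$f_Da <- sc$m_Da
  column$params$transport$f_Dw <- sc$m_Dw
  column
}

## Column-integrated response series for the sweep (mol or mean quantities).
response_series <- function(column, result) {
  geom <- column$geometry
  cell_vol <- geom$dz * geom$area
  prof <- tidyr::pivot_wider(result$profiles, names_from = "variable",
                             values_from = "value")
  por <- column$cells$porosity[match(prof$depth_cm, geom$z_centers * 100)]
  prof$Vw_L <- por * prof$S_l * cell_vol * 1000
  prof$Vg <- por * (1 - prof$S_l) * cell_vol
  dplyr::summarise(
    dplyr::group_by(prof, .data$time_days),
    liquid_saturation = mean(.data$S_l),
    pH = .data$pH[1],                       # 2 cm-most archived cell
    total_aqueous_Fe = sum((.data$Fe2 + .data$Fe3aq) * .data$Vw_L),
    free_DOM = sum((.data$DOM_L + .data$DOM_A) * .data$Vw_L),
    total_acetate = sum(.data$acetate * .data$Vw_L),
    total_CH4 = sum(.data$CH4aq * .data$Vw_L + .data$gas_CH4 * .data$Vg),
    .groups = "drop")
}

#' Hydraulic sensitivity sweep
#'
#' Runs the base case plus the requested scenarios over a fixed horizon
#' (default 100 days, the preset's phase plan cycled/truncated to fit) and
#' extracts the six response series: column-mean liquid saturation, surface
#' pH, total aqueous Fe, free DOM, total acetate, and total CH4.
#'
#' @param preset Preset name or `column_preset`.
#' @param scenarios Character vector of scenario names
#'   (see [scenario_specs()]); `"base"` is always included.
#' @param horizon_days Sweep horizon (days).
#' @param ... Passed to [run_experiment()].
#' @return A `sweep_result`: list with `responses` (tibble `scenario`,
#'   `time_days`, six response columns) and `runs` (named list of
#'   `simulation_result`s).
#' @export
sensitivity_sweep <- function(preset, scenarios = c("ksat10", "ksat01"),
                              horizon_days = 100, ...) {
  scenarios <- union("base", scenarios)
  specs <- scenario_specs(scenarios)
  runs <- list(); resp <- list()
  for (sc in specs) {
    col <- apply_scenario(build_column(preset), sc)
    res <- run_experiment(col, horizon_days = horizon_days, ...)
    runs[[sc$name]] <- res
    resp[[sc$name]] <- dplyr::mutate(response_series(col, res),
                                     scenario = sc$name, .before = 1)
  }
  structure(list(responses = dplyr::bind_rows(resp), runs = runs),
            class = "sweep_result")
}

#' Compare a simulation with an observation bundle
#'
#' Interpolates each observed series (CO2/CH4 flux from headspace samples,
#' VWC, porewater pH and DOC) linearly onto the simulation's archive times
#' within the overlapping window and reports per-variable (and depth) RMSE,
#' bias (simulation minus observation) and Spearman rank correlation.
#'
#' @param sim A `simulation_result`.
#' @param obs An `observation_bundle` ([generate_bundle()]).
#' @return Tibble `variable`, `depth_cm`, `n`, `rmse`, `bias`,
#'   `spearman_rho`.
#' @export
compare_sim_to_obs <- function(sim, obs) {
  metrics <- function(t_sim, v_sim, t_obs, v_obs) {
    lo <- max(min(t_sim), min(t_obs)); hi <- min(max(t_sim), max(t_obs))
    sel <- t_sim >= lo & t_sim <= hi
    if (!any(sel)) stop("no overlapping time range", call. = FALSE)
    oi <- approx(t_obs, v_obs, xout = t_sim[sel])$y
    d <- v_sim[sel] - oi
    tibble::tibble(n = sum(sel), rmse = sqrt(mean(d^2)), bias = mean(d),
                   spearman_rho = suppressWarnings(
                     cor(v_sim[sel], oi, method = "spearman")))
  }
  out <- list()
  hg <- sim$headspace_geom %||% sim$final_state$headspace
  hs <- new_headspace(Q = hg$Q, V = hg$V, A = hg$A)
  for (g in c("CO2", "CH4")) {
    obs_fl <- invert_flux(obs$headspace_samples, hs, gas = g)
    sim_fl <- dplyr::filter(sim$fluxes, .data$gas == g)
    out[[paste0(g, "_flux")]] <- dplyr::mutate(
      metrics(sim_fl$time_days, sim_fl$flux_umol_per_s_per_m2,
              obs_fl$time_days, obs_fl$flux_umol_per_s_per_m2),
      variable = paste0(tolower(g), "_flux"), depth_cm = NA_real_)
  }
  for (d in unique(obs$vwc$depth_cm)) {
    o <- dplyr::filter(obs$vwc, .data$depth_cm == d)
    s <- dplyr::filter(sim$vwc, .data$depth_cm == d)
    if (!nrow(s)) next
    out[[paste0("vwc", d)]] <- dplyr::mutate(
      metrics(s$time_days, s$vwc, o$time_days, o$vwc),
      variable = "vwc", depth_cm = d)
  }
  for (d in unique(obs$porewater$depth_cm)) {
    o <- dplyr::filter(obs$porewater, .data$depth_cm == d)
    for (v in c("pH", "doc_mg_L")) {
      sv <- if (v == "pH") "pH" else NULL
      s <- dplyr::filter(sim$profiles, .data$variable == "pH")
      s <- dplyr::filter(s, abs(.data$depth_cm - d) ==
                           min(abs(.data$depth_cm - d)))
      if (v == "doc_mg_L") {
        w <- tidyr::pivot_wider(
          dplyr::filter(sim$profiles,
                        .data$variable %in% c("DOM_L", "DOM_A", "acetate")),
          names_from = "variable", values_from = "value")
        w <- dplyr::filter(w, abs(.data$depth_cm - d) ==
                             min(abs(.data$depth_cm - d)))
        s <- tibble::tibble(
          time_days = w$time_days, depth_cm = w$depth_cm, variable = "doc",
          value = .const$mg_C_per_mol *
            (w$DOM_L + w$DOM_A + 2 * w$acetate))
      }
      out[[paste0(v, d)]] <- dplyr::mutate(
        metrics(s$time_days, s$value, o$time_days, o[[v]]),
        variable = v, depth_cm = d)
    }
  }
  dplyr::bind_rows(out)[, c("variable", "depth_cm", "n", "rmse", "bias",
                            "spearman_rho")]
}
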