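## hydrology: van Genuchten retention, Mualem permeability, sharp-interface
## water-table drainage, saturation events, sensor extraction.
##
## Water flow uses a moving water-table approximation: cells below the table
## are saturated; cells above it hold the hydrostatic van Genuchten profile
## anchored at the table.  Gravity drainage removes water at a Darcy rate set
## by the harmonic-mean saturated conductivity of the flow path below the
## table; the new table position is found by mass bookkeeping, so water
## balance is exact by construction.

#' Effective saturation from matric head (van Genuchten)
#'
#' `S_e = [1 + (alpha |psi|)^n]^-(1 - 1/n)` for `psi < 0`, 1 otherwise.
#'
#' @param psi Matric head (m, negative in the unsaturated zone). Vectorised.
#' @param vg List with `alpha` (1/m), `n_vg`, and optionally `S_r`, `K_sat`.
#' @return Effective saturation in `[0, 1]`.
#' @seealso [matric_head()] for the exact inverse.
#' @export
effective_saturation <- function(psi, vg) {
  m <- 1 - 1 / vg$n_vg
  ifelse(psi >= 0, 1, (1 + (vg$alpha * abs(psi))^vg$n_vg)^(-m))
}

#' Matric head from effective saturation (inverse retention curve)
#'
#' @param S_e Effective saturation in `(0, 1]`.
#' @inheritParams effective_saturation
#' @return Matric head (m), 0 at `S_e = 1`.
#' @export
matric_head <- function(S_e, vg) {
  m <- 1 - 1 / vg$n_vg
  ifelse(S_e >= 1, 0, -(S_e^(-1 / m) - 1)^(1 / vg$n_vg) / vg$alpha)
}

#' Mualem relative permeability
#'
#' `k_rel = sqrt(S_e) * (1 - (1 - S_e^(1/m))^m)^2`, monotone in `S_e`.
#'
#' @inheritParams matric_head
#' @return Relative permeability in `[0, 1]`.
#' @export
relative_permeability <- function(S_e, vg) {
  m <- 1 - 1 / vg$n_vg
  S_e <- pmin(pmax(S_e, 0), 1)
  sqrt(S_e) * (1 - (1 - S_e^(1 / m))^m)^2
}

## Liquid saturation of each cell for a water table at depth z_wt:
## hydrostatic psi = -(z_wt - z) above the table, saturated below.
saturation_profile <- function(z_wt, cells, geom) {
  psi <- pmin(0, -(z_wt - geom$z_centers))
  m <- 1 - 1 / cells$n_vg
  Se <- ifelse(psi >= 0, 1, (1 + (cells$alpha * abs(psi))^cells$n_vg)^(-m))
  cells$S_r + (1 - cells$S_r) * Se
}

## Total column water volume (m^3) for a table depth
water_storage <- function(z_wt, cells, geom) {
  sum(cells$porosity * saturation_profile(z_wt, cells, geom)) *
    geom$dz * geom$area
}

## Water volume stored above each interface k = 1..n+1 (m^3); interface k
## sits at depth (k-1)*dz.
storage_above_interfaces <- function(S_l, cells, geom) {
  c(0, cumsum(cells$porosity * S_l * geom$dz * geom$area))
}

## Invert storage: table depth whose hydrostatic profile holds volume W.
## Monotone in z_wt, solved by bisection to machine-level tolerance.
table_for_storage <- function(W, cells, geom) {
  f <- function(z) water_storage(z, cells, geom) - W
  if (f(0) <= 0) return(0)
  if (f(geom$soil_depth) >= 0) return(geom$soil_depth)
  uniroot(f, c(0, geom$soil_depth), tol = 1e-13)$root
}

## Harmonic-mean saturated conductivity of the drainage path from the water
## table to the column base (the basal sand is absorbed into a free-drainage
## boundary).
path_conductivity <- function(z_wt, cells, geom) {
  below <- geom$z_centers > z_wt
  if (!any(below)) below[geom$n_cells] <- TRUE
  L <- sum(below) * geom$dz
  L / sum(geom$dz / cells$K_sat[below])
}

#' Advance water flow over one step
#'
#' In `gravity` mode with the valve open, water drains at a Darcy rate equal
#' to the harmonic-mean `K_sat` of the saturated path below the water table
#' (unit-gradient free drainage); drainage stops when the table reaches the
#' column base.  In `prescribed_outflow` mode the cumulative outflow tracks
#' a supplied `time (days) -> cumulative volume (m^3)` series.  Water balance
#' is exact: the change in stored water equals minus the outflow volume.
#'
#' @param column A `column` from [build_column()].
#' @param state Current `column_state`.
#' @param dt Time step (s), > 0.
#' @param mode `"gravity"` (default), `"prescribed_outflow"`, or `"closed"`
#'   (valve shut; no flow).
#' @param outflow_series For prescribed mode, a data frame with columns
#'   `time_days` and `cumulative_outflow_m3` (non-decreasing).
#' @return List: `state` (updated), `outflow_volume` (m^3 this step), and
#'   `interface_flux` (length `n_cells + 1`, downward water volume crossing
#'   each cell interface this step, m^3).
#' @export
step_flow <- function(column, state, dt, mode = "gravity",
                      outflow_series = NULL) {
  stopifnot(dt > 0)
  geom <- column$geometry; cells <- column$cells
  n <- geom$n_cells
  if (mode == "closed") {
    state$time <- state$time + dt
    return(list(state = state, outflow_volume = 0,
                interface_flux = numeric(n + 1)))
  }
  W0 <- sum(cells$porosity * state$S_l) * geom$dz * geom$area
  above0 <- storage_above_interfaces(state$S_l, cells, geom)
  if (mode == "gravity") {
    if (state$z_wt >= geom$soil_depth) {
      state$time <- state$time + dt
      return(list(state = state, outflow_volume = 0,
                  interface_flux = numeric(n + 1)))
    }
    q <- path_conductivity(state$z_wt, cells, geom)  # m/s
    dV <- q * geom$area * dt
    W_min <- water_storage(geom$soil_depth, cells, geom)
    dV <- min(dV, W0 - W_min)
  } else if (mode == "prescribed_outflow") {
    stopifnot(!is.null(outflow_series))
    os <- outflow_series
    if (is.unsorted(os$time_days) || is.unsorted(os$cumulative_outflow_m3)) {
      stop("prescribed outflow series must be non-decreasing in time and volume",
           call. = FALSE)
    }
    t_new <- (state$time + dt) / 86400
    target <- approx(os$time_days, os$cumulative_outflow_m3, xout = t_new,
                     rule = 2)$y
    dV <- max(0, target - state$cum_outflow)
    dV <- min(dV, W0 - water_storage(geom$soil_depth, cells, geom))
  } else {
    stop("unknown flow mode '", mode, "'", call. = FALSE)
  }
  z_new <- table_for_storage(W0 - dV, cells, geom)
  S_new <- saturation_profile(z_new, cells, geom)
  above1 <- storage_above_interfaces(S_new, cells, geom)
  flux <- above0 - above1            # downward volume through each interface
  flux[n + 1] <- dV                  # bottom outflow, exact
  state$S_l <- S_new
  state$z_wt <- z_new
  state$cum_outflow <- state$cum_outflow + dV
  state$time <- state$time + dt
  list(state = state, outflow_volume = dV, interface_flux = flux)
}

#' Re-saturate the column (water addition event)
#'
#' With the valve closed, distilled water is added at the top at a constant
#' rate over `duration_h` hours until every cell is saturated.  The added
#' water carries zero solutes.  This helper performs the whole event in one
#' call and returns per-substep interface fluxes so solute advection can
#' follow the fill front; [run_experiment()] applies it incrementally.
#'
#' @param column A `column`.
#' @param state Current state.
#' @param duration_h Fill duration (hours).
#' @param n_sub Number of uniform substeps for the fill.
#' @return List: `state` (saturated), `added_volume` (m^3), and
#'   `substeps`, a list of per-substep `interface_flux` vectors (downward
#'   positive; the top interface carries the added water).
#' @export
saturate_event <- function(column, state, duration_h = 2, n_sub = 12) {
  geom <- column$geometry; cells <- column$cells
  n <- geom$n_cells
  W_sat <- sum(cells$porosity) * geom$dz * geom$area
  W0 <- sum(cells$porosity * state$S_l) * geom$dz * geom$area
  need <- W_sat - W0
  if (need <= 1e-15) {
    state$z_wt <- 0
    return(list(state = state, added_volume = 0, substeps = list()))
  }
  substeps <- vector("list", n_sub)
  W <- W0
  for (k in seq_len(n_sub)) {
    above0 <- storage_above_interfaces(state$S_l, cells, geom)
    W <- W0 + need * k / n_sub
    z_new <- table_for_storage(W, cells, geom)
    S_new <- saturation_profile(z_new, cells, geom)
    above1 <- storage_above_interfaces(S_new, cells, geom)
    ## downward flux through interface i = storage increase at/below cell i
    tot0 <- above0[n + 1]; tot1 <- above1[n + 1]
    flux <- (tot1 - tot0) - (above1 - above0)
    state$S_l <- S_new
    state$z_wt <- z_new
    substeps[[k]] <- flux
  }
  state$time <- state$time + duration_h * 3600
  state$cum_added <- state$cum_added + need
  list(state = state, added_volume = need, substeps = substeps)
}

#' Volumetric water content at the sensor depths
#'
#' VWC = porosity x liquid saturation at the cell nearest each sensor
#' (2, 15 and 27 cm).
#'
#' @param column A `column`.
#' @param state A `column_state` (default: the column's own state).
#' @return Tibble with `depth_cm` and `vwc` (m^3/m^3).
#' @export
vwc_at_sensors <- function(column, state = column$state) {
  idx <- cell_at_depth(.sensor_depths$vwc, column$geometry)
  tibble::tibble(depth_cm = .sensor_depths$vwc * 100,
                 vwc = column$cells$porosity[idx] * state$S_l[idx])
}
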