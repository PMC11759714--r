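## transport: Millington-Quirk effective diffusivities, implicit two-phase
## diffusion, upwind aqueous advection with the drainage water, gas-phase
## displacement, and instantaneous Henry equilibration.

#' Millington-Quirk effective diffusivity
#'
#' `D_eff = D0 * theta^(10/3) / porosity^2` for the phase holding volumetric
#' content `theta` in a medium of total porosity `n`.
#'
#' @param D0 Free-phase diffusivity (m^2/s).
#' @param theta_phase Volumetric content of the phase (0..porosity).
#' @param porosity Total porosity.
#' @return Effective diffusivity (m^2/s). Vectorised.
#' @export
effective_diffusivity <- function(D0, theta_phase, porosity) {
  D0 * theta_phase^(10 / 3) / porosity^2
}

## Precompute the implicit finite-volume diffusion factorisation for one
## phase and step; theta is constant between flow steps, so the runner
## reuses this across its transport cycles.
diffuse_factor <- function(column, state, dt, phase) {
  geom <- column$geometry; cells <- column$cells
  tp <- column$params$transport
  n <- geom$n_cells
  dz <- geom$dz
  if (phase == "aqueous") {
    theta <- cells$porosity * state$S_l
    D0 <- tp$D_w0 * (tp$f_Dw %||% 1)
  } else {
    theta <- cells$porosity * (1 - state$S_l)
    D0 <- tp$D_a0 * (tp$f_Da %||% 1)
  }
  Deff <- effective_diffusivity(D0, theta, cells$porosity)
  Di <- ifelse(Deff[-n] > 0 & Deff[-1] > 0,
               2 * Deff[-n] * Deff[-1] / (Deff[-n] + Deff[-1]), 0)
  w <- theta * dz / dt
  lower <- -Di / dz
  upper <- -Di / dz
  diagm <- w + c(Di / dz, 0) + c(0, Di / dz)
  empty <- theta <= 0
  if (any(empty)) {
    diagm[empty] <- 1
    lower[empty[-1] | empty[-n]] <- 0
    upper[empty[-1] | empty[-n]] <- 0
  }
  ## dense inverse of the (well-conditioned) tridiagonal operator: each
  ## subsequent solve is then a single BLAS multiply over all species
  A <- diag(diagm, n)
  A[cbind(2:n, 1:(n - 1))] <- lower
  A[cbind(1:(n - 1), 2:n)] <- upper
  list(phase = phase, Ainv = solve(A),
       w = ifelse(empty, 1, w), empty = empty, n = n)
}

## Solve the factored system for a (matrix) right-hand side of
## concentrations; returns the new concentrations.
diffuse_solve <- function(fac, conc) {
  d <- fac$Ainv %*% (conc * fac$w)
  dimnames(d) <- dimnames(conc)
  d
}

#' Diffuse one phase over a step (implicit, mass conservative)
#'
#' Solves the finite-volume diffusion equation for every species of the
#' phase simultaneously (all species share one free-phase diffusivity), with
#' no-flux boundaries; soil-headspace exchange is handled separately by
#' [surface_exchange()].  Fully implicit, so unconditionally stable and free
#' of negative concentrations; interior mass is conserved to round-off.
#'
#' @param column A `column`.
#' @param state Current state.
#' @param dt Step (s), > 0.
#' @param phase `"aqueous"` or `"gas"`.
#' @return Updated state.
#' @export
diffuse <- function(column, state, dt, phase = c("aqueous", "gas")) {
  stopifnot(dt > 0)
  phase <- match.arg(phase)
  fac <- diffuse_factor(column, state, dt, phase)
  if (phase == "aqueous") {
    state$aq <- diffuse_solve(fac, state$aq)
  } else {
    state$gas <- diffuse_solve(fac, state$gas)
  }
  state
}

#' Advect aqueous solutes with the drainage (or fill) water
#'
#' First-order upwind transport using the per-interface water volumes from
#' [step_flow()] or [saturate_event()].  Solute leaving the bottom interface
#' accumulates in `state$effluent`; water entering the top interface during
#' a fill carries zero solutes.  Mass (column + effluent) is conserved to
#' round-off.
#'
#' @param column A `column`.
#' @param state State *after* the corresponding flow step (saturations
#'   updated).
#' @param interface_flux Downward water volume (m^3) through each of the
#'   `n_cells + 1` interfaces during the step.
#' @param theta_old Liquid volume fraction of each cell before the flow step.
#' @return Updated state.
#' @export
advect <- function(column, state, interface_flux, theta_old) {
  geom <- column$geometry
  n <- geom$n_cells
  cell_vol <- geom$dz * geom$area                    # m^3 bulk per cell
  Vw_old <- theta_old * cell_vol * 1000              # L
  Vw_new <- column$cells$porosity * state$S_l * cell_vol * 1000
  fx <- interface_flux * 1000                        # L through interfaces
  ## Courant check in donor-cell terms
  donors <- pmax(Vw_old, 1e-12)
  if (any(abs(fx[-1]) > donors + 1e-9)) {
    stop("advection Courant violation: an interface moved more water than ",
         "its donor cell holds; sub-step the flow (suggested substeps: ",
         ceiling(max(abs(fx[-1]) / donors)), ")", call. = FALSE)
  }
  mass <- state$aq * Vw_old                          # mol per cell
  ## upwind donor concentrations: downward flux takes the cell above;
  ## the top interface donor is the added water (zero concentration)
  for (i in seq_len(n + 1)) {
    if (fx[i] == 0) next
    if (fx[i] > 0) {                                 # downward
      cdon <- if (i == 1) 0 else state$aq[i - 1, ]
      moles <- cdon * fx[i]
      if (i > 1) mass[i - 1, ] <- mass[i - 1, ] - moles
      if (i <= n) mass[i, ] <- mass[i, ] + moles
      else state$effluent <- state$effluent + moles
    } else {                                         # upward (not produced
      cdon <- if (i > n) 0 else state$aq[i, ]        # by current modes)
      moles <- cdon * (-fx[i])
      if (i <= n) mass[i, ] <- mass[i, ] - moles
      if (i > 1) mass[i - 1, ] <- mass[i - 1, ] + moles
    }
  }
  conc <- mass / ifelse(Vw_new > 0, Vw_new, 1)
  conc[Vw_new <= 0, ] <- 0
  state$aq <- pmax(conc, 0)
  state
}

## Gas-phase displacement companion to advect(): when drainage opens gas
## volume, replacement air cascades downward from the headspace; when a fill
## closes gas volume, displaced soil gas vents upward into the headspace.
## Conserves moles exactly (vented moles are added to the headspace).
displace_gas <- function(column, state, theta_a_old) {
  geom <- column$geometry
  n <- geom$n_cells
  cell_vol <- geom$dz * geom$area
  Vg_old <- theta_a_old * cell_vol
  Vg_new <- column$cells$porosity * (1 - state$S_l) * cell_vol
  dV <- Vg_new - Vg_old
  mass <- state$gas * Vg_old
  vol <- Vg_old
  hs <- state$headspace
  if (sum(dV) > 1e-18) {
    ## drainage opened gas volume: replacement air cascades down from the
    ## headspace; downward flux through interface i = volume created at or
    ## below cell i.  Donor concentrations track the running cell mass.
    flux <- c(rev(cumsum(rev(pmax(dV, 0)))), 0)
    for (i in seq_len(n)) {
      f <- flux[i]
      if (f <= 0) next
      if (i == 1) {
        cdon <- hs$C
        hs$C <- hs$C - f * cdon / hs$V
      } else {
        cdon <- if (vol[i - 1] > 0) mass[i - 1, ] / vol[i - 1] else 0 * hs$C
        mass[i - 1, ] <- mass[i - 1, ] - f * cdon
        vol[i - 1] <- vol[i - 1] - f
      }
      mass[i, ] <- mass[i, ] + f * cdon
      vol[i] <- vol[i] + f
    }
  } else if (sum(dV) < -1e-18) {
    ## fill closed gas volume: displaced soil gas is pushed upward and vents
    ## into the headspace; upward flux through interface i = volume destroyed
    ## at or below cell i.
    flux <- c(rev(cumsum(rev(pmax(-dV, 0)))), 0)
    for (i in rev(seq_len(n))) {
      f <- flux[i]
      if (f <= 0) next
      cdon <- if (vol[i] > 0) mass[i, ] / vol[i] else 0 * hs$C
      mass[i, ] <- mass[i, ] - f * cdon
      vol[i] <- vol[i] - f
      if (i == 1) {
        hs$C <- hs$C + f * cdon / hs$V
      } else {
        mass[i - 1, ] <- mass[i - 1, ] + f * cdon
        vol[i - 1] <- vol[i - 1] + f
      }
    }
  }
  conc <- mass / ifelse(Vg_new > 0, Vg_new, 1)
  conc[Vg_new <= 0, ] <- 0
  state$gas <- pmax(conc, 0)
  state$headspace <- hs
  state
}

#' Equilibrate volatile species between water and soil gas in every cell
#'
#' Instantaneous Henry partitioning: after the call,
#' `C_aq = K_cc * C_gas` (concentrations in common units) for O2, CO2
#' (as DIC's CO2*, see Details) and CH4, with total moles in each cell
#' conserved exactly.  In saturated cells all mass is aqueous.
#'
#' @details DIC partitions through its dissolved CO2 fraction: only
#'   `f_co2(pH) * DIC` exchanges with the gas phase.  The fraction is
#'   evaluated at the cell's current diagnostic pH, which is a standard
#'   operator-splitting approximation.
#'
#' @param column A `column`.
#' @param state Current state.
#' @param pH Optional per-cell pH vector used for the DIC split (default:
#'   solved from the charge balance).
#' @return Updated state.
#' @export
equilibrate_phases <- function(column, state, pH = NULL) {
  cells <- column$cells
  henry <- column$params$transport$henry
  theta_w <- cells$porosity * state$S_l          # water volume fraction
  theta_a <- cells$porosity * (1 - state$S_l)
  if (is.null(pH)) pH <- state$pH %||% column_ph(column, state)
  ## fraction of DIC present as dissolved CO2 at the current pH
  h <- 10^(-pH)
  K1 <- 10^(-.const$pK1); K2 <- 10^(-.const$pK2)
  f_co2 <- 1 / (1 + K1 / h + K1 * K2 / h^2)
  has_gas <- theta_a > 0
  map <- list(O2 = "O2aq", CH4 = "CH4aq")
  for (g in c("O2", "CH4")) {
    aqs <- map[[g]]
    Kcc <- henry[[g]]
    Caq3 <- state$aq[, aqs] * 1000               # mol/m^3 water
    total <- Caq3 * theta_w + state$gas[, g] * theta_a   # mol/m^3 bulk
    Cg <- total / (Kcc * theta_w + theta_a)
    ## Kcc * Cg reduces to total/theta_w when theta_a = 0 (all aqueous)
    state$gas[, g] <- Cg * has_gas
    state$aq[, aqs] <- Kcc * Cg / 1000
  }
  ## CO2: exchangeable aqueous pool is f_co2 * DIC
  Kcc <- henry$CO2
  DIC3 <- state$aq[, "DIC"] * 1000
  exch <- f_co2 * DIC3
  inert <- DIC3 - exch
  total <- exch * theta_w + state$gas[, "CO2"] * theta_a
  Cg <- total / (Kcc * theta_w + theta_a)
  state$gas[, "CO2"] <- Cg * has_gas
  state$aq[, "DIC"] <- (inert + Kcc * Cg) / 1000
  state
}
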