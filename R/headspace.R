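## headspace_cstr: continuous stirred tank reactor headspace — forward gas
## dynamics under purge flow, soil-headspace exchange, and inversion of
## concentration samples to surface fluxes.
##
## The headspace obeys V dC/dt = Q (C_in - C) + F A with purge flow Q,
## headspace volume V, column cross-section A and surface flux F; the update
## over a step with constant F is the exact exponential solution, so the
## forward model is stable for any dt and the steady state is
## C_ss = C_in + F A / Q.

#' Construct a headspace state
#'
#' @param Q Purge flow (m^3/s); default 5 mL/min.
#' @param V Headspace volume (m^3); default 0.5 L.
#' @param A Column cross-sectional area (m^2); default the 7.5 cm tube.
#' @param C Initial gas concentrations (mol/m^3); default inflow air.
#' @param C_in Inflow air composition (mol/m^3).
#' @return List of class `"headspace"` with fields `C`, `Q`, `V`, `A`, `C_in`.
#' @export
new_headspace <- function(Q = 5 * 1e-6 / 60, V = 0.5e-3,
                          A = pi * 0.075^2 / 4,
                          C = air_composition(), C_in = air_composition()) {
  stopifnot(Q > 0, V > 0, A > 0, all(C >= 0))
  structure(list(C = C, Q = Q, V = V, A = A, C_in = C_in),
            class = "headspace")
}

#' Advance the headspace CSTR one step under a constant surface flux
#'
#' Exact exponential update of `V dC/dt = Q (C_in - C) + F A`.
#'
#' @param hs A headspace state ([new_headspace()]).
#' @param surface_flux Named flux per gas (mol/m^2/s, positive from soil to
#'   headspace); gases absent from the vector get zero flux.
#' @param dt Step (s), > 0.
#' @return The headspace with updated `C`.
#' @export
cstr_step <- function(hs, surface_flux, dt) {
  stopifnot(dt > 0)
  F <- setNames(numeric(length(hs$C)), names(hs$C))
  common <- intersect(names(surface_flux), names(F))
  F[common] <- surface_flux[common]
  C_ss <- hs$C_in + F * hs$A / hs$Q
  hs$C <- C_ss + (hs$C - C_ss) * exp(-hs$Q * dt / hs$V)
  hs
}

#' Diffusive gas exchange between the top soil cell and the headspace
#'
#' Half-cell gradient coupling: with an unsaturated top cell the flux is
#' `D_a,eff (C_gas,top - C_hs) / (dz/2)`; with a saturated top cell an
#' aqueous film controls, `D_w,eff (C_aq,top - K_cc C_hs) / (dz/2)` with the
#' aqueous concentration in mol/m^3.  Sign convention: positive upward
#' (soil to headspace).
#'
#' @param column A `column`.
#' @param state Current state.
#' @return Named flux vector (mol/m^2/s) for O2, CO2, CH4.
#' @export
surface_exchange <- function(column, state) {
  cells <- column$cells; tp <- column$params$transport
  dz <- column$geometry$dz
  hsC <- state$headspace$C
  theta_a <- cells$porosity[1] * (1 - state$S_l[1])
  theta_w <- cells$porosity[1] * state$S_l[1]
  out <- setNames(numeric(3), .gas_species)
  if (theta_a > 1e-9) {
    Da <- effective_diffusivity(tp$D_a0 * (tp$f_Da %||% 1), theta_a,
                                cells$porosity[1])
    for (g in .gas_species) {
      out[g] <- Da * (state$gas[1, g] - hsC[[g]]) / (dz / 2)
    }
  } else {
    Dw <- effective_diffusivity(tp$D_w0 * (tp$f_Dw %||% 1), theta_w,
                                cells$porosity[1])
    aq_of <- c(O2 = "O2aq", CO2 = "DIC", CH4 = "CH4aq")
    pH1 <- (state$pH %||% column_ph(column, state))[1]
    h <- 10^(-pH1)
    K1 <- 10^(-.const$pK1); K2 <- 10^(-.const$pK2)
    f_co2 <- 1 / (1 + K1 / h + K1 * K2 / h^2)
    for (g in .gas_species) {
      Caq3 <- state$aq[1, aq_of[[g]]] * 1000        # mol/m^3 water
      if (g == "CO2") Caq3 <- Caq3 * f_co2          # only CO2* exchanges
      Kcc <- tp$henry[[g]]
      out[g] <- Dw * (Caq3 - Kcc * hsC[[g]]) / (dz / 2)
    }
  }
  out
}

#' Invert headspace concentration samples to surface fluxes
#'
#' Quasi-steady mode inverts the CSTR steady state,
#' `F = Q (C - C_in) / A`; transient mode adds the storage term
#' `V dC/dt / A` using centred finite differences (one-sided at the ends).
#' Quasi-steady is the default: the sampling interval (1-4 days) is much
#' longer than the headspace residence time V/Q (100 min at the defaults).
#'
#' @param samples Data frame with columns `time_days` and `concentration`
#'   (mol/m^3), strictly increasing in time; or columns `time_days`,
#'   `gas`, `concentration_ppmv` as written by the observation bundle, in
#'   which case each gas is inverted separately.
#' @param hs Headspace state supplying `Q`, `V`, `A`, `C_in`.
#' @param gas When `samples` uses the ppmv schema: which gas to invert.
#' @param mode `"quasi_steady"` (default) or `"transient"`.
#' @return Tibble `time_days`, `flux_umol_per_s_per_m2`.
#' @export
invert_flux <- function(samples, hs, gas = NULL,
                        mode = c("quasi_steady", "transient")) {
  mode <- match.arg(mode)
  if (!is.null(gas) && "concentration_ppmv" %in% names(samples)) {
    samples <- dplyr::filter(samples, .data$gas == !!gas)
    samples <- dplyr::transmute(
      samples, time_days = .data$time_days,
      concentration = .data$concentration_ppmv * 1e-6 * .const$air_molar_density)
    C_in <- hs$C_in[[gas]]
  } else {
    C_in <- if (!is.null(gas)) hs$C_in[[gas]] else hs$C_in[[1]]
  }
  t <- samples$time_days
  C <- samples$concentration
  if (length(t) < 2) stop("need at least two samples", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  flux <- hs$Q * (C - C_in) / hs$A               # mol/m^2/s
  if (mode == "transient") {
    ts <- t * 86400
    n <- length(ts)
    dCdt <- numeric(n)
    dCdt[1] <- (C[2] - C[1]) / (ts[2] - ts[1])
    dCdt[n] <- (C[n] - C[n - 1]) / (ts[n] - ts[n - 1])
    if (n > 2) {
      dCdt[2:(n - 1)] <- (C[3:n] - C[1:(n - 2)]) / (ts[3:n] - ts[1:(n - 2)])
    }
    flux <- flux + hs$V * dCdt / hs$A
  }
  tibble::tibble(time_days = t, flux_umol_per_s_per_m2 = flux * 1e6)
}
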