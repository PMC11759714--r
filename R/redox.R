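## redox_network: Monod-kinetic microbial reaction network and solid-phase
## exchanges.  Nine reactions:
##   R1 hydrolysis            POC -> DOM_L
##   R2 sorption exchange     DOM_L <-> MAOC
##   R3 aerobic respiration   DOM_L + O2 -> DIC
##   R4 fermentation          DOM_L -> 1/3 acetate + 1/3 DIC + 2/3 H2
##   R5 Fe(III) oxide redn    acetate + 8 FeIII_oxide -> 2 DIC + 8 Fe2
##   R6 FeIII_OM reduction    as R5 on the organic-complexed pool, releasing
##                            r_CFe mol C per mol Fe as DOM (f_L labile)
##   R7 Fe(II) oxidation      Fe2 + 1/4 O2 -> Fe(III) (f_aq stays aqueous)
##   R8 acetoclastic methano. acetate -> CH4 + DIC
##   R9 hydrogenotrophic m.   4 H2 + DIC -> CH4
## Anaerobic reactions (R4, R5, R6, R8, R9) carry the oxygen inhibition term
## I(O2) = K_I / (K_I + [O2aq]).  Guild biomasses are static multipliers.

.reaction_names <- paste0("R", 1:9)

## Per-cell rate matrix. aq: cells x species (mol/L); sol: cells x solids
## (mol/g-dwt); conv: g-dwt per litre of porewater; guilds: cells x 6.
## Returns cells x 9 rates, each in mol/L/s of the reaction's primary unit.
rate_matrix <- function(aq, sol, conv, guilds, k) {
  mono <- function(x, K) x / (K + x)
  inhib <- k$K_I / (k$K_I + aq[, "O2aq"])
  cbind(
    R1 = k$k_hyd * sol[, "POC"] * conv,
    R2 = k$k_att * aq[, "DOM_L"] - k$k_det * sol[, "MAOC"] * conv,
    R3 = k$Vmax_R3 * guilds[, "aerobe"] *
      mono(aq[, "DOM_L"], k$K_DOM) * mono(aq[, "O2aq"], k$K_O2),
    R4 = k$Vmax_R4 * guilds[, "fermenter"] *
      mono(aq[, "DOM_L"], k$K_DOM) * inhib,
    R5 = k$Vmax_R5 * guilds[, "Fe_reducer"] *
      mono(aq[, "acetate"], k$K_ac) * mono(sol[, "FeIII_oxide"], k$K_FeIII) *
      inhib,
    R6 = k$Vmax_R6 * guilds[, "Fe_reducer"] *
      mono(aq[, "acetate"], k$K_ac) * mono(sol[, "FeIII_OM"], k$K_FeIII) *
      inhib,
    R7 = k$k_ox * guilds[, "Fe_oxidizer"] * aq[, "Fe2"] * aq[, "O2aq"],
    R8 = k$Vmax_R8 * guilds[, "ac_methanogen"] *
      mono(aq[, "acetate"], k$K_ac) * inhib,
    R9 = k$Vmax_R9 * guilds[, "h2_methanogen"] *
      mono(aq[, "H2"], k$K_H2) * mono(aq[, "DIC"], k$K_DIC) * inhib)
}

## Time derivatives of (aq, sol) given a rate matrix r (cells x 9).
## R2 is the net sorption rate (attach - detach) and may be negative.
pool_derivs <- function(r, conv, k) {
  d_aq <- cbind(
    O2aq   = -r[, "R3"] - r[, "R7"] / 4,
    DOM_L  = r[, "R1"] - r[, "R2"] - r[, "R3"] - r[, "R4"] +
      k$f_L * k$r_CFe * 8 * r[, "R6"],
    DOM_A  = (1 - k$f_L) * k$r_CFe * 8 * r[, "R6"],
    acetate = r[, "R4"] / 3 - r[, "R5"] - r[, "R6"] - r[, "R8"],
    H2     = 2 * r[, "R4"] / 3 - 4 * r[, "R9"],
    Fe2    = 8 * (r[, "R5"] + r[, "R6"]) - r[, "R7"],
    Fe3aq  = k$f_aq * r[, "R7"],
    CH4aq  = r[, "R8"] + r[, "R9"],
    DIC    = r[, "R3"] + r[, "R4"] / 3 + 2 * (r[, "R5"] + r[, "R6"]) +
      r[, "R8"] - r[, "R9"])
  d_sol <- cbind(
    POC = -r[, "R1"] / conv,
    MAOC = r[, "R2"] / conv,
    FeIII_oxide = (-8 * r[, "R5"] + (1 - k$f_aq) * r[, "R7"]) / conv,
    FeIII_OM = -8 * r[, "R6"] / conv)
  list(aq = d_aq, sol = d_sol)
}

#' Reaction rates for a single cell
#'
#' Evaluates the nine-reaction Monod network at the cell's current
#' composition.  Rates are non-negative (R2 is reported as the net sorption
#' rate and may be negative), zero whenever a required substrate is zero,
#' and saturate at `Vmax * guild` as substrates grow large.
#'
#' @param cell List with `aq` (named, mol/L), `sol` (named, mol/g-dwt),
#'   `conv` (g dry soil per litre of porewater), `guilds` (named factors).
#' @param params Kinetics list (the `kinetics` element of
#'   [load_reaction_params()]).
#' @return Named numeric vector of nine reaction rates (mol/L/s).
#' @export
rate_vector <- function(cell, params = load_reaction_params()$kinetics) {
  r <- rate_matrix(rbind(cell$aq[.aq_species]),
                   rbind(cell$sol[.sol_species]),
                   cell$conv, rbind(cell$guilds[.guilds]), params)
  setNames(drop(r), .reaction_names)
}

## Fast unnamed-matrix derivative kernel for the integrator.  Column order
## fixed: aq = .aq_species (O2aq, DOM_L, DOM_A, acetate, H2, Fe2, Fe3aq,
## CH4aq, DIC), sol = .sol_species (POC, MAOC, FeIII_oxide, FeIII_OM),
## guilds = .guilds.
derivs_fast <- function(aq, sol, conv, guilds, k) {
  O2 <- aq[, 1L]; DOML <- aq[, 2L]; ac <- aq[, 4L]; H2 <- aq[, 5L]
  Fe2 <- aq[, 6L]; DIC <- aq[, 9L]
  inhib <- k$K_I / (k$K_I + O2)
  mDOM <- DOML / (k$K_DOM + DOML)
  mac <- ac / (k$K_ac + ac)
  r1 <- k$k_hyd * sol[, 1L] * conv
  r2 <- k$k_att * DOML - k$k_det * sol[, 2L] * conv
  r3 <- k$Vmax_R3 * guilds[, 1L] * mDOM * O2 / (k$K_O2 + O2)
  r4 <- k$Vmax_R4 * guilds[, 2L] * mDOM * inhib
  r5 <- k$Vmax_R5 * guilds[, 3L] * mac *
    sol[, 3L] / (k$K_FeIII + sol[, 3L]) * inhib
  r6 <- k$Vmax_R6 * guilds[, 3L] * mac *
    sol[, 4L] / (k$K_FeIII + sol[, 4L]) * inhib
  r7 <- k$k_ox * guilds[, 4L] * Fe2 * O2
  r8 <- k$Vmax_R8 * guilds[, 5L] * mac * inhib
  r9 <- k$Vmax_R9 * guilds[, 6L] * H2 / (k$K_H2 + H2) *
    DIC / (k$K_DIC + DIC) * inhib
  d_aq <- matrix(0, nrow(aq), 9L)
  d_aq[, 1L] <- -r3 - r7 / 4
  d_aq[, 2L] <- r1 - r2 - r3 - r4 + k$f_L * k$r_CFe * 8 * r6
  d_aq[, 3L] <- (1 - k$f_L) * k$r_CFe * 8 * r6
  d_aq[, 4L] <- r4 / 3 - r5 - r6 - r8
  d_aq[, 5L] <- 2 * r4 / 3 - 4 * r9
  d_aq[, 6L] <- 8 * (r5 + r6) - r7
  d_aq[, 7L] <- k$f_aq * r7
  d_aq[, 8L] <- r8 + r9
  d_aq[, 9L] <- r3 + r4 / 3 + 2 * (r5 + r6) + r8 - r9
  d_sol <- matrix(0, nrow(aq), 4L)
  d_sol[, 1L] <- -r1 / conv
  d_sol[, 2L] <- r2 / conv
  d_sol[, 3L] <- (-8 * r5 + (1 - k$f_aq) * r7) / conv
  d_sol[, 4L] <- -8 * r6 / conv
  list(aq = d_aq, sol = d_sol)
}

## Adaptive Heun integrator over a matrix of cells with positivity-preserving
## substeps and step-doubling error control.
integrate_cells <- function(aq, sol, conv, guilds, dt, k,
                            tol = 1e-6, max_halvings = 20) {
  t_done <- 0
  h <- dt
  dn_aq <- dimnames(aq); dn_sol <- dimnames(sol)
  dimnames(aq) <- NULL; dimnames(sol) <- NULL
  guilds <- unname(guilds)
  floor_c <- 1e-9                 # abs floor for the relative error norm
  heun <- function(aq, sol, h, d1) {
    aq1 <- aq + h * d1$aq; sol1 <- sol + h * d1$sol
    if (any(aq1 < 0) || any(sol1 < 0)) return(NULL)
    d2 <- derivs_fast(aq1, sol1, conv, guilds, k)
    aq2 <- aq + h / 2 * (d1$aq + d2$aq)
    sol2 <- sol + h / 2 * (d1$sol + d2$sol)
    if (any(aq2 < 0) || any(sol2 < 0)) return(NULL)
    list(aq = aq2, sol = sol2)
  }
  while (t_done < dt - 1e-9) {
    h <- min(h, dt - t_done)
    d1 <- derivs_fast(aq, sol, conv, guilds, k)
    ## positivity pre-limit: Monod rates vanish with their substrates, so
    ## y / |dy| is bounded below by K/Vmax and this cannot collapse to zero
    dec_aq <- d1$aq < 0 & aq > 0
    dec_sol <- d1$sol < 0 & sol > 0
    h_pos <- min(Inf,
                 if (any(dec_aq)) min(aq[dec_aq] / -d1$aq[dec_aq]),
                 if (any(dec_sol)) min(sol[dec_sol] / -d1$sol[dec_sol]))
    h <- min(h, 0.45 * h_pos)
    halvings <- 0
    repeat {
      full <- heun(aq, sol, h, d1)
      ok <- FALSE
      if (!is.null(full)) {
        half1 <- heun(aq, sol, h / 2, d1)
        if (!is.null(half1)) {
          d1b <- derivs_fast(half1$aq, half1$sol, conv, guilds, k)
          half2 <- heun(half1$aq, half1$sol, h / 2, d1b)
          if (!is.null(half2)) {
            err <- max(abs(full$aq - half2$aq) /
                         pmax(abs(half2$aq), floor_c),
                       abs(full$sol - half2$sol) /
                         pmax(abs(half2$sol), floor_c))
            if (err <= tol) {
              aq <- half2$aq; sol <- half2$sol
              t_done <- t_done + h
              if (err < tol / 16) h <- h * 2
              ok <- TRUE
            }
          }
        }
      }
      if (ok) break
      h <- h / 2
      halvings <- halvings + 1
      if (halvings > max_halvings) {
        stop("reaction integration failed to reach tolerance ", tol,
             " after ", max_halvings, " step halvings (worst cell: ",
             which.max(rowSums(abs(d1$aq))), ")", call. = FALSE)
      }
    }
  }
  dimnames(aq) <- dn_aq; dimnames(sol) <- dn_sol
  list(aq = aq, sol = sol)
}

#' Integrate the reaction network in one cell
#'
#' Adaptive Heun (trapezoidal predictor-corrector) integration with
#' positivity-preserving substeps (pools are never clipped; the step is
#' halved instead) and step-doubling local error control.
#'
#' @inheritParams rate_vector
#' @param dt Integration window (s), > 0.
#' @param tol Relative local-error tolerance (default `1e-6`).
#' @return The cell with updated `aq` and `sol`.
#' @export
integrate_reactions <- function(cell, dt,
                                params = load_reaction_params()$kinetics,
                                tol = 1e-6) {
  stopifnot(dt > 0)
  out <- integrate_cells(rbind(cell$aq[.aq_species]),
                         rbind(cell$sol[.sol_species]),
                         cell$conv, rbind(cell$guilds[.guilds]),
                         dt, params, tol = tol)
  cell$aq <- setNames(drop(out$aq), .aq_species)
  cell$sol <- setNames(drop(out$sol), .sol_species)
  cell
}

## Column-level reaction step used by the runner (vectorised across cells).
react_column <- function(column, state, dt, tol = 5e-3) {
  theta_w <- column$cells$porosity * state$S_l
  conv <- column$cells$bulk_density * 1000 / pmax(theta_w, 1e-6)
  out <- integrate_cells(state$aq, state$sol, conv,
                         column$cells$guilds, dt,
                         column$params$kinetics, tol = tol)
  state$aq <- out$aq
  state$sol <- out$sol
  state
}

#' Time to oxygen depletion after re-saturation
#'
#' Scans a completed simulation for the onset of the first saturation phase
#' and reports the hours until dissolved oxygen falls below 1% of
#' air-saturation at every archived depth.
#'
#' @param result A `simulation_result` from [run_experiment()].
#' @param threshold_frac Fraction of air-saturation defining depletion
#'   (default 0.01).
#' @return Hours from saturation onset to column-wide depletion, or `Inf` if
#'   oxygen never depletes (e.g. an abiotic run).
#' @export
o2_consumption_check <- function(result, threshold_frac = 0.01) {
  plan <- result$plan
  sat <- plan$phases[plan$phases$kind == "saturate", ]
  if (!nrow(sat)) stop("run has no saturation phase", call. = FALSE)
  onset <- sat$t_start[1]
  thr <- threshold_frac * .o2_airsat()
  o2 <- dplyr::filter(result$profiles, .data$variable == "O2aq",
                      .data$time_days >= onset)
  by_time <- dplyr::summarise(dplyr::group_by(o2, .data$time_days),
                              worst = max(.data$value), .groups = "drop")
  hit <- by_time$time_days[by_time$worst < thr]
  if (!length(hit)) return(Inf)
  (min(hit) - onset) * 24
}
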