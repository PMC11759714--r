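## geochem: charge-balance pH speciation and derived porewater observables.
##
## The diagnostic pH is the root of the charge balance
##   [H+] + 2[Fe2+] + Z - [OH-] - [HCO3-] - 2[CO3--] - [Ac-] = 0
## with carbonate pK1 = 6.35, pK2 = 10.33, acetate pKa = 4.76, pKw = 14.0
## (25 degC constants, used unadjusted; the 4-25 degC correction shifts pH by
## under 0.2 units and is neglected).  Speciation is diagnostic only: solving
## it never alters the transported totals.

## Charge-balance residual (mol charge/L); vectorised over pH.  B_T is an
## optional static organic weak-acid (humic) buffer pool with pKa `pKa_B`,
## representing the high pH-buffering capacity of organic-rich tundra soil;
## it defaults to zero so the bare carbonate/acetate/iron balance is the
## base contract.
charge_balance <- function(pH, DIC_T, Ac_T, Fe2_T, Z, B_T = 0, pKa_B = 5.5) {
  h <- 10^(-pH)
  oh <- 10^(-(.const$pKw - pH))
  K1 <- 10^(-.const$pK1); K2 <- 10^(-.const$pK2); Ka <- 10^(-.const$pKa_ac)
  den <- 1 + K1 / h + K1 * K2 / h^2
  hco3 <- DIC_T * (K1 / h) / den
  co3 <- DIC_T * (K1 * K2 / h^2) / den
  ac <- Ac_T * Ka / (Ka + h)
  Kb <- 10^(-pKa_B)
  buf <- B_T * Kb / (Kb + h)
  h + 2 * Fe2_T + Z - oh - hco3 - 2 * co3 - ac - buf
}

#' Solve the charge-balance pH of a porewater sample
#'
#' Finds the unique root of the charge balance on pH 2-12 by Brent's method
#' and polishes it by bisection until the residual is below `1e-12` mol/L.
#'
#' @param DIC_T Total dissolved inorganic carbon (mol/L).
#' @param Ac_T Total acetate (mol/L).
#' @param Fe2_T Ferrous iron (mol/L).
#' @param Z Conservative net cation charge (mol charge/L).
#' @param B_T Total static organic (humic) weak-acid buffer (mol/L,
#'   default 0).
#' @param pKa_B Buffer pKa (default 5.5).
#' @return List: `pH`, `residual` (mol/L), and `species` (named vector with
#'   `H`, `OH`, `HCO3`, `CO3`, `CO2aq`, `Ac`).
#' @export
solve_ph <- function(DIC_T = 0, Ac_T = 0, Fe2_T = 0, Z = 0, B_T = 0,
                     pKa_B = 5.5) {
  stopifnot(is.finite(DIC_T), is.finite(Ac_T), is.finite(Fe2_T), is.finite(Z))
  f <- function(p) charge_balance(p, DIC_T, Ac_T, Fe2_T, Z, B_T, pKa_B)
  lo <- 2; hi <- 12
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0 || fhi > 0) {
    stop("charge balance has no root on pH [2, 12]: residual at 2 = ",
         format(flo), ", at 12 = ", format(fhi), call. = FALSE)
  }
  pH <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  ## bisection polish on the residual itself
  a <- max(lo, pH - 1e-6); b <- min(hi, pH + 1e-6)
  if (f(a) < 0) a <- lo
  if (f(b) > 0) b <- hi
  for (i in 1:100) {
    if (abs(f(pH)) < 1e-12) break
    mid <- (a + b) / 2
    if (f(mid) > 0) a <- mid else b <- mid
    pH <- (a + b) / 2
  }
  h <- 10^(-pH)
  K1 <- 10^(-.const$pK1); K2 <- 10^(-.const$pK2); Ka <- 10^(-.const$pKa_ac)
  den <- 1 + K1 / h + K1 * K2 / h^2
  list(pH = pH, residual = f(pH),
       species = c(H = h, OH = 10^(-(.const$pKw - pH)),
                   HCO3 = DIC_T * (K1 / h) / den,
                   CO3 = DIC_T * (K1 * K2 / h^2) / den,
                   CO2aq = DIC_T / den,
                   Ac = Ac_T * Ka / (Ka + h)))
}

## Conservative charge that makes the charge balance close at a target pH.
charge_for_ph <- function(pH, DIC_T = 0, Ac_T = 0, Fe2_T = 0, B_T = 0) {
  -charge_balance(pH, DIC_T, Ac_T, Fe2_T, 0, B_T)
}

## Diagnostic pH for every cell of a column state: vectorised bisection of
## the charge balance (monotone decreasing in pH) to ~1e-15 pH units.
column_ph <- function(column, state) {
  n <- column$geometry$n_cells
  DIC <- state$aq[, "DIC"]; Ac <- state$aq[, "acetate"]
  Fe2 <- state$aq[, "Fe2"]; Z <- column$cells$Z
  B <- column$cells$buffer
  lo <- rep(2, n); hi <- rep(12, n)
  for (k in 1:52) {
    mid <- (lo + hi) / 2
    up <- charge_balance(mid, DIC, Ac, Fe2, Z, B) > 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  (lo + hi) / 2
}

#' Derived porewater observables for a cell
#'
#' Computes the measured quantities from the model pools: dissolved organic
#' carbon `DOC = 12011 * (DOM_L + DOM_A + 2 * acetate)` mg C/L, the ratio of
#' ferrous to total dissolved iron (1 when no iron is present), and a SUVA
#' proxy: the DOC-weighted mean specific absorbance of the labile
#' (`s_L = 1.0`) and aromatic (`s_A = 4.5` L/mg/m) DOM pools, so preferential
#' consumption of labile DOM raises the proxy.
#'
#' @param aq Named numeric vector of aqueous concentrations (mol/L) with at
#'   least `DOM_L`, `DOM_A`, `acetate`, `Fe2`, `Fe3aq`.
#' @param s_L,s_A Specific absorbances of the two DOM pools (L/mg/m).
#' @return Tibble with `doc_mg_per_L`, `fe2_over_fetot`, `suva_proxy`.
#' @export
derived_chem <- function(aq, s_L = 1.0, s_A = 4.5) {
  doc <- .const$mg_C_per_mol *
    (aq[["DOM_L"]] + aq[["DOM_A"]] + 2 * aq[["acetate"]])
  fet <- aq[["Fe2"]] + aq[["Fe3aq"]]
  dom <- aq[["DOM_L"]] + aq[["DOM_A"]]
  tibble::tibble(
    doc_mg_per_L = doc,
    fe2_over_fetot = if (fet > 0) aq[["Fe2"]] / fet else 1,
    suva_proxy = if (dom > 0) {
      (s_L * aq[["DOM_L"]] + s_A * aq[["DOM_A"]]) / dom
    } else NA_real_)
}
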