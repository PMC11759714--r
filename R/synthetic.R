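## synthetic_experiment: seeded generator of an observation bundle emulating
## the column experiment's measurement streams.  Anchor values (printed
## observations) are imposed exactly after shape generation — by affine
## rescaling for the flux benchmarks and by noise-free control points for
## the porewater and profile tables — so the analysis operations recover
## them exactly; truncated multiplicative noise (sigma 2%, cut at 2.5 sigma)
## perturbs only non-anchor points.

## truncated standard-normal multiplicative factors
tnoise <- function(n, sigma = 0.02, trunc = 2.5) {
  x <- pmax(pmin(stats::rnorm(n), trunc), -trunc)
  1 + sigma * x
}

## linear interpolation through control points (2-column matrix time, value)
shape_interp <- function(ctrl, t) {
  approx(ctrl[, 1], ctrl[, 2], xout = t, rule = 2)$y
}

## Porewater sampling grid (weekly) and its anchor times for a plan
porewater_times <- function(plan) {
  total <- max(plan$phases$t_end)
  t <- seq(0, floor(total), by = 7)
  sat <- plan$phases[plan$phases$kind == "saturate", ][1, ]
  list(t = t,
       last_presat = max(t[t <= sat$t_start]),
       sat_samples = t[t > sat$t_start & t <= sat$t_end],
       last_sat = max(t[t > sat$t_start & t <= sat$t_end]))
}

#' Default flux-profile specification for a preset
#'
#' Phase-wise CO2 shapes (rise-dip-rise for the upland column, gradual rise
#' to a plateau for the thermokarst column) with the printed drain-phase
#' mean and run-maximum targets, and CH4 shapes (trace for UC; pulses around
#' days 35 and 80 for TC).  The maximum is held as a constant plateau for
#' 3 days, much longer than five headspace residence times.
#'
#' @param preset_name `"UC"` or `"TC"`.
#' @return Named list (per gas) of shape controls and targets.
#' @export
flux_profile_spec <- function(preset_name) {
  if (toupper(preset_name) == "UC") {
    list(
      CO2 = list(
        controls = cbind(
          c(0, 2, 5, 9, 14, 20, 28, 31.95,
            32.1, 52.9,
            53.1, 57, 61, 62.9, 66, 69, 75, 81),
          c(0.05, 0.65, 0.95, 0.78, 0.73, 0.95, 1.08, 1.04,
            0.02, 0.01,
            0.23, 0.93, 1.35, 1.702, 1.702, 1.17, 0.98, 0.84)),
        plateau = c(62.9, 66),
        drain_mean = 140.8, run_max = 234),
      CH4 = list(
        controls = cbind(c(0, 20, 40, 60, 81), c(0.2, 0.4, 0.3, 0.5, 0.3)),
        plateau = NULL, pulses = NULL,
        drain_mean = NULL, run_max = 0.04))
  } else {
    list(
      CO2 = list(
        controls = cbind(
          c(0, 6, 14, 22, 28, 29.6, 33.4, 36.9,
            37.1, 55.9,
            56.1, 62, 68, 74, 80, 86, 91),
          c(0.02, 0.06, 0.14, 0.28, 0.50, 1.0, 1.0, 0.55,
            0.02, 0.01,
            0.06, 0.18, 0.30, 0.36, 0.33, 0.28, 0.24)),
        plateau = c(29.6, 33.4),
        drain_mean = 33.9, run_max = 87),
      CH4 = list(
        controls = cbind(c(0, 37, 56, 91), c(0.02, 0.02, 0.015, 0.02)),
        plateau = NULL,
        pulses = list(list(center = 35, width = 1.2, amp = 1.0),
                      list(center = 80, width = 1.2, amp = 0.55)),
        drain_mean = NULL, run_max = 1.6))
  }
}

#' Generate true surface-flux series and forward-modelled headspace samples
#'
#' Builds a noisy flux shape per gas, imposes the drain-phase sample-mean and
#' run-maximum anchors exactly by affine rescaling (the plateau region is
#' noise-free so the maximum is held constant for at least five residence
#' times), forward-integrates the headspace CSTR exactly on a fine grid, and
#' samples the headspace at the requested times.
#'
#' @param spec Flux-profile spec ([flux_profile_spec()]).
#' @param hs Headspace state ([new_headspace()]).
#' @param sample_times Sampling times (days); the interval must exceed five
#'   residence times `V/Q`.
#' @param plan Phase plan (drain-phase classification of the samples).
#' @param seed Integer seed.
#' @return List: `true_flux` and `headspace_samples` tibbles, plus the fine
#'   `grid` series.
#' @export
generate_flux_and_headspace <- function(spec, hs, sample_times, plan,
                                        seed = 42) {
  set.seed(seed)
  res_days <- hs$V / hs$Q / 86400
  if (min(diff(sample_times)) < 5 * res_days) {
    stop("sample interval must be at least 5 CSTR residence times (",
         signif(5 * res_days, 3), " d)", call. = FALSE)
  }
  tf <- seq(0, max(sample_times), by = 0.005)
  drain_samples <- sample_times[phase_of(sample_times, plan) == "drain"]
  out_flux <- list(); out_hs <- list(); out_fine <- list()
  for (g in names(spec)) {
    sp <- spec[[g]]
    if (!is.null(sp$drain_mean) && !is.null(sp$run_max) &&
        sp$run_max < sp$drain_mean) {
      stop("infeasible flux spec for ", g,
           ": run maximum below drain-phase mean", call. = FALSE)
    }
    raw <- shape_interp(sp$controls, tf)
    if (!is.null(sp$pulses)) {
      for (pu in sp$pulses) {
        raw <- raw + pu$amp * exp(-0.5 * ((tf - pu$center) / pu$width)^2)
      }
    }
    anchor <- rep(FALSE, length(tf))
    if (!is.null(sp$plateau)) {
      anchor <- tf >= sp$plateau[1] & tf <= sp$plateau[2]
    }
    ## temporally smooth noise (0.5-day knots): the headspace averages over
    ## its residence time, so white noise at the integration grid would be
    ## unrecoverable by inversion rather than a measurement-like wiggle
    knots <- seq(0, max(tf) + 0.5, by = 0.5)
    fac <- approx(knots, tnoise(length(knots)), xout = tf)$y
    raw[!anchor] <- raw[!anchor] * fac[!anchor]
    raw <- pmax(raw, 0)
    if (!is.null(sp$plateau)) {
      ## the plateau is the run maximum: noise near its edges must not
      ## overtop it, or the maximum anchor would land off-plateau
      raw <- pmin(raw, max(raw[anchor]))
    }
    if (!is.null(sp$drain_mean)) {
      m_raw <- mean(approx(tf, raw, xout = drain_samples, rule = 2)$y)
      x_raw <- max(raw)
      a <- (sp$run_max - sp$drain_mean) / (x_raw - m_raw)
      b <- sp$drain_mean - a * m_raw
      if (b < 0) {
        stop("infeasible flux spec for ", g, ": shape drain-mean/maximum ",
             "ratio exceeds the target ratio (offset would be negative)",
             call. = FALSE)
      }
      flux <- a * raw + b
    } else if (!is.null(sp$run_max)) {
      flux <- raw / max(raw) * sp$run_max
    } else {
      flux <- raw
    }
    ## exact CSTR forward integration, piecewise-constant flux (umol -> mol);
    ## the purge ran before the first sample, so the headspace starts at the
    ## steady state of the initial flux
    C <- numeric(length(tf))
    C[1] <- hs$C_in[[g]] + flux[1] * 1e-6 * hs$A / hs$Q
    k <- hs$Q / hs$V
    for (i in 2:length(tf)) {
      dt_s <- (tf[i] - tf[i - 1]) * 86400
      C_ss <- hs$C_in[[g]] + flux[i - 1] * 1e-6 * hs$A / hs$Q
      C[i] <- C_ss + (C[i - 1] - C_ss) * exp(-k * dt_s)
    }
    Cs <- approx(tf, C, xout = sample_times)$y
    out_flux[[g]] <- tibble::tibble(
      time_days = sample_times, gas = g,
      flux_umol_per_s_per_m2 = approx(tf, flux, xout = sample_times)$y)
    out_hs[[g]] <- tibble::tibble(
      time_days = sample_times, gas = g,
      concentration_ppmv = Cs / .const$air_molar_density * 1e6)
    out_fine[[g]] <- tibble::tibble(time_days = tf, gas = g, flux = flux,
                                    concentration = C)
  }
  list(true_flux = dplyr::bind_rows(out_flux),
       headspace_samples = dplyr::bind_rows(out_hs),
       grid = dplyr::bind_rows(out_fine))
}

## Porewater control tables per preset.  Columns: depth_cm, then a list of
## control points; `rise` entries are imposed exactly against the
## last-presaturation sample.
porewater_shapes <- function(preset_name, pt) {
  lp <- pt$last_presat; ls <- pt$last_sat
  mid <- pt$sat_samples[ceiling(length(pt$sat_samples) / 2)]
  end <- max(pt$t)
  if (toupper(preset_name) == "UC") {
    ph <- list(
      `2`  = cbind(c(0, lp, mid, ls, (ls + end) / 2, end),
                   c(6.4, 6.35, 5.2, 4.6, 5.4, 5.8)),
      `12` = cbind(c(0, lp, mid, ls, (ls + end) / 2, end),
                   c(6.3, 6.28, 5.1, 4.4, 5.2, 5.6)),
      `22` = cbind(c(0, lp, ls, end), c(6.2, 6.18, 5.9, 6.1)),
      `32` = cbind(c(0, lp, ls, end), c(6.3, 6.32, 6.45, 6.35)),
      `42` = cbind(c(0, lp, ls, end), c(6.4, 6.42, 6.55, 6.45)))
    fe <- list(
      `2`  = cbind(c(0, lp, mid, ls, end), c(0.50, 0.42, 0.80, 0.88, 0.55)),
      `12` = cbind(c(0, lp, mid, ls, end), c(0.55, 0.48, 0.82, 0.90, 0.60)),
      `22` = cbind(c(0, lp, ls, end), c(0.60, 0.55, 0.85, 0.65)),
      `32` = cbind(c(0, lp, ls, end), c(0.70, 0.68, 0.88, 0.75)),
      `42` = cbind(c(0, lp, ls, end), c(0.80, 0.78, 0.90, 0.85)))
    doc_rise <- c(`2` = 374, `12` = 400, `22` = 103, `32` = 86, `42` = 30)
    suva <- cbind(c(0, end), c(1.6, 3.4))
  } else {
    ph <- list(
      `2`  = cbind(c(0, lp, mid, ls, (ls + end) / 2, end),
                   c(7.2, 7.15, 6.4, 6.0, 6.5, 6.7)),
      `12` = cbind(c(0, lp, mid, ls, (ls + end) / 2, end),
                   c(6.7, 6.68, 6.2, 5.85, 6.2, 6.4)),
      `22` = cbind(c(0, lp, ls, end), c(6.8, 6.78, 6.7, 6.75)),
      `32` = cbind(c(0, lp, ls, end), c(6.9, 6.9, 7.0, 6.95)),
      `42` = cbind(c(0, lp, ls, end), c(7.0, 7.0, 7.1, 7.05)))
    fe <- lapply(setNames(nm = c("2", "12", "22", "32", "42")), function(d) {
      cbind(c(0, lp, ls, end), c(0.95, 0.90, 0.93, 0.88))
    })
    doc_rise <- c(`2` = 0, `12` = 0, `22` = 0, `32` = 0, `42` = 0)
    suva <- cbind(c(0, end), c(2.0, 3.6))
  }
  list(ph = ph, fe = fe, doc_rise = doc_rise, suva = suva)
}

#' Generate the porewater DOC table
#'
#' Weekly Rhizon-depth DOC series.  For the upland column, initial values are
#' drawn from 95-131 mg/L, the saturation-phase rise (last saturation sample
#' minus last pre-saturation sample) is imposed exactly per depth
#' (374/400/103/86 mg/L at 2/12/22/32 cm), and the run maximum of 556 mg/L is
#' placed mid-saturation at 2 cm.  The thermokarst column has no rise beyond
#' noise (the two comparison samples are anchor points with zero base rise).
#'
#' @param preset Preset name or `column_preset`.
#' @param seed Integer seed.
#' @return Tibble `time_days`, `depth_cm`, `doc_mg_L`.
#' @export
generate_doc_series <- function(preset, seed = 42) {
  set.seed(seed + 1L)
  if (is.character(preset)) preset <- load_preset(preset)
  plan <- phase_plan(preset)
  pt <- porewater_times(plan)
  shapes <- porewater_shapes(preset$name, pt)
  lp <- pt$last_presat; ls <- pt$last_sat
  mid <- pt$sat_samples[ceiling(length(pt$sat_samples) / 2)]
  end <- max(pt$t)
  is_uc <- toupper(preset$name) == "UC"
  out <- list()
  for (d in names(shapes$doc_rise)) {
    rise <- shapes$doc_rise[[d]]
    v0 <- if (is_uc) stats::runif(1, 95, 131) else stats::runif(1, 60, 110)
    vlp <- v0 + if (is_uc) stats::runif(1, 10, 25) else 0
    vls <- vlp + rise
    vmid <- if (is_uc && d == "2") {
      556                                  # run maximum anchor
    } else if (is_uc) {
      vlp + 0.9 * rise
    } else {
      vlp
    }
    vend <- if (is_uc) vlp + 0.45 * rise else v0
    ctrl <- cbind(c(0, lp, mid, ls, (ls + end) / 2, end),
                  c(v0, vlp, vmid, vls, (vls + vend) / 2, vend))
    vals <- shape_interp(ctrl, pt$t)
    anchor <- pt$t %in% c(0, lp, mid, ls)
    vals[!anchor] <- vals[!anchor] * tnoise(sum(!anchor))
    out[[d]] <- tibble::tibble(time_days = pt$t,
                               depth_cm = as.numeric(d),
                               doc_mg_L = vals)
  }
  dplyr::bind_rows(out)
}

#' Generate the pre/post sequential iron-extraction tables
#'
#' Exact (noise-free) pool tables.  The upland column's organic-bound iron
#' moves from the organic layer (-51 umol Fe/g-dwt) to the mineral layer
#' (+44); every other pool, and every thermokarst pool, is unchanged.
#'
#' @param preset Preset name or `column_preset`.
#' @return List of tibbles `pre` and `post`, columns `layer`, `pool`,
#'   `umol_fe_per_g`.
#' @export
generate_fe_extractions <- function(preset) {
  if (is.character(preset)) name <- toupper(preset) else name <- preset$name
  pools <- c("exchangeable", "organic_bound", "poorly_crystalline",
             "crystalline")
  layers <- c("org", "min", "deep")
  pre_vals <- if (name == "UC") {
    c(8, 120, 45, 30,   10, 60, 80, 55,   12, 40, 60, 70)
  } else {
    c(10, 80, 30, 25,   12, 50, 60, 45,   9, 35, 55, 60)
  }
  pre <- tibble::tibble(layer = rep(layers, each = 4),
                        pool = rep(pools, 3),
                        umol_fe_per_g = pre_vals)
  post <- pre
  if (name == "UC") {
    post$umol_fe_per_g[post$layer == "org" & post$pool == "organic_bound"] <-
      pre$umol_fe_per_g[pre$layer == "org" & pre$pool == "organic_bound"] - 51
    post$umol_fe_per_g[post$layer == "min" & post$pool == "organic_bound"] <-
      pre$umol_fe_per_g[pre$layer == "min" & pre$pool == "organic_bound"] + 44
  }
  list(pre = pre, post = post)
}

#' Generate soil core depth profiles
#'
#' Monotone-trend profiles over 10 cm increments whose surface and deepest
#' values hit the printed anchors exactly: gravimetric water content
#' (UC 5.37 -> 0.95, TC 7.67 -> 0.77 g/g-dwt), carbon (UC 48 -> 15%, TC
#' 32 -> 18%), C:N (UC 44 -> 24), and KCl-extractable ferrous iron with the
#' thermokarst 8x the upland in the top 30 cm.
#'
#' @param preset Preset name or `column_preset`.
#' @param seed Integer seed.
#' @return Tibble `depth_cm`, `theta_g`, `pH_KCl`, `fe2_KCl_umol_g`,
#'   `pct_C`, `CN`.
#' @export
generate_depth_profiles <- function(preset, seed = 42) {
  set.seed(seed + 2L)
  if (is.character(preset)) name <- toupper(preset) else name <- preset$name
  depth <- seq(5, 65, by = 10)
  n <- length(depth)
  ramp <- function(top, bottom) top + (bottom - top) * (depth - depth[1]) /
    (depth[n] - depth[1])
  mid_noise <- function(x, sigma = 0.02) {
    x[2:(n - 1)] <- x[2:(n - 1)] * tnoise(n - 2, sigma)
    x
  }
  if (name == "UC") {
    theta_g <- mid_noise(ramp(5.37, 0.95))
    pct_C <- mid_noise(ramp(48, 15))
    CN <- mid_noise(ramp(44, 24))
    pH_KCl <- mid_noise(ramp(4.5, 6.5), 0.01)
    fe2 <- c(4, 6, 9, 12, 15, 18, 20)
  } else {
    theta_g <- mid_noise(ramp(7.67, 0.77))
    pct_C <- mid_noise(ramp(32, 18))
    CN <- mid_noise(c(26, 26, 27, 30, 33, 34, 34))
    pH_KCl <- mid_noise(ramp(5.5, 6.8), 0.01)
    fe2 <- c(8, 6, 9, 12, 15, 18, 20)    # top-30 entries overwritten below
    fe2[1:3] <- 8 * c(4, 6, 9)           # 8x the UC top-30 values, exact
    fe2[4:7] <- c(25, 20, 18, 16)
  }
  tibble::tibble(depth_cm = depth, theta_g = theta_g, pH_KCl = pH_KCl,
                 fe2_KCl_umol_g = fe2, pct_C = pct_C, CN = CN)
}

## outflow / vwc / o2 sensor fixtures (shapes only; no printed anchors)
generate_sensor_series <- function(preset, seed) {
  set.seed(seed + 3L)
  plan <- phase_plan(preset)
  ph <- plan$phases
  total <- max(ph$t_end)
  is_uc <- toupper(preset$name) == "UC"
  t <- seq(0, total, by = 0.5)
  drains <- ph[ph$kind == "drain", ]
  sat <- ph[ph$kind == "saturate", ][1, ]
  ## cumulative outflow: saturating exponentials per drain phase with noisy
  ## increments (keeps the series non-decreasing)
  tau <- if (is_uc) c(6, 8) else c(25, 30)
  amp <- if (is_uc) c(1200, 700) else c(1000, 800)
  cum <- numeric(length(t))
  for (i in seq_len(nrow(drains))) {
    tt <- pmax(0, pmin(t, drains$t_end[i]) - drains$t_start[i])
    cum <- cum + amp[i] * (1 - exp(-tt / tau[i]))
  }
  inc <- diff(c(0, cum)) * tnoise(length(t))
  outflow <- tibble::tibble(time_days = t,
                            cumulative_outflow_mL = cumsum(pmax(inc, 0)))
  ## VWC: porosity under saturation, exponential dry-down during drains
  por <- vapply(.sensor_depths$vwc, function(d) {
    ly <- if (d <= 0.15) preset$layers[[1]] else preset$layers[[2]]
    ly$porosity
  }, 0)
  floor_vwc <- if (is_uc) c(0.72, 0.60, 0.55) else c(0.68, 0.58, 0.55)
  tau_v <- if (is_uc) c(4, 8, 14) else c(18, 22, 30)
  vwc <- purrr::map_dfr(seq_along(por), function(j) {
    v <- rep(por[j], length(t))
    for (i in seq_len(nrow(drains))) {
      inwin <- t >= drains$t_start[i]
      tt <- pmax(0, pmin(t, drains$t_end[i]) - drains$t_start[i])
      v <- pmin(v, por[j] - (por[j] - floor_vwc[j]) * (1 - exp(-tt / tau_v[j])) *
                  (t >= drains$t_start[i] & t <= drains$t_end[i]) -
                  0 * inwin)
    }
    v[t > sat$t_start & t <= sat$t_end] <- por[j]
    tibble::tibble(time_days = t, depth_cm = .sensor_depths$vwc[j] * 100,
                   vwc = v * tnoise(length(t), 0.005))
  })
  ## O2 (% volume): logistic oxygenation during drains, near-zero when
  ## saturated and at the column base
  delay <- if (is_uc) c(1, 4, 9, 60) else c(3, 12, 22, 60)
  o2 <- purrr::map_dfr(seq_along(.sensor_depths$o2), function(j) {
    v <- numeric(length(t))
    for (i in seq_len(nrow(drains))) {
      tt <- t - drains$t_start[i] - delay[j]
      lo <- 20.5 / (1 + exp(-tt / 1.5))
      lo[t < drains$t_start[i] | t > drains$t_end[i]] <- 0
      v <- pmax(v, lo)
    }
    v[t > sat$t_start & t <= sat$t_end] <- 0.05
    v <- pmax(v, 0.02)
    tibble::tibble(time_days = t, depth_cm = .sensor_depths$o2[j] * 100,
                   o2_pct = v * tnoise(length(t), 0.02))
  })
  list(outflow = outflow, vwc = vwc, o2 = o2)
}

#' Generate a full synthetic observation bundle
#'
#' Deterministic per seed.  Assembles every measurement stream of a column
#' experiment: cumulative outflow, VWC and O2 sensor series, headspace gas
#' samples produced by exact forward CSTR integration of the anchor-exact
#' flux profiles, weekly porewater chemistry at the five Rhizon depths,
#' pre/post sequential iron extractions, and soil depth profiles.
#'
#' @param preset_name `"UC"` or `"TC"`.
#' @param seed Integer seed (default 42).
#' @return An `observation_bundle`: list of tibbles (`outflow`, `vwc`, `o2`,
#'   `headspace_samples`, `true_flux`, `porewater`, `fe_pre`, `fe_post`,
#'   `depth_profiles`) plus `preset`, `seed`, `plan`.
#' @export
generate_bundle <- function(preset_name, seed = 42) {
  preset <- load_preset(preset_name)
  plan <- phase_plan(preset)
  pt <- porewater_times(plan)
  shapes <- porewater_shapes(preset$name, pt)
  ## porewater pH / Fe ratio / SUVA
  set.seed(seed)
  pw <- purrr::map_dfr(names(shapes$ph), function(d) {
    phv <- shape_interp(shapes$ph[[d]], pt$t)
    anchor <- pt$t %in% c(0, pt$last_sat)
    phv[!anchor] <- phv[!anchor] + 0.03 *
      pmax(pmin(stats::rnorm(sum(!anchor)), 2.5), -2.5)
    fev <- shape_interp(shapes$fe[[d]], pt$t)
    fev <- pmin(pmax(fev * tnoise(length(fev)), 0), 1)
    su <- shape_interp(shapes$suva, pt$t) * tnoise(length(pt$t), 0.005)
    tibble::tibble(time_days = pt$t, depth_cm = as.numeric(d),
                   pH = phv, fe2_ratio = fev, suva = su)
  })
  doc <- generate_doc_series(preset, seed)
  pw <- dplyr::left_join(pw, doc, by = c("time_days", "depth_cm"))
  sens <- generate_sensor_series(preset, seed)
  geom <- column_geometry(preset)
  hs <- new_headspace(Q = preset$headspace$flow_mL_min * 1e-6 / 60,
                      V = preset$headspace$volume_L * 1e-3, A = geom$area)
  gas_t <- seq(0, floor(max(plan$phases$t_end)), by = 2)
  fx <- generate_flux_and_headspace(flux_profile_spec(preset$name), hs,
                                    gas_t, plan, seed = seed)
  fe <- generate_fe_extractions(preset)
  structure(list(
    preset = preset$name, seed = seed, plan = plan,
    outflow = sens$outflow, vwc = sens$vwc, o2 = sens$o2,
    headspace_samples = fx$headspace_samples,
    true_flux = fx$true_flux,
    porewater = pw[, c("time_days", "depth_cm", "pH", "fe2_ratio",
                       "doc_mg_L", "suva")],
    fe_pre = fe$pre, fe_post = fe$post,
    depth_profiles = generate_depth_profiles(preset, seed)),
    class = "observation_bundle")
}
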