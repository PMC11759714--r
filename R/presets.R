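## column_core: presets, geometry, phase schedules, column state construction

#' Load a packaged or external column preset
#'
#' Presets are hierarchical YAML files (`schema: 1`) describing column
#' geometry, the drain/saturate phase schedule, the headspace, and the two
#' soil layers (organic over mineral) with their hydraulic and biogeochemical
#' parameterisation.  The packaged presets are `"UC"` (upland tundra core)
#' and `"TC"` (thermokarst channel core).
#'
#' @param preset Either a preset name (`"UC"` or `"TC"`, case-insensitive) or
#'   a path to a YAML preset file.
#' @return A nested list mirroring the file, with class `"column_preset"`.
#' @export
load_preset <- function(preset) {
  path <- if (file.exists(preset)) {
    preset
  } else {
    p <- system.file("extdata", "presets",
                     paste0(tolower(preset), ".yml"),
                     package = "redoxcolumn")
    if (!nzchar(p)) {
      stop("unknown preset '", preset, "': expected 'UC', 'TC', ",
           "or a path to a preset YAML file", call. = FALSE)
    }
    p
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema) || cfg$schema != 1) {
    stop("unsupported preset schema '", cfg$schema %||% "<missing>",
         "'; supported versions: 1", call. = FALSE)
  }
  structure(cfg, class = "column_preset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load the packaged reaction-network and transport parameter set
#'
#' @param path Optional path to an alternative parameter YAML file.
#' @return A list with elements `kinetics` and `transport`.
#' @export
load_reaction_params <- function(path = NULL) {
  path <- path %||% system.file("extdata", "presets", "reactions.yml",
                                package = "redoxcolumn")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema) || cfg$schema != 1) {
    stop("unsupported reaction parameter schema; supported versions: 1",
         call. = FALSE)
  }
  cfg[c("kinetics", "transport")]
}

#' Column geometry from a preset
#'
#' @param preset A `column_preset` (or name accepted by [load_preset()]).
#' @return A list with `diameter`, `soil_depth`, `n_cells`, `dz`, `area`
#'   (m^2, exactly `pi * diameter^2 / 4`), and `z_centers` (cell-center
#'   depths, m, positive downward).
#' @export
column_geometry <- function(preset) {
  if (is.character(preset)) preset <- load_preset(preset)
  g <- preset$geometry
  dz <- g$soil_depth / g$n_cells
  list(diameter = g$diameter,
       soil_depth = g$soil_depth,
       n_cells = g$n_cells,
       dz = dz,
       area = pi * g$diameter^2 / 4,
       z_centers = (seq_len(g$n_cells) - 0.5) * dz)
}

#' Phase schedule from a preset
#'
#' @inheritParams column_geometry
#' @return A list with `phases` (tibble `kind`, `duration_days`, `t_start`,
#'   `t_end` in days) and `water_addition_hours`.
#' @export
phase_plan <- function(preset) {
  if (is.character(preset)) preset <- load_preset(preset)
  kinds <- vapply(preset$phases, `[[`, "", "kind")
  durs  <- vapply(preset$phases, `[[`, 0, "duration")
  ends  <- cumsum(durs)
  list(phases = tibble::tibble(kind = kinds,
                               duration_days = durs,
                               t_start = c(0, head(ends, -1)),
                               t_end = ends),
       water_addition_hours = preset$water_addition_hours %||% 2)
}

#' Phase windows of a plan as a tidy table
#'
#' @param plan A plan as returned by [phase_plan()].
#' @return The `phases` tibble with a `phase_id` column.
#' @export
phase_windows <- function(plan) {
  dplyr::mutate(plan$phases, phase_id = dplyr::row_number(),
                .before = 1)
}

## Classify sample times (days) into phase kinds; boundary times belong to
## the phase that ends there (a sample taken the day a phase ends still
## reflects that phase).
phase_of <- function(time_days, plan) {
  ph <- plan$phases
  kind <- rep(NA_character_, length(time_days))
  for (i in seq_len(nrow(ph))) {
    sel <- if (i == 1) {
      time_days >= ph$t_start[i] & time_days <= ph$t_end[i]
    } else {
      time_days > ph$t_start[i] & time_days <= ph$t_end[i]
    }
    kind[sel] <- ph$kind[i]
  }
  kind
}

## Resolve per-cell parameter vectors from the layered preset
resolve_layers <- function(preset, geom) {
  z <- geom$z_centers
  n <- geom$n_cells
  take <- function(f) {
    out <- rep(NA_real_, n)
    for (ly in preset$layers) {
      sel <- z >= ly$z_top & z < ly$z_bot + 1e-12
      out[sel] <- f(ly)
    }
    out
  }
  layer_name <- rep(NA_character_, n)
  for (ly in preset$layers) {
    layer_name[z >= ly$z_top & z < ly$z_bot + 1e-12] <- ly$name
  }
  aq <- sapply(.aq_species, function(s) take(function(ly) ly$init_aqueous[[s]] %||% 0))
  sol <- sapply(.sol_species, function(s) take(function(ly) ly$init_pools[[s]] %||% 0))
  gld <- sapply(.guilds, function(s) take(function(ly) ly$guild_factors[[s]] %||% 0))
  list(layer = layer_name,
       porosity = take(function(ly) ly$porosity),
       bulk_density = take(function(ly) ly$bulk_density),
       alpha = take(function(ly) ly$vg$alpha),
       n_vg = take(function(ly) ly$vg$n_vg),
       S_r = take(function(ly) ly$vg$S_r),
       K_sat = take(function(ly) ly$vg$K_sat),
       init_pH = take(function(ly) ly$init_pH %||% 7),
       buffer = take(function(ly) ly$buffer_mol_L %||% 0),
       C_per_Fe_OM = take(function(ly) ly$init_pools$C_per_Fe_OM %||% 0),
       init_aq = aq, init_sol = sol, guilds = gld)
}

#' Build a ready-to-run column from a preset
#'
#' Assembles the spatial grid, per-cell parameter fields, phase schedule and
#' initial state for a named column.  The column starts fully saturated (the
#' experiments began two days after saturating the packed soil), with the
#' net conservative charge `Z` of each layer chosen so the initial
#' charge-balance pH equals the layer's `init_pH` anchor.
#'
#' @param preset Preset name (`"UC"`, `"TC"`) or path, or a loaded
#'   `column_preset`.
#' @param params Reaction/transport parameter list
#'   (default [load_reaction_params()]).
#' @return A list of class `"column"` with elements `preset_name`, `geometry`,
#'   `plan`, `cells` (per-cell parameter fields), `params`, and `state`
#'   (the initial [column state][new_column_state]).
#' @export
build_column <- function(preset, params = load_reaction_params()) {
  if (is.character(preset)) preset <- load_preset(preset)
  viol <- validate_preset(preset)
  if (length(viol)) {
    stop("invalid preset '", preset$name, "':\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  }
  geom <- column_geometry(preset)
  plan <- phase_plan(preset)
  cells <- resolve_layers(preset, geom)
  ## calibrate per-cell conservative charge so initial pH hits the anchor
  cells$Z <- vapply(seq_len(geom$n_cells), function(i) {
    charge_for_ph(cells$init_pH[i],
                  DIC_T = cells$init_aq[i, "DIC"],
                  Ac_T = cells$init_aq[i, "acetate"],
                  Fe2_T = cells$init_aq[i, "Fe2"],
                  B_T = cells$buffer[i])
  }, 0)
  state <- new_column_state(preset, geom, cells, params)
  structure(list(preset_name = preset$name, preset = preset,
                 geometry = geom, plan = plan, cells = cells,
                 params = params, state = state),
            class = "column")
}

#' Initial column state
#'
#' The column starts fully saturated (water table at the surface), with
#' aqueous, gas, and solid pools taken from the preset layers and the
#' headspace at inflow-air composition.
#'
#' @param preset,geom,cells,params Internals produced by [build_column()].
#' @return A list of class `"column_state"`: `time` (s), `S_l`, `aq`
#'   (cells x species, mol/L), `gas` (cells x gases, mol/m^3), `sol`
#'   (cells x solids, mol/g-dwt), `z_wt` (water-table depth, m),
#'   `headspace`, `cum_outflow` (m^3), `effluent` (mol per species),
#'   `hs_export`/`hs_import` (cumulative mol through the purge outlet/inlet).
#' @export
new_column_state <- function(preset, geom, cells, params) {
  n <- geom$n_cells
  hs <- preset$headspace
  state <- list(
    time = 0,
    S_l = rep(1, n),
    z_wt = 0,
    aq = cells$init_aq,
    gas = matrix(0, n, length(.gas_species),
                 dimnames = list(NULL, .gas_species)),
    sol = cells$init_sol,
    headspace = list(
      C = air_composition(),
      Q = hs$flow_mL_min * 1e-6 / 60,   # m^3/s
      V = hs$volume_L * 1e-3,           # m^3
      A = geom$area,
      C_in = air_composition()),
    cum_outflow = 0,
    cum_added = 0,
    effluent = setNames(numeric(length(.aq_species)), .aq_species),
    hs_export = setNames(numeric(3), .gas_species),
    hs_import = setNames(numeric(3), .gas_species))
  class(state) <- "column_state"
  state
}

#' Validate a preset against its type invariants
#'
#' Reports (rather than fails): returns a character vector of violations,
#' empty when the preset satisfies every invariant.
#'
#' @param preset A `column_preset` or preset name.
#' @return Character vector of violation messages, each naming the offending
#'   field and the rule it breaks.
#' @export
validate_preset <- function(preset) {
  if (is.character(preset)) preset <- load_preset(preset)
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  g <- preset$geometry
  if (is.null(g)) {
    add("geometry: missing")
  } else {
    if (g$diameter <= 0) add("geometry$diameter: must be > 0")
    if (g$soil_depth <= 0) add("geometry$soil_depth: must be > 0")
    if (g$n_cells < 1 || g$n_cells != round(g$n_cells)) {
      add("geometry$n_cells: must be a positive integer")
    }
  }
  ph <- preset$phases
  if (is.null(ph) || !length(ph)) {
    add("phases: missing")
  } else {
    if (any(vapply(ph, `[[`, 0, "duration") <= 0)) {
      add("phases$duration: all durations must be > 0")
    }
    if (ph[[1]]$kind != "drain") add("phases: first phase must be 'drain'")
    if (!all(vapply(ph, `[[`, "", "kind") %in% c("drain", "saturate"))) {
      add("phases$kind: must be 'drain' or 'saturate'")
    }
  }
  for (ly in preset$layers) {
    at <- function(field) paste0("layers[", ly$name, "]$", field)
    if (ly$porosity <= 0 || ly$porosity >= 1) {
      add(paste0(at("porosity"), ": must satisfy 0 < porosity < 1"))
    }
    if (ly$z_top >= ly$z_bot) add(paste0(at("z_top"), ": requires z_top < z_bot"))
    if (ly$bulk_density <= 0) add(paste0(at("bulk_density"), ": must be > 0"))
    vg <- ly$vg
    if (vg$alpha <= 0) add(paste0(at("vg$alpha"), ": must be > 0"))
    if (vg$n_vg <= 1) add(paste0(at("vg$n_vg"), ": must be > 1"))
    if (vg$S_r < 0 || vg$S_r >= 1) {
      add(paste0(at("vg$S_r"), ": must satisfy 0 <= S_r < 1"))
    }
    if (vg$K_sat <= 0) add(paste0(at("vg$K_sat"), ": must be > 0"))
    pools <- unlist(ly$init_pools)
    if (any(pools < 0)) add(paste0(at("init_pools"), ": all pools must be >= 0"))
    aqv <- unlist(ly$init_aqueous)
    if (any(aqv < 0)) add(paste0(at("init_aqueous"), ": all totals must be >= 0"))
    gf <- unlist(ly$guild_factors)
    if (any(gf < 0)) add(paste0(at("guild_factors"), ": must be >= 0"))
  }
  v
}

## Sensor and sampler depths (m), mapped to nearest cell centers at use sites
.sensor_depths <- list(
  vwc = c(0.02, 0.15, 0.27),
  o2 = c(0.01, 0.085, 0.185, 0.36),
  rhizon = c(0.02, 0.12, 0.22, 0.32, 0.42))

## Nearest-cell index for a set of depths
cell_at_depth <- function(depth_m, geom) {
  vapply(depth_m, function(d) which.min(abs(geom$z_centers - d)), 0L)
}
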