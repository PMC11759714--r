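## io: observation-bundle and simulation-result archives as directories of
## plain CSVs with a JSON manifest (schema 1).  CSV dialect: UTF-8, comma
## separated, '.' decimal, units embedded in column names.

.bundle_tables <- c(outflow = "outflow.csv", vwc = "vwc.csv", o2 = "o2.csv",
                    headspace_samples = "headspace_samples.csv",
                    true_flux = "true_flux.csv", porewater = "porewater.csv",
                    fe_pre = "fe_extractions_pre.csv",
                    fe_post = "fe_extractions_post.csv",
                    depth_profiles = "depth_profiles.csv")

.bundle_required_cols <- list(
  outflow = c("time_days", "cumulative_outflow_mL"),
  vwc = c("time_days", "depth_cm", "vwc"),
  o2 = c("time_days", "depth_cm", "o2_pct"),
  headspace_samples = c("time_days", "gas", "concentration_ppmv"),
  true_flux = c("time_days", "gas", "flux_umol_per_s_per_m2"),
  porewater = c("time_days", "depth_cm", "pH", "fe2_ratio", "doc_mg_L",
                "suva"),
  fe_pre = c("layer", "pool", "umol_fe_per_g"),
  fe_post = c("layer", "pool", "umol_fe_per_g"),
  depth_profiles = c("depth_cm", "theta_g", "pH_KCl", "fe2_KCl_umol_g",
                     "pct_C", "CN"))

## Canonical CSV writer: doubles rendered at 15 significant digits so that
## write -> read -> write is byte-stable and values round-trip within 5e-16
## relative.
write_csv_canonical <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- sprintf("%.15g", out[[nm]])
      v[is.na(out[[nm]])] <- NA_character_
      out[[nm]] <- v
    }
  }
  readr::write_csv(out, path, quote = "needed")
}

#' Write an observation bundle to a directory
#'
#' One CSV per table plus `manifest.json` recording the schema version,
#' preset, seed and phase plan.
#'
#' @param bundle An `observation_bundle`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(.bundle_tables)) {
    write_csv_canonical(bundle[[nm]], file.path(dir, .bundle_tables[[nm]]))
  }
  manifest <- list(schema = 1, kind = "observation_bundle",
                   preset = bundle$preset, seed = bundle$seed,
                   phases = as.data.frame(
                     bundle$plan$phases[, c("kind", "duration_days")]),
                   water_addition_hours = bundle$plan$water_addition_hours)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an observation bundle from a directory
#'
#' Validates the manifest schema and each table's required columns.
#'
#' @param dir Directory written by [write_bundle()].
#' @return An `observation_bundle`.
#' @export
read_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(manifest$schema) || manifest$schema != 1) {
    stop("unsupported bundle schema '", manifest$schema %||% "<missing>",
         "'; supported versions: 1", call. = FALSE)
  }
  out <- list(preset = manifest$preset, seed = manifest$seed)
  ends <- cumsum(manifest$phases$duration_days)
  out$plan <- list(
    phases = tibble::tibble(kind = manifest$phases$kind,
                            duration_days = manifest$phases$duration_days,
                            t_start = c(0, head(ends, -1)), t_end = ends),
    water_addition_hours = manifest$water_addition_hours)
  for (nm in names(.bundle_tables)) {
    path <- file.path(dir, .bundle_tables[[nm]])
    if (!file.exists(path)) {
      stop("bundle table missing: ", .bundle_tables[[nm]], call. = FALSE)
    }
    tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(.bundle_required_cols[[nm]], names(tb))
    if (length(missing)) {
      stop(.bundle_tables[[nm]], ": missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out[[nm]] <- tb
  }
  structure(out, class = "observation_bundle")
}

#' Write a simulation result archive
#'
#' One tidy CSV per output table plus a manifest with the configuration
#' hash, seed and numerics.
#'
#' @param result A `simulation_result`.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("profiles", "fluxes", "headspace", "outflow", "vwc",
               "mass_balance")) {
    write_csv_canonical(result[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  hs <- result$final_state$headspace
  manifest <- c(result$manifest,
                list(kind = "simulation_result",
                     phases = as.data.frame(
                       result$plan$phases[, c("kind", "duration_days")]),
                     water_addition_hours = result$plan$water_addition_hours,
                     headspace = list(Q = hs$Q, V = hs$V, A = hs$A)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulation result archive
#'
#' Reloads the tables written by [write_simulation()] into a
#' `simulation_result` (without the full final state; the headspace
#' geometry is restored from the manifest).
#'
#' @param dir Directory written by [write_simulation()].
#' @return A `simulation_result`.
#' @export
read_simulation <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(manifest$schema) || manifest$schema != 1) {
    stop("unsupported simulation schema '", manifest$schema %||% "<missing>",
         "'; supported versions: 1", call. = FALSE)
  }
  out <- list(preset_name = manifest$preset, manifest = manifest)
  ends <- cumsum(manifest$phases$duration_days)
  out$plan <- list(
    phases = tibble::tibble(kind = manifest$phases$kind,
                            duration_days = manifest$phases$duration_days,
                            t_start = c(0, head(ends, -1)), t_end = ends),
    water_addition_hours = manifest$water_addition_hours)
  for (nm in c("profiles", "fluxes", "headspace", "outflow", "vwc",
               "mass_balance")) {
    out[[nm]] <- readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                                 show_col_types = FALSE, progress = FALSE)
  }
  out$headspace_geom <- manifest$headspace
  structure(out, class = "simulation_result")
}

usage_text <- function() {
  paste(
    "usage: redoxcolumn <command> [options]",
    "",
    "commands:",
    "  generate-fixtures --preset UC|TC [--seed N] --out DIR",
    "  simulate          --preset UC|TC [--mode gravity|prescribed]",
    "                    [--outflow CSV] [--seed N] [--days N] --out DIR",
    "  sweep             --preset UC|TC [--scenario name[,name...]]",
    "                    [--days N] --out DIR",
    "  analyze           --bundle DIR --out FILE.json",
    "  compare           --sim DIR --obs DIR --out FILE.csv",
    sep = "\n")
}

parse_flags <- function(argv) {
  flags <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    if (i == length(argv) || startsWith(argv[i + 1], "--")) {
      stop("flag ", a, " needs a value", call. = FALSE)
    }
    flags[[substring(a, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line dispatcher
#'
#' Subcommands: `generate-fixtures`, `simulate`, `sweep`, `analyze`,
#' `compare`.  Thin wrapper over the package functions, intended to be
#' called from an `Rscript` front-end (see `inst/cli/redoxcolumn.R`).
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code: 0 on success, 2 on usage errors, 1 on
#'   execution errors.
#' @export
cli_dispatch <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv) || argv[1] %in% c("-h", "--help", "help")) {
    cat(usage_text(), "\n")
    return(invisible(if (length(argv)) 0L else 2L))
  }
  cmd <- argv[1]
  flags <- tryCatch(parse_flags(argv[-1]), error = function(e) e)
  if (inherits(flags, "error") ||
      !cmd %in% c("generate-fixtures", "simulate", "sweep", "analyze",
                  "compare")) {
    if (inherits(flags, "error")) message(conditionMessage(flags))
    else message("unknown command: ", cmd)
    cat(usage_text(), "\n")
    return(invisible(2L))
  }
  seed <- as.integer(flags$seed %||% 42)
  need <- function(f) {
    if (is.null(flags[[f]])) stop("--", f, " is required", call. = FALSE)
    flags[[f]]
  }
  code <- tryCatch({
    switch(cmd,
      "generate-fixtures" = {
        bundle <- generate_bundle(toupper(need("preset")), seed = seed)
        write_bundle(bundle, need("out"))
        message("wrote bundle for ", bundle$preset, " (seed ", seed,
                ") to ", flags$out)
      },
      "simulate" = {
        mode <- flags$mode %||% "gravity"
        mode <- if (mode == "prescribed") "prescribed_outflow" else mode
        os <- if (!is.null(flags$outflow)) {
          readr::read_csv(flags$outflow, show_col_types = FALSE)
        } else NULL
        days <- if (!is.null(flags$days)) as.numeric(flags$days) else NULL
        res <- run_experiment(toupper(need("preset")), flow_mode = mode,
                              outflow_series = os, seed = seed,
                              horizon_days = days, quiet = FALSE)
        write_simulation(res, need("out"))
        mb <- res$mass_balance
        message("mass balance closure: ",
                paste(sprintf("%s %.2e", mb$quantity, mb$closure),
                      collapse = ", "))
      },
      "sweep" = {
        sc <- strsplit(flags$scenario %||% "ksat10,ksat01", ",")[[1]]
        days <- if (!is.null(flags$days)) as.numeric(flags$days) else 100
        sw <- sensitivity_sweep(toupper(need("preset")), scenarios = sc,
                                horizon_days = days, seed = seed)
        dir.create(need("out"), recursive = TRUE, showWarnings = FALSE)
        readr::write_csv(sw$responses,
                         file.path(flags$out, "responses.csv"))
        for (nm in names(sw$runs)) {
          write_simulation(sw$runs[[nm]], file.path(flags$out, nm))
        }
        message("sweep scenarios: ", paste(names(sw$runs), collapse = ", "))
      },
      "analyze" = {
        bundle <- read_bundle(need("bundle"))
        report <- analyze_bundle(bundle)
        jsonlite::write_json(report, need("out"), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        message("wrote analysis report to ", flags$out)
      },
      "compare" = {
        sim <- read_simulation(need("sim"))
        obs <- read_bundle(need("obs"))
        cmp <- compare_sim_to_obs(sim, obs)
        readr::write_csv(cmp, need("out"))
        message("wrote comparison metrics to ", flags$out)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

#' Standard analysis report of an observation bundle
#'
#' Applies the data-reduction operations to a bundle: CSTR flux inversion
#' and phase statistics per gas, DOC increases per depth, iron
#' redistribution, and the CO2-flux-versus-saturation rank correlation
#' (column-mean VWC as the saturation proxy).
#'
#' @param bundle An `observation_bundle`.
#' @param n_perm Permutations for the rank-correlation test.
#' @param seed Seed for the permutation draw.
#' @return A nested list (JSON-ready report).
#' @export
analyze_bundle <- function(bundle, n_perm = 10000, seed = 1) {
  geom <- column_geometry(load_preset(bundle$preset))
  hs <- new_headspace(A = geom$area)
  plan <- bundle$plan
  flux_stats <- list()
  for (g in c("CO2", "CH4")) {
    fl <- invert_flux(bundle$headspace_samples, hs, gas = g)
    st <- phase_statistics(fl, plan)
    flux_stats[[g]] <- as.data.frame(st)
  }
  doc <- sapply(sort(unique(bundle$porewater$depth_cm)), function(d) {
    doc_increase(bundle$porewater, plan, d)
  })
  names(doc) <- paste0("depth_", sort(unique(bundle$porewater$depth_cm)), "_cm")
  fe <- iron_redistribution(bundle$fe_pre, bundle$fe_post)
  co2 <- invert_flux(bundle$headspace_samples, hs, gas = "CO2")
  vwc_mean <- dplyr::summarise(
    dplyr::group_by(bundle$vwc, .data$time_days),
    vwc = mean(.data$vwc), .groups = "drop")
  sat_at <- approx(vwc_mean$time_days, vwc_mean$vwc,
                   xout = co2$time_days, rule = 2)$y
  rc <- rank_correlation(co2$flux_umol_per_s_per_m2, sat_at,
                         n_perm = n_perm, seed = seed)
  list(schema = 1, preset = bundle$preset, seed = bundle$seed,
       flux_phase_statistics = flux_stats,
       doc_increase_mg_L = as.list(doc),
       iron_redistribution = as.data.frame(fe$delta),
       co2_flux_vs_saturation = rc)
}
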