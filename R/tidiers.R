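## broom-style tidiers and ggplot2 visualisation for result objects

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @return The long profile tibble (`time_days`, `depth_cm`, `variable`,
#'   `value`).
#' @export
tidy.simulation_result <- function(x, ...) x$profiles

#' One-row summary of a simulation result
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @return Tibble with the preset, run length, cumulative outflow, drain and
#'   saturation CO2 flux means, and the worst mass-balance closure.
#' @export
glance.simulation_result <- function(x, ...) {
  co2 <- dplyr::filter(x$fluxes, .data$gas == "CO2")
  kind <- phase_of(co2$time_days, x$plan)
  tibble::tibble(
    preset = x$preset_name,
    days = max(x$outflow$time_days),
    cumulative_outflow_mL = max(x$outflow$cumulative_outflow_mL),
    co2_drain_mean = mean(co2$flux_umol_per_s_per_m2[!is.na(kind) & kind == "drain"]),
    co2_saturate_mean = mean(co2$flux_umol_per_s_per_m2[!is.na(kind) & kind == "saturate"]),
    worst_closure = max(abs(x$mass_balance$closure)))
}

#' Tidy a sweep result
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return Long tibble `scenario`, `time_days`, `response`, `value`.
#' @export
tidy.sweep_result <- function(x, ...) {
  tidyr::pivot_longer(x$responses, -c("scenario", "time_days"),
                      names_to = "response", values_to = "value")
}

#' Plot the depth-time evolution of a simulated variable
#'
#' @param object A `simulation_result`.
#' @param variable Profile variable to show (default `"S_l"`).
#' @param ... Unused.
#' @return A ggplot object (depth-time heat map).
#' @export
autoplot.simulation_result <- function(object, variable = "S_l", ...) {
  d <- dplyr::filter(object$profiles, .data$variable == !!variable)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_days, .data$depth_cm,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (days)", y = "depth (cm)", fill = variable) +
    ggplot2::theme_minimal()
}

#' Plot sweep response series by scenario
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object, one facet per response variable.
#' @export
autoplot.sweep_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_days, .data$value,
                                  colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot surface gas fluxes of a simulation
#'
#' @param result A `simulation_result`.
#' @param gases Which gases to draw.
#' @return A ggplot object with phase windows shaded.
#' @export
plot_fluxes <- function(result, gases = c("CO2", "CH4")) {
  d <- dplyr::filter(result$fluxes, .data$gas %in% gases)
  sat <- dplyr::filter(result$plan$phases, .data$kind == "saturate")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_days,
                                  .data$flux_umol_per_s_per_m2)) +
    ggplot2::geom_rect(data = sat,
                       ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~gas, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (days)", y = "flux (umol m-2 s-1)") +
    ggplot2::theme_minimal()
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> preset", x$preset_name, "\n")
  cat("  ", nrow(x$plan$phases), "phases over",
      max(x$plan$phases$t_end), "days;",
      length(unique(x$profiles$time_days)), "archive times\n")
  mb <- x$mass_balance
  cat(sprintf("  mass closure: %s\n",
              paste(sprintf("%s %.2e", mb$quantity, mb$closure),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.observation_bundle <- function(x, ...) {
  cat("<observation_bundle> preset", x$preset, "seed", x$seed, "\n")
  for (nm in names(.bundle_tables)) {
    cat(sprintf("  %-18s %5d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
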