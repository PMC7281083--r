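#' Experimental print condition
#'
#' Factor levels of the transition-distance characterization: extrusion
#' pressure, nozzle inner diameter, and whether the printhead's inner
#' channels carry the hydrophobic silicone coating.
#'
#' @param pressure_psi Extrusion pressure in psi (> 0; the characterization
#'   range is 25-55 psi).
#' @param nozzle_id_um Nozzle inner diameter in micrometres (> 0; typically
#'   200, 250, 330 or 430).
#' @param coated `TRUE` for a silicone-coated printhead.
#' @param bioink_pair Label of the ink pair (default `"red-blue"`).
#' @return An object of class `print_condition`.
#' @export
print_condition <- function(pressure_psi, nozzle_id_um, coated = FALSE,
                            bioink_pair = "red-blue") {
  if (!is_scalar_number(pressure_psi) || pressure_psi <= 0) {
    it_stop("`pressure_psi` must be > 0.", "inktransition_invalid_input")
  }
  if (!is_scalar_number(nozzle_id_um) || nozzle_id_um <= 0) {
    it_stop("`nozzle_id_um` must be > 0.", "inktransition_invalid_input")
  }
  structure(list(pressure_psi = pressure_psi,
                 nozzle_id_um = nozzle_id_um,
                 coated = isTRUE(coated),
                 bioink_pair = as.character(bioink_pair)),
            class = "print_condition")
}

as_print_condition <- function(x) {
  if (inherits(x, "print_condition")) return(x)
  if (is.list(x) && all(c("pressure_psi", "nozzle_id_um") %in% names(x))) {
    return(print_condition(x$pressure_psi, x$nozzle_id_um,
                           coated = isTRUE(x$coated),
                           bioink_pair = x$bioink_pair %||% "red-blue"))
  }
  it_stop("Cannot interpret `condition` as a print_condition.",
          "inktransition_invalid_input")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.print_condition <- function(x, ...) {
  cat(sprintf("<print_condition> %g psi, %g um nozzle, %s, inks %s\n",
              x$pressure_psi, x$nozzle_id_um,
              ifelse(x$coated, "coated", "regular"), x$bioink_pair))
  invisible(x)
}

#' Summarize transition distances per print condition
#'
#' Aggregates measured (or diffusion-corrected) transition distances over
#' distinct print conditions, reporting n, mean, sd (0 when n = 1), min and
#' max per condition, ordered by pressure, then nozzle diameter, then
#' coating. Flagged measurements (clipped at a profile boundary, or
#' negative after correction) are excluded by default.
#'
#' @param results A list of `transition_result`s carrying conditions, or a
#'   tibble from [transition_table()].
#' @param use_corrected Summarize `corrected_mm` instead of `distance_mm`.
#'   It is an error if any included result lacks a correction.
#' @param include_flagged Keep flagged measurements (default `FALSE`).
#' @return A tibble with one row per condition: `pressure_psi`,
#'   `nozzle_id_um`, `coated`, `bioink_pair`, `n`, `mean_mm`, `sd_mm`,
#'   `min_mm`, `max_mm`, `used_corrected`.
#' @export
summarize_conditions <- function(results, use_corrected = FALSE,
                                 include_flagged = FALSE) {
  tab <- if (is.data.frame(results)) results else transition_table(results)
  if (nrow(tab) == 0) {
    return(tibble::tibble(pressure_psi = numeric(), nozzle_id_um = numeric(),
                          coated = logical(), bioink_pair = character(),
                          n = integer(), mean_mm = numeric(), sd_mm = numeric(),
                          min_mm = numeric(), max_mm = numeric(),
                          used_corrected = logical()))
  }
  if (any(is.na(tab$pressure_psi) | is.na(tab$nozzle_id_um))) {
    it_stop("Every result must carry a print condition for aggregation.",
            "inktransition_invalid_input")
  }
  if (!include_flagged) {
    tab <- tab[tab$flags == "" | is.na(tab$flags), , drop = FALSE]
  }
  value <- if (use_corrected) tab$corrected_mm else tab$distance_mm
  if (use_corrected && anyNA(value)) {
    it_stop("use_corrected = TRUE but some results have no diffusion correction.",
            "inktransition_invalid_input")
  }
  tab$.value <- value
  tab |>
    dplyr::group_by(.data$pressure_psi, .data$nozzle_id_um, .data$coated,
                    .data$bioink_pair) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_mm = mean(.data$.value),
                     sd_mm = ifelse(dplyr::n() > 1, stats::sd(.data$.value), 0),
                     min_mm = min(.data$.value),
                     max_mm = max(.data$.value),
                     .groups = "drop") |>
    dplyr::mutate(used_corrected = use_corrected) |>
    dplyr::arrange(.data$pressure_psi, .data$nozzle_id_um, .data$coated)
}

#' Descriptive trend diagnostics over the condition grid
#'
#' For each (nozzle, coated) cell with at least two pressure levels,
#' reports the least-squares slope of the mean transition distance versus
#' pressure; and for each (pressure, coated) cell with at least two nozzle
#' sizes, the slope versus nozzle inner diameter. These are descriptive
#' slopes (sign and magnitude), not hypothesis tests — they render the
#' qualitative statements "transition distance increases with pressure"
#' and "decreases with nozzle diameter in coated printheads" as numbers.
#'
#' @param summaries Output of [summarize_conditions()].
#' @return A list of class `trend_report` with tibbles `pressure_trends`
#'   (`nozzle_id_um`, `coated`, `n_levels`, `slope_mm_per_psi`) and
#'   `nozzle_trends` (`pressure_psi`, `coated`, `n_levels`,
#'   `slope_mm_per_um`); cells with too few levels carry `NA` slopes.
#' @export
trend_report <- function(summaries) {
  slope_of <- function(x, y) {
    if (length(unique(x)) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(y ~ x))["x"])
  }
  pressure_trends <- summaries |>
    dplyr::group_by(.data$nozzle_id_um, .data$coated) |>
    dplyr::summarise(n_levels = length(unique(.data$pressure_psi)),
                     slope_mm_per_psi = slope_of(.data$pressure_psi, .data$mean_mm),
                     .groups = "drop") |>
    dplyr::arrange(.data$nozzle_id_um, .data$coated)
  nozzle_trends <- summaries |>
    dplyr::group_by(.data$pressure_psi, .data$coated) |>
    dplyr::summarise(n_levels = length(unique(.data$nozzle_id_um)),
                     slope_mm_per_um = slope_of(.data$nozzle_id_um, .data$mean_mm),
                     .groups = "drop") |>
    dplyr::arrange(.data$pressure_psi, .data$coated)
  structure(list(pressure_trends = pressure_trends,
                 nozzle_trends = nozzle_trends),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("Transition-distance trends (descriptive least-squares slopes)\n")
  cat("\nMean distance vs pressure, per nozzle x coating:\n")
  print(x$pressure_trends)
  cat("\nMean distance vs nozzle diameter, per pressure x coating:\n")
  print(x$nozzle_trends)
  invisible(x)
}

#' Plot condition summaries in the characterization layout
#'
#' Mean transition distance (error bars: +/- sd) against pressure, one
#' panel per nozzle inner diameter, regular and coated printheads as
#' separate series.
#'
#' @param summaries Output of [summarize_conditions()].
#' @return A ggplot object.
#' @export
plot_condition_summaries <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$pressure_psi, y = .data$mean_mm,
                               color = ifelse(.data$coated, "coated", "regular"))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_mm - .data$sd_mm,
                                        ymax = .data$mean_mm + .data$sd_mm),
                           width = 0.8) +
    ggplot2::facet_wrap(~nozzle_id_um, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Pressure (psi)", y = "Transition distance (mm)",
                  color = "Printhead") +
    ggplot2::theme_bw()
}
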