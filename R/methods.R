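#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a whole-body kinetics result into long format
#'
#' @param x A `kinetics_result` from [wholebody_kinetics()].
#' @param ... Unused.
#' @return A long tibble with `midpoint`, `phase`, `flux`, `value`.
#' @export
tidy.kinetics_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = -dplyr::all_of(c("t1", "t2", "midpoint", "phase")),
      names_to = "flux", values_to = "value"
    ) |>
    dplyr::select(dplyr::all_of(c("midpoint", "phase", "flux", "value")))
}

#' One-row summary of a whole-body kinetics result
#'
#' Reports the fasting baseline (-45 min midpoint), the postprandial peaks
#' of total and oral appearance, and the net protein gain AUC over the
#' postprandial midpoints.
#'
#' @param x A `kinetics_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.kinetics_result <- function(x, ...) {
  post <- dplyr::filter(tibble::as_tibble(x), .data$midpoint > 0)
  tibble::tibble(
    baseline_ra_total = baseline_summary(x$midpoint, x$ra_total, "kinetics"),
    baseline_net_gain_g_day = baseline_summary(x$midpoint, x$net_gain_g_day,
                                               "kinetics"),
    peak_ra_total = max(post$ra_total),
    peak_ra_oral = max(post$ra_oral),
    peak_hydroxylation = max(post$hydroxylation),
    net_gain_auc_g_kg = auc_trapezoid(post$midpoint,
                                      post$net_gain_g_day / 1440),
    n_midpoints = nrow(x)
  )
}

#' Plot whole-body flux trajectories
#'
#' @param object A `kinetics_result`.
#' @param fluxes Which flux columns to facet (default the four appearance/
#'   disposal rates and the gram-per-day series).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetics_result <- function(object,
                                     fluxes = c("ra_total", "ra_oral",
                                                "ra_endo", "rd_total",
                                                "hydroxylation",
                                                "net_gain_g_day"),
                                     ...) {
  df <- tidy(object) |> dplyr::filter(.data$flux %in% fluxes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~flux, scales = "free_y") +
    ggplot2::labs(x = "time relative to meal (min)", y = NULL,
                  title = "Whole-body phenylalanine kinetics") +
    ggplot2::theme_minimal()
}

#' Tidy an arteriovenous balance result into long format
#'
#' @param x An `av_balance_result` from [av_balance()].
#' @param ... Unused.
#' @return A long tibble with `time`, `analyte`, `metric`, `value`.
#' @export
tidy.av_balance_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = dplyr::any_of(c("net_balance", "fractional_extraction",
                             "uptake", "release")),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::select(dplyr::all_of(c("time", "analyte", "metric", "value")))
}

#' One-row summary of an arteriovenous balance result
#'
#' @param x An `av_balance_result`.
#' @param ... Unused.
#' @return One row per analyte: fasting and postprandial mean net balance,
#'   mean uptake and release where available.
#' @export
glance.av_balance_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::summarise(
      fasting_net_balance = mean(.data$net_balance[.data$time < 0]),
      postprandial_net_balance = mean(.data$net_balance[.data$time > 0]),
      mean_uptake = mean(.data$uptake, na.rm = TRUE),
      mean_release = mean(.data$release, na.rm = TRUE),
      .by = dplyr::all_of("analyte")
    )
}

#' Plot arteriovenous balance trajectories
#'
#' @param object An `av_balance_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.av_balance_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$analyte)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time relative to meal (min)", y = NULL,
                  title = "Tissue-bed amino acid balance") +
    ggplot2::theme_minimal()
}
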