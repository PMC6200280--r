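# ggplot2 helpers for the three result types.

#' Plot a trajectory
#'
#' Time courses of selected species or readouts.
#'
#' @param object A `"pd1_trajectory"` from [simulate_scenario()].
#' @param vars Columns to plot (default the percentage recruitments that
#'   are defined for the scenario).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pd1_trajectory
#' @export
autoplot.pd1_trajectory <- function(object,
                                    vars = c("pct_bound_shp2",
                                             "pct_bound_pi3k",
                                             "pct_bound_zap70",
                                             "pct_active_lck"), ...) {
  vars <- vars[vars %in% names(object)]
  df <- tidyr::pivot_longer(as_tibble(object)[c("time", vars)],
                            -"time", names_to = "quantity")
  df <- dplyr::filter(df, !is.na(.data$value))
  ggplot(df, aes(x = .data$time / 60, y = .data$value,
                 colour = .data$quantity)) +
    geom_line() +
    labs(x = "time (min)", y = "value",
         title = attr(object, "scenario_label")) +
    theme_bw()
}

#' Plot a PD-1 dose-response scan
#'
#' Normalized phosphorylation (% of the zero-PD-1 signal) against PD-1
#' surface density on a log axis, one curve per readout.
#'
#' @param object A `"pd1_dose_response"` from [scan_pd1()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pd1_dose_response
#' @export
autoplot.pd1_dose_response <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$dose_nm > 0)
  ggplot(df, aes(x = .data$dose_density, y = .data$normalized,
                 colour = .data$molecule)) +
    geom_line() + geom_point(size = 0.8) +
    scale_x_log10() +
    labs(x = "PD-1 (molecules/um^2)", y = "phosphorylation (% of no PD-1)") +
    theme_bw()
}

#' Plot MPSA sensitivities
#'
#' Bar plot of the per-parameter K-S statistics of one module.
#'
#' @param object An `"mpsa_result"` from [run_mpsa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpsa_result
#' @export
autoplot.mpsa_result <- function(object, ...) {
  df <- dplyr::mutate(object$ks,
                      parameter = factor(.data$parameter,
                                         levels = rev(.data$parameter)))
  ggplot(df, aes(x = .data$parameter, y = .data$ks)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "K-S statistic", title = object$module) +
    theme_bw()
}
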