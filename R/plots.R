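#' Plot simulation trajectories
#'
#' Carbon pools over time on a log10 y scale: substrates, reserve, structure,
#' cumulative CO2 and necromass.
#'
#' @param object a `deb_sim` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.deb_sim <- function(object, ...) {
  df <- tidy(object) |>
    filter(!.data$pool %in% c("m_E", "r", "BP_cum"), .data$value > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value,
                                   colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "mol C per litre",
                  title = paste("isolate", object$isolate)) +
    ggplot2::theme_minimal()
}

#' Plot the uptake strategy trade-off curve
#'
#' `Vmax` against `K` along a porter-density sweep, with point colour giving
#' the specific affinity (`Vmax/K`).
#'
#' @param object a `deb_tradeoff` tibble from [tradeoff_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.deb_tradeoff <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$K, .data$Vmax,
                                       colour = .data$specific_affinity)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "K (mM)",
                  y = expression(V[max] ~ "(mol substrate mol C"^-1 ~ h^-1 * ")"),
                  colour = expression(V[max] / K)) +
    ggplot2::theme_minimal()
}

#' Plot phenotype distributions by growth regime
#'
#' Histogram of realized growth rates with the regime threshold marked, as
#' produced by [classify_regimes()].
#'
#' @param phenotypes classified phenotype table.
#' @param bins histogram bins.
#' @return A ggplot.
#' @export
plot_regimes <- function(phenotypes, bins = 40) {
  thr <- attr(phenotypes, "threshold")
  df <- phenotypes |> filter(is.finite(.data$r_realized), .data$r_realized > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$r_realized,
                                        fill = .data$regime)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(r[realized] ~ (h^-1)), y = "simulations") +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = 2)
  }
  p
}

#' Plot the rate-yield relationship
#'
#' CUE against realized growth rate per substrate class and response group.
#'
#' @param phenotypes phenotype table with `class`, `r_realized`, `CUE`.
#' @return A ggplot.
#' @export
plot_rate_yield <- function(phenotypes) {
  df <- phenotypes |> filter(is.finite(.data$r_realized), is.finite(.data$CUE))
  ggplot2::ggplot(df, ggplot2::aes(.data$r_realized, .data$CUE,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(r[realized] ~ (h^-1)), y = "CUE") +
    ggplot2::theme_minimal()
}
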