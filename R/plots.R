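#' Plot simulated TE-load trajectories
#'
#' One line per replicate of mean TE load against generation, with an
#' overall least-squares trend (the same line whose slope
#' [fit_loss_regression()] converts into copies lost per 1000
#' generations).
#'
#' @param object A `"te_trajectory"` tibble.
#' @param trend Add the pooled linear trend?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_trajectory
#' @export
autoplot.te_trajectory <- function(object, trend = TRUE, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$generation,
                                    y = .data$mean_load,
                                    group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "Generation", y = "Mean TE load (copies)") +
    ggplot2::theme_minimal()
  if (trend)
    p <- p + ggplot2::geom_smooth(ggplot2::aes(group = NULL),
                                  method = "lm", formula = y ~ x,
                                  se = TRUE, colour = "black",
                                  linewidth = 0.8)
  p
}

#' Compare sexual and asexual TE-load trajectories
#'
#' Overlays the trajectories of two experiments (conventionally red for
#' the occasionally sexual regime and blue for the wholly asexual one)
#' with per-mode linear trends.
#'
#' @param sexual,asexual `"te_trajectory"` tibbles from
#'   [run_experiment()].
#' @return A ggplot object.
#' @export
plot_load_comparison <- function(sexual, asexual) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(sexual), mode = "sexual"),
    dplyr::mutate(tibble::as_tibble(asexual), mode = "asexual")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$generation,
                                    y = .data$mean_load,
                                    colour = .data$mode)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$mode,
                                                        .data$replicate)),
                       alpha = 0.4, linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(sexual = "#c0392b",
                                            asexual = "#2980b9")) +
    ggplot2::labs(x = "Generation", y = "Mean TE load (copies)",
                  colour = "Reproduction") +
    ggplot2::theme_minimal()
}

#' Plot coverage-corrected counts against generation
#'
#' Residual TE counts (after [residualize()]) against generation,
#' coloured by reproductive mode, with per-mode linear trends — the
#' standard view of coverage-corrected insertion counts over
#' experimental time.
#'
#' @param table A count table with `mode`, `generation`, `coverage`
#'   and `count`; residualised on the fly if no `resid` column is
#'   present.
#' @return A ggplot object.
#' @export
plot_residuals <- function(table) {
  if (!"resid" %in% names(table)) table <- residualize(table)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$generation,
                                      y = .data$resid,
                                      colour = .data$mode)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(sexual = "#c0392b",
                                            asexual = "#2980b9")) +
    ggplot2::labs(x = "Generation", y = "TE count (coverage residual)",
                  colour = "Reproduction") +
    ggplot2::theme_minimal()
}
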