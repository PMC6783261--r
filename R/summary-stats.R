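#' Linear-model estimate of TE loss from trajectories
#'
#' Fits an ordinary least-squares line to mean TE load versus generation
#' and converts the slope to the implied number of copies lost over
#' 1000 generations (`tes_lost_1000 = -slope * 1000`). By default the
#' (generation, mean_load) points of all replicates are pooled into one
#' fit; `method = "per_replicate"` instead fits each replicate and
#' averages the estimates (equivalent in expectation for balanced
#' sampling).
#'
#' @param trajectories A `"te_trajectory"` tibble, e.g. from
#'   [run_experiment()], with columns `replicate`, `generation`,
#'   `mean_load`.
#' @param method `"pooled"` (default) or `"per_replicate"`.
#' @return An object of class `"te_loss_fit"`: a list with `slope`
#'   (copies per generation), `intercept`, `se_slope`, `tes_lost_1000`,
#'   `n_points`, `n_replicates` and `method`. Use [generics::tidy()] /
#'   [generics::glance()] for tibble views.
#' @examples
#' traj <- tibble::tibble(replicate = 1L, generation = seq(0, 990, 90),
#'                        mean_load = 50 - 0.009 * seq(0, 990, 90))
#' fit_loss_regression(traj)$tes_lost_1000
#' @export
fit_loss_regression <- function(trajectories,
                                method = c("pooled", "per_replicate")) {
  method <- match.arg(method)
  stopifnot(all(c("replicate", "generation", "mean_load") %in%
                  names(trajectories)))
  if (length(unique(trajectories$generation)) < 2L)
    stop("at least two distinct sampled generations are required",
         call. = FALSE)

  if (method == "pooled") {
    fit <- stats::lm(mean_load ~ generation, data = trajectories)
    co <- summary(fit)$coefficients
    slope <- co["generation", "Estimate"]
    se <- co["generation", "Std. Error"]
    intercept <- co["(Intercept)", "Estimate"]
  } else {
    per <- trajectories |>
      dplyr::group_by(.data$replicate) |>
      dplyr::group_map(~ stats::coef(stats::lm(mean_load ~ generation,
                                               data = .x)))
    slopes <- vapply(per, `[[`, numeric(1), "generation")
    intercepts <- vapply(per, `[[`, numeric(1), "(Intercept)")
    slope <- mean(slopes)
    intercept <- mean(intercepts)
    se <- if (length(slopes) > 1L)
      stats::sd(slopes) / sqrt(length(slopes)) else NA_real_
  }

  structure(
    list(
      slope = slope,
      intercept = intercept,
      se_slope = se,
      tes_lost_1000 = -slope * 1000,
      n_points = nrow(trajectories),
      n_replicates = length(unique(trajectories$replicate)),
      method = method
    ),
    class = "te_loss_fit"
  )
}

#' @export
print.te_loss_fit <- function(x, ...) {
  cat("<te_loss_fit>\n")
  cat(sprintf("  slope: %.5g copies/generation (SE %.3g), intercept %.4g\n",
              x$slope, x$se_slope, x$intercept))
  cat(sprintf("  implied loss over 1000 generations: %.3g copies\n",
              x$tes_lost_1000))
  cat(sprintf("  fit: %s over %d points from %d replicate(s)\n",
              x$method, x$n_points, x$n_replicates))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_loss_regression
#' @param x A `"te_loss_fit"` object.
#' @param ... Unused.
#' @method tidy te_loss_fit
#' @export
tidy.te_loss_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se_slope)
  )
}

#' @rdname fit_loss_regression
#' @method glance te_loss_fit
#' @export
glance.te_loss_fit <- function(x, ...) {
  tibble::tibble(
    tes_lost_1000 = x$tes_lost_1000,
    slope = x$slope,
    se_slope = x$se_slope,
    n_points = x$n_points,
    n_replicates = x$n_replicates,
    method = x$method
  )
}

#' First sampled generation at which the modifier is fixed
#'
#' Scans each replicate's trajectory for the first sampled generation at
#' which the modifier-allele frequency reaches `threshold` (1.0 by
#' default: allele counts are discrete, so exact fixation is
#' observable).
#'
#' @param trajectories A `"te_trajectory"` tibble.
#' @param threshold Frequency treated as fixation.
#' @return A tibble with one row per replicate: `replicate`,
#'   `fixation_generation` (`NA` if the threshold is never reached).
#' @export
modifier_fixation_time <- function(trajectories, threshold = 1.0) {
  stopifnot(all(c("replicate", "generation", "modifier_freq") %in%
                  names(trajectories)))
  trajectories |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(
      fixation_generation = {
        hit <- .data$generation[.data$modifier_freq >= threshold]
        if (length(hit)) min(hit) else NA_integer_
      },
      .groups = "drop"
    )
}
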