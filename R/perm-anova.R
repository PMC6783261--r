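#' Drop samples with insufficient sequencing coverage
#'
#' Pooled-sequencing TE detection is unreliable below one-fold mean
#' per-base coverage, so such samples are excluded from all analyses.
#' The boundary is strict: exactly `min_coverage` is retained.
#'
#' @param table A tibble with a `coverage` column (and ideally `strain`
#'   and `generation` for informative messages).
#' @param min_coverage Exclusion threshold (default 1, i.e. one-fold).
#' @return The filtered tibble; each exclusion is reported via
#'   [message()].
#' @export
coverage_filter <- function(table, min_coverage = 1) {
  stopifnot("coverage" %in% names(table))
  drop <- which(table$coverage < min_coverage)
  if (length(drop)) {
    for (i in drop) {
      label <- if (all(c("strain", "generation") %in% names(table))) {
        sprintf("%s at generation %s", table$strain[i], table$generation[i])
      } else {
        sprintf("row %d", i)
      }
      message(sprintf(
        "excluding sample %s: coverage %.3g below %.3g-fold",
        label, table$coverage[i], min_coverage))
    }
    table <- table[-drop, , drop = FALSE]
  }
  table
}

#' Residualise TE counts on sequencing coverage
#'
#' TE detection probability rises with coverage, so observed counts are
#' regressed on mean coverage by ordinary least squares and the
#' residuals (observed minus fitted) carry the coverage-corrected
#' signal. If coverage is (numerically) constant the fallback is a
#' mean-only fit, i.e. centred counts.
#'
#' @param table A tibble with `count` and `coverage` columns; at least
#'   3 rows.
#' @return The input tibble with a `resid` column appended.
#' @examples
#' tab <- tibble::tibble(coverage = c(2, 4, 8, 10),
#'                       count = 3 * c(2, 4, 8, 10))
#' residualize(tab)$resid          # all ~0
#' @export
residualize <- function(table) {
  stopifnot(all(c("count", "coverage") %in% names(table)))
  if (nrow(table) < 3L)
    stop("residualisation needs at least 3 rows", call. = FALSE)
  if (stats::var(table$coverage) < .Machine$double.eps) {
    table$resid <- table$count - mean(table$count)
  } else {
    fit <- stats::lm(count ~ coverage, data = table)
    table$resid <- as.numeric(stats::resid(fit))
  }
  table
}

# ordered design matrix for count ~ coverage + generation + mode +
# generation:mode, with mode coded 0/1 (asexual = reference by sort order)
anova_design <- function(table) {
  modes <- sort(unique(as.character(table$mode)))
  if (length(modes) != 2L)
    stop("both reproductive modes must be present", call. = FALSE)
  if (length(unique(table$generation)) < 2L)
    stop("at least two distinct generations are required", call. = FALSE)
  mode01 <- as.numeric(as.character(table$mode) == modes[2])
  X <- cbind(
    `(Intercept)` = 1,
    coverage = table$coverage,
    generation = as.numeric(table$generation),
    mode = mode01,
    `generation:mode` = as.numeric(table$generation) * mode01
  )
  # locate a collinear term, if any, by stepwise rank
  qr_full <- qr(X)
  if (qr_full$rank < ncol(X)) {
    r_prev <- 0L
    for (j in seq_len(ncol(X))) {
      r <- qr(X[, seq_len(j), drop = FALSE])$rank
      if (r == r_prev)
        stop("design is rank deficient: term '", colnames(X)[j],
             "' is collinear with earlier terms", call. = FALSE)
      r_prev <- r
    }
  }
  X
}

# sequential (type-I) F statistics for the non-intercept columns of X,
# given an orthonormal basis Q of X in column order. y may be a matrix
# (columns = permuted responses).
sequential_f <- function(Q, y, df_res) {
  y <- as.matrix(y)
  qty <- crossprod(Q, y)                     # k x B
  rss <- colSums(y * y) - colSums(qty * qty) # residual SS per column
  ss <- qty[-1L, , drop = FALSE]^2           # 1-df sequential SS per term
  sweep(ss, 2L, rss / df_res, "/")           # F = (SS/1) / (RSS/df_res)
}

perm_p <- function(f_obs, f_star) {
  if (!is.finite(f_obs)) return(1)
  (1 + sum(f_star >= f_obs, na.rm = TRUE)) / (1 + length(f_star))
}

#' Permutation ANOVA of TE counts with a coverage covariate
#'
#' Fits the linear model
#' `count ~ coverage + generation + mode + generation:mode` (generation
#' numeric, mode a two-level factor) and computes term F statistics by
#' sequential type-I sums of squares in that order. Term p-values come
#' from an empirical permutation null rather than F-distribution
#' theory: `p = (1 + #{F* >= F_obs}) / (1 + n_permutations)`.
#'
#' Two permutation schemes are available. `"freedman_lane"` (default)
#' permutes, for each tested term, the residuals of the reduced model
#' containing the terms that precede it in the formula, adds them back
#' to the reduced-model fit and recomputes the term's sequential F on
#' the reconstructed response (the sequential Freedman-Lane scheme;
#' for the generation term this is exactly the classical
#' residuals-after-covariate permutation, which holds the level more
#' exactly than raw response shuffling when a nuisance covariate is
#' present). `"manly"` permutes the raw response, which is cheaper (one
#' permutation set serves all terms) and asymptotically equivalent
#' under exchangeability.
#'
#' Rows are sorted internally by (mode, generation, coverage, count)
#' before permuting, so results are exactly invariant to the row order
#' of the input.
#'
#' @param table Tibble with columns `strain`, `mode` (two levels),
#'   `generation`, `coverage`, `count`.
#' @param n_permutations Number of permutations (default 10000).
#' @param seed Mandatory RNG seed for the permutation draw.
#' @param scheme `"freedman_lane"` or `"manly"`.
#' @param filter_coverage If `TRUE` (default), [coverage_filter()] is
#'   applied first, dropping samples below one-fold coverage.
#' @return An object of class `"te_perm_anova"`; `tidy()` gives the
#'   per-term table (term, df, sumsq, statistic, p.value), `glance()`
#'   a one-row summary with `p_coverage`, `p_generation`, `p_mode`,
#'   `p_interaction`.
#' @export
perm_anova <- function(table, n_permutations = 10000L, seed,
                       scheme = c("freedman_lane", "manly"),
                       filter_coverage = TRUE) {
  scheme <- match.arg(scheme)
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  stopifnot(all(c("mode", "generation", "coverage", "count") %in% names(table)))
  if (filter_coverage) table <- coverage_filter(table)
  table <- table[order(table$mode, table$generation, table$coverage,
                       table$count), , drop = FALSE]

  X <- anova_design(table)
  y <- as.numeric(table$count)
  n <- length(y)
  k <- ncol(X)
  df_res <- n - k
  if (df_res < 1L) stop("not enough rows for the full model", call. = FALSE)

  qrx <- qr(X)
  Q <- qr.Q(qrx)
  f_obs <- sequential_f(Q, y, df_res)[, 1]
  ss_obs <- crossprod(Q, y)[-1L, 1]^2

  B <- as.integer(n_permutations)
  set.seed(seed)
  # B permutations of row indices, shared across terms
  perms <- replicate(B, sample.int(n))

  terms <- colnames(X)[-1L]
  p_vals <- numeric(length(terms))
  if (scheme == "manly") {
    y_star <- matrix(y[perms], nrow = n)
    f_star <- sequential_f(Q, y_star, df_res)
    for (j in seq_along(terms)) p_vals[j] <- perm_p(f_obs[j], f_star[j, ])
  } else {
    for (j in seq_along(terms)) {
      # reduced model: intercept plus the terms preceding term j
      qz <- qr(X[, seq_len(j), drop = FALSE])
      fitted_z <- qr.fitted(qz, y)
      resid_z <- qr.resid(qz, y)
      y_star <- fitted_z + matrix(resid_z[perms], nrow = n)
      f_star <- sequential_f(Q, y_star, df_res)[j, ]
      p_vals[j] <- perm_p(f_obs[j], f_star)
    }
  }

  structure(
    list(
      table = tibble::tibble(
        term = terms,
        df = 1L,
        sumsq = as.numeric(ss_obs),
        statistic = as.numeric(f_obs),
        p.value = p_vals
      ),
      n_permutations = B,
      scheme = scheme,
      n_obs = n,
      seed = seed
    ),
    class = "te_perm_anova"
  )
}

#' @export
print.te_perm_anova <- function(x, ...) {
  cat(sprintf("<te_perm_anova> %s scheme, %d permutations, n = %d\n",
              x$scheme, x$n_permutations, x$n_obs))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @rdname perm_anova
#' @param x A `"te_perm_anova"` object.
#' @param ... Unused.
#' @method tidy te_perm_anova
#' @export
tidy.te_perm_anova <- function(x, ...) x$table

#' @rdname perm_anova
#' @method glance te_perm_anova
#' @export
glance.te_perm_anova <- function(x, ...) {
  p <- stats::setNames(x$table$p.value, x$table$term)
  tibble::tibble(
    p_coverage = unname(p["coverage"]),
    p_generation = unname(p["generation"]),
    p_mode = unname(p["mode"]),
    p_interaction = unname(p["generation:mode"]),
    n_permutations = x$n_permutations,
    n_obs = x$n_obs,
    scheme = x$scheme
  )
}

#' TEs lost over 1000 generations from a residual slope
#'
#' Regresses coverage-corrected residual counts on generation by
#' ordinary least squares and converts the slope to the number of TE
#' copies lost over `horizon` generations: `tes_lost = -slope *
#' horizon`. The implied final copy number is
#' `ancestral_full_length - tes_lost`. A positive slope therefore
#' yields a negative loss, i.e. a gain, by the same sign convention.
#'
#' @param residuals Numeric residual counts (e.g. the `resid` column of
#'   [residualize()] applied to the asexual samples).
#' @param generations Generation of each residual.
#' @param ancestral_full_length Full-length TE copies in the ancestor
#'   (default 50).
#' @param horizon Generations over which the loss is projected.
#' @return A one-row tibble: `slope`, `se_slope`, `tes_lost`,
#'   `final_count`.
#' @examples
#' gens <- rep(seq(0, 990, 90), 4)
#' res <- -0.009 * gens
#' res <- res - mean(res)
#' tes_lost_from_residual_slope(res, gens)
#' @export
tes_lost_from_residual_slope <- function(residuals, generations,
                                         ancestral_full_length = 50,
                                         horizon = 1000) {
  if (length(residuals) != length(generations))
    stop("residuals and generations must have equal length", call. = FALSE)
  if (length(unique(generations)) < 2L)
    stop("at least two distinct generations are required", call. = FALSE)
  fit <- stats::lm(residuals ~ generations)
  co <- summary(fit)$coefficients
  slope <- co["generations", "Estimate"]
  se <- co["generations", "Std. Error"]
  tibble::tibble(
    slope = slope,
    se_slope = se,
    tes_lost = -slope * horizon,
    final_count = ancestral_full_length + slope * horizon
  )
}

#' Coverage-corrected TE loss for one reproductive mode
#'
#' Convenience pipeline mirroring the published analysis: drop
#' low-coverage samples, restrict to one reproductive mode, residualise
#' counts on coverage and convert the residual-versus-generation slope
#' into copies lost over 1000 generations.
#'
#' @param table A count table (`strain`, `mode`, `generation`,
#'   `coverage`, `count`).
#' @param mode Which reproductive mode to analyse (default
#'   `"asexual"`).
#' @inheritParams tes_lost_from_residual_slope
#' @return See [tes_lost_from_residual_slope()].
#' @export
estimate_te_loss <- function(table, mode = "asexual",
                             ancestral_full_length = 50, horizon = 1000) {
  stopifnot("mode" %in% names(table))
  tab <- coverage_filter(table)
  tab <- tab[as.character(tab$mode) == mode, , drop = FALSE]
  tab <- residualize(tab)
  tes_lost_from_residual_slope(tab$resid, tab$generation,
                               ancestral_full_length, horizon)
}
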