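# small Gaussian table with known structure
gauss_table <- function(n_per_cell = 3, effect_gen = 0, effect_int = 0,
                        sd = 1, seed = 1) {
  set.seed(seed)
  tab <- tidyr::expand_grid(
    mode = c("sexual", "asexual"),
    generation = seq(0, 990, 198),
    rep = seq_len(n_per_cell)
  )
  tab$strain <- paste0(substr(tab$mode, 1, 1), tab$rep)
  tab$coverage <- runif(nrow(tab), 2, 20)
  asex <- tab$mode == "asexual"
  tab$count <- 40 + 0.2 * tab$coverage + effect_gen * tab$generation +
    effect_int * tab$generation * asex + rnorm(nrow(tab), 0, sd)
  tab[, c("strain", "mode", "generation", "coverage", "count")]
}

test_that("residualisation removes the coverage trend", {
  tab <- tibble::tibble(coverage = c(2, 4, 8, 16),
                        count = 5 + 3 * c(2, 4, 8, 16))
  expect_equal(residualize(tab)$resid, rep(0, 4), tolerance = 1e-10)

  # counts unrelated to coverage: residuals are centred counts
  tab2 <- tibble::tibble(coverage = rep(10, 5), count = c(1, 2, 3, 4, 10))
  expect_equal(residualize(tab2)$resid, tab2$count - mean(tab2$count))

  expect_error(residualize(tab2[1:2, ]), "3 rows")
})

test_that("coverage filtering drops strictly sub-onefold samples", {
  tab <- tibble::tibble(strain = c("a", "b", "c"), generation = c(0, 90, 90),
                        coverage = c(0.8, 1.0, 5), count = 1:3)
  expect_message(kept <- coverage_filter(tab), "coverage 0.8")
  expect_equal(kept$strain, c("b", "c"))
  expect_silent(coverage_filter(kept))
})

test_that("permutation p-values respect their structural invariants", {
  tab <- gauss_table(seed = 5)
  res <- perm_anova(tab, n_permutations = 199, seed = 9)
  p <- tidy(res)$p.value
  expect_true(all(p >= 1 / 200 & p <= 1))

  # invariant to row order
  res_shuf <- perm_anova(tab[sample(nrow(tab)), ], n_permutations = 199,
                         seed = 9)
  expect_equal(tidy(res_shuf)$p.value, p)

  # invariant to affine rescaling of the response
  tab2 <- dplyr::mutate(tab, count = 3.7 * count + 11)
  res_aff <- perm_anova(tab2, n_permutations = 199, seed = 9)
  expect_equal(tidy(res_aff)$p.value, p)

  # constant response: degenerate F, p = 1 for every term
  tab3 <- dplyr::mutate(tab, count = 7)
  res_const <- perm_anova(tab3, n_permutations = 99, seed = 2)
  expect_true(all(tidy(res_const)$p.value == 1))
})

test_that("both permutation schemes approach the classical F test", {
  # Gaussian errors, all tested effects null: the empirical permutation
  # null must reproduce the F-distribution p-values
  tab <- gauss_table(n_per_cell = 4, sd = 3, seed = 7)
  fit <- stats::lm(count ~ coverage + generation * mode, data = tab)
  p_classic <- stats::anova(fit)[["Pr(>F)"]][1:4]

  for (scheme in c("freedman_lane", "manly")) {
    res <- perm_anova(tab, n_permutations = 10000, seed = 31, scheme = scheme)
    expect_lt(max(abs(tidy(res)$p.value - p_classic)), 0.02)
  }
})

test_that("rank-deficient designs are rejected with the term named", {
  tab <- gauss_table(seed = 13)
  tab$coverage <- tab$generation        # coverage aliases generation
  expect_error(perm_anova(tab, n_permutations = 9, seed = 1), "generation")

  one_mode <- dplyr::filter(gauss_table(), mode == "sexual")
  expect_error(perm_anova(one_mode, n_permutations = 9, seed = 1),
               "both reproductive modes")
})

test_that("residual slopes convert to TEs lost over 1000 generations", {
  gens <- rep(seq(0, 990, 90), 4)

  flat <- tes_lost_from_residual_slope(rep(0, length(gens)), gens)
  expect_equal(flat$tes_lost, 0)
  expect_equal(flat$final_count, 50)

  res <- -0.009 * gens; res <- res - mean(res)
  est <- tes_lost_from_residual_slope(res, gens)
  expect_equal(est$tes_lost, 9, tolerance = 1e-9)
  expect_equal(est$final_count, 41, tolerance = 1e-9)

  # positive slope reports a gain (negative loss) by the sign convention
  gain <- tes_lost_from_residual_slope(0.002 * gens, gens)
  expect_lt(gain$tes_lost, 0)
  expect_gt(gain$final_count, 50)

  expect_error(tes_lost_from_residual_slope(c(1, 2), c(5, 5)),
               "distinct generations")
})

test_that("the convenience pipeline reproduces the manual steps", {
  sim <- gen_count_table(seed = 17)
  manual <- sim$counts |>
    dplyr::filter(mode == "asexual") |>
    residualize()
  expected <- tes_lost_from_residual_slope(manual$resid, manual$generation)
  est <- estimate_te_loss(sim$counts)
  expect_equal(est$tes_lost, expected$tes_lost)
})
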