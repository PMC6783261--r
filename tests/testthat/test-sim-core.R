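test_that("fitness follows the log-quadratic cost and its contracts", {
  expect_equal(fitness(0, 0.3, 0.7), 1.0)
  expect_equal(fitness(50, 0.001, 0), exp(-0.05))
  expect_equal(fitness(2, 0.1, 0.2), exp(-0.2 - 0.4))
  # vectorised and strictly decreasing when any cost is positive
  w <- fitness(0:100, 0.001, 1e-5)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(fitness(-1, 0.1, 0), "n must be")
  expect_error(fitness(1, -0.1, 0), ">= 0")
})

test_that("transposition adds copies at empty sites and never removes", {
  g <- te_genome(1:10, n_chromosomes = 2L, loci_per_chromosome = 10L)
  set.seed(1)
  expect_identical(transpose(g, 0)$sites, g$sites)
  # u = 1 with enough empty sites: every copy duplicates exactly once
  g2 <- transpose(g, 1)
  expect_equal(copy_number(g2), 20)
  expect_true(all(g$sites %in% g2$sites))
  # saturation: pending insertions beyond the last empty site are skipped
  g_full <- te_genome(1:19, n_chromosomes = 2L, loci_per_chromosome = 10L)
  expect_equal(copy_number(transpose(g_full, 1)), 20)
  expect_error(transpose(g, 1.2), "u_eff")
})

test_that("transposition gain matches the binomial expectation n*u", {
  set.seed(11)
  g <- te_genome(sample.int(3200, 50))
  reps <- 20000
  gains <- replicate(reps, copy_number(transpose(g, 0.01))) - 50
  se <- sqrt(50 * 0.01 * 0.99 / reps)
  expect_lt(abs(mean(gains) - 0.5), 3 * se)
})

test_that("excision removes copies binomially, boosted by the modifier", {
  g <- te_genome(1:10, n_chromosomes = 2L, loci_per_chromosome = 10L)
  set.seed(2)
  expect_identical(excise(g, 0)$sites, g$sites)
  expect_equal(copy_number(excise(g, 1)), 0)

  carrier <- te_genome(sample.int(3200, 50), modifier = TRUE)
  reps <- 20000
  losses <- 50 - replicate(reps, copy_number(excise(carrier, 0.001, 0.002)))
  se <- sqrt(50 * 0.003 * 0.997 / reps)
  expect_lt(abs(mean(losses) - 0.15), 3 * se)
  # the modifier state itself is untouched
  expect_true(excise(carrier, 0.5, 0.1)$modifier)
})

test_that("parent sampling is fitness-weighted Wright-Fisher", {
  pop <- structure(
    list(genomes = list(integer(), 1:50), modifier = c(FALSE, FALSE),
         n = c(0L, 50L), generation = 0L,
         n_chromosomes = 16L, loci_per_chromosome = 200L),
    class = "te_population")
  p_neutral <- toy_params()
  set.seed(3)
  idx <- select_parents(pop, p_neutral, 1000)
  expect_length(idx, 1000)
  expect_true(all(idx %in% 1:2))

  # analytic two-individual case: P(n = 0 parent) = 1 / (1 + exp(-5))
  p_sel <- toy_params(a = 0.1)
  draws <- 20000
  idx <- select_parents(pop, p_sel, draws)
  p_expect <- 1 / (1 + exp(-5))
  se <- sqrt(p_expect * (1 - p_expect) / draws)
  expect_lt(abs(mean(idx == 1L) - p_expect), 3 * se)
})

test_that("recombination produces a mosaic of parental chromosomes", {
  set.seed(4)
  p1 <- te_genome(sample.int(3200, 50), modifier = TRUE)
  p2 <- te_genome(sample.int(3200, 40), modifier = FALSE)

  # identical parents reproduce themselves exactly
  expect_identical(recombine(p1, p1)$sites, p1$sites)

  # every offspring site occurs in at least one parent
  for (i in 1:50) {
    child <- recombine(p1, p2)
    expect_true(all(child$sites %in% c(p1$sites, p2$sites)))
    expect_true(!is.unsorted(child$sites))
    expect_false(anyDuplicated(child$sites) > 0)
  }

  # expected offspring load is the parental midpoint (50 x 0 cross)
  loaded <- te_genome(sample.int(3200, 50))
  empty <- te_genome(integer())
  reps <- 4000
  loads <- replicate(reps, copy_number(recombine(loaded, empty)))
  expect_lt(abs(mean(loads) - 25), 3 * sd(loads) / sqrt(reps))

  # the modifier is unlinked: inherited from either parent with prob 1/2
  mods <- replicate(2000, recombine(p1, p2)$modifier)
  expect_lt(abs(mean(mods) - 0.5), 3 * sqrt(0.25 / 2000))

  p_small <- te_genome(1:3, n_chromosomes = 2L, loci_per_chromosome = 10L)
  expect_error(recombine(p1, p_small), "layout")
})

test_that("founding creates a clonal deme and burn-in mutates it neutrally", {
  set.seed(5)
  p <- toy_params(pop_size = 30L, founder_copies = 5L)
  pop <- found_population(p)
  expect_length(pop$genomes, 30)
  expect_true(all(vapply(pop$genomes, identical, logical(1), pop$genomes[[1]])))
  expect_equal(unique(pop$n), 5L)
  expect_equal(pop$generation, 0L)

  expect_error(found_population(toy_params(founder_copies = 21L)), "exceeds")

  # burn-in branching expectation: E[n] = 50 * ((1+u)(1-v))^20
  set.seed(6)
  p2 <- sim_params(pop_size = 4000L, founder_copies = 50L,
                   burn_in_generations = 20L, u = 0.01, v = 0.01)
  pop2 <- found_population(p2)
  expected <- 50 * ((1 + 0.01) * (1 - 0.01))^20
  se <- sd(pop2$n) / sqrt(length(pop2$n))
  expect_lt(abs(mean(pop2$n) - expected), 3 * se)
})

test_that("one generation preserves deme size and neutral copy numbers", {
  set.seed(7)
  p <- toy_params(pop_size = 25L)
  pop <- found_population(p)
  nxt <- step_generation(pop, p)
  expect_length(nxt$genomes, 25)
  expect_equal(nxt$generation, 1L)
  # u = v = 0: every offspring genome is a copy of some parent genome
  expect_true(all(nxt$n == 5L))
  expect_true(all(vapply(nxt$genomes, identical, logical(1), pop$genomes[[1]])))

  # sexual generation keeps N and produces mosaics of parental sites
  ps <- toy_params(pop_size = 12L, sex_interval = 1L)
  pop <- found_population(ps)
  nxt <- step_generation(pop, ps)
  expect_length(nxt$genomes, 12)
  all_sites <- unique(unlist(pop$genomes))
  expect_true(all(unlist(nxt$genomes) %in% all_sites))
})

test_that("asexual neutral decay follows the closed form n0 (1-v)^t", {
  # u = 0, v = 0.005, no selection: E[load at t] = 50 * 0.995^t
  losses <- vapply(1:5, function(r) {
    p <- sim_params(pop_size = 1500L, total_generations = 200L,
                    burn_in_generations = 0L,
                    u = 0, v = 0.005, sample_every = 200L, seed = 80L)
    tail(run_replicate(p, r)$mean_load, 1)
  }, numeric(1))
  expected <- 50 * 0.995^200
  se <- sd(losses) / sqrt(length(losses))
  expect_lt(abs(mean(losses) - expected), 3 * se)
})

test_that("trajectories have the contracted shape and are reproducible", {
  p <- toy_params(total_generations = 23L, sample_every = 5L)
  tr <- run_replicate(p, 1)
  expect_equal(nrow(tr), 23 %/% 5 + 1)
  expect_equal(tr$generation, c(0L, 5L, 10L, 15L, 20L))

  # u = v = 0, no modifier effect: load constant across samples
  expect_true(all(tr$mean_load == tr$mean_load[1]))

  # identical master seed gives identical experiments, replicates differ
  p2 <- toy_params(u = 0.05, v = 0.02, total_generations = 20L)
  e1 <- run_experiment(p2)
  e2 <- run_experiment(p2)
  expect_identical(e1, e2)
  expect_false(identical(
    dplyr::filter(e1, replicate == 1)$mean_load,
    dplyr::filter(e1, replicate == 2)$mean_load
  ))
})

test_that("modifier frequency is a pure inheritance process", {
  # no selection, no rates: modifier frequency only drifts, stays in [0,1],
  # and is absorbed at 0/1 in asexual runs
  p <- toy_params(pop_size = 10L, total_generations = 40L,
                  sample_every = 1L, modifier_init_freq = 0.5)
  tr <- run_replicate(p, 1, seed = 99)
  expect_true(all(tr$modifier_freq >= 0 & tr$modifier_freq <= 1))
  hit <- which(tr$modifier_freq %in% c(0, 1))
  if (length(hit)) {
    expect_true(all(tr$modifier_freq[hit[1]:nrow(tr)] ==
                      tr$modifier_freq[hit[1]]))
  }
})
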