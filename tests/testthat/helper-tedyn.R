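# shared fixtures for the test suite

# tiny neutral scenario for contract checks; any field can be overridden
toy_params <- function(pop_size = 20L, n_chromosomes = 2L,
                       loci_per_chromosome = 10L, founder_copies = 5L,
                       burn_in_generations = 0L, total_generations = 10L,
                       sample_every = 5L, u = 0, v = 0, a = 0, b = 0,
                       n_replicates = 2L, seed = 42L, ...) {
  sim_params(pop_size = pop_size, n_chromosomes = n_chromosomes,
             loci_per_chromosome = loci_per_chromosome,
             founder_copies = founder_copies,
             burn_in_generations = burn_in_generations,
             total_generations = total_generations,
             sample_every = sample_every, u = u, v = v, a = a, b = b,
             n_replicates = n_replicates, seed = seed, ...)
}

# balanced 4 + 4 strain count table with explicit values
flat_count_table <- function(generations = seq(0, 990, 90),
                             coverage = 10, count = 40) {
  tidyr::expand_grid(
    strain = c("S1", "S2", "S3", "S4", "A1", "A2", "A3", "A4"),
    generation = generations
  ) |>
    dplyr::mutate(
      mode = ifelse(startsWith(strain, "S"), "sexual", "asexual"),
      coverage = coverage,
      count = count
    )
}
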