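#' Relative fitness of a TE-carrying individual
#'
#' Log-quadratic fitness function `w(n) = exp(-a * n - b * n^2 / 2)`
#' for an individual carrying `n` TE copies: `a` is the linear selection
#' strength per copy and `b` the synergistic epistasis strength (the
#' marginal cost of a copy grows with the load when `b > 0`).
#'
#' @param n Non-negative TE copy number (vectorised).
#' @param a Linear selection strength, `a >= 0`.
#' @param b Epistasis strength, `b >= 0`.
#' @return Relative fitness in `(0, 1]`, same length as `n`.
#' @examples
#' fitness(0, 0.001, 0)            # 1
#' fitness(50, 0.001, 0)           # exp(-0.05)
#' @export
fitness <- function(n, a, b) {
  if (any(n < 0)) stop("copy number n must be >= 0", call. = FALSE)
  if (a < 0 || b < 0) stop("a and b must be >= 0", call. = FALSE)
  exp(-a * n - 0.5 * b * n^2)
}

# ---- genome representation --------------------------------------------------
# A genome is a sorted integer vector of occupied site indices in
# 1..(n_chromosomes * loci_per_chromosome); site s lies on chromosome
# (s - 1) %/% loci_per_chromosome + 1. The population stores genomes as a
# plain list of such vectors plus a logical modifier vector, so the
# generation loop works on flat vectors.

#' Construct a single haploid genome
#'
#' @param sites Integer vector of occupied insertion sites (1-based,
#'   global indexing across chromosomes).
#' @param modifier Logical: does this genome carry the excision-rate
#'   modifier allele?
#' @param n_chromosomes,loci_per_chromosome Genome layout.
#' @return An object of class `"te_genome"`.
#' @examples
#' g <- te_genome(c(1L, 5L, 201L), modifier = FALSE)
#' copy_number(g)
#' @export
te_genome <- function(sites = integer(), modifier = FALSE,
                      n_chromosomes = 16L, loci_per_chromosome = 200L) {
  sites <- sort(unique(as.integer(sites)))
  n_sites <- n_chromosomes * loci_per_chromosome
  if (length(sites) && (sites[1] < 1L || sites[length(sites)] > n_sites))
    stop("site indices must lie in 1..", n_sites, call. = FALSE)
  structure(
    list(sites = sites, modifier = isTRUE(modifier)),
    n_chromosomes = as.integer(n_chromosomes),
    loci_per_chromosome = as.integer(loci_per_chromosome),
    class = "te_genome"
  )
}

#' @rdname te_genome
#' @param genome A `"te_genome"`.
#' @export
copy_number <- function(genome) length(genome$sites)

#' @export
print.te_genome <- function(x, ...) {
  cat(sprintf("<te_genome> %d copies over %d x %d loci; modifier %s\n",
              length(x$sites), attr(x, "n_chromosomes"),
              attr(x, "loci_per_chromosome"),
              if (x$modifier) "present" else "absent"))
  invisible(x)
}

# insert `gain` new copies at uniformly chosen empty sites; silently caps
# at the number of empty sites (never reached at yeast-like loads)
insert_new_copies <- function(sites, gain, n_sites) {
  empty_n <- n_sites - length(sites)
  k <- min(gain, empty_n)
  if (k == 0L) return(sites)
  empty <- if (length(sites)) seq_len(n_sites)[-sites] else seq_len(n_sites)
  new <- empty[sample.int(empty_n, k)]
  sort(c(sites, new))
}

remove_copies <- function(sites, loss) {
  n <- length(sites)
  k <- min(loss, n)
  if (k == 0L) return(sites)
  sites[-sample.int(n, k)]
}

#' Transposition step for one genome
#'
#' Each existing copy independently spawns one new copy with probability
#' `u_eff`; every new copy lands at a site drawn uniformly from the
#' currently empty sites. Existing copies are never removed. If no empty
#' site remains a pending insertion is silently skipped.
#'
#' @param genome A [te_genome()].
#' @param u_eff Transposition probability per copy, in `[0, 1]`.
#' @return The mutated genome.
#' @export
transpose <- function(genome, u_eff) {
  if (u_eff < 0 || u_eff > 1) stop("u_eff must be in [0, 1]", call. = FALSE)
  n_sites <- attr(genome, "n_chromosomes") * attr(genome, "loci_per_chromosome")
  gain <- stats::rbinom(1L, length(genome$sites), u_eff)
  genome$sites <- insert_new_copies(genome$sites, gain, n_sites)
  genome
}

#' Excision step for one genome
#'
#' Each copy is independently removed with probability
#' `v + modifier_delta_v` if the genome carries the modifier allele and
#' `v` otherwise. The modifier state itself is untouched.
#'
#' @param genome A [te_genome()].
#' @param v Baseline excision probability per copy.
#' @param modifier_delta_v Additive excision-rate increase in modifier
#'   carriers.
#' @return The mutated genome.
#' @export
excise <- function(genome, v, modifier_delta_v = 0) {
  v_eff <- v + if (genome$modifier) modifier_delta_v else 0
  if (v_eff < 0 || v_eff > 1)
    stop("effective excision probability must be in [0, 1]", call. = FALSE)
  loss <- stats::rbinom(1L, length(genome$sites), v_eff)
  genome$sites <- remove_copies(genome$sites, loss)
  genome
}

# recombine two site vectors; Poisson(1) crossovers per chromosome at
# uniform positions, starting parent per chromosome chosen fairly.
# Returns the offspring site vector (sorted).
recombine_sites <- function(s1, s2, n_chromosomes, loci) {
  ks <- stats::rpois(n_chromosomes, 1)
  total <- sum(ks)
  bp <- if (total) {
    sort((rep.int(seq_len(n_chromosomes), ks) - 1L) * loci +
           stats::runif(total, 0, loci))
  } else {
    numeric()
  }
  before <- c(0L, cumsum(ks))            # crossovers on earlier chromosomes
  start1 <- stats::runif(n_chromosomes) < 0.5  # TRUE: chromosome starts on parent 1

  from_parent1 <- function(sites) {
    if (!length(sites)) return(logical())
    chrom0 <- (sites - 1L) %/% loci      # 0-based chromosome index
    # locus centre on the global axis is sites - 0.5
    n_before <- findInterval(sites - 0.5, bp) - before[chrom0 + 1L]
    (n_before %% 2L == 0L) == start1[chrom0 + 1L]
  }

  keep1 <- from_parent1(s1)
  keep2 <- !from_parent1(s2)
  sort(c(s1[keep1], s2[keep2]))
}

#' Recombine two haploid genomes
#'
#' Models a sexual reproduction event: the two parental haploids fuse
#' and a recombinant haploid offspring is produced with a Poisson
#' (mean 1) number of crossovers per chromosome at uniform positions;
#' the starting parent of each chromosome is chosen fairly. The modifier
#' allele is unlinked and inherited from either parent with probability
#' 1/2, independently of all chromosomes.
#'
#' @param parent1,parent2 [te_genome()] objects with identical layout.
#' @return A recombinant `"te_genome"`.
#' @export
recombine <- function(parent1, parent2) {
  lay1 <- c(attr(parent1, "n_chromosomes"), attr(parent1, "loci_per_chromosome"))
  lay2 <- c(attr(parent2, "n_chromosomes"), attr(parent2, "loci_per_chromosome"))
  if (!identical(lay1, lay2))
    stop("parents have mismatched genome layouts", call. = FALSE)
  sites <- recombine_sites(parent1$sites, parent2$sites, lay1[1], lay1[2])
  te_genome(sites,
            modifier = if (stats::runif(1) < 0.5) parent1$modifier else parent2$modifier,
            n_chromosomes = lay1[1], loci_per_chromosome = lay1[2])
}

# ---- population -------------------------------------------------------------

#' Found a population from a single TE-carrying individual
#'
#' A founder genome receives `founder_copies` TE insertions at uniformly
#' chosen sites (without replacement) and populates the whole deme
#' clonally. The modifier allele is then assigned to each individual
#' independently with probability `modifier_init_freq`, and
#' `burn_in_generations` cycles of transposition followed by excision
#' are applied to every individual separately, with no selection and no
#' resampling.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `"te_population"` with elements `genomes`
#'   (list of site vectors), `modifier` (logical), `n` (integer copy
#'   numbers) and `generation` (0 after founding).
#' @export
found_population <- function(params) {
  validate_sim_params(params)
  n_sites <- params$n_chromosomes * params$loci_per_chromosome
  founder <- sort(sample.int(n_sites, params$founder_copies))
  N <- params$pop_size
  pop <- structure(
    list(
      genomes = rep(list(founder), N),
      modifier = stats::runif(N) < params$modifier_init_freq,
      n = rep.int(params$founder_copies, N),
      generation = 0L,
      n_chromosomes = params$n_chromosomes,
      loci_per_chromosome = params$loci_per_chromosome
    ),
    class = "te_population"
  )
  for (i in seq_len(params$burn_in_generations)) {
    pop <- mutate_population(pop, params$u, params)
  }
  pop
}

#' @export
print.te_population <- function(x, ...) {
  cat(sprintf(
    "<te_population> N = %d at generation %d; mean load %.2f; modifier freq %.3f\n",
    length(x$genomes), x$generation, mean(x$n), mean(x$modifier)))
  invisible(x)
}

# one transposition-then-excision pass over all individuals (no selection)
mutate_population <- function(pop, u_eff, params) {
  N <- length(pop$genomes)
  n_sites <- pop$n_chromosomes * pop$loci_per_chromosome
  gains <- stats::rbinom(N, pop$n, u_eff)
  for (i in which(gains > 0L)) {
    pop$genomes[[i]] <- insert_new_copies(pop$genomes[[i]], gains[i], n_sites)
  }
  if (any(gains > 0L)) pop$n <- lengths(pop$genomes)
  v_eff <- params$v + params$modifier_delta_v * pop$modifier
  losses <- stats::rbinom(N, pop$n, v_eff)
  for (i in which(losses > 0L)) {
    pop$genomes[[i]] <- remove_copies(pop$genomes[[i]], losses[i])
  }
  if (any(losses > 0L)) pop$n <- lengths(pop$genomes)
  pop
}

#' Sample parents proportional to fitness
#'
#' Wright-Fisher sampling with selection: `count` draws with
#' replacement, each individual's probability proportional to
#' `fitness(copy_number, a, b)`.
#'
#' @param pop A `"te_population"`.
#' @param params A [sim_params()] object (supplies `a` and `b`).
#' @param count Number of parents to draw (defaults to the deme size).
#' @return Integer vector of parent indices.
#' @export
select_parents <- function(pop, params, count = length(pop$genomes)) {
  N <- length(pop$genomes)
  if (N == 0L) stop("population is empty", call. = FALSE)
  if (params$a == 0 && params$b == 0) {
    sample.int(N, count, replace = TRUE)
  } else {
    sample.int(N, count, replace = TRUE, prob = fitness(pop$n, params$a, params$b))
  }
}

#' Advance the population by one generation
#'
#' One generation is a round of fitness-proportional parent sampling and
#' reproduction, with transposition acting during reproduction, followed
#' by excision of every offspring's copies. If the new generation index
#' is a multiple of `sex_interval` (and `sex_interval > 0`), every
#' offspring is instead produced by fusion of two distinct
#' fitness-sampled parents and recombination, with transposition at rate
#' `u_meiotic` applied to the recombinant. The deme size is constant.
#'
#' @param pop A `"te_population"`.
#' @param params A [sim_params()] object.
#' @return The next-generation `"te_population"`.
#' @export
step_generation <- function(pop, params) {
  gen_next <- pop$generation + 1L
  N <- length(pop$genomes)
  sexual <- params$sex_interval > 0L && gen_next %% params$sex_interval == 0L

  if (!sexual) {
    parents <- select_parents(pop, params)
    pop$genomes <- pop$genomes[parents]
    pop$modifier <- pop$modifier[parents]
    pop$n <- pop$n[parents]
    pop <- mutate_population(pop, params$u, params)
  } else {
    p1 <- select_parents(pop, params)
    p2 <- select_parents(pop, params)
    clash <- which(p2 == p1)
    while (length(clash)) {
      p2[clash] <- select_parents(pop, params, length(clash))
      clash <- clash[p2[clash] == p1[clash]]
    }
    offspring <- vector("list", N)
    for (i in seq_len(N)) {
      offspring[[i]] <- recombine_sites(pop$genomes[[p1[i]]],
                                        pop$genomes[[p2[i]]],
                                        pop$n_chromosomes,
                                        pop$loci_per_chromosome)
    }
    from1 <- stats::runif(N) < 0.5
    pop$genomes <- offspring
    pop$modifier <- ifelse(from1, pop$modifier[p1], pop$modifier[p2])
    pop$n <- lengths(offspring)
    pop <- mutate_population(pop, params$u_meiotic, params)
  }
  pop$generation <- gen_next
  pop
}

#' Run one simulation replicate
#'
#' Founds the population, iterates [step_generation()] for
#' `total_generations` generations and records the mean TE load, load
#' variance and modifier-allele frequency every `sample_every`
#' generations, including generation 0 (right after burn-in).
#'
#' @param params A [sim_params()] object.
#' @param replicate_id Replicate label stored in the output.
#' @param seed RNG seed for this replicate; defaults to
#'   `params$seed + replicate_id` (the sequential spawning rule used by
#'   [run_experiment()]).
#' @return A tibble of class `"te_trajectory"` with columns `replicate`,
#'   `generation`, `mean_load`, `var_load`, `modifier_freq`.
#' @examples
#' p <- sim_params(pop_size = 50, total_generations = 30, u = 0, v = 0,
#'                 sample_every = 10, seed = 1)
#' run_replicate(p)
#' @export
run_replicate <- function(params, replicate_id = 1L, seed = NULL) {
  validate_sim_params(params)
  if (is.null(seed)) seed <- params$seed + replicate_id
  set.seed(seed)
  pop <- found_population(params)
  n_samples <- params$total_generations %/% params$sample_every + 1L
  gens <- integer(n_samples)
  mean_load <- var_load <- mod_freq <- numeric(n_samples)
  record <- function(k) {
    gens[k] <<- pop$generation
    mean_load[k] <<- mean(pop$n)
    var_load[k] <<- if (length(pop$n) > 1L) stats::var(pop$n) else 0
    mod_freq[k] <<- mean(pop$modifier)
  }
  record(1L)
  k <- 1L
  for (g in seq_len(params$total_generations)) {
    pop <- step_generation(pop, params)
    if (g %% params$sample_every == 0L) {
      k <- k + 1L
      record(k)
    }
  }
  out <- tibble::tibble(
    replicate = as.integer(replicate_id),
    generation = gens,
    mean_load = mean_load,
    var_load = var_load,
    modifier_freq = mod_freq
  )
  class(out) <- c("te_trajectory", class(out))
  out
}

#' Run all replicates of a scenario
#'
#' Runs `params$n_replicates` independent replicates with seeds derived
#' deterministically from the master seed (`params$seed + replicate`),
#' so an identical master seed reproduces the experiment bit for bit.
#'
#' @param params A [sim_params()] object.
#' @param progress If `TRUE`, report per-replicate progress via
#'   [message()].
#' @return A `"te_trajectory"` tibble with all replicates stacked.
#' @examples
#' p <- sim_params(pop_size = 50, total_generations = 20, n_replicates = 2,
#'                 u = 0, v = 0, sample_every = 10, seed = 7)
#' run_experiment(p)
#' @export
run_experiment <- function(params, progress = FALSE) {
  validate_sim_params(params)
  out <- purrr::map(seq_len(params$n_replicates), function(r) {
    if (progress) message("replicate ", r, "/", params$n_replicates)
    run_replicate(params, replicate_id = r)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("te_trajectory", class(out))
  out
}
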