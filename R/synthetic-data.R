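#' Synthetic per-sample TE count table with known truth
#'
#' Emulates the data structure of the yeast experimental-evolution
#' design: `n_sexual_strains` sexual and `n_asexual_strains` asexual
#' strains sampled at `time_points` generations, with a latent
#' full-length TE count following a mode-specific linear trend plus
#' Gaussian noise, and an observed count thinned binomially by a
#' coverage-dependent detection probability
#' `p_det = 1 - exp(-k * coverage)`. The rate `k` is calibrated so that
#' `p_det(1x) = detectable_fraction`: at one-fold coverage roughly half
#' (24/50 by default) of the ancestral full-length insertions are
#' detectable, and detection saturates at deeper coverage.
#'
#' @param n_sexual_strains,n_asexual_strains Number of strains per
#'   reproductive mode (4 + 4 by default).
#' @param time_points Sampled generations (default 0, 90, ..., 990).
#' @param ancestral_full_length Latent full-length copies at
#'   generation 0.
#' @param detectable_fraction Detection probability at one-fold
#'   coverage (default 24/50).
#' @param asexual_slope,sexual_slope Latent trend in copies per
#'   generation for each mode.
#' @param coverage_range Mean per-base coverage is drawn uniformly from
#'   this range for every sample.
#' @param noise_sd Standard deviation of the Gaussian noise on the
#'   latent count.
#' @param seed RNG seed; identical seeds give identical tables.
#' @return A list with `counts` (tibble: `strain`, `mode`,
#'   `generation`, `coverage`, `count`) and `truth` (the same rows plus
#'   `true_count` and `p_det`), plus the generating `config`.
#' @examples
#' sim <- gen_count_table(seed = 1)
#' head(sim$counts)
#' @export
gen_count_table <- function(n_sexual_strains = 4L,
                            n_asexual_strains = 4L,
                            time_points = seq(0L, 990L, by = 90L),
                            ancestral_full_length = 50,
                            detectable_fraction = 24 / 50,
                            asexual_slope = -0.009,
                            sexual_slope = 0,
                            coverage_range = c(2, 20),
                            noise_sd = 2,
                            seed = 1L) {
  stopifnot(all(diff(time_points) > 0), detectable_fraction > 0,
            detectable_fraction <= 1, noise_sd >= 0)
  set.seed(seed)
  k_det <- -log(1 - min(detectable_fraction, 1 - 1e-12))

  design <- tidyr::expand_grid(
    strain = c(sprintf("S%d", seq_len(n_sexual_strains)),
               sprintf("A%d", seq_len(n_asexual_strains))),
    generation = as.integer(time_points)
  )
  design$mode <- ifelse(startsWith(design$strain, "S"), "sexual", "asexual")
  slope <- ifelse(design$mode == "asexual", asexual_slope, sexual_slope)

  n_row <- nrow(design)
  latent <- ancestral_full_length + slope * design$generation +
    stats::rnorm(n_row, 0, noise_sd)
  latent <- pmax(latent, 0)
  size <- as.integer(round(latent))
  coverage <- stats::runif(n_row, coverage_range[1], coverage_range[2])
  p_det <- 1 - exp(-k_det * coverage)
  observed <- stats::rbinom(n_row, size, p_det)

  counts <- tibble::tibble(
    strain = design$strain,
    mode = design$mode,
    generation = design$generation,
    coverage = coverage,
    count = observed
  )
  truth <- dplyr::mutate(counts, true_count = latent, p_det = p_det)
  list(
    counts = counts,
    truth = truth,
    config = list(
      ancestral_full_length = ancestral_full_length,
      detectable_fraction = detectable_fraction,
      asexual_slope = asexual_slope,
      sexual_slope = sexual_slope,
      coverage_range = coverage_range,
      noise_sd = noise_sd,
      k_det = k_det,
      seed = seed
    )
  )
}

mcclintock_callers <- c("ngs_te_mapper", "relocate", "temp",
                        "retroseq", "popoolationte", "te-locate")

#' Synthetic insertion-call table with known composition
#'
#' Generates an insertion-call table of the kind produced downstream of
#' multi-detector insertion-calling pipelines: each true insertion has
#' a class-consistent length (full-length within the canonical window,
#' solo LTR in 220-420 bp, truncated in between), is reported by 1-6
#' detectors, and each detector call jitters the breakpoint by at most
#' `position_jitter` bp. Distinct insertions are placed at least
#' `spacing` bp apart, so generator truth is recoverable exactly by
#' [deduplicate_insertions()] and [classify_insertions()] whenever
#' `2 * position_jitter <= position_tolerance < spacing -
#' 2 * position_jitter`.
#'
#' @param n_full,n_solo,n_truncated Number of true insertions per
#'   class.
#' @param detectors_per_insertion Set of possible detector counts per
#'   insertion (sampled uniformly).
#' @param position_jitter Maximum absolute breakpoint jitter per call
#'   (bp).
#' @param spacing Minimum distance between distinct insertions (bp).
#' @param strain,generation Sample labels stored in the records.
#' @param families Family reference table ([ty_family_lengths()]).
#' @param seed RNG seed.
#' @return A list with `records` (tibble: `strain`, `generation`,
#'   `chromosome`, `position`, `length`, `family`, `detector`,
#'   `reference_flag`) and `truth` (one row per true insertion with its
#'   class and detector count).
#' @examples
#' fix <- gen_insertion_records(n_full = 3, n_solo = 2, n_truncated = 1,
#'                              seed = 1)
#' nrow(fix$truth)
#' @export
gen_insertion_records <- function(n_full = 24L, n_solo = 100L,
                                  n_truncated = 10L,
                                  detectors_per_insertion = 1:6,
                                  position_jitter = 50L,
                                  spacing = 10000L,
                                  strain = "anc", generation = 0L,
                                  families = ty_family_lengths(),
                                  seed = 1L) {
  stopifnot(n_full >= 0, n_solo >= 0, n_truncated >= 0,
            position_jitter >= 0, spacing > 4L * position_jitter)
  set.seed(seed)
  n_total <- n_full + n_solo + n_truncated
  chroms <- paste0("chr", as.character(utils::as.roman(1:16)))

  empty_records <- tibble::tibble(
    strain = character(), generation = integer(), chromosome = character(),
    position = integer(), length = integer(), family = character(),
    detector = character(), reference_flag = logical()
  )
  if (n_total == 0L) {
    return(list(records = empty_records,
                truth = tibble::tibble(
                  insertion_id = integer(), chromosome = character(),
                  position = integer(), family = character(),
                  class = character(), n_detectors = integer())))
  }

  cls <- rep(c("full_length", "solo_LTR", "truncated"),
             times = c(n_full, n_solo, n_truncated))
  fam <- sample(families$family, n_total, replace = TRUE)
  canon <- families$full_length[match(fam, families$family)]

  len <- integer(n_total)
  for (i in seq_len(n_total)) {
    len[i] <- switch(
      cls[i],
      full_length = canon[i] + sample(-500:500, 1L),
      solo_LTR = sample(220:420, 1L),
      truncated = sample(421:(canon[i] - 501L), 1L)
    )
  }

  # round-robin chromosome assignment with per-chromosome slots keeps
  # distinct insertions >= `spacing` bp apart
  chrom_idx <- rep_len(seq_along(chroms), n_total)
  slot <- stats::ave(seq_len(n_total), chrom_idx, FUN = seq_along)
  base_pos <- as.integer(slot * spacing)

  n_det <- sample(detectors_per_insertion, n_total, replace = TRUE)
  truth <- tibble::tibble(
    insertion_id = seq_len(n_total),
    chromosome = chroms[chrom_idx],
    position = base_pos,
    family = fam,
    class = cls,
    n_detectors = as.integer(n_det)
  )

  records <- purrr::map(seq_len(n_total), function(i) {
    dets <- sample(mcclintock_callers, n_det[i])
    jit <- if (position_jitter > 0L)
      sample((-position_jitter):position_jitter, n_det[i], replace = TRUE)
    else rep(0L, n_det[i])
    tibble::tibble(
      strain = strain,
      generation = as.integer(generation),
      chromosome = chroms[chrom_idx[i]],
      position = as.integer(base_pos[i] + jit),
      length = len[i],
      family = fam[i],
      detector = dets,
      reference_flag = TRUE
    )
  }) |> dplyr::bind_rows()

  list(records = records, truth = truth)
}

#' Synthetic TE-mapped read counts with a programmed load decline
#'
#' Generates per-sample total and TE-mapped read counts for one strain
#' whose genome-wide TE read fraction declines linearly by
#' `total_reduction` (as a proportion of the baseline fraction) between
#' the first and last time point, so [te_read_fraction()] recovers the
#' programmed decline up to integer rounding of read counts.
#'
#' @param time_points Sampled generations.
#' @param baseline_fraction TE read fraction at the first time point.
#' @param total_reduction Proportional reduction of the fraction at the
#'   last time point (0.235 mirrors a 23.5% total load reduction).
#' @param mean_reads Mean total mapped reads per sample.
#' @param seed RNG seed (total read depths are drawn uniformly within
#'   +/-50% of `mean_reads`).
#' @return A tibble with `generation`, `total_mapped_reads`,
#'   `te_mapped_reads` and `true_fraction`.
#' @export
gen_read_count_table <- function(time_points = seq(0L, 990L, by = 90L),
                                 baseline_fraction = 0.035,
                                 total_reduction = 0.235,
                                 mean_reads = 3e6,
                                 seed = 1L) {
  stopifnot(baseline_fraction > 0, baseline_fraction < 1,
            total_reduction < 1)
  set.seed(seed)
  span <- max(time_points) - min(time_points)
  frac <- baseline_fraction *
    (1 - total_reduction * (time_points - min(time_points)) / span)
  total <- round(stats::runif(length(time_points),
                              0.5 * mean_reads, 1.5 * mean_reads))
  tibble::tibble(
    generation = as.integer(time_points),
    total_mapped_reads = total,
    te_mapped_reads = round(total * frac),
    true_fraction = frac
  )
}
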