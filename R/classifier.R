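#' Canonical Ty family lengths
#'
#' Editable reference table of canonical full-length element sizes and
#' LTR lengths (bp) for the five *S. cerevisiae* Ty families, compiled
#' from the yeast TE literature. Used by [classify_insertions()] to
#' decide whether a called insertion length is compatible with a
#' full-length element, a solo LTR or a truncated copy.
#'
#' @return A tibble with columns `family`, `full_length`, `ltr_length`.
#' @examples
#' ty_family_lengths()
#' @export
ty_family_lengths <- function() {
  tibble::tibble(
    family = c("Ty1", "Ty2", "Ty3", "Ty4", "Ty5"),
    full_length = c(5918L, 5959L, 5351L, 6223L, 5375L),
    ltr_length = c(334L, 332L, 340L, 371L, 251L)
  )
}

#' Length-based classification of TE insertion calls
#'
#' Tags each insertion by its called length: `full_length` if the
#' length is within `full_window` bp of the family's canonical size
#' (internal sequence plus two LTRs), `solo_LTR` if it falls in the
#' solo-LTR window (220-420 bp by default, family independent),
#' `truncated` if it lies between the solo-LTR ceiling and the
#' full-length window floor, and `other` otherwise. Records of unknown
#' family can never be called `full_length` or `truncated`; if such a
#' record is long enough that the call would have mattered, it is tagged
#' `other` with a warning.
#'
#' @param records Tibble of insertion calls with at least `length` and
#'   `family` columns.
#' @param families Family reference table, see [ty_family_lengths()].
#' @param full_window Half-width of the full-length window (bp).
#' @param solo_range Inclusive `[min, max]` solo-LTR length window (bp).
#' @return `records` with a `class` column appended (factor with levels
#'   full_length, solo_LTR, truncated, other).
#' @examples
#' recs <- tibble::tibble(family = c("Ty1", "Ty1", "Ty2"),
#'                        length = c(5900L, 300L, 1500L))
#' classify_insertions(recs)$class
#' @export
classify_insertions <- function(records, families = ty_family_lengths(),
                                full_window = 500, solo_range = c(220, 420)) {
  stopifnot(all(c("length", "family") %in% names(records)))
  if (any(records$length <= 0)) stop("lengths must be > 0", call. = FALSE)
  canonical <- stats::setNames(families$full_length, families$family)
  len <- as.numeric(records$length)
  canon <- unname(canonical[as.character(records$family)])  # NA if unknown

  is_solo <- len >= solo_range[1] & len <= solo_range[2]
  is_full <- !is.na(canon) & abs(len - canon) <= full_window
  is_trunc <- !is.na(canon) & len > solo_range[2] & len < canon - full_window

  cls <- rep("other", length(len))
  cls[is_trunc] <- "truncated"
  cls[is_solo] <- "solo_LTR"
  cls[is_full] <- "full_length"

  unknown_long <- is.na(canon) & !is_solo
  if (any(unknown_long))
    warning(sum(unknown_long), " record(s) of unknown family outside the ",
            "solo-LTR window were tagged 'other'", call. = FALSE)

  records$class <- factor(cls, levels = c("full_length", "solo_LTR",
                                          "truncated", "other"))
  records
}

#' Deduplicate insertion calls made by multiple detectors
#'
#' Complementary insertion detectors report the same event at slightly
#' different breakpoints. Calls from the same strain, generation,
#' chromosome and family whose positions chain within
#' `position_tolerance` bp of a neighbour (single-linkage clustering
#' along the chromosome) are merged into one insertion, so an insertion
#' with evidence from several programs is counted only once. The merged
#' record keeps the median position, the union of detectors and the
#' median called length.
#'
#' @param records Tibble with columns `strain`, `generation`,
#'   `chromosome`, `position` (0-based leftmost coordinate), `length`,
#'   `family`, `detector`.
#' @param position_tolerance Maximum bp gap between neighbouring calls
#'   merged into one insertion (default 100).
#' @return A tibble of unique insertions: grouping keys plus `position`
#'   (median), `length` (median), `n_detectors`, `detectors`
#'   (comma-collapsed, deduplicated) and `dedup_group` id.
#' @examples
#' calls <- tibble::tibble(
#'   strain = "A", generation = 0L, chromosome = "chrI",
#'   position = c(1000L, 1010L, 1050L), length = 334L,
#'   family = "Ty1", detector = c("relocate", "temp", "retroseq"))
#' deduplicate_insertions(calls, position_tolerance = 100)
#' @export
deduplicate_insertions <- function(records, position_tolerance = 100) {
  needed <- c("strain", "generation", "chromosome", "position",
              "length", "family", "detector")
  stopifnot(all(needed %in% names(records)))
  if (nrow(records) == 0L) {
    out <- records[, setdiff(needed, "detector"), drop = FALSE]
    out$n_detectors <- integer()
    out$detectors <- character()
    out$dedup_group <- integer()
    return(tibble::as_tibble(out))
  }

  out <- records |>
    dplyr::group_by(.data$strain, .data$generation, .data$chromosome,
                    .data$family) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::mutate(
      .cluster = cumsum(c(1L, diff(.data$position) > position_tolerance))
    ) |>
    dplyr::group_by(.data$.cluster, .add = TRUE) |>
    dplyr::summarise(
      position = stats::median(.data$position),
      length = stats::median(.data$length),
      n_detectors = length(unique(.data$detector)),
      detectors = paste(sort(unique(.data$detector)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::select(-".cluster") |>
    dplyr::arrange(.data$strain, .data$generation, .data$chromosome,
                   .data$position)
  out$dedup_group <- seq_len(nrow(out))
  out
}

#' Fraction of reads mapping to TEs
#'
#' Genome-wide TE load measured as the fraction of TE-mapped reads out
#' of all mappable reads, without distinguishing active from inactive
#' copies.
#'
#' @param te_mapped_reads Reads mapped to the TE library (vectorised).
#' @param total_mapped_reads Total mappable reads.
#' @return `te_mapped_reads / total_mapped_reads`, in `[0, 1]`.
#' @examples
#' te_read_fraction(250, 1000)
#' @export
te_read_fraction <- function(te_mapped_reads, total_mapped_reads) {
  if (any(total_mapped_reads <= 0))
    stop("total_mapped_reads must be > 0", call. = FALSE)
  if (any(te_mapped_reads < 0))
    stop("te_mapped_reads must be >= 0", call. = FALSE)
  if (any(te_mapped_reads > total_mapped_reads))
    stop("te_mapped_reads cannot exceed total_mapped_reads", call. = FALSE)
  te_mapped_reads / total_mapped_reads
}
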