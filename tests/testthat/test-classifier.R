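test_that("multi-detector calls of one insertion collapse to one record", {
  calls <- tibble::tibble(
    strain = "A1", generation = 0L, chromosome = "chrI",
    position = c(1000L, 1010L, 1050L), length = 334L, family = "Ty1",
    detector = c("relocate", "temp", "retroseq")
  )
  uniq <- deduplicate_insertions(calls, position_tolerance = 100)
  expect_equal(nrow(uniq), 1)
  expect_equal(uniq$n_detectors, 3L)
  expect_equal(uniq$position, 1010)

  # two same-family insertions 10 kb apart stay separate
  two <- dplyr::bind_rows(calls, dplyr::mutate(calls, position = position + 10000L))
  expect_equal(nrow(deduplicate_insertions(two, 100)), 2)

  # different families at the same spot are never merged
  fam2 <- dplyr::bind_rows(calls, dplyr::mutate(calls, family = "Ty2"))
  expect_equal(nrow(deduplicate_insertions(fam2, 100)), 2)

  expect_equal(nrow(deduplicate_insertions(calls[0, ], 100)), 0)
})

test_that("deduplication is idempotent", {
  set.seed(8)
  fix <- gen_insertion_records(n_full = 10, n_solo = 20, n_truncated = 5,
                               seed = 8)
  once <- deduplicate_insertions(fix$records, 100)
  again <- once |>
    dplyr::mutate(detector = detectors) |>
    deduplicate_insertions(100)
  expect_equal(nrow(again), nrow(once))
  expect_equal(again$position, once$position)
})

test_that("length windows assign the published class tags", {
  fams <- ty_family_lengths()
  recs <- tibble::tibble(
    family = c("Ty1", "Ty1", "Ty1", "Ty1", "Ty1", "Ty1", "Ty2"),
    length = c(300L,        # solo LTR window
               5900L,       # within 500 bp of Ty1 canonical 5918
               219L,        # below the solo floor
               421L,        # just above the solo ceiling -> truncated
               5918L - 500L,# exact edge of the full-length window
               5000L,       # between windows -> truncated
               300L)        # solo is family independent
  )
  cls <- classify_insertions(recs, fams)$class
  expect_equal(as.character(cls),
               c("solo_LTR", "full_length", "other", "truncated",
                 "full_length", "truncated", "solo_LTR"))

  # unknown family outside the solo window cannot be full length
  unk <- tibble::tibble(family = "TyX", length = 5900L)
  expect_warning(out <- classify_insertions(unk), "unknown family")
  expect_equal(as.character(out$class), "other")

  expect_error(classify_insertions(tibble::tibble(family = "Ty1", length = 0L)),
               "> 0")
})

test_that("classification partitions every record exactly once", {
  set.seed(9)
  recs <- tibble::tibble(
    family = sample(c(ty_family_lengths()$family, "unknown"), 500, TRUE),
    length = sample(1:7000, 500, TRUE)
  )
  out <- suppressWarnings(classify_insertions(recs))
  expect_equal(nrow(out), 500)
  expect_false(any(is.na(out$class)))
  expect_equal(sum(table(out$class)), 500)
})

test_that("read fractions are validated ratios", {
  expect_equal(te_read_fraction(250, 1000), 0.25)
  expect_equal(te_read_fraction(0, 1000), 0)
  expect_equal(te_read_fraction(c(1, 2), c(4, 4)), c(0.25, 0.5))
  expect_error(te_read_fraction(1, 0), "> 0")
  expect_error(te_read_fraction(5, 4), "exceed")
})
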