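test_that("fixture generation is deterministic and self-consistent", {
  spec <- fixture_spec(n_series = 8L, members_range = c(2L, 5L),
                       n_decoys = 6L, seed = 17L, n_two_site = 2L)
  fx1 <- generate_fixture(spec)
  fx2 <- generate_fixture(spec)
  expect_identical(fx1$activities, fx2$activities)
  expect_identical(length(fx1$truth$series), 8L)
  expect_identical(length(fx1$truth$decoys), 6L)
  ## activity records always satisfy the curation filters
  flt <- filter_records(fx1$activities)
  expect_identical(unname(flt$report["kept"]), nrow(fx1$activities))
  ## designed truth is arithmetically consistent with the constraints
  for (s in fx1$truth$series) {
    expect_gte(length(s$members), 2L)
    if (s$kind == "two_site") {
      expect_identical(s$expected_cover_size, 2L)
      expect_true(is.na(s$expected_scaffold))
    } else {
      expect_true(nzchar(s$expected_scaffold))
    }
  }
})

test_that("the default stated world covers the constraint boundaries", {
  fx <- default_fixture()
  kinds <- vapply(fx$truth$series, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "two_site"), 4L)
  expect_true("boundary_cap" %in% kinds)
  expect_true("boundary_ratio" %in% kinds)
  cap <- fx$truth$series[[which(kinds == "boundary_cap")]]
  ## substituent sizes 12, 13 (kept) and 14 (excluded) around the cap
  expect_identical(length(cap$members), 3L)
  expect_identical(length(cap$excluded), 1L)
  ratio <- fx$truth$series[[which(kinds == "boundary_ratio")]]
  expect_identical(length(ratio$excluded), 1L)
  expect_identical(length(fx$truth$decoys), 50L)
  sizes <- vapply(fx$truth$series, function(s) length(s$members), integer(1))
  expect_true(all(sizes >= 2L & sizes <= 10L))
})

test_that("decoys pass curation but never enter a series", {
  spec <- fixture_spec(n_series = 6L, n_decoys = 10L, seed = 23L,
                       n_two_site = 1L)
  fx <- generate_fixture(spec)
  fit <- asb_scaffolds(fx$activities)
  expect_identical(length(unique(fit$series$series_id)), 6L)
  expect_true(all(fx$truth$decoys %in% fit$compounds$compound_id))
  expect_false(any(fx$truth$decoys %in% fit$series$compound_id))
  ## decoy structures are unique and distinct from members
  expect_identical(anyDuplicated(fit$compounds$smiles), 0L)
})
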