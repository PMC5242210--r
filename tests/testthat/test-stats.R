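synthetic_stage_tables <- function() {
  ## 4 series; 3 with SK; 2 with ASB scaffolds
  series <- data.frame(
    series_id = rep(c("S1", "S2", "S3", "S4"), times = c(3, 2, 2, 2)),
    compound_id = sprintf("C%02d", 1:9), stringsAsFactors = FALSE)
  sk <- data.frame(series_id = c("S1", "S1", "S2", "S3"),
                   compound_id = c("C01", "C02", "C04", "C06"),
                   stringsAsFactors = FALSE)
  scaffolds <- data.frame(series_id = c("S1", "S2"), scaffold = c("*a", "*b"),
                          heavy_atoms = c(9L, 7L), source_sk = c("C01", "C04"),
                          n_qualifying_cores = 1L, n_members = c(3L, 2L),
                          stringsAsFactors = FALSE)
  ann <- data.frame(compound_id = series$compound_id,
                    target_id = c("T1", "T1", "T2", "T1", "T1", "T3", "T3",
                                  "T4", "T4"),
                    measurement_type = "Ki", potency_nM = 10,
                    n_measurements = 1L, stringsAsFactors = FALSE)
  list(series = series, sk = sk, scaffolds = scaffolds, ann = ann)
}

test_that("series inherit the union of member target annotations", {
  x <- synthetic_stage_tables()
  sa <- annotate_series(x$series, x$ann)
  expect_identical(sa$multiplicity_class,
                   c("multi", "single", "single", "single"))
  expect_identical(sa$targets[sa$series_id == "S1"], "T1;T2")
  expect_identical(sa$n_targets, c(2L, 1L, 1L, 1L))
  ## a member without any annotation is a pipeline-integrity error
  expect_error(annotate_series(x$series, x$ann[-1, , drop = FALSE]),
               "without any target annotation")
})

test_that("stage statistics report nested counts with percentages", {
  x <- synthetic_stage_tables()
  sa <- annotate_series(x$series, x$ann)
  st <- compute_stats(x$series, x$sk, x$scaffolds, sa)
  expect_identical(st$all_series$n_series, 4L)
  expect_identical(st$with_sk$n_series, 3L)
  expect_identical(st$with_asb$n_series, 2L)
  expect_equal(unname(st$percent), c(100, 75, 50))
  ## single + multi = series count per stage
  for (stage in c("all_series", "with_sk", "with_asb")) {
    expect_identical(st[[stage]]$n_single_target + st[[stage]]$n_multi_target,
                     st[[stage]]$n_series)
  }
  ## monotone nonincreasing counts across stages
  for (f in c("n_series", "n_compounds", "n_targets")) {
    expect_true(st$all_series[[f]] >= st$with_sk[[f]] &&
                  st$with_sk[[f]] >= st$with_asb[[f]])
  }
  tab <- stats_table(st)
  expect_identical(tab$with_sk[1], "3 (75%)")
  expect_identical(tab$with_asb[1], "2 (50%)")
  expect_identical(tab$all_series[5], "-")  # SK count undefined at stage 1
})

test_that("degenerate stats render cleanly", {
  ## one series of two compounds: mean size 2.0 everywhere populated
  series <- data.frame(series_id = "S1", compound_id = c("A", "B"),
                       stringsAsFactors = FALSE)
  sk <- series
  sc <- data.frame(series_id = "S1", scaffold = "*a", heavy_atoms = 5L,
                   source_sk = "A", n_qualifying_cores = 1L, n_members = 2L,
                   stringsAsFactors = FALSE)
  ann <- data.frame(compound_id = c("A", "B"), target_id = "T1",
                    measurement_type = "IC50", potency_nM = 1,
                    n_measurements = 1L, stringsAsFactors = FALSE)
  st <- compute_stats(series, sk, sc, annotate_series(series, ann))
  tab <- stats_table(st)
  expect_true(all(tab[tab$statistic == "Mean", -1] == "2.0"))
  ## no series at all: zero counts, undefined cells rendered as "-"
  st0 <- compute_stats(series[0, ], sk[0, ], sc[0, ],
                       annotate_series(series[0, ], ann))
  tab0 <- stats_table(st0)
  expect_identical(tab0$all_series[1], "0")
  expect_identical(tab0$all_series[6], "-")
})
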