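records_base <- function() {
  r <- make_activities(sprintf("C%02d", 1:6),
                       c("CCO", "OCC", "CCN", "CCC(=O)O", "CCOC", "CCS"),
                       target = sprintf("T%03d", c(1, 2, 1, 1, 1, 1)))
  r
}

test_that("record filtering applies every high-confidence criterion", {
  r <- records_base()
  r$standard_relation[1] <- ">"
  r$confidence_score[2] <- 8L
  r$organism[3] <- "Rattus norvegicus"
  r$standard_type[4] <- "EC50"
  r$standard_units[5] <- "percent"
  flt <- filter_records(r)
  expect_identical(unname(flt$report["kept"]), 1L)
  expect_identical(flt$records$compound_id, "C06")
  expect_identical(unname(flt$report["relation"]), 1L)
  expect_identical(unname(flt$report["confidence_score"]), 1L)
  expect_identical(unname(flt$report["organism"]), 1L)
  expect_identical(unname(flt$report["measurement_type"]), 1L)
  expect_identical(unname(flt$report["unit"]), 1L)

  ## empty input: empty output, zeroed diagnostics
  empty <- filter_records(r[0, , drop = FALSE])
  expect_identical(nrow(empty$records), 0L)
  expect_true(all(empty$report == 0L))
})

test_that("unit conversion normalizes potencies to nM", {
  r <- make_activities(c("A", "A", "A"), "CCO")
  r$standard_value <- c(1, 1000, 0.001)
  r$standard_units <- c("uM", "nM", "mM")
  flt <- filter_records(r)
  expect_equal(flt$records$value_nM, c(1000, 1000, 1000))
})

test_that("filter tightening is monotone in retained count", {
  set.seed(11)
  r <- make_activities(sprintf("C%03d", 1:60),
                       sample(c("CCO", "CCN", "CCC"), 60, replace = TRUE))
  r$standard_relation <- sample(c("=", ">", "<"), 60, replace = TRUE)
  r$confidence_score <- sample(7:9, 60, replace = TRUE)
  r$standard_type <- sample(c("Ki", "IC50", "EC50"), 60, replace = TRUE)
  loose <- curation_config(confidence_score = 9, relations = c("=", ">", "<"),
                           measurement_types = c("Ki", "IC50", "EC50"))
  kept_loose <- filter_records(r, loose)$report["kept"]
  for (tight in list(curation_config(relations = c("=", ">")),
                     curation_config(measurement_types = "Ki"),
                     curation_config())) {
    expect_lte(filter_records(r, tight)$report["kept"], kept_loose)
  }
})

test_that("potency aggregation is a guarded geometric mean", {
  expect_equal(aggregate_potency(100)$potency_nM, 100)
  ## sqrt(5 * 8) computed by hand
  agg <- aggregate_potency(c(5, 8))
  expect_equal(agg$potency_nM, 6.324555, tolerance = 1e-6)
  expect_identical(agg$n_measurements, 2L)
  ## values spanning more than one order of magnitude are discarded
  expect_null(aggregate_potency(c(100, 2000)))
  expect_equal(aggregate_potency(c(100, 1000))$potency_nM,
               exp(mean(log(c(100, 1000)))))
  ## scale equivariance
  v <- c(3.2, 7.7, 12.1)
  expect_equal(aggregate_potency(17 * v)$potency_nM,
               17 * aggregate_potency(v)$potency_nM)
})

test_that("compound set is deduplicated by canonical structure", {
  r <- make_activities(c("A1", "A2", "B1"), c("CCO", "OCC", "CCN"),
                       target = c("T001", "T002", "T001"))
  cur <- build_compound_set(r)
  ## CCO written two ways is one compound with two target annotations
  expect_identical(nrow(cur$compounds), 2L)
  eth <- cur$annotations[cur$annotations$compound_id == "A1", ]
  expect_setequal(eth$target_id, c("T001", "T002"))

  ## a compound whose only record is approximate disappears entirely
  r2 <- r
  r2$standard_relation[3] <- "~"
  cur2 <- build_compound_set(r2)
  expect_false("B1" %in% cur2$compounds$compound_id)

  ## replicate values out of range: annotation and compound are dropped
  r3 <- make_activities(c("X", "X"), "CCOC", value = c(10, 500))
  cur3 <- build_compound_set(r3)
  expect_identical(nrow(cur3$compounds), 0L)
  expect_identical(unname(cur3$report["potency_range"]), 1L)
})

test_that("curation is idempotent on its own output", {
  r <- make_activities(c("A", "B", "C"), c("CCO", "CCN", "CCOC"),
                       value = c(12, 40, 900))
  cur <- build_compound_set(r)
  back <- make_activities(cur$annotations$compound_id,
                          cur$compounds$smiles[
                            match(cur$annotations$compound_id,
                                  cur$compounds$compound_id)],
                          target = cur$annotations$target_id,
                          value = cur$annotations$potency_nM)
  cur2 <- build_compound_set(back)
  expect_identical(cur2$compounds, cur$compounds)
  expect_equal(cur2$annotations$potency_nM, cur$annotations$potency_nM)
})
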