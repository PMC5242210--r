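fake_mmps2 <- function(a, b, core, core_ha = 5L) {
  data.frame(compound_a = a, compound_b = b, core = core,
             core_ha = core_ha, sub_a = paste0("*", a), sub_a_ha = 1L,
             sub_b = paste0("*", b), sub_b_ha = 1L, rule_id = "amide",
             stringsAsFactors = FALSE)
}

pipeline_parts <- function(mmps) {
  net <- build_network(mmps)
  ser <- extract_series(net)
  sk <- find_sk_compounds(ser, net)
  list(net = net, ser = ser, sk = sk)
}

test_that("SK compounds are the members connected to every other member", {
  ## clique of 3: all SK
  p <- pipeline_parts(fake_mmps2(c("A", "A", "B"), c("B", "C", "C"), "*C"))
  expect_setequal(p$sk$compound_id, c("A", "B", "C"))
  ## path A-B, A-C: only the hub
  p2 <- pipeline_parts(fake_mmps2(c("A", "A"), c("B", "C"),
                                  c("c1", "c2")))
  expect_identical(p2$sk$compound_id, "A")
  ## 4-cycle: every degree is 2 < 3, no SK at all
  p3 <- pipeline_parts(fake_mmps2(c("A", "B", "C", "A"),
                                  c("B", "C", "D", "D"), "*C"))
  expect_identical(nrow(p3$sk), 0L)
  expect_identical(nrow(qualifying_cores(p3$ser, p3$sk, fake_mmps2(
    c("A"), c("B"), "*C"))), 0L)
})

test_that("qualifying cores must back MMPs to every other analog", {
  ## benzamide triple: single qualifying core from every SK compound
  fit <- cached("benzamide_fit", asb_scaffolds(benzamide_activities()))
  qc <- fit$qualifying_cores
  expect_identical(nrow(qc), 1L)
  expect_identical(qc$core, "*C(=O)c1ccccc1")
  expect_identical(qc$core_ha, 8L)
  expect_setequal(fit$sk_compounds$compound_id, c("BZM1", "BZM2", "BZM3"))

  ## two-site series: SK exists but no single core reaches both sites
  fit2 <- cached("two_site_fit", asb_scaffolds(two_site_activities()))
  expect_identical(fit2$sk_compounds$compound_id, "TSA")
  expect_identical(nrow(fit2$qualifying_cores), 0L)
  expect_identical(nrow(fit2$scaffolds), 0L)

  ## series of two: the shared core qualifies
  p <- pipeline_parts(fake_mmps2("A", "B", "*CC", 4L))
  qc2 <- qualifying_cores(p$ser, p$sk, fake_mmps2("A", "B", "*CC", 4L))
  expect_identical(qc2$core, "*CC")
  expect_identical(qc2$source_sk, "A")  # lexicographic collapse across SK
})

test_that("scaffold selection takes the largest core, ties lexicographic", {
  qc <- data.frame(series_id = c("S1", "S1", "S2", "S2"),
                   core = c("*small", "*big", "*zz", "*aa"),
                   core_ha = c(8L, 11L, 9L, 9L),
                   source_sk = "A", stringsAsFactors = FALSE)
  sel <- select_asb_scaffold(qc)
  expect_identical(sel$scaffold[sel$series_id == "S1"], "*big")
  expect_identical(sel$heavy_atoms[sel$series_id == "S1"], 11L)
  expect_identical(sel$scaffold[sel$series_id == "S2"], "*aa")
  expect_identical(sel$n_qualifying_cores, c(2L, 2L))
  ## empty candidates: no scaffold
  expect_identical(nrow(select_asb_scaffold(qc[0, , drop = FALSE])), 0L)
})

test_that("core covers are minimal and only computed without a scaffold", {
  ## two-site trio: cover of size 2, found exactly
  fit2 <- cached("two_site_fit", asb_scaffolds(two_site_activities()))
  expect_identical(nrow(fit2$covers), 1L)
  expect_identical(fit2$covers$cover_size, 2L)
  expect_identical(fit2$covers$method, "exact")

  ## star of 4 leaves via 4 distinct cores: cover of size 4
  mm <- fake_mmps2(rep("H", 4), c("L1", "L2", "L3", "L4"),
                   c("c1", "c2", "c3", "c4"))
  p <- pipeline_parts(mm)
  expect_identical(p$sk$compound_id, "H")
  cov <- compute_core_cover(p$ser, p$sk, mm)
  expect_identical(cov$cover_size, 4L)

  ## a series that has a scaffold is skipped by the cover step
  fit <- cached("benzamide_fit", asb_scaffolds(benzamide_activities()))
  expect_identical(nrow(fit$covers), 0L)

  ## greedy fallback kicks in above the exact-enumeration threshold
  cov2 <- compute_core_cover(p$ser, p$sk, mm, max_exact = 2L)
  expect_identical(cov2$cover_size, 4L)
  expect_identical(cov2$method, "greedy")
})
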