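test_that("canonicalization maps equivalent notations to one string", {
  res <- cached("canon_basic", canonicalize(
    c("C(C)N", "CCN", "c1ccccc1C(=O)NC", "CNC(=O)c1ccccc1",
      "CC(=O)[O-].[Na+]", "not_a_smiles", "CCNC(=O)c1ccccc1")))
  expect_identical(res$canonical[1], res$canonical[2])
  expect_identical(res$canonical[3], res$canonical[4])
  ## idempotence: canonical output canonicalizes to itself
  again <- cached("canon_idem", canonicalize(res$canonical[c(2, 4, 7)]))
  expect_identical(again$canonical, res$canonical[c(2, 4, 7)])
  ## salt stripping keeps the largest covalent component, with a diagnostic
  expect_identical(res$n_stripped[5], 1L)
  expect_false(grepl("Na", res$canonical[5]))
  ## parse failure is reported, not fatal
  expect_identical(res$error[6], "parse_failure")
  expect_identical(res$canonical[6], "")
})

test_that("heavy-atom counts exclude hydrogens and attachment points", {
  ha <- cached("ha_basic",
               count_heavy_atoms(c("[*]NC", "[*]C(=O)c1ccccc1", "[*]N",
                                   "CNC(=O)c1ccccc1")))
  expect_identical(ha, c(2L, 8L, 1L, 10L))
})

test_that("single-cut fragmentation follows the RECAP bond rules", {
  cpds <- data.frame(
    compound_id = c("benzamide_nme", "benzene", "methoxy_amide", "diether"),
    smiles = c("CNC(=O)c1ccccc1", "c1ccccc1", "COc1ccccc1C(=O)NC",
               "COc1ccc(OC)cc1"),
    stringsAsFactors = FALSE)
  frags <- cached("frags_basic", enumerate_recap_cuts(cpds))

  ## N-methylbenzamide: one amide bond, both orientations
  bz <- frags[frags$parent_id == "benzamide_nme", ]
  expect_identical(nrow(bz), 2L)
  expect_setequal(bz$core, c("*C(=O)c1ccccc1", "*NC"))
  expect_setequal(bz$sub, c("*C(=O)c1ccccc1", "*NC"))
  expect_true(all(bz$rule_id == "amide"))
  expect_identical(sort(bz$core_ha + bz$sub_ha), c(10L, 10L))

  ## benzene: no cleavable acyclic bond
  expect_identical(nrow(frags[frags$parent_id == "benzene", ]), 0L)

  ## 2-methoxy-N-methylbenzamide: ether (twice) and amide cuts
  mo <- frags[frags$parent_id == "methoxy_amide", ]
  expect_gte(length(unique(paste(mo$rule_id, pmin(mo$core, mo$sub)))), 3L)
  expect_gte(nrow(mo), 4L)
  expect_setequal(unique(mo$rule_id), c("ether", "amide"))

  ## molecular symmetry: the two methoxy groups collapse to one pair set
  de <- frags[frags$parent_id == "diether", ]
  expect_identical(nrow(de), 4L)
  expect_identical(anyDuplicated(paste(de$core, de$sub)), 0L)
})

test_that("fragment pairs reassemble to their parent (round trip)", {
  cpds <- data.frame(
    compound_id = c("a", "b", "c", "d", "e"),
    smiles = c("CNC(=O)c1ccccc1", "COc1ccccc1C(=O)NC", "CC(=O)OC1CCCCC1",
               "CNS(=O)(=O)c1ccc(Cl)cc1", "C[N+](C)(C)Cc1ccccc1"),
    stringsAsFactors = FALSE)
  canon <- cached("roundtrip_canon", canonical_smiles(cpds$smiles))
  cpds$smiles <- canon
  frags <- cached("roundtrip_frags", enumerate_recap_cuts(cpds))
  expect_gt(nrow(frags), 6L)
  rejoined <- cached("roundtrip_join",
                     reassemble_fragments(frags$core, frags$sub))
  expect_identical(rejoined,
                   canon[match(frags$parent_id, cpds$compound_id)])
  ## atom conservation across every cut
  parent_ha <- count_heavy_atoms(canon)
  expect_identical(frags$core_ha + frags$sub_ha,
                   parent_ha[match(frags$parent_id, cpds$compound_id)])
})

test_that("the rule table is configurable and validated", {
  rules <- recap_rules()
  expect_identical(nrow(rules), 11L)
  expect_true(all(grepl(":1", rules$smarts, fixed = TRUE)))
  ## a restricted dialect: amide rule only
  path <- tempfile(fileext = ".tsv")
  utils::write.table(rules[rules$rule_id == "amide", ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  frags <- enumerate_recap_cuts(
    data.frame(compound_id = "x", smiles = "COc1ccccc1C(=O)NC",
               stringsAsFactors = FALSE),
    recap_rules(path))
  expect_identical(unique(frags$rule_id), "amide")
  expect_identical(nrow(frags), 2L)
})
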