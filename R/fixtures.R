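## Seeded synthetic fixtures: analog series with known ground truth.
##
## Series are built by joining a template core (one attachment point) with
## enumerated R-groups at a RECAP-cleavable bond (amide, ester or aryl
## ether; these rules are unambiguous across RECAP dialects). Templates and
## R-groups are pure hydrocarbons apart from the functional group, so the
## joined compounds contain no unplanned cleavable bonds, cross-series
## shared cores are impossible, and the designed core is provably the
## largest qualifying core of its series. Decoys are saturated pure-carbon
## structures with no cleavable bond at all, so they can never enter an
## analog series.

fixture_templates <- function() {
  rbind(
    data.frame(family = "amide",
               template = paste0("*C(=O)c1ccc", vapply(0:8, function(k)
                 if (k == 0) "" else paste0("(", strrep("C", k), ")"),
                 character(1)), "cc1"),
               stringsAsFactors = FALSE),
    data.frame(family = "ester",
               template = paste0("*C(=O)C1CCC", vapply(0:8, function(k)
                 if (k == 0) "" else paste0("(", strrep("C", k), ")"),
                 character(1)), "CC1"),
               stringsAsFactors = FALSE),
    data.frame(family = "ether",
               template = paste0("*Oc1ccc(", strrep("C", 1:8), ")cc1"),
               stringsAsFactors = FALSE))
}

fixture_rgroups <- function() {
  list(
    ## no "*N": a primary amide N has degree 1 and RECAP dialects
    ## (including ours) do not cleave it
    amide = c("*NC", "*NCC", "*NCCC", "*NC(C)C", "*NCCCC", "*NCC(C)C",
              "*NC(C)CC", "*NCCCCC", "*NCC(C)(C)C", "*NCCCCCC",
              "*NCCC(C)CC", "*NCCCC(C)C"),
    ester = c("*OC", "*OCC", "*OCCC", "*OC(C)C", "*OCCCC", "*OCC(C)C",
              "*OCCCCC", "*OC(C)(C)C", "*OCCCCCC", "*OCCC(C)C",
              "*OCCCCCCC", "*OCC(C)CC"),
    ether = c("*C", "*CC", "*CCC", "*C(C)C", "*CCCC", "*CC(C)C",
              "*C(C)(C)C", "*CCCCC", "*CCC(C)C", "*CCCCCC", "*CC(C)(C)C",
              "*CCCCCCC"))
}

## Boundary series: a 26-heavy-atom acyl core with N-alkyl substituents of
## 2, 12, 13 and 14 heavy atoms. The 13-atom substituent sits exactly at
## both limits (cap 13; core = 2 x 13), the 14-atom one must be excluded.
boundary_cap_template <- "*C(=O)C(CCCCCCCCCCCC)CCCCCCCCCCC"
boundary_cap_rgroups <- c("*NC", paste0("*N", strrep("C", c(11, 12, 13))))

## Ratio series: benzamide acyl core (8 heavy atoms) with substituents of
## 2, 3, 4 and 5 heavy atoms; the 4-atom substituent sits exactly at the
## 2.0 core:substituent ratio, the 5-atom one (ratio 1.6) must be excluded.
ratio_template <- "*C(=O)c1ccccc1"
ratio_rgroups <- c("*NC", "*NCC", "*NCCC", "*NCCCC")

## Two-site series: one base compound varied independently at an aryl ether
## and an amide site. Only the base forms MMPs with every analog, no single
## core spans both sites, and the minimum core cover has size 2.
two_site_smiles <- function(ring_tag, site1, site2) {
  ring <- if (ring_tag == "") "cc1" else paste0("c(", ring_tag, ")c1")
  paste0("C", site1, "Oc1ccc", ring, "C(=O)NC", site2)
}
two_site_ring_tags <- c("", "Cl", "F", "C", "CC", "CCC")

fixture_decoy_pool <- function(n) {
  pool <- c(vapply(4:28, function(k) strrep("C", k), character(1)),
            vapply(1:15, function(k) paste0("CC(C)", strrep("C", k)),
                   character(1)),
            vapply(1:10, function(k) paste0(strrep("C", k), "C1CCCCC1"),
                   character(1)))
  if (n > length(pool)) stop("at most ", length(pool), " decoys available")
  pool[seq_len(n)]
}

#' Specification of a synthetic fixture
#'
#' Describes a seeded, fully deterministic compound set with known ground
#' truth: `n_series` analog series (each one template core enumerated with
#' distinct R-groups), among them designed edge cases (a substituent-size
#' boundary series spanning 12/13/14 heavy atoms, a core:substituent ratio
#' boundary series, and two-site series whose truth is a core cover rather
#' than a scaffold), plus `n_decoys` compounds that enter no series.
#' Synthetic potencies are drawn log-uniformly from 1 to 10^4 nM and always
#' pass curation; targets follow a simple multi-target model.
#'
#' @param n_series total number of designed series.
#' @param members_range inclusive range of series sizes to draw from.
#' @param n_decoys number of isolated decoy compounds.
#' @param seed integer seed fixing all randomness.
#' @param n_targets size of the synthetic target pool.
#' @param multi_target_fraction fraction of series annotated with a second
#'   target.
#' @param n_two_site number of two-site (core-cover) series among
#'   `n_series`.
#' @param include_boundary_series include the two designed boundary series.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_series = 25L, members_range = c(2L, 10L),
                         n_decoys = 50L, seed = 1L, n_targets = 10L,
                         multi_target_fraction = 0.3, n_two_site = 4L,
                         include_boundary_series = TRUE) {
  n_special <- n_two_site + 2L * include_boundary_series
  if (n_two_site > length(two_site_ring_tags)) {
    stop("at most ", length(two_site_ring_tags), " two-site series available")
  }
  if (n_series < n_special) stop("n_series too small for the designed edge cases")
  if (n_series - n_special > nrow(fixture_templates())) {
    stop("template pool exhausted; at most ",
         nrow(fixture_templates()) + n_special, " series")
  }
  structure(list(n_series = as.integer(n_series),
                 members_range = as.integer(members_range),
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed),
                 n_targets = as.integer(n_targets),
                 multi_target_fraction = multi_target_fraction,
                 n_two_site = as.integer(n_two_site),
                 include_boundary_series = include_boundary_series),
            class = "fixture_spec")
}

## synthetic activity records for one compound on one target
fixture_records <- function(compound_id, smiles, target_id) {
  value <- 10^stats::runif(1, 0, 4)
  n_rep <- sample(1:2, 1)
  values <- if (n_rep == 2L) c(value, value * stats::runif(1, 0.5, 2)) else value
  data.frame(compound_id = unname(compound_id), smiles = unname(smiles),
             target_id = target_id, organism = "Homo sapiens",
             relationship_type = "D", confidence_score = 9L,
             standard_type = sample(c("Ki", "IC50"), 1),
             standard_relation = "=",
             standard_value = signif(values, 6), standard_units = "nM",
             stringsAsFactors = FALSE)
}

fixture_targets <- function(spec, rank) {
  primary <- sprintf("T%03d", 1L + (rank - 1L) %% spec$n_targets)
  extra <- character()
  if (stats::runif(1) < spec$multi_target_fraction && spec$n_targets > 1L) {
    extra <- sample(setdiff(sprintf("T%03d", seq_len(spec$n_targets)),
                            primary), 1)
  }
  c(primary, extra)
}

#' Generate ground-truth analog series
#'
#' Builds the designed series of a [fixture_spec()]: compounds (template
#' joined with R-groups at the cleavable bond), synthetic activity records
#' that satisfy the curation filters, and a truth object recording for each
#' series the expected members, exclusions (substituents violating the size
#' constraints), SK set, ASB scaffold canonical string (or `NA` for
#' two-site series) and expected core-cover size.
#'
#' @param spec a [fixture_spec()].
#' @return list with `activities` (curation-format data.frame) and `truth`.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  constraints <- mmp_constraints()
  templates <- fixture_templates()
  rpools <- fixture_rgroups()

  ## heavy atoms of every fragment we may use, one bridge call
  frag_smiles <- unique(c(templates$template, unlist(rpools),
                          boundary_cap_template, boundary_cap_rgroups,
                          ratio_template, ratio_rgroups))
  finfo <- canonicalize(frag_smiles)
  if (any(nzchar(finfo$error))) stop("fixture fragment failed to parse")
  fha <- stats::setNames(finfo$heavy_atoms, frag_smiles)
  fcanon <- stats::setNames(finfo$canonical, frag_smiles)

  n_single <- spec$n_series - spec$n_two_site -
    2L * spec$include_boundary_series
  ## keep the ratio/boundary templates exclusive to their designed series
  avail <- templates[!(templates$template %in%
                         c(ratio_template, boundary_cap_template)), ,
                     drop = FALSE]
  pick <- avail[sample(nrow(avail), n_single), , drop = FALSE]

  designs <- list()
  for (i in seq_len(n_single)) {
    template <- pick$template[i]
    family <- pick$family[i]
    ## only R-groups every pair of which satisfies the constraints
    pool <- rpools[[family]]
    pool <- pool[fha[pool] <= constraints$max_substituent_heavy_atoms &
                   fha[template] >=
                     constraints$core_to_substituent_ratio * fha[pool]]
    size <- sample(seq(spec$members_range[1], spec$members_range[2]), 1)
    size <- min(size, length(pool))
    if (size < 2L) stop("template ", template, " supports no series")
    designs[[length(designs) + 1L]] <-
      list(kind = "single_site", template = template,
           rgroups = sample(pool, size), excluded_rgroups = character())
  }
  if (spec$include_boundary_series) {
    designs[[length(designs) + 1L]] <-
      list(kind = "boundary_cap", template = boundary_cap_template,
           rgroups = boundary_cap_rgroups[1:3],
           excluded_rgroups = boundary_cap_rgroups[4])
    designs[[length(designs) + 1L]] <-
      list(kind = "boundary_ratio", template = ratio_template,
           rgroups = ratio_rgroups[1:3],
           excluded_rgroups = ratio_rgroups[4])
  }
  for (i in seq_len(spec$n_two_site)) {
    designs[[length(designs) + 1L]] <-
      list(kind = "two_site", ring_tag = two_site_ring_tags[i],
           n_site1 = sample(1:3, 1), n_site2 = sample(1:3, 1))
  }

  activities <- list()
  truth_series <- list()
  join_queue <- list()
  for (s in seq_along(designs)) {
    d <- designs[[s]]
    sid <- sprintf("D%02d", s)
    if (d$kind == "two_site") {
      alk <- c("", "C", "CC", "CCC")
      ids <- sprintf("%sM%02d", sid, seq_len(1L + d$n_site1 + d$n_site2))
      smi <- c(two_site_smiles(d$ring_tag, "", ""),
               vapply(alk[1L + seq_len(d$n_site1)], function(a)
                 two_site_smiles(d$ring_tag, a, ""), character(1)),
               vapply(alk[1L + seq_len(d$n_site2)], function(a)
                 two_site_smiles(d$ring_tag, "", a), character(1)))
      truth_series[[sid]] <- list(
        design_id = sid, kind = d$kind, members = ids,
        excluded = character(), expected_sk = ids[1L],
        expected_scaffold = NA_character_, expected_cover_size = 2L)
      member_smi <- smi
    } else {
      all_r <- c(d$rgroups, d$excluded_rgroups)
      ids <- sprintf("%sM%02d", sid, seq_along(all_r))
      join_queue[[sid]] <- data.frame(id = ids, core = d$template,
                                      sub = all_r, stringsAsFactors = FALSE)
      n_in <- length(d$rgroups)
      truth_series[[sid]] <- list(
        design_id = sid, kind = d$kind, members = ids[seq_len(n_in)],
        excluded = ids[-seq_len(n_in)], expected_sk = ids[seq_len(n_in)],
        expected_scaffold = unname(fcanon[d$template]),
        expected_cover_size = NA_integer_)
      member_smi <- NULL # filled after the batched join
    }
    targets <- fixture_targets(spec, s)
    truth_series[[sid]]$targets <- targets
    truth_series[[sid]]$pending_smiles <- member_smi
  }

  ## one batched join call for all template + R-group compounds
  jq <- do.call(rbind, join_queue)
  joined <- if (is.null(jq)) NULL else {
    res <- reassemble_fragments(jq$core, jq$sub)
    if (anyNA(res)) stop("fixture join failed")
    stats::setNames(res, jq$id)
  }

  for (sid in names(truth_series)) {
    tr <- truth_series[[sid]]
    ids <- c(tr$members, tr$excluded)
    smi <- if (is.null(tr$pending_smiles)) unname(joined[ids]) else
      tr$pending_smiles
    truth_series[[sid]]$smiles <- stats::setNames(smi, ids)
    truth_series[[sid]]$pending_smiles <- NULL
    for (k in seq_along(ids)) {
      tgt <- tr$targets[1L]
      ## second target, when present, annotates a subset of members;
      ## the first member always carries it so the annotation cannot vanish
      if (length(tr$targets) > 1L && (k == 1L || stats::runif(1) < 0.5)) {
        tgt <- c(tgt, tr$targets[2L])
      }
      for (t in tgt) {
        activities[[length(activities) + 1L]] <-
          fixture_records(ids[k], smi[k], t)
      }
    }
  }
  activities <- do.call(rbind, activities)
  rownames(activities) <- NULL
  all_smi <- unlist(lapply(truth_series, `[[`, "smiles"))
  if (anyDuplicated(canonical_smiles(unique(all_smi)))) {
    stop("fixture generation produced duplicate structures")
  }
  list(activities = activities,
       truth = list(spec = unclass(spec), series = truth_series))
}

#' Generate decoy compounds
#'
#' Saturated pure-carbon structures without any RECAP-cleavable bond: they
#' pass curation (valid structures with valid activity records) but cannot
#' form MMPs, so they must appear in no analog series.
#'
#' @param spec a [fixture_spec()].
#' @return data.frame of activity records for `spec$n_decoys` decoys.
#' @export
generate_decoys <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  smi <- fixture_decoy_pool(spec$n_decoys)
  rows <- lapply(seq_along(smi), function(i) {
    fixture_records(sprintf("DEC%03d", i), smi[i],
                    sprintf("T%03d", 1L + (i - 1L) %% spec$n_targets))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame())
  }
  rownames(out) <- NULL
  out
}

#' Generate the complete fixture: series plus decoys
#'
#' @param spec a [fixture_spec()].
#' @return list with `activities` (series and decoy records) and `truth`
#'   (per-series expectations plus the decoy identifier list).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  ser <- generate_series(spec)
  dec <- generate_decoys(spec)
  activities <- if (nrow(dec)) rbind(ser$activities, dec) else ser$activities
  truth <- ser$truth
  truth$decoys <- if (nrow(dec)) unique(dec$compound_id) else character()
  list(activities = activities, truth = truth)
}
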