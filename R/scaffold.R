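#' Identify structural key (SK) compounds
#'
#' An SK compound forms an MMP with every other member of its series, i.e.
#' its degree within the series equals series size minus one. SK compounds
#' are the central chemical entities of a series; a series may have none
#' (e.g. a chordless cycle of MMP relationships).
#'
#' @param series membership table from [extract_series()].
#' @param network the `mmp_network` the series were extracted from.
#' @return data.frame with columns `series_id`, `compound_id`, one row per
#'   SK compound.
#' @export
find_sk_compounds <- function(series, network) {
  stopifnot(inherits(network, "mmp_network"))
  empty <- data.frame(series_id = character(), compound_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(series) == 0L) return(empty)
  deg <- igraph::degree(network$graph)
  sizes <- series_sizes(series)
  need <- sizes[series$series_id] - 1L
  ## within-series degree equals global degree: components are disjoint
  is_sk <- deg[series$compound_id] == need
  out <- series[is_sk, c("series_id", "compound_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate qualifying MMP cores of a series
#'
#' A core qualifies when it belongs to an SK compound and backs an MMP
#' relationship from that SK compound to every other member of the series.
#' Qualifying cores are pooled across all SK compounds of a series and
#' deduplicated by canonical core string (the lexicographically smallest
#' source compound is recorded).
#'
#' @param series membership table from [extract_series()].
#' @param sk SK table from [find_sk_compounds()].
#' @param mmps MMP table from [generate_mmps()].
#' @return data.frame with columns `series_id`, `core`, `core_ha`,
#'   `source_sk`.
#' @export
qualifying_cores <- function(series, sk, mmps) {
  empty <- data.frame(series_id = character(), core = character(),
                      core_ha = integer(), source_sk = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sk) == 0L || nrow(mmps) == 0L) return(empty)
  sizes <- series_sizes(series)
  ## long form: one row per (compound, partner, core)
  long <- rbind(
    data.frame(cpd = mmps$compound_a, partner = mmps$compound_b,
               core = mmps$core, core_ha = mmps$core_ha,
               stringsAsFactors = FALSE),
    data.frame(cpd = mmps$compound_b, partner = mmps$compound_a,
               core = mmps$core, core_ha = mmps$core_ha,
               stringsAsFactors = FALSE))
  long <- long[long$cpd %in% sk$compound_id, , drop = FALSE]
  if (nrow(long) == 0L) return(empty)
  sk_series <- stats::setNames(sk$series_id, sk$compound_id)
  long$series_id <- unname(sk_series[long$cpd])
  key <- paste(long$series_id, long$cpd, long$core, sep = "\r")
  npart <- tapply(long$partner, key, function(x) length(unique(x)))
  first <- long[!duplicated(key), , drop = FALSE]
  first$n_partners <- as.integer(npart[paste(first$series_id, first$cpd,
                                             first$core, sep = "\r")])
  qual <- first[first$n_partners == sizes[first$series_id] - 1L, ,
                drop = FALSE]
  if (nrow(qual) == 0L) return(empty)
  ## collapse duplicates across SK compounds of the same series
  qual <- qual[order(qual$series_id, qual$core, qual$cpd), , drop = FALSE]
  qual <- qual[!duplicated(paste(qual$series_id, qual$core, sep = "\r")), ,
               drop = FALSE]
  out <- data.frame(series_id = qual$series_id, core = qual$core,
                    core_ha = as.integer(qual$core_ha),
                    source_sk = qual$cpd, stringsAsFactors = FALSE)
  out <- out[order(out$series_id, -out$core_ha, out$core), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the analog series-based scaffold of each series
#'
#' The ASB scaffold of a series is its largest qualifying core by
#' non-hydrogen atom count; ties are broken deterministically by
#' lexicographic order of the canonical core string. Series without a
#' qualifying core yield no scaffold (see [compute_core_cover()]).
#'
#' @param qcores qualifying-core table from [qualifying_cores()].
#' @param series membership table (used for member counts).
#' @return data.frame with columns `series_id`, `scaffold`, `heavy_atoms`,
#'   `source_sk`, `n_qualifying_cores`, `n_members`.
#' @export
select_asb_scaffold <- function(qcores, series = NULL) {
  empty <- data.frame(series_id = character(), scaffold = character(),
                      heavy_atoms = integer(), source_sk = character(),
                      n_qualifying_cores = integer(), n_members = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(qcores) == 0L) return(empty)
  q <- qcores[order(qcores$series_id, -qcores$core_ha, qcores$core), ,
              drop = FALSE]
  ncand <- table(q$series_id)
  best <- q[!duplicated(q$series_id), , drop = FALSE]
  out <- data.frame(series_id = best$series_id, scaffold = best$core,
                    heavy_atoms = best$core_ha, source_sk = best$source_sk,
                    n_qualifying_cores =
                      as.integer(ncand[best$series_id]),
                    stringsAsFactors = FALSE)
  sizes <- if (is.null(series)) NULL else series_sizes(series)
  out$n_members <- if (is.null(sizes)) NA_integer_ else
    as.integer(sizes[out$series_id])
  out <- out[order(out$series_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Per-core covered-member sets for one series: a core of an SK compound
## covers the SK compounds possessing it plus every member linked to such an
## SK compound by an MMP with exactly that core.
core_cover_sets <- function(members, sk_ids, long) {
  long <- long[long$cpd %in% sk_ids & long$partner %in% members, ,
               drop = FALSE]
  if (nrow(long) == 0L) return(list())
  covered <- tapply(seq_len(nrow(long)), long$core, function(idx) {
    sort(unique(c(long$cpd[idx], long$partner[idx])))
  })
  covered[order(names(covered))]
}

min_set_cover_exact <- function(sets, universe) {
  nm <- names(sets)
  for (k in seq_along(sets)) {
    picks <- utils::combn(length(sets), k, simplify = FALSE)
    for (p in picks) {
      if (all(universe %in% unlist(sets[p], use.names = FALSE))) {
        return(nm[p])
      }
    }
  }
  NULL
}

min_set_cover_greedy <- function(sets, universe) {
  chosen <- character()
  left <- universe
  while (length(left)) {
    gain <- vapply(sets, function(s) sum(left %in% s), integer(1))
    if (max(gain) == 0L) return(NULL)
    ## largest gain, ties by core string for determinism
    best <- names(sets)[order(-gain, names(sets))][1L]
    chosen <- c(chosen, best)
    left <- setdiff(left, sets[[best]])
    sets <- sets[names(sets) != best]
  }
  chosen
}

#' Minimum core cover for series without an ASB scaffold
#'
#' For series that have SK compounds but no single qualifying core, finds a
#' minimum-cardinality set of SK-compound cores whose covered-member sets
#' jointly span the whole series. The minimum is found exactly by
#' enumeration when at most `max_exact` candidate cores exist, otherwise by
#' greedy set cover (flagged in the `method` column). A series whose members
#' cannot all be reached from SK cores yields no cover.
#'
#' @param series membership table from [extract_series()].
#' @param sk SK table from [find_sk_compounds()].
#' @param mmps MMP table from [generate_mmps()].
#' @param scaffolds scaffold table from [select_asb_scaffold()]; series
#'   listed there are skipped (they have a single covering core).
#' @param max_exact largest candidate-core count solved exactly.
#' @return data.frame with columns `series_id`, `cover_size`, `cores`
#'   (`;`-joined, sorted), `method` (`"exact"` or `"greedy"`).
#' @export
compute_core_cover <- function(series, sk, mmps, scaffolds = NULL,
                               max_exact = 20L) {
  empty <- data.frame(series_id = character(), cover_size = integer(),
                      cores = character(), method = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sk) == 0L || nrow(mmps) == 0L) return(empty)
  with_scaffold <- if (is.null(scaffolds)) character() else
    scaffolds$series_id
  todo <- setdiff(unique(sk$series_id), with_scaffold)
  if (length(todo) == 0L) return(empty)
  long <- rbind(
    data.frame(cpd = mmps$compound_a, partner = mmps$compound_b,
               core = mmps$core, stringsAsFactors = FALSE),
    data.frame(cpd = mmps$compound_b, partner = mmps$compound_a,
               core = mmps$core, stringsAsFactors = FALSE))
  rows <- lapply(sort(todo), function(sid) {
    members <- series$compound_id[series$series_id == sid]
    sk_ids <- sk$compound_id[sk$series_id == sid]
    sets <- core_cover_sets(members, sk_ids, long)
    if (length(sets) == 0L) return(NULL)
    if (length(sets) <= max_exact) {
      cover <- min_set_cover_exact(sets, members)
      method <- "exact"
    } else {
      cover <- min_set_cover_greedy(sets, members)
      method <- "greedy"
    }
    if (is.null(cover)) return(NULL)
    data.frame(series_id = sid, cover_size = length(cover),
               cores = paste(sort(cover), collapse = ";"),
               method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
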