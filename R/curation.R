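#' Curation settings for high-confidence activity data
#'
#' Defaults reproduce the selection used to assemble the compound pool:
#' direct interactions (`relationship_type` \"D\") with human targets at the
#' highest assay confidence (score 9), Ki or IC50 endpoints only, exact
#' measurements only (records qualified with \">\", \"<\" or \"~\" are
#' discarded), and potencies convertible to nM. Replicate measurements for a
#' compound-target pair are combined as a geometric mean provided they all
#' fall within the same order of magnitude, operationalized as
#' `max/min <= max_fold_range` (default 10).
#'
#' @param relationship_type accepted target relationship code.
#' @param confidence_score required target confidence score.
#' @param organism required target organism.
#' @param measurement_types accepted endpoint types.
#' @param relations accepted relation qualifiers.
#' @param max_fold_range largest allowed max/min ratio when aggregating
#'   replicate potencies for one compound-target-endpoint triple.
#' @param unit_to_nM named vector of multiplicative factors to nM.
#' @return list of class `curation_config`.
#' @export
curation_config <- function(relationship_type = "D",
                            confidence_score = 9L,
                            organism = "Homo sapiens",
                            measurement_types = c("Ki", "IC50"),
                            relations = "=",
                            max_fold_range = 10,
                            unit_to_nM = c(M = 1e9, mM = 1e6, uM = 1e3,
                                           "µM" = 1e3, nM = 1, pM = 1e-3)) {
  stopifnot(max_fold_range >= 1)
  structure(list(relationship_type = relationship_type,
                 confidence_score = as.integer(confidence_score),
                 organism = organism,
                 measurement_types = measurement_types,
                 relations = relations,
                 max_fold_range = max_fold_range,
                 unit_to_nM = unit_to_nM),
            class = "curation_config")
}

activity_columns <- c("compound_id", "smiles", "target_id", "organism",
                      "relationship_type", "confidence_score",
                      "standard_type", "standard_relation",
                      "standard_value", "standard_units")

#' Filter activity records to the high-confidence subset
#'
#' Applies the selection criteria of [curation_config()] record by record
#' and converts surviving potencies to nM. Each rejection is tallied by the
#' first criterion that failed, so the report explains exactly where records
#' were lost.
#'
#' @param records data.frame with the columns named in
#'   `asbscaffold:::activity_columns`.
#' @param config a [curation_config()].
#' @return list with `records` (retained rows plus a `value_nM` column) and
#'   `report` (named integer vector of rejection counts, including `kept`).
#' @export
filter_records <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  missing_cols <- setdiff(activity_columns, names(records))
  if (length(missing_cols)) {
    stop("missing activity columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(records)
  reasons <- c("missing_field", "relationship_type", "confidence_score",
               "organism", "measurement_type", "relation", "unit",
               "nonpositive_value")
  reject <- rep(NA_character_, n)
  mark <- function(bad, why) ifelse(is.na(reject) & bad, why, reject)

  val <- suppressWarnings(as.numeric(records$standard_value))
  conf <- suppressWarnings(as.integer(records$confidence_score))
  incomplete <- !stats::complete.cases(
    records[, setdiff(activity_columns, "smiles")]) | is.na(val) |
    !nzchar(trimws(as.character(records$compound_id)))
  reject <- mark(incomplete, "missing_field")
  reject <- mark(records$relationship_type != config$relationship_type,
                 "relationship_type")
  reject <- mark(is.na(conf) | conf != config$confidence_score,
                 "confidence_score")
  reject <- mark(records$organism != config$organism, "organism")
  reject <- mark(!records$standard_type %in% config$measurement_types,
                 "measurement_type")
  reject <- mark(!records$standard_relation %in% config$relations, "relation")
  reject <- mark(!records$standard_units %in% names(config$unit_to_nM), "unit")
  reject <- mark(val <= 0, "nonpositive_value")

  keep <- is.na(reject)
  kept <- records[keep, , drop = FALSE]
  kept$value_nM <- val[keep] *
    unname(config$unit_to_nM[as.character(kept$standard_units)])
  report <- vapply(reasons, function(r) sum(reject == r, na.rm = TRUE),
                   integer(1))
  report <- c(input = n, kept = sum(keep), report)
  rownames(kept) <- NULL
  list(records = kept, report = report)
}

#' Geometric-mean potency aggregation
#'
#' Combines replicate potency values (nM) for one compound-target-endpoint
#' triple into a single annotation, provided all values fall into the same
#' order of magnitude (`max/min <= max_fold_range`); otherwise the triple is
#' discarded and contributes no annotation.
#'
#' @param values numeric vector of positive potencies in nM.
#' @param max_fold_range dynamic-range threshold (default 10, one log unit).
#' @return list with `potency_nM` (geometric mean) and `n_measurements`, or
#'   `NULL` when the values span more than the allowed range.
#' @examples
#' \dontrun{
#' aggregate_potency(c(5, 8))$potency_nM   # 6.3246
#' aggregate_potency(c(100, 2000))         # NULL: ratio 20 > 10
#' }
#' @export
aggregate_potency <- function(values, max_fold_range = 10) {
  stopifnot(length(values) >= 1L, all(values > 0))
  if (max(values) / min(values) > max_fold_range) return(NULL)
  list(potency_nM = exp(mean(log(values))), n_measurements = length(values))
}

#' Build the curated, structure-deduplicated compound set
#'
#' Runs the full curation path: record filtering, structure canonicalization
#' (with salt stripping), deduplication by canonical structure, and
#' geometric-mean potency aggregation per compound-target-endpoint triple.
#' Records whose structures fail to parse are dropped with a diagnostic
#' count; compounds whose every annotation was discarded (by filtering or by
#' the same-order-of-magnitude rule) do not appear in the output. When
#' several input identifiers map to one canonical structure, the
#' lexicographically smallest identifier represents the compound.
#'
#' @param records raw activity records (see [filter_records()]).
#' @param config a [curation_config()].
#' @return list of class `curated_set` with `compounds` (compound_id, smiles,
#'   heavy_atoms), `annotations` (compound_id, target_id, measurement_type,
#'   potency_nM, n_measurements) and `report` (rejection tallies).
#' @export
build_compound_set <- function(records, config = curation_config()) {
  flt <- filter_records(records, config)
  rec <- flt$records
  report <- flt$report

  empty <- list(
    compounds = data.frame(compound_id = character(), smiles = character(),
                           heavy_atoms = integer(), stringsAsFactors = FALSE),
    annotations = data.frame(compound_id = character(), target_id = character(),
                             measurement_type = character(),
                             potency_nM = numeric(), n_measurements = integer(),
                             stringsAsFactors = FALSE),
    report = report)
  if (nrow(rec) == 0L) {
    report["structure_failure"] <- 0L
    report["potency_range"] <- 0L
    empty$report <- report
    return(structure(empty, class = "curated_set"))
  }

  ## canonicalize each distinct input SMILES once
  smi <- unique(as.character(rec$smiles))
  canon <- canonicalize(smi)
  bad <- nzchar(canon$error)
  report["structure_failure"] <- sum(as.character(rec$smiles) %in% smi[bad])
  lookup_canon <- stats::setNames(canon$canonical, smi)
  lookup_ha <- stats::setNames(canon$heavy_atoms, smi)
  rec$canonical <- unname(lookup_canon[as.character(rec$smiles)])
  rec$heavy_atoms <- unname(lookup_ha[as.character(rec$smiles)])
  rec <- rec[nzchar(rec$canonical), , drop = FALSE]

  ## one representative identifier per canonical structure
  rep_id <- tapply(as.character(rec$compound_id), rec$canonical,
                   function(x) min(x))
  rec$rep_id <- unname(rep_id[rec$canonical])

  ## aggregate potencies per structure/target/endpoint
  key <- paste(rec$rep_id, rec$target_id, rec$standard_type, sep = "\r")
  groups <- split(seq_len(nrow(rec)), key)
  rows <- lapply(groups, function(idx) {
    agg <- aggregate_potency(rec$value_nM[idx], config$max_fold_range)
    if (is.null(agg)) return(NULL)
    data.frame(compound_id = rec$rep_id[idx[1L]],
               target_id = as.character(rec$target_id[idx[1L]]),
               measurement_type = as.character(rec$standard_type[idx[1L]]),
               potency_nM = agg$potency_nM,
               n_measurements = agg$n_measurements,
               stringsAsFactors = FALSE)
  })
  report["potency_range"] <- sum(vapply(rows, is.null, logical(1)))
  annotations <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(annotations)) annotations <- empty$annotations
  annotations <- annotations[order(annotations$compound_id,
                                   annotations$target_id,
                                   annotations$measurement_type), ,
                             drop = FALSE]
  rownames(annotations) <- NULL

  keep_struct <- !duplicated(rec$canonical) &
    rec$rep_id %in% annotations$compound_id
  compounds <- data.frame(compound_id = rec$rep_id[keep_struct],
                          smiles = rec$canonical[keep_struct],
                          heavy_atoms = as.integer(rec$heavy_atoms[keep_struct]),
                          stringsAsFactors = FALSE)
  compounds <- compounds[order(compounds$compound_id), , drop = FALSE]
  rownames(compounds) <- NULL
  report["compounds"] <- nrow(compounds)

  structure(list(compounds = compounds, annotations = annotations,
                 report = report), class = "curated_set")
}
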