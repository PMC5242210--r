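#' Annotate analog series with target activity
#'
#' Series inherit activity from their members: the target set of a series is
#' the union of its members' target annotations, and a series (or its ASB
#' scaffold) is classed `single` or `multi` according to whether that union
#' holds one or several targets. Ki- and IC50-derived annotations are pooled
#' for target counting; per-endpoint target counts are also reported.
#'
#' @param series membership table from [extract_series()].
#' @param annotations annotation table from [build_compound_set()].
#' @return data.frame with columns `series_id`, `n_targets`, `targets`
#'   (`;`-joined, sorted), `multiplicity_class`, `n_targets_Ki`,
#'   `n_targets_IC50`.
#' @export
annotate_series <- function(series, annotations) {
  empty <- data.frame(series_id = character(), n_targets = integer(),
                      targets = character(), multiplicity_class = character(),
                      n_targets_Ki = integer(), n_targets_IC50 = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(series) == 0L) return(empty)
  missing_ann <- setdiff(series$compound_id, annotations$compound_id)
  if (length(missing_ann)) {
    stop("series members without any target annotation: ",
         paste(utils::head(missing_ann, 5L), collapse = ", "),
         " (curation must guarantee annotations)")
  }
  merged <- merge(series, annotations, by = "compound_id")
  per <- function(df) {
    split_targets <- tapply(df$target_id, df$series_id,
                            function(x) sort(unique(x)))
    split_targets
  }
  all_t <- per(merged)
  ki_t <- per(merged[merged$measurement_type == "Ki", , drop = FALSE])
  ic_t <- per(merged[merged$measurement_type == "IC50", , drop = FALSE])
  sids <- sort(unique(series$series_id))
  n_of <- function(tab, s) if (s %in% names(tab)) length(tab[[s]]) else 0L
  n_t <- vapply(sids, function(s) n_of(all_t, s), integer(1))
  out <- data.frame(
    series_id = sids,
    n_targets = n_t,
    targets = vapply(sids, function(s) paste(all_t[[s]], collapse = ";"),
                     character(1)),
    multiplicity_class = ifelse(n_t == 1L, "single", "multi"),
    n_targets_Ki = vapply(sids, function(s) n_of(ki_t, s), integer(1)),
    n_targets_IC50 = vapply(sids, function(s) n_of(ic_t, s), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

stage_stats <- function(sids, series, sk, series_ann) {
  sub <- series[series$series_id %in% sids, , drop = FALSE]
  ann <- series_ann[series_ann$series_id %in% sids, , drop = FALSE]
  sizes <- series_sizes(sub)
  n_sk <- sum(sk$series_id %in% sids)
  list(n_series = length(sids),
       n_single_target = sum(ann$multiplicity_class == "single"),
       n_multi_target = sum(ann$multiplicity_class == "multi"),
       n_compounds = length(unique(sub$compound_id)),
       n_sk_compounds = n_sk,
       size_min = if (length(sizes)) min(sizes) else NA_integer_,
       size_max = if (length(sizes)) max(sizes) else NA_integer_,
       size_mean = if (length(sizes)) round(mean(sizes), 1) else NA_real_,
       n_targets = length(unique(unlist(strsplit(ann$targets, ";",
                                                 fixed = TRUE)))))
}

#' Pipeline statistics across the three scaffold stages
#'
#' Summarizes the analog-series landscape in three nested stages: all
#' series, series with at least one SK compound, and series with an ASB
#' scaffold. Counts are monotonically nonincreasing across stages;
#' percentages are relative to the all-series stage. Single- and
#' multi-target rows sum to the series count of each stage.
#'
#' @param series membership table from [extract_series()].
#' @param sk SK table from [find_sk_compounds()].
#' @param scaffolds scaffold table from [select_asb_scaffold()].
#' @param series_ann series annotation table from [annotate_series()].
#' @return object of class `asb_stats`: list of three per-stage summaries
#'   (`all_series`, `with_sk`, `with_asb`) plus `percent` (series
#'   percentages vs all).
#' @export
compute_stats <- function(series, sk, scaffolds, series_ann) {
  all_ids <- unique(series$series_id)
  sk_ids <- intersect(all_ids, unique(sk$series_id))
  asb_ids <- intersect(all_ids, unique(scaffolds$series_id))
  stages <- list(all_series = stage_stats(all_ids, series, sk, series_ann),
                 with_sk = stage_stats(sk_ids, series, sk, series_ann),
                 with_asb = stage_stats(asb_ids, series, sk, series_ann))
  n_all <- stages$all_series$n_series
  pct <- function(n) if (n_all > 0) round(100 * n / n_all) else NA_real_
  structure(c(stages,
              list(percent = c(all_series = pct(n_all),
                               with_sk = pct(stages$with_sk$n_series),
                               with_asb = pct(stages$with_asb$n_series)))),
            class = "asb_stats")
}

#' Render pipeline statistics as a table
#'
#' One row per statistic, one column per stage, mirroring the conventional
#' reporting layout (counts with stage percentages in the series row, size
#' range and one-decimal mean, target counts). Undefined cells are rendered
#' as `"-"`.
#'
#' @param stats an `asb_stats` object from [compute_stats()].
#' @return data.frame of formatted strings.
#' @export
stats_table <- function(stats) {
  stopifnot(inherits(stats, "asb_stats"))
  fmt_n <- function(x) format(x, big.mark = ",", trim = TRUE)
  col <- function(stage, p) {
    s <- stats[[stage]]
    series_cell <- if (s$n_series == 0L) "0" else fmt_n(s$n_series)
    if (!is.na(p) && stage != "all_series" && s$n_series > 0L) {
      series_cell <- sprintf("%s (%d%%)", series_cell, as.integer(p))
    }
    c(series_cell,
      fmt_n(s$n_single_target),
      fmt_n(s$n_multi_target),
      fmt_n(s$n_compounds),
      if (stage == "all_series") "-" else fmt_n(s$n_sk_compounds),
      if (is.na(s$size_min)) "-" else sprintf("%d-%d", s$size_min, s$size_max),
      if (is.na(s$size_mean)) "-" else sprintf("%.1f", s$size_mean),
      fmt_n(s$n_targets))
  }
  out <- data.frame(
    statistic = c("Analog series (n)", "Single target", "Multiple targets",
                  "Compounds (n)", "SK compounds (n)", "Analog series size",
                  "Mean", "Targets (n)"),
    all_series = col("all_series", stats$percent["all_series"]),
    with_sk = col("with_sk", stats$percent["with_sk"]),
    with_asb = col("with_asb", stats$percent["with_asb"]),
    stringsAsFactors = FALSE)
  out
}

#' @export
print.asb_stats <- function(x, ...) {
  cat("Analog series, SK compounds and ASB scaffolds\n\n")
  print(stats_table(x), row.names = FALSE, right = FALSE)
  invisible(x)
}
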