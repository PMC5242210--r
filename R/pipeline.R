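#' Extract analog series and ASB scaffolds from activity data
#'
#' Runs the complete analysis: activity-record curation, retrosynthetic
#' single-cut fragmentation, size-constrained MMP generation by core
#' indexing, MMP-network construction, analog-series extraction (connected
#' components), SK-compound identification, qualifying-core enumeration,
#' ASB-scaffold selection (largest qualifying core), minimum core covers
#' for series without a single qualifying core, series target annotation
#' and pipeline statistics.
#'
#' @param activities data.frame of raw activity records (see
#'   [read_activity_table()] for the expected columns) or a `curated_set`
#'   from [build_compound_set()].
#' @param rules RECAP rule table from [recap_rules()].
#' @param constraints an [mmp_constraints()].
#' @param curation a [curation_config()].
#' @param max_exact_cover largest candidate-core count for exact set cover.
#' @return object of class `asb_analysis`; a list with elements
#'   `compounds`, `annotations`, `curation_report`, `fragments`, `mmps`,
#'   `network`, `series`, `sk_compounds`, `qualifying_cores`, `scaffolds`,
#'   `covers`, `series_annotations`, `stats`.
#' @examples
#' \dontrun{
#' fx <- generate_fixture(fixture_spec(seed = 7))
#' fit <- asb_scaffolds(fx$activities)
#' summary(fit)
#' }
#' @export
asb_scaffolds <- function(activities, rules = recap_rules(),
                          constraints = mmp_constraints(),
                          curation = curation_config(),
                          max_exact_cover = 20L) {
  curated <- if (inherits(activities, "curated_set")) activities else
    build_compound_set(activities, curation)
  fragments <- enumerate_recap_cuts(curated$compounds, rules)
  mmps <- generate_mmps(fragments, constraints)
  network <- build_network(mmps)
  series <- extract_series(network)
  sk <- find_sk_compounds(series, network)
  qcores <- qualifying_cores(series, sk, mmps)
  scaffolds <- select_asb_scaffold(qcores, series)
  covers <- compute_core_cover(series, sk, mmps, scaffolds,
                               max_exact = max_exact_cover)
  series_ann <- annotate_series(series, curated$annotations)
  stats <- compute_stats(series, sk, scaffolds, series_ann)
  structure(list(compounds = curated$compounds,
                 annotations = curated$annotations,
                 curation_report = curated$report,
                 fragments = fragments, mmps = mmps, network = network,
                 series = series, sk_compounds = sk,
                 qualifying_cores = qcores, scaffolds = scaffolds,
                 covers = covers, series_annotations = series_ann,
                 stats = stats,
                 constraints = constraints, curation = curation),
            class = "asb_analysis")
}

#' @export
print.asb_analysis <- function(x, ...) {
  cat("Analog series-based scaffold analysis\n")
  cat(sprintf("  compounds:       %d (curated, unique structures)\n",
              nrow(x$compounds)))
  cat(sprintf("  MMPs:            %d over %d network edges\n",
              nrow(x$mmps), nrow(x$network$edges)))
  cat(sprintf("  analog series:   %d\n",
              length(unique(x$series$series_id))))
  cat(sprintf("  with SK:         %d\n",
              length(unique(x$sk_compounds$series_id))))
  cat(sprintf("  ASB scaffolds:   %d\n", nrow(x$scaffolds)))
  cat(sprintf("  core covers:     %d (series without a single qualifying core)\n",
              nrow(x$covers)))
  invisible(x)
}

#' @export
summary.asb_analysis <- function(object, ...) {
  object$stats
}

#' Plot the MMP network of an analysis
#'
#' Draws the MMP network with nodes grouped by analog series; SK compounds
#' are shown as squares. Mostly useful for fixture-sized datasets.
#'
#' @param x an `asb_analysis`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.asb_analysis <- function(x, ...) {
  g <- x$network$graph
  if (igraph::vcount(g) == 0L) {
    plot.new()
    return(invisible(x))
  }
  sid <- stats::setNames(x$series$series_id, x$series$compound_id)
  member_series <- sid[igraph::V(g)$name]
  igraph::V(g)$color <- as.integer(factor(member_series))
  igraph::V(g)$shape <- ifelse(igraph::V(g)$name %in%
                                 x$sk_compounds$compound_id,
                               "square", "circle")
  igraph::plot.igraph(g, vertex.label.cex = 0.6, vertex.size = 8, ...)
  invisible(x)
}
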