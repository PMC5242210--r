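#' Read an activity table from delimited text
#'
#' Reads a compound/activity table with named header columns. A column map
#' translates export dialects (e.g. ChEMBL column names) onto the canonical
#' names used by the curation module. Rows whose mandatory fields cannot be
#' read are skipped with a diagnostic; if more than `max_malformed` of all
#' rows are malformed the read aborts.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param column_map named character vector mapping canonical names
#'   (`compound_id`, `smiles`, ...) to the file's column names; identity
#'   when `NULL`.
#' @param max_malformed largest tolerated malformed-row fraction.
#' @return data.frame with the canonical activity columns; attribute
#'   `n_malformed` carries the skipped-row count.
#' @export
read_activity_table <- function(path, sep = "\t", column_map = NULL,
                                max_malformed = 0.5) {
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           fill = TRUE, blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) {
    warning("empty activity table: ", path)
  }
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      if (!column_map[[canonical]] %in% names(raw)) {
        stop("mapped column not found: ", column_map[[canonical]])
      }
      names(raw)[names(raw) == column_map[[canonical]]] <- canonical
    }
  }
  missing_cols <- setdiff(activity_columns, names(raw))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, activity_columns, drop = FALSE]
  mandatory <- c("compound_id", "smiles", "target_id", "standard_value")
  bad <- !stats::complete.cases(raw[, mandatory, drop = FALSE]) |
    !nzchar(trimws(as.character(raw$smiles)))
  if (nrow(raw) > 0L && mean(bad) > max_malformed) {
    stop(sprintf("%d/%d malformed rows exceeds the threshold",
                 sum(bad), nrow(raw)))
  }
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Read compounds from an SDF (V2000) file
#'
#' Structures are canonicalized on read; records that fail to parse are
#' skipped with a diagnostic count.
#'
#' @param path SDF file path.
#' @return data.frame with columns `compound_id`, `smiles`, `heavy_atoms`;
#'   attribute `n_failed` counts unparseable records.
#' @export
read_sdf_compounds <- function(path) {
  out <- run_bridge("sdf2smi", path)
  failed <- nzchar(as.character(out$error))
  ok <- out[!failed, , drop = FALSE]
  canon <- canonicalize(as.character(ok$smiles))
  res <- data.frame(compound_id = as.character(ok$id),
                    smiles = canon$canonical,
                    heavy_atoms = canon$heavy_atoms,
                    stringsAsFactors = FALSE)
  attr(res, "n_failed") <- sum(failed) + sum(nzchar(canon$error))
  res
}

#' Write compounds to an SDF (V2000) file
#'
#' @param compounds data.frame with columns `compound_id`, `smiles`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf_compounds <- function(compounds, path) {
  fin <- tempfile(fileext = ".tsv")
  on.exit(unlink(fin), add = TRUE)
  write_bridge_tsv(data.frame(id = compounds$compound_id,
                              smiles = compounds$smiles,
                              stringsAsFactors = FALSE), fin)
  args <- c(bridge_script(), "smi2sdf", "--in", fin, "--out", path)
  status <- system2(python_binary(), shQuote(args), stdout = FALSE, stderr = "")
  if (status != 0L) stop("SDF write failed", call. = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

#' Write all result tables of an analysis
#'
#' Writes every stage of an [asb_scaffolds()] analysis as TSV (compounds,
#' annotations, fragments, MMPs, network edges, series, SK compounds,
#' qualifying cores, scaffolds, covers, statistics), the curation report
#' and statistics as JSON, and a manifest with stage counts and MD5 hashes
#' of every written file. Output is deterministic for fixed input.
#'
#' @param result an `asb_analysis`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_asb_outputs <- function(result, dir) {
  stopifnot(inherits(result, "asb_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(dir, name)
  tables <- list(compounds = result$compounds,
                 annotations = result$annotations,
                 fragments = result$fragments,
                 mmps = result$mmps,
                 network_edges = result$network$edges,
                 series = result$series,
                 sk_compounds = result$sk_compounds,
                 qualifying_cores = result$qualifying_cores,
                 scaffolds = result$scaffolds,
                 covers = result$covers,
                 series_annotations = result$series_annotations,
                 stats = stats_table(result$stats))
  files <- character()
  for (name in names(tables)) {
    files[name] <- write_tsv(tables[[name]], p(paste0(name, ".tsv")))
  }
  jsonlite::write_json(as.list(result$curation_report),
                       p("curation_report.json"), auto_unbox = TRUE)
  files["curation_report"] <- p("curation_report.json")
  jsonlite::write_json(unclass(result$stats), p("stats.json"),
                       auto_unbox = TRUE, digits = NA)
  files["stats_json"] <- p("stats.json")
  manifest <- list(
    stage_counts = list(
      compounds = nrow(result$compounds),
      fragments = nrow(result$fragments),
      mmps = nrow(result$mmps),
      network_edges = nrow(result$network$edges),
      series = length(unique(result$series$series_id)),
      series_with_sk = length(unique(result$sk_compounds$series_id)),
      asb_scaffolds = nrow(result$scaffolds),
      core_covers = nrow(result$covers)),
    constraints = unclass(result$constraints),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    names(files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Run the pipeline from a configuration
#'
#' Thin orchestration over [read_activity_table()], [asb_scaffolds()] and
#' [write_asb_outputs()]: validates the configuration, executes
#' curate-fragment-mmp-series-scaffold-annotate-stats, and writes all
#' tables plus a manifest. Rerunning on identical input and configuration
#' reproduces identical outputs.
#'
#' @param config named list (or path to a JSON file) with elements `input`
#'   (activity table path), `output_dir`, and optionally `sep`,
#'   `column_map`, `rules` (rule file path), `max_substituent_heavy_atoms`,
#'   `core_to_substituent_ratio`, plus [curation_config()] overrides under
#'   `curation`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$input), !is.null(config$output_dir))
  if (!file.exists(config$input)) stop("input not found: ", config$input)
  rules <- recap_rules(config$rules)
  constraints <- mmp_constraints(
    max_substituent_heavy_atoms = config$max_substituent_heavy_atoms %||% 13L,
    core_to_substituent_ratio = config$core_to_substituent_ratio %||% 2)
  curation <- do.call(curation_config, as.list(config$curation))
  activities <- read_activity_table(config$input,
                                    sep = config$sep %||% "\t",
                                    column_map = config$column_map)
  result <- asb_scaffolds(activities, rules = rules,
                          constraints = constraints, curation = curation)
  write_asb_outputs(result, config$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
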