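#' Build the MMP network
#'
#' Nodes are compounds participating in at least one MMP; one edge per
#' unordered compound pair, annotated with all cores shared by that pair
#' (several MMP records between the same two compounds collapse onto one
#' edge). The network has no self-loops by construction.
#'
#' @param mmps MMP table from [generate_mmps()].
#' @return object of class `mmp_network`: list with `nodes` (character),
#'   `edges` (data.frame `compound_a`, `compound_b`, `n_cores`, `cores` with
#'   cores `;`-joined in sorted order) and `graph` (an igraph object).
#' @export
build_network <- function(mmps) {
  if (nrow(mmps) == 0L) {
    edges <- data.frame(compound_a = character(), compound_b = character(),
                        n_cores = integer(), cores = character(),
                        stringsAsFactors = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(nodes = character(), edges = edges, graph = g),
                     class = "mmp_network"))
  }
  a <- pmin(mmps$compound_a, mmps$compound_b)
  b <- pmax(mmps$compound_a, mmps$compound_b)
  stopifnot(all(a != b))
  key <- paste(a, b, sep = "\r")
  cores <- tapply(mmps$core, key, function(x) paste(sort(unique(x)),
                                                    collapse = ";"))
  ncores <- tapply(mmps$core, key, function(x) length(unique(x)))
  first <- !duplicated(key)
  edges <- data.frame(compound_a = a[first], compound_b = b[first],
                      stringsAsFactors = FALSE)
  edges$n_cores <- as.integer(ncores[key[first]])
  edges$cores <- as.character(cores[key[first]])
  edges <- edges[order(edges$compound_a, edges$compound_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(edges[, c("compound_a", "compound_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "mmp_network")
}

#' @export
print.mmp_network <- function(x, ...) {
  cat("MMP network:", length(x$nodes), "compounds,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Extract analog series as connected components
#'
#' Each disjoint component of the MMP network is one analog series. Every
#' node has at least one edge (isolated compounds never enter the network),
#' so all series have two or more members. Series are numbered
#' deterministically by their lexicographically smallest member identifier.
#'
#' @param network an `mmp_network` from [build_network()].
#' @return data.frame with columns `series_id`, `compound_id`, ordered by
#'   series then member.
#' @export
extract_series <- function(network) {
  stopifnot(inherits(network, "mmp_network"))
  if (length(network$nodes) == 0L) {
    return(data.frame(series_id = character(), compound_id = character(),
                      stringsAsFactors = FALSE))
  }
  comp <- igraph::components(network$graph)
  member <- split(igraph::V(network$graph)$name, comp$membership)
  anchor <- vapply(member, function(m) min(m), character(1))
  member <- member[order(anchor)]
  out <- data.frame(
    series_id = rep(sprintf("S%05d", seq_along(member)), lengths(member)),
    compound_id = unlist(lapply(member, sort), use.names = FALSE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sizes of analog series
#'
#' @param series membership table from [extract_series()].
#' @return named integer vector of member counts per `series_id`.
#' @export
series_sizes <- function(series) {
  if (nrow(series) == 0L) return(stats::setNames(integer(), character()))
  tab <- table(series$series_id)
  stats::setNames(as.integer(tab), names(tab))
}
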