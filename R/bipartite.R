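#' Build a bipartite species-transect network
#'
#' One node per transect and per species, and an edge wherever a species
#' was recorded at least once on a transect (presence threshold: count >=
#' 1; abundance is used only by the diversity statistics, not the
#' networks).
#'
#' @param matrix A site abundance matrix from [to_abundance_matrix()].
#' @return An undirected bipartite igraph graph with vertex attributes
#'   \code{kind} ("transect"/"species") and \code{type} (TRUE for
#'   species), and graph attribute \code{site_id}.
#' @export
build_bipartite <- function(matrix) {
  stopifnot(inherits(matrix, "vegnet_abundance"))
  counts <- matrix$counts
  idx <- which(counts >= 1L, arr.ind = TRUE)
  edges_to_bipartite(rownames(counts)[idx[, 1L]],
                     colnames(counts)[idx[, 2L]],
                     site_id = matrix$site_id,
                     all_transects = rownames(counts),
                     all_species = colnames(counts))
}

#' Standardise a network
#'
#' Removes edge directionality, duplicate edges and self-loops, the
#' standardisation applied before any community analysis so that
#' partitions from different algorithms are comparable.  Idempotent.
#'
#' @param network An igraph graph.
#' @return The simplified undirected graph.
#' @export
simplify_network <- function(network) {
  g <- igraph::as_undirected(network, mode = "collapse")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Count species associations in a site network
#'
#' Two species recorded on the same transect are "associated".  The event
#' count sums, over transects, every unordered species pair on that
#' transect (choose(deg, 2)); the unique-pair count collapses pairs
#' co-occurring on several transects to one.
#'
#' @param network A simplified bipartite network.
#' @return A list with integers \code{events} and \code{unique_pairs}.
#' @export
count_associations <- function(network) {
  deg <- igraph::degree(network)[igraph::V(network)$kind == "transect"]
  events <- sum(choose(deg, 2))
  proj <- species_projection(network)
  list(events = as.integer(events),
       unique_pairs = igraph::ecount(proj))
}

#' Project a bipartite network onto its species
#'
#' Weighted species-species graph in which the edge weight w_ij is the
#' number of transects shared by species i and j (the dot product of the
#' two species' presence columns).  Species with no co-occurrence remain
#' as isolated nodes.
#'
#' @param network A simplified bipartite network.
#' @return A weighted undirected igraph graph over the species nodes.
#' @export
species_projection <- function(network) {
  proj <- igraph::bipartite_projection(network, multiplicity = TRUE,
                                       which = "true")
  proj$site_id <- network$site_id
  proj
}

#' Export a network as GraphML
#'
#' @param network An igraph graph.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
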