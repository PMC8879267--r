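#' Write a bipartite network as a SIF edge list
#'
#' Emits one tab-separated line per edge,
#' \code{transect<TAB>occurs_in<TAB>species}, sorted by transect then
#' species so output is deterministic.  The relation label is fixed to
#' \code{occurs_in}: the survey edge lists are two-column
#' (location, species) and standard SIF requires a relation.
#'
#' @param network A bipartite [igraph][igraph::igraph-package] graph as
#'   produced by [build_bipartite()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sif <- function(network, path) {
  ed <- igraph::as_data_frame(network, what = "edges")
  kind <- igraph::V(network)$kind
  names(kind) <- igraph::V(network)$name
  if (nrow(ed)) {
    # orient every edge transect -> species regardless of storage order
    flip <- kind[ed$from] == "species"
    tmp <- ed$from[flip]
    ed$from[flip] <- ed$to[flip]
    ed$to[flip] <- tmp
    ed <- ed[order(ed$from, ed$to), , drop = FALSE]
    lines <- paste(ed$from, "occurs_in", ed$to, sep = "\t")
  } else {
    lines <- character()
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a SIF edge list into a bipartite network
#'
#' Expects three tab-separated columns (source transect, relation, target
#' species).  Malformed lines raise an error naming the line number.
#'
#' @param path Path to a SIF file.
#' @param site_id Optional site id to attach to the graph.
#' @return A bipartite igraph graph with vertex attribute \code{kind}
#'   (\code{"transect"} or \code{"species"}) and logical \code{type}
#'   (\code{TRUE} for species).
#' @export
read_sif <- function(path, site_id = NA_character_) {
  if (!file.exists(path)) stop("SIF file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad))
    stop("malformed SIF line ", bad[1L], ": expected 3 tab-separated fields")
  transects <- vapply(parts, `[[`, "", 1L)
  species <- vapply(parts, `[[`, "", 3L)
  edges_to_bipartite(transects, species, site_id = site_id)
}

# Assemble a bipartite graph from parallel transect/species edge vectors.
edges_to_bipartite <- function(transects, species, site_id = NA_character_,
                               all_transects = NULL, all_species = NULL) {
  tn <- sort(unique(c(transects, all_transects)))
  sn <- sort(unique(c(species, all_species)))
  clash <- intersect(tn, sn)
  if (length(clash))
    stop("node id(s) used as both transect and species: ",
         paste(clash, collapse = ", "))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(tn) + length(sn),
                            name = c(tn, sn),
                            kind = c(rep("transect", length(tn)),
                                     rep("species", length(sn))),
                            type = c(rep(FALSE, length(tn)),
                                     rep(TRUE, length(sn))))
  if (length(transects))
    g <- igraph::add_edges(g, rbind(match(transects, c(tn, sn)),
                                    match(species, c(tn, sn))))
  g <- igraph::simplify(g)
  g$site_id <- site_id
  g
}
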