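#' MCODE parameter set
#'
#' Defaults mirror the published defaults of the molecular-complex
#' detection algorithm: degree cutoff 2, node score cutoff 0.2, k-core 2,
#' haircut on, fluff off.
#'
#' @param degree_cutoff Minimum degree for a vertex to seed a cluster.
#' @param node_score_cutoff Fractional weight drop allowed from the seed
#'   (a neighbour joins if its weight exceeds
#'   \code{(1 - node_score_cutoff) * seed weight}).
#' @param k_core Minimum core retained by the haircut step.
#' @param haircut Remove singly-connected cluster members (reduce each
#'   cluster to its k-core)?
#' @param fluff Add high-density boundary neighbours after the haircut
#'   (clusters may then overlap)?
#' @return A list of class \code{mcode_params}.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, haircut = TRUE, fluff = FALSE) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff <= 1,
            degree_cutoff >= 0, k_core >= 1)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff)),
            class = "mcode_params")
}

#' MCODE vertex weights
#'
#' Weight of a vertex = k x density of the highest k-core of its closed
#' neighbourhood subgraph, density = 2E / (n (n - 1)).  Isolated vertices
#' weigh 0.
#'
#' @param graph A simplified igraph graph.
#' @return Named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(graph) {
  vn <- igraph::V(graph)$name
  w <- setNames(numeric(length(vn)), vn)
  for (v in vn) {
    nb <- igraph::neighbors(graph, v)$name
    sub <- igraph::induced_subgraph(graph, c(v, nb))
    n <- igraph::vcount(sub)
    if (n < 2L) next
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) next
    core_sub <- igraph::induced_subgraph(sub, names(core)[core == kmax])
    nc <- igraph::vcount(core_sub)
    dens <- if (nc < 2L) 0 else 2 * igraph::ecount(core_sub) / (nc * (nc - 1))
    w[v] <- kmax * dens
  }
  w
}

#' MCODE clustering
#'
#' Seeds at the highest-weight unvisited vertex and traverses outward,
#' including unvisited neighbours whose weight exceeds
#' \code{(1 - node_score_cutoff)} times the seed weight; the haircut then
#' reduces each cluster to its k-core (removing singly-connected
#' members).  Clusters are ranked by score = density x size.  All
#' tie-breaks use vertex name order, so the result is deterministic.
#'
#' @param graph A simplified igraph graph.
#' @param params An [mcode_params()] list.
#' @return A list of clusters, each a list with \code{members} (sorted
#'   vertex names), \code{score}, \code{density} and \code{seed}; ranked
#'   by decreasing score.
#' @export
mcode_clusters <- function(graph, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  w <- mcode_vertex_weights(graph)
  if (!length(w)) return(list())
  deg <- igraph::degree(graph)
  visited <- setNames(logical(length(w)), names(w))
  seeds <- names(w)[order(-w, names(w))]  # weight desc, name asc within ties
  clusters <- list()
  for (seed in seeds) {
    if (visited[seed] || w[seed] <= 0 || deg[seed] < params$degree_cutoff)
      next
    thresh <- (1 - params$node_score_cutoff) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) {
        for (u in igraph::neighbors(graph, v)$name) {
          if (!visited[u] && w[u] > thresh) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- sort(nxt)
    }
    if (params$haircut) {
      sub <- igraph::induced_subgraph(graph, members)
      core <- igraph::coreness(sub)
      members <- names(core)[core >= params$k_core]
    }
    if (params$fluff && length(members)) {
      boundary <- setdiff(
        unique(unlist(lapply(members, function(v)
          igraph::neighbors(graph, v)$name))), members)
      add <- boundary[w[boundary] > params$node_score_cutoff]
      members <- c(members, add)
    }
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(graph, members)
    n <- igraph::vcount(sub)
    dens <- 2 * igraph::ecount(sub) / (n * (n - 1))
    clusters[[length(clusters) + 1L]] <-
      list(members = sort(members), score = dens * n, density = dens,
           seed = seed)
  }
  if (!length(clusters)) return(list())
  ord <- order(-vapply(clusters, `[[`, 0, "score"),
               vapply(clusters, function(cl) cl$members[1L], ""))
  clusters[ord]
}

#' Partition a graph with MCODE
#'
#' Wraps [mcode_clusters()] into the partition interface used by the
#' clique extraction step: MCODE clusters become communities and all
#' remaining vertices are appended as singleton communities (MCODE leaves
#' sparse regions unassigned).
#'
#' @inheritParams mcode_clusters
#' @return A \code{vegnet_partition}.
#' @export
mcode_partition <- function(graph, params = mcode_params()) {
  cl <- mcode_clusters(graph, params)
  comm <- lapply(cl, `[[`, "members")
  rest <- setdiff(igraph::V(graph)$name, unlist(comm))
  comm <- c(comm, as.list(sort(rest)))
  comm <- comm[order(vapply(comm, `[[`, "", 1L))]
  q <- if (igraph::ecount(graph) > 0) modularity_q(graph, comm) else NA_real_
  membership <- setNames(rep(seq_along(comm), lengths(comm)),
                         unlist(comm, use.names = FALSE))
  membership <- membership[igraph::V(graph)$name]
  structure(list(communities = comm, membership = membership,
                 modularity = q, method = "mcode"),
            class = "vegnet_partition")
}
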