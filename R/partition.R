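#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = (1/2m) \sum_{ij} [A_{ij} - k_i k_j / (2m)] \delta(c_i, c_j)}
#' on the simple undirected graph.
#'
#' @param graph A simplified igraph graph with at least one edge.
#' @param communities A list of character vectors of vertex names, or a
#'   membership vector named by vertex.
#' @return Modularity Q.
#' @export
modularity_q <- function(graph, communities) {
  m <- igraph::ecount(graph)
  if (m == 0L) stop("modularity undefined on a graph with no edges")
  membership <- as_membership(graph, communities)
  ed <- igraph::as_data_frame(graph, what = "edges")
  deg <- igraph::degree(graph)
  # fraction of edges inside each community minus the degree-null expectation
  q <- 0
  for (c_id in unique(membership)) {
    inside <- sum(membership[ed$from] == c_id & membership[ed$to] == c_id)
    d_c <- sum(deg[membership[names(deg)] == c_id])
    q <- q + inside / m - (d_c / (2 * m))^2
  }
  q
}

as_membership <- function(graph, communities) {
  vn <- igraph::V(graph)$name
  if (is.list(communities)) {
    all_nodes <- unlist(communities, use.names = FALSE)
    if (anyDuplicated(all_nodes))
      stop("communities must be disjoint")
    if (!setequal(all_nodes, vn))
      stop("communities must cover the graph's vertex set exactly")
    membership <- setNames(rep(seq_along(communities),
                               lengths(communities)), all_nodes)
  } else {
    if (is.null(names(communities)))
      stop("membership vector must be named by vertex")
    if (!setequal(names(communities), vn))
      stop("membership must cover the graph's vertex set exactly")
    membership <- communities
  }
  membership[vn]
}

#' Greedy modularity agglomeration
#'
#' Clauset-Newman-Moore style community detection: start from singleton
#' communities and repeatedly perform the merge with the largest
#' modularity gain while a strictly positive gain exists.  Ties are broken
#' by the lexicographically smallest pair of community labels (a
#' community's label is its smallest member name), making the result
#' deterministic.  Only communities joined by at least one edge are ever
#' merged, so communities never span connected components.
#'
#' @param graph A simplified undirected igraph graph with >= 1 edge.
#' @return An object of class \code{vegnet_partition}: list with
#'   \code{communities} (list of sorted vertex-name vectors, ordered by
#'   label), \code{membership}, \code{modularity} and \code{method}.
#' @export
greedy_modularity_partition <- function(graph) {
  m <- igraph::ecount(graph)
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  if (m == 0L) stop("graph has no edges")
  vn <- igraph::V(graph)$name
  comm <- as.list(vn)                      # community id -> member names
  deg <- igraph::degree(graph)
  d_c <- as.numeric(deg[vn])               # community total degree
  ed <- igraph::as_data_frame(graph, what = "edges")
  ci <- setNames(seq_along(vn), vn)        # vertex -> community index
  eps <- 1e-12
  repeat {
    a <- ci[ed$from]; b <- ci[ed$to]
    lo <- pmin(a, b); hi <- pmax(a, b)
    live <- lo != hi
    if (!any(live)) break
    key <- paste(lo[live], hi[live])
    e_ab <- tapply(rep(1L, sum(live)), key, sum)
    pair <- do.call(rbind, strsplit(names(e_ab), " ", fixed = TRUE))
    pa <- as.integer(pair[, 1L]); pb <- as.integer(pair[, 2L])
    dq <- as.numeric(e_ab) / m - d_c[pa] * d_c[pb] / (2 * m * m)
    best <- max(dq)
    if (best <= eps) break
    cand <- which(dq >= best - eps)
    if (length(cand) > 1L) {
      # smallest (label_a, label_b) pair, labels = smallest member names
      la <- vapply(pa[cand], function(i) comm[[i]][1L], "")
      lb <- vapply(pb[cand], function(i) comm[[i]][1L], "")
      l1 <- pmin(la, lb); l2 <- pmax(la, lb)
      cand <- cand[order(l1, l2)][1L]
    }
    ia <- pa[cand]; ib <- pb[cand]
    comm[[ia]] <- sort(c(comm[[ia]], comm[[ib]]))
    comm[[ib]] <- character()
    d_c[ia] <- d_c[ia] + d_c[ib]
    d_c[ib] <- 0
    ci[ci == ib] <- ia
  }
  keep <- lengths(comm) > 0L
  comm <- comm[keep]
  comm <- comm[order(vapply(comm, `[[`, "", 1L))]
  membership <- setNames(rep(seq_along(comm), lengths(comm)),
                         unlist(comm, use.names = FALSE))[vn]
  structure(list(communities = comm, membership = membership,
                 modularity = modularity_q(graph, comm),
                 method = "greedy_modularity"),
            class = "vegnet_partition")
}

#' @export
print.vegnet_partition <- function(x, ...) {
  cat(length(x$communities), "communities (", x$method, "), Q =",
      round(x$modularity, 4), "\n")
  invisible(x)
}
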