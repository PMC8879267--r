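#' MCL parameter set
#'
#' @param inflation Inflation exponent r > 1 (entrywise power; the
#'   classic default is 2).  Larger values give finer clusters.
#' @param expansion Expansion exponent e >= 2 (matrix power, i.e. random
#'   walk length per iteration).
#' @param self_loop_weight Self-loop weight added to every node before
#'   normalisation (regularisation ensuring aperiodicity).
#' @param prune_threshold Entries below this value are set to zero after
#'   each inflation (columns are then renormalised); 0 disables pruning.
#' @param convergence_tol Stop when the largest entry change across one
#'   iteration falls below this.
#' @param max_iterations Iteration cap; non-convergence warns and the
#'   current matrix is interpreted.
#' @return A list of class \code{mcl_params}.
#' @export
mcl_params <- function(inflation = 2, expansion = 2L, self_loop_weight = 1,
                       prune_threshold = 1e-5, convergence_tol = 1e-8,
                       max_iterations = 100L) {
  stopifnot(inflation > 1, expansion >= 2, expansion == round(expansion),
            self_loop_weight >= 0, prune_threshold >= 0, convergence_tol > 0,
            max_iterations >= 1)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 self_loop_weight = self_loop_weight,
                 prune_threshold = prune_threshold,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations)),
            class = "mcl_params")
}

#' Markov clustering (MCL)
#'
#' Simulates stochastic flow on a weighted undirected graph: self-loops
#' are added, the adjacency matrix is column-normalised, and expansion
#' (matrix power) alternates with inflation (entrywise power followed by
#' column renormalisation) until the flow matrix stops changing.
#' Attractors are the nodes with positive return flow; clusters are the
#' weakly connected components of the attractor graph, and a node
#' attracted to several attractors joins the cluster of its largest-flow
#' attractor (ties broken by name).
#'
#' @param graph A weighted undirected igraph graph (missing weights are
#'   treated as 1), or a symmetric non-negative adjacency matrix with
#'   dimnames.
#' @param params An [mcl_params()] list.
#' @return An object of class \code{vegnet_mcl}: list with
#'   \code{clusters} (list of sorted name vectors, ordered by first
#'   member), \code{iterations} and \code{converged}.
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  stopifnot(inherits(params, "mcl_params"))
  A <- mcl_adjacency(graph)
  n <- nrow(A)
  if (n == 0L) stop("graph has no nodes")
  nodes <- rownames(A)
  diag(A) <- diag(A) + params$self_loop_weight
  M <- normalise_columns(A)
  converged <- FALSE
  it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    E <- M
    for (k in seq_len(params$expansion - 1L)) E <- E %*% M
    Inf_ <- E^params$inflation
    if (params$prune_threshold > 0) {
      # never prune a column's largest entry
      keep_max <- cbind(max.col(t(Inf_), ties.method = "first"), seq_len(n))
      small <- Inf_ < params$prune_threshold
      small[keep_max] <- FALSE
      Inf_[small] <- 0
    }
    M_new <- normalise_columns(Inf_)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge in ", params$max_iterations,
            " iterations; interpreting the current flow matrix")
  structure(list(clusters = interpret_flow(M, nodes),
                 iterations = it, converged = converged),
            class = "vegnet_mcl")
}

mcl_adjacency <- function(graph) {
  if (igraph::is_igraph(graph)) {
    attr_name <- if ("weight" %in% igraph::edge_attr_names(graph))
      "weight" else NULL
    A <- as.matrix(igraph::as_adjacency_matrix(
      igraph::as_undirected(graph, mode = "collapse"),
      attr = attr_name, sparse = FALSE))
  } else {
    A <- as.matrix(graph)
    if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
    if (is.null(rownames(A)))
      rownames(A) <- colnames(A) <- paste0("v", seq_len(nrow(A)))
  }
  if (any(A < 0)) stop("edge weights must be non-negative")
  A
}

normalise_columns <- function(M) {
  cs <- colSums(M)
  if (any(cs == 0)) stop("zero column in flow matrix")
  sweep(M, 2L, cs, "/")
}

# Cluster interpretation of a converged flow matrix.
interpret_flow <- function(M, nodes) {
  thr <- 1e-6
  attractors <- which(diag(M) > thr)
  if (!length(attractors)) attractors <- seq_along(nodes)  # degenerate
  # attractor graph: attractors i, j are linked if either flows to the other
  sub <- M[attractors, attractors, drop = FALSE]
  link <- (sub > thr) | (t(sub) > thr)
  comp <- components_from_links(link)
  # assign every node to its largest-flow attractor's component
  flows <- M[attractors, , drop = FALSE]
  cluster_of <- integer(length(nodes))
  for (j in seq_along(nodes)) {
    f <- flows[, j]
    best <- max(f)
    if (best <= thr && j %in% attractors) {
      cluster_of[j] <- comp[match(j, attractors)]
    } else {
      cand <- which(f >= best - 1e-12 & f > thr)
      if (!length(cand)) cand <- which.max(f)
      cand <- cand[order(nodes[attractors[cand]])][1L]
      cluster_of[j] <- comp[cand]
    }
  }
  cl <- split(nodes, cluster_of)
  cl <- lapply(unname(cl), sort)
  cl[order(vapply(cl, `[[`, "", 1L))]
}

# connected components of a small logical adjacency matrix
components_from_links <- function(link) {
  n <- nrow(link)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1L]]
      stack <- stack[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, which(link[v, ] & comp == 0L))
    }
  }
  comp
}

#' @export
print.vegnet_mcl <- function(x, ...) {
  cat("MCL:", length(x$clusters), "clusters after", x$iterations,
      "iterations", if (!x$converged) "(not converged)", "\n")
  invisible(x)
}
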