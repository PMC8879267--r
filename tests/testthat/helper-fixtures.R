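# Fixture graphs and independent brute-force oracles shared by the tests.

make_named_graph <- function(edges) {
  igraph::make_graph(edges, directed = FALSE)
}

k4_edges <- function(prefix) {
  v <- paste0(prefix, 1:4)
  as.vector(utils::combn(v, 2))
}

# two triangles joined by one bridge (c-d)
two_triangles_bridge <- function() {
  make_named_graph(c("a", "b", "b", "c", "a", "c",
                     "d", "e", "e", "f", "d", "f",
                     "c", "d"))
}

# two K4s joined by one bridge (a1-b1)
two_k4_bridge <- function() {
  make_named_graph(c(k4_edges("a"), k4_edges("b"), "a1", "b1"))
}

k4_plus_pendant <- function() {
  make_named_graph(c(as.vector(utils::combn(c("a", "b", "c", "d"), 2)),
                     "a", "p"))
}

star3 <- function() {
  make_named_graph(c("c", "l1", "c", "l2", "c", "l3"))
}

triangle <- function() {
  make_named_graph(c("a", "b", "b", "c", "a", "c"))
}

toy_survey_path <- function() {
  system.file("extdata/toy/toy_survey.csv", package = "vegnet")
}
toy_species_path <- function() {
  system.file("extdata/toy/toy_species.csv", package = "vegnet")
}
ridge_cliques_path <- function() {
  system.file("extdata/delhi_ridge_cliques.csv", package = "vegnet")
}

toy_meta <- function() read_species_metadata(toy_species_path())
toy_survey <- function() read_survey(toy_survey_path(), toy_meta())

# --- independent oracles -------------------------------------------------

# exhaustive best-modularity partition by enumerating all set partitions
exhaustive_best_partition <- function(g) {
  vn <- igraph::V(g)$name
  n <- length(vn)
  stopifnot(n <= 9)
  best <- -Inf
  bestp <- NULL
  gen <- function(i, groups) {
    if (i > n) {
      q <- modularity_q(g, groups)
      if (q > best) {
        best <<- q
        bestp <<- groups
      }
      return(invisible())
    }
    for (k in seq_along(groups)) {
      g2 <- groups
      g2[[k]] <- c(g2[[k]], vn[i])
      gen(i + 1, g2)
    }
    gen(i + 1, c(groups, list(vn[i])))
  }
  gen(2, list(vn[1]))
  list(Q = best, partition = bestp)
}

# naive UPGMA: explicit cluster lists, average over all member pairs
brute_upgma_heights <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- Inf
    pick <- NULL
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best) {
        best <- avg
        pick <- c(j, i)
      }
    }
    heights <- c(heights, best)
    merged <- c(clusters[[pick[1L]]], clusters[[pick[2L]]])
    clusters <- c(clusters[-pick], list(merged))
  }
  heights
}

# dense full-precision MCL without pruning, used as the reference run
reference_mcl_clusters <- function(g, inflation = 2, expansion = 2,
                                   self_loop = 1, iters = 200) {
  p <- mcl_params(inflation = inflation, expansion = expansion,
                  self_loop_weight = self_loop, prune_threshold = 0,
                  convergence_tol = 1e-12, max_iterations = iters)
  mcl_cluster(g, p)$clusters
}

# seeded Erdos-Renyi style random named graph
random_graph <- function(n, p, seed) {
  set.seed(seed)
  vn <- sprintf("v%02d", seq_len(n))
  pairs <- utils::combn(vn, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[1L] <- TRUE
  igraph::graph_from_edgelist(t(pairs[, keep, drop = FALSE]),
                              directed = FALSE)
}

# two disconnected dense bipartite blocks (3 transects + 4 species each)
planted_blocks_graph <- function() {
  g <- igraph::make_empty_graph(directed = FALSE)
  v1 <- c(paste0("T", 1:3), c("AA", "BB", "CC", "DD"))
  v2 <- c(paste0("U", 1:3), c("EE", "FF", "GG", "HH"))
  g <- igraph::add_vertices(g, 14, name = c(v1, v2))
  for (t in paste0("T", 1:3)) for (s in c("AA", "BB", "CC", "DD"))
    g <- igraph::add_edges(g, c(t, s))
  for (t in paste0("U", 1:3)) for (s in c("EE", "FF", "GG", "HH"))
    g <- igraph::add_edges(g, c(t, s))
  g
}

# exhaustive optimum of a disconnected graph: communities never span
# components at the optimum, and Q is additive over communities, so each
# component can be enumerated separately against the global edge count
exhaustive_componentwise_Q <- function(g) {
  m <- igraph::ecount(g)
  comps <- igraph::components(g)
  total <- 0
  deg <- igraph::degree(g)
  for (cid in seq_len(comps$no)) {
    vn <- names(comps$membership)[comps$membership == cid]
    best <- -Inf
    gen <- function(i, groups) {
      if (i > length(vn)) {
        q <- 0
        sub <- igraph::induced_subgraph(g, vn)
        for (grp in groups) {
          inside <- igraph::ecount(igraph::induced_subgraph(g, grp))
          q <- q + inside / m - (sum(deg[grp]) / (2 * m))^2
        }
        best <<- max(best, q)
        return(invisible())
      }
      for (k in seq_along(groups)) {
        g2 <- groups
        g2[[k]] <- c(g2[[k]], vn[i])
        gen(i + 1, g2)
      }
      gen(i + 1, c(groups, list(vn[i])))
    }
    gen(2, list(vn[1]))
    total <- total + best
  }
  total
}
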