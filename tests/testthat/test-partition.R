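test_that("modularity matches hand-evaluated bridge graphs and igraph", {
  g1 <- two_triangles_bridge()
  q1 <- modularity_q(g1, list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(q1, 5 / 14, tolerance = 1e-12)

  g2 <- two_k4_bridge()
  q2 <- modularity_q(g2, list(paste0("a", 1:4), paste0("b", 1:4)))
  expect_equal(q2, 11 / 26, tolerance = 1e-12)

  # all nodes in one community gives Q = 0
  expect_equal(modularity_q(g1, list(igraph::V(g1)$name)), 0, tolerance = 1e-12)

  # cross-check against igraph on random graphs and random partitions
  set.seed(3)
  for (i in 1:5) {
    g <- random_graph(8, 0.4, seed = 100 + i)
    vn <- igraph::V(g)$name
    memb <- sample(1:3, length(vn), replace = TRUE)
    names(memb) <- vn
    expect_equal(modularity_q(g, memb),
                 igraph::modularity(g, memb[vn]), tolerance = 1e-12)
  }

  edgeless <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(2, name = c("x", "y"))
  expect_error(modularity_q(edgeless, list(c("x", "y"))), "no edges")
})

test_that("greedy agglomeration attains the exhaustive optimum on small graphs", {
  graphs <- list(two_triangles_bridge(), two_k4_bridge(),
                 random_graph(7, 0.35, seed = 21),
                 random_graph(8, 0.3, seed = 22),
                 random_graph(8, 0.5, seed = 23))
  for (g in graphs) {
    p <- greedy_modularity_partition(g)
    ex <- exhaustive_best_partition(g)
    expect_equal(p$modularity, ex$Q, tolerance = 1e-10)
    # reported Q always equals modularity recomputed from the definition
    expect_equal(p$modularity, modularity_q(g, p$communities),
                 tolerance = 1e-12)
  }
  # the bridge graphs split exactly at the bridge
  p2 <- greedy_modularity_partition(two_k4_bridge())
  expect_equal(p2$communities, list(paste0("a", 1:4), paste0("b", 1:4)))
})

test_that("greedy agglomeration never merges across components", {
  tri2 <- igraph::make_graph(c("a", "b", "b", "c", "a", "c",
                               "x", "y", "y", "z", "x", "z"),
                             directed = FALSE)
  p <- greedy_modularity_partition(tri2)
  expect_equal(length(p$communities), 2L)
  expect_setequal(vapply(p$communities, paste, "", collapse = ","),
                  c("a,b,c", "x,y,z"))

  # planted bipartite blocks with no edges between are recovered exactly
  blocks <- igraph::make_empty_graph(directed = FALSE)
  v1 <- c(paste0("T", 1:3), c("AA", "BB", "CC", "DD"))
  v2 <- c(paste0("U", 1:3), c("EE", "FF", "GG", "HH"))
  blocks <- igraph::add_vertices(blocks, 14, name = c(v1, v2))
  for (t in paste0("T", 1:3)) for (s in c("AA", "BB", "CC", "DD"))
    blocks <- igraph::add_edges(blocks, c(t, s))
  for (t in paste0("U", 1:3)) for (s in c("EE", "FF", "GG", "HH"))
    blocks <- igraph::add_edges(blocks, c(t, s))
  pb <- greedy_modularity_partition(blocks)
  expect_equal(length(pb$communities), 2L)
  expect_setequal(lapply(pb$communities, sort), list(sort(v1), sort(v2)))

  expect_error(greedy_modularity_partition(
    igraph::make_empty_graph(directed = FALSE)), "empty")
})

test_that("greedy result agrees with igraph fast-greedy on the fixtures", {
  for (g in list(two_triangles_bridge(), two_k4_bridge())) {
    ours <- greedy_modularity_partition(g)
    ig <- igraph::cluster_fast_greedy(g)
    expect_equal(ours$modularity, max(ig$modularity), tolerance = 1e-10)
  }
})

test_that("MCODE vertex weights follow the closed-neighbourhood core rule", {
  # isolated node weighs zero
  iso <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(1, name = "z")
  expect_equal(unname(mcode_vertex_weights(iso)), 0)

  # triangle member: closed neighbourhood is the triangle, 2-core, density 1
  expect_equal(unname(mcode_vertex_weights(triangle())["a"]), 2)

  # centre of a 3-leaf star: 1-core of 4 nodes / 3 edges -> 1 * 0.5
  expect_equal(unname(mcode_vertex_weights(star3())["c"]), 0.5)

  # K4 members weigh 3 (3-core, density 1); a pendant neighbour weighs 1
  w <- mcode_vertex_weights(k4_plus_pendant())
  expect_equal(unname(w[c("a", "b", "c", "d")]), rep(3, 4))
  expect_equal(unname(w["p"]), 1)

  # in the double K4, all eight vertices (bridge ends included) weigh 3
  expect_equal(unname(mcode_vertex_weights(two_k4_bridge())), rep(3, 8))
})

test_that("MCODE clusters match hand traces of the seed-and-expand rule", {
  # K4 with a pendant: the pendant's weight (1) is below 0.8 * 3, so the
  # cluster is exactly the K4
  cl <- mcode_clusters(k4_plus_pendant())
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$members, c("a", "b", "c", "d"))
  expect_equal(cl[[1]]$density, 1)

  # empty graph: no clusters
  expect_equal(mcode_clusters(igraph::make_empty_graph(directed = FALSE)),
               list())

  # double K4: every vertex weighs 3, so expansion crosses the bridge and
  # a single cluster spans both K4s (seed-and-expand does not cut
  # equally dense bridges; the modularity partitioner does)
  cl2 <- mcode_clusters(two_k4_bridge())
  expect_equal(length(cl2), 1L)
  expect_equal(cl2[[1]]$members, sort(c(paste0("a", 1:4), paste0("b", 1:4))))

  # clusters are vertex-disjoint and built from positive-weight nodes
  g <- random_graph(20, 0.25, seed = 31)
  cls <- mcode_clusters(g)
  members <- unlist(lapply(cls, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  w <- mcode_vertex_weights(g)
  expect_true(all(w[members] > 0))
})

test_that("clique extraction keeps species only, ranks and finds hubs", {
  tab <- toy_survey()
  meta <- toy_meta()
  g <- build_bipartite(to_abundance_matrix(tab, "S1"))
  part <- greedy_modularity_partition(g)
  cl <- extract_species_cliques(part, g, meta)
  expect_setequal(unique(cl$species_code[cl$clique_rank == 1]),
                  c("AAA", "BBB", "LC"))
  expect_true(all(cl$species_code %in% meta$code))
  # each species belongs to exactly one clique
  expect_equal(anyDuplicated(cl$species_code), 0L)
  # hub of a star community is its centre
  star_g <- edges_to <- igraph::make_graph(
    c("T1", "AA", "T1", "BB", "T2", "AA"), directed = FALSE)
  igraph::V(star_g)$kind <- c("transect", "species", "species", "transect")
  hubs <- identify_hubs(c("AA", "BB"), star_g, c("T1", "T2", "AA", "BB"))
  expect_equal(hubs, "AA")
  # ties return all hubs, code-sorted
  hubs2 <- identify_hubs(c("AAA", "BBB", "LC"), g,
                         part$communities[[which(vapply(
                           part$communities, function(x) "LC" %in% x, TRUE))]])
  expect_equal(hubs2, c("AAA", "BBB", "LC"))

  # a community of transects only yields no clique
  fake <- structure(list(communities = list(c("S1T1", "S1T2")),
                         membership = NULL, modularity = 0,
                         method = "manual"), class = "vegnet_partition")
  sub <- igraph::induced_subgraph(g, c("S1T1", "S1T2"))
  expect_equal(nrow(extract_species_cliques(fake, sub)), 0L)
})
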