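make_am <- function(counts_row, site = "HK") {
  m <- matrix(as.integer(counts_row), nrow = 1,
              dimnames = list(paste0(site, 1), names(counts_row)))
  structure(list(site_id = site, counts = m,
                 species_totals = colSums(m), total = sum(m)),
            class = "vegnet_abundance")
}

test_that("rank abundance normalises, sorts and breaks ties by code", {
  am <- make_am(c(A = 6L, B = 3L, C = 1L))
  # codes are free-form here; metadata validation is tested elsewhere
  ra <- rank_abundance(am)
  expect_equal(ra$species_code, c("A", "B", "C"))
  expect_equal(ra$relative_abundance, c(0.6, 0.3, 0.1))
  expect_equal(ra$rank, 1:3)
  expect_equal(sum(ra$relative_abundance), 1)

  ra2 <- rank_abundance(make_am(c(B = 2L, A = 2L)))
  expect_equal(ra2$species_code, c("A", "B"))

  ra3 <- rank_abundance(make_am(c(Z = 9L)))
  expect_equal(ra3$relative_abundance, 1)

  empty <- make_am(c(A = 0L))
  expect_error(rank_abundance(empty), "empty")
})

test_that("analytic rarefaction matches enumeration, vegan and Monte Carlo", {
  # exhaustive oracle for counts (2,2), n = 2: of the C(4,2) = 6 equally
  # likely subsamples, 4 contain both species and 2 only one -> 5/3
  pool <- c(1, 1, 2, 2)
  subsets <- utils::combn(4, 2)
  exp_rich <- mean(apply(subsets, 2, function(ix) length(unique(pool[ix]))))
  expect_equal(exp_rich, 5 / 3)
  expect_equal(rarefaction_richness(c(2, 2), 2), 5 / 3)

  # edge cases: full sample returns observed richness; single species -> 1
  expect_equal(rarefaction_richness(c(4, 3, 2), 9), 3)
  expect_equal(rarefaction_richness(c(7), 3), 1)
  expect_equal(rarefaction_richness(c(2, 2), 0), 0)
  expect_error(rarefaction_richness(c(2, 2), 5), "<=")

  # independent implementation in vegan agrees
  counts <- c(10, 5, 3, 2, 1, 1)
  for (n in c(1, 5, 10, 22)) {
    expect_equal(rarefaction_richness(counts, n),
                 as.numeric(vegan::rarefy(counts, n)), tolerance = 1e-10)
  }

  # Monte-Carlo agreement within 3 standard errors on random vectors
  set.seed(42)
  for (rep in 1:3) {
    cts <- sample(1:12, 5, replace = TRUE)
    n <- sample(seq_len(sum(cts)), 1)
    draws <- 10000L
    pool <- rep(seq_along(cts), cts)
    sims <- vapply(seq_len(draws),
                   function(i) length(unique(sample(pool, n))), 0)
    se <- stats::sd(sims) / sqrt(draws)
    expect_lt(abs(rarefaction_richness(cts, n) - mean(sims)),
              max(3 * se, 1e-9))
  }

  # monotone non-decreasing in n
  curve <- rarefaction_curve(counts, 0:22)
  expect_true(all(diff(curve$expected_richness) >= -1e-12))
})

test_that("Bray-Curtis matches the formula, is symmetric and bounded", {
  expect_equal(bray_curtis(c(1, 2, 3), c(2, 1, 0)), 5 / 9)
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(2, 0), c(0, 5)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")

  set.seed(7)
  for (i in 1:20) {
    a <- stats::rpois(6, 3)
    b <- stats::rpois(6, 3)
    if (sum(a) + sum(b) == 0) next
    bc <- bray_curtis(a, b)
    manual <- 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
    expect_equal(bc, manual, tolerance = 1e-12)
    expect_equal(bc, bray_curtis(b, a))
    expect_gte(bc, 0)
    expect_lte(bc, 1)
    expect_equal(bc == 0, all(a == b))
  }
})

test_that("UPGMA reproduces hand agglomeration and brute force to size 6", {
  d <- matrix(c(0, 2, 8,
                2, 0, 6,
                8, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- upgma(d)
  expect_equal(h$height, c(2, 7))

  # two samples: single merge at their distance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  expect_equal(upgma(d2)$height, 3)

  # ultrametric input is reproduced exactly
  du <- matrix(c(0, 1, 4, 4,
                 1, 0, 4, 4,
                 4, 4, 0, 2,
                 4, 4, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(sort(upgma(du)$height), c(1, 2, 4))

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")

  # brute-force agglomeration oracle on random matrices up to size 6
  set.seed(11)
  for (n in 3:6) for (rep in 1:3) {
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.1, 2)
    m <- m + t(m)
    expect_equal(sort(upgma(m)$height), sort(brute_upgma_heights(m)),
                 tolerance = 1e-10)
  }
})

test_that("Newick export carries merge-height depths", {
  d <- matrix(c(0, 2, 8, 2, 0, 6, 8, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(upgma(d), tmp)
  phy <- ape::read.tree(tmp)
  depths <- ape::node.depth.edgelength(phy)
  # root-to-leaf depth equals the root merge height
  expect_equal(max(depths[seq_along(phy$tip.label)]), 7)
})

test_that("Pearson exclusion test matches the product-moment formula", {
  res <- pearson_exclusion_test(1:5, c(2, 1, 4, 3, 6))
  expect_equal(res$r, 10 / sqrt(148), tolerance = 1e-12)
  r <- res$r
  tstat <- r * sqrt((5 - 2) / (1 - r^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), df = 3),
               tolerance = 1e-12)
  expect_equal(res$n, 5L)

  expect_equal(pearson_exclusion_test(1:4, -(1:4))$r, -1)
  expect_equal(pearson_exclusion_test(1:4, 1:4)$r, 1)
  # r = 0 gives p = 1
  expect_equal(pearson_exclusion_test(c(-1, 0, 1), c(1, 0, 1))$p_value, 1)
  expect_error(pearson_exclusion_test(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson_exclusion_test(1:2, 2:1), "at least 3")
})

test_that("site Bray-Curtis pools transect counts per site", {
  tab <- toy_survey()
  d <- bray_curtis_sites(tab)
  expect_equal(attr(d, "Size"), 2L)
  pooled <- function(s) {
    sp <- sort(unique(tab$species_code))
    v <- setNames(numeric(length(sp)), sp)
    sub <- tab[tab$site == s, ]
    for (i in seq_len(nrow(sub)))
      v[sub$species_code[i]] <- v[sub$species_code[i]] + sub$count[i]
    v
  }
  expect_equal(as.numeric(d), bray_curtis(pooled("S1"), pooled("S2")))
})
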