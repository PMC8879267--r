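#' Rank abundance table for one site
#'
#' Relative abundance p_i = N_i / N per species, sorted descending with
#' ties broken by species code, ranks 1..S.
#'
#' @param matrix A site abundance matrix from [to_abundance_matrix()].
#' @param meta Optional species metadata; adds a \code{status} column.
#' @return Data frame with columns \code{species_code}, \code{status} (if
#'   \code{meta} given), \code{abundance}, \code{relative_abundance},
#'   \code{rank}.
#' @export
rank_abundance <- function(matrix, meta = NULL) {
  stopifnot(inherits(matrix, "vegnet_abundance"))
  if (matrix$total <= 0) stop("empty abundance matrix: no individuals")
  n_i <- matrix$species_totals
  ord <- order(-n_i, names(n_i))
  out <- data.frame(species_code = names(n_i)[ord],
                    abundance = as.integer(n_i[ord]),
                    relative_abundance = as.numeric(n_i[ord]) / matrix$total,
                    rank = seq_along(n_i),
                    stringsAsFactors = FALSE)
  if (!is.null(meta))
    out <- data.frame(out[1L],
                      status = meta$status[match(out$species_code, meta$code)],
                      out[-1L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Expected species richness under rarefaction
#'
#' Analytic (hypergeometric) rarefaction: the expected number of species
#' in a random subsample of \code{n} of the N observed individuals,
#' \deqn{E[S_n] = \sum_i [1 - C(N - N_i, n) / C(N, n)].}
#' Deterministic by default; \code{method = "resample"} estimates the same
#' quantity by Monte-Carlo subsampling for cross-validation.
#'
#' @param counts Positive integer per-species totals N_i.
#' @param n Subsample size, 0 <= n <= sum(counts).
#' @param method \code{"analytic"} (default) or \code{"resample"}.
#' @param draws Number of Monte-Carlo draws for \code{"resample"}.
#' @param seed Optional seed for \code{"resample"}.
#' @return Expected richness (a single number).
#' @export
rarefaction_richness <- function(counts, n, method = c("analytic", "resample"),
                                 draws = 1000L, seed = NULL) {
  method <- match.arg(method)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("no positive counts")
  if (any(counts != round(counts))) stop("counts must be integers")
  N <- sum(counts)
  if (n < 0 || n > N) stop("subsample size n must satisfy 0 <= n <= ", N)
  if (n == 0) return(0)
  if (method == "analytic") {
    # lchoose keeps the terms stable for large N
    return(sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n))))
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- rep(seq_along(counts), counts)
  mean(vapply(seq_len(draws),
              function(i) length(unique(sample(pool, n))), 0))
}

#' Rarefaction curve
#'
#' @inheritParams rarefaction_richness
#' @param sizes Integer vector of subsample sizes.
#' @return Data frame with columns \code{n} and \code{expected_richness}.
#' @export
rarefaction_curve <- function(counts, sizes) {
  data.frame(n = sizes,
             expected_richness = vapply(sizes, function(s)
               rarefaction_richness(counts, s), 0))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \deqn{BC = 1 - 2 \sum_i \min(a_i, b_i) / (\sum_i a_i + \sum_i b_i)}
#'
#' @param a,b Equal-length non-negative count vectors, not both all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  if (sum(a) + sum(b) == 0)
    stop("Bray-Curtis is undefined for two all-zero vectors")
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Site-by-site Bray-Curtis dissimilarity matrix
#'
#' Pools each site's counts over its transects (whole sites are the
#' comparison unit) and returns the pairwise Bray-Curtis matrix.
#'
#' @param table A survey table.
#' @return A \code{dist} object over the site ids.
#' @export
bray_curtis_sites <- function(table) {
  sites <- sort(unique(table$site))
  if (length(sites) < 2L) stop("need at least two sites")
  species <- sort(unique(table$species_code))
  pooled <- matrix(0, length(sites), length(species),
                   dimnames = list(sites, species))
  agg <- stats::aggregate(count ~ site + species_code, data = table, FUN = sum)
  pooled[cbind(match(agg$site, sites), match(agg$species_code, species))] <-
    agg$count
  vegan::vegdist(pooled, method = "bray")
}

#' UPGMA cluster analysis
#'
#' Unweighted pair-group (average linkage) agglomeration of a
#' dissimilarity matrix; the height of each merge is the average
#' dissimilarity between the merged clusters (merge distance, not
#' half-distance).
#'
#' @param d A symmetric dissimilarity matrix with zero diagonal, or a
#'   \code{dist} object.
#' @return An \code{hclust} tree.
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
      stop("dissimilarity matrix must be symmetric")
    if (any(diag(d) != 0)) stop("dissimilarity matrix must have zero diagonal")
    d <- as.dist(d)
  }
  if (attr(d, "Size") < 2L) stop("need at least two samples")
  hclust(d, method = "average")
}

#' Write a dendrogram as Newick
#'
#' Branch lengths are scaled so the root-to-leaf depth equals the merge
#' height of the root (merge-distance convention).
#'
#' @param tree An \code{hclust} tree (e.g. from [upgma()]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  phy$edge.length <- phy$edge.length * 2  # as.phylo halves merge heights
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Pearson test for abundance-level exclusion
#'
#' Product-moment correlation between the relative abundances of two
#' focal species across sampling units, with a two-sided p-value from the
#' t distribution on n - 2 degrees of freedom.  A significantly negative
#' r is the abundance-level signature of competitive exclusion.
#'
#' @param x,y Paired relative abundances (n >= 3, neither constant).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return A list of class \code{vegnet_correlation} with \code{r},
#'   \code{p_value}, \code{n} and \code{alpha}.
#' @export
pearson_exclusion_test <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), alpha = alpha),
            class = "vegnet_correlation")
}

#' @export
print.vegnet_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, two-sided p = %.4g, alpha = %g)\n",
              x$r, x$n, x$p_value, x$alpha))
  invisible(x)
}

#' Correlation between the relative abundances of two focal species
#'
#' Pairs the two focals' relative abundances per sampling unit
#' (transects by default for larger n, or whole sites) and runs
#' [pearson_exclusion_test()].
#'
#' @param table A survey table.
#' @param focal Character vector of two species codes.
#' @param unit \code{"transect"} or \code{"site"}.
#' @inheritParams pearson_exclusion_test
#' @return A \code{vegnet_correlation}.
#' @export
focal_correlation <- function(table, focal, unit = c("transect", "site"),
                              alpha = 0.05) {
  unit <- match.arg(unit)
  stopifnot(length(focal) == 2L)
  if (unit == "transect") {
    key <- transect_node_id(table$site, table$transect)
  } else {
    key <- as.character(table$site)
  }
  units <- sort(unique(key))
  tot <- rowsum(as.numeric(table$count), key)[units, 1L]
  f1 <- rowsum(as.numeric(table$count) * (table$species_code == focal[1L]),
               key)[units, 1L]
  f2 <- rowsum(as.numeric(table$count) * (table$species_code == focal[2L]),
               key)[units, 1L]
  keep <- tot > 0
  pearson_exclusion_test(f1[keep] / tot[keep], f2[keep] / tot[keep],
                         alpha = alpha)
}
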