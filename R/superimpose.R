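#' Extract a focal species' clique partners across all sites
#'
#' For every clique (pooled over sites) containing the focal species,
#' each co-member's weight is incremented by one, so a partner's weight
#' is the number of times that association was observed across the
#' study.
#'
#' @param cliques A clique data frame (all sites stacked) with columns
#'   \code{site}, \code{clique_rank}, \code{species_code}.
#' @param focal Focal species code.
#' @return Named integer vector of partner weights (possibly empty),
#'   sorted by partner code.
#' @export
extract_focal_edges <- function(cliques, focal) {
  known <- unique(cliques$species_code)
  if (!focal %in% known)
    stop("unknown focal code '", focal, "': not present in any clique table")
  key <- paste(cliques$site, cliques$clique_rank)
  with_focal <- unique(key[cliques$species_code == focal])
  partners <- cliques$species_code[key %in% with_focal &
                                     cliques$species_code != focal]
  if (!length(partners)) return(setNames(integer(), character()))
  tab <- table(partners)
  setNames(as.integer(tab), names(tab))
}

#' Merge two focal partner sets and classify shared vs exclusive
#'
#' A partner associated with both focals is \code{shared}; partners of
#' only one focal form that focal's exclusive module.  Module strength is
#' reported as (number of partners, total edge weight).
#'
#' @param edges1,edges2 Named weight vectors from [extract_focal_edges()].
#' @param focal Character vector of the two focal codes (labels only).
#' @param meta Optional species metadata for partner status labels.
#' @return An object of class \code{vegnet_focal_graph}: list with
#'   \code{focal}, \code{edges} (data frame focal/partner/weight/class),
#'   \code{partners} (per-class code lists) and \code{modules} (per-class
#'   size and total weight).
#' @export
merge_and_classify <- function(edges1, edges2, focal = c("LC", "PJ"),
                               meta = NULL) {
  stopifnot(length(focal) == 2L)
  shared <- sort(intersect(names(edges1), names(edges2)))
  ex1 <- sort(setdiff(names(edges1), names(edges2)))
  ex2 <- sort(setdiff(names(edges2), names(edges1)))
  class_of <- c(setNames(rep("shared", length(shared)), shared),
                setNames(rep("exclusive_focal1", length(ex1)), ex1),
                setNames(rep("exclusive_focal2", length(ex2)), ex2))
  ed <- rbind(
    if (length(edges1))
      data.frame(focal = focal[1L], partner = names(edges1),
                 weight = as.integer(edges1), stringsAsFactors = FALSE),
    if (length(edges2))
      data.frame(focal = focal[2L], partner = names(edges2),
                 weight = as.integer(edges2), stringsAsFactors = FALSE))
  if (is.null(ed))
    ed <- data.frame(focal = character(), partner = character(),
                     weight = integer(), stringsAsFactors = FALSE)
  ed$class <- unname(class_of[ed$partner])
  if (!is.null(meta))
    ed$partner_status <- meta$status[match(ed$partner, meta$code)]
  ed <- ed[order(ed$focal, ed$partner), , drop = FALSE]
  rownames(ed) <- NULL
  modules <- data.frame(
    class = c("shared", "exclusive_focal1", "exclusive_focal2"),
    n_partners = c(length(shared), length(ex1), length(ex2)),
    total_weight = c(sum(ed$weight[ed$class == "shared"]),
                     sum(ed$weight[ed$class == "exclusive_focal1"]),
                     sum(ed$weight[ed$class == "exclusive_focal2"])),
    stringsAsFactors = FALSE)
  structure(list(focal = focal, edges = ed,
                 partners = list(shared = shared, exclusive_focal1 = ex1,
                                 exclusive_focal2 = ex2),
                 modules = modules),
            class = "vegnet_focal_graph")
}

#' @export
print.vegnet_focal_graph <- function(x, ...) {
  cat("Focal association graph for", x$focal[1L], "vs", x$focal[2L], "\n")
  print(x$modules)
  invisible(x)
}

#' Check clique-level exclusion of two focal species
#'
#' A site passes when no clique at that site contains both focals; the
#' global flag is the conjunction over sites.
#'
#' @param cliques A stacked clique data frame.
#' @param focal_pair Character vector of the two focal codes.
#' @return A list with named logical \code{per_site} and logical
#'   \code{global}.
#' @export
site_exclusion_check <- function(cliques, focal_pair = c("LC", "PJ")) {
  stopifnot(length(focal_pair) == 2L)
  sites <- sort(unique(cliques$site))
  key <- paste(cliques$site, cliques$clique_rank)
  both <- unique(key[cliques$species_code == focal_pair[1L]])
  both <- intersect(both,
                    unique(key[cliques$species_code == focal_pair[2L]]))
  offending_sites <- unique(cliques$site[key %in% both])
  per_site <- setNames(!(sites %in% offending_sites), sites)
  list(per_site = per_site, global = all(per_site))
}

#' Markov clustering of the combined focal association graph
#'
#' Builds the weighted graph of both focals and their partners (edge
#' weight = association count) and clusters it with MCL; each resulting
#' module is annotated with its dominant partner class.
#'
#' @param graph A \code{vegnet_focal_graph} from [merge_and_classify()].
#' @param params MCL parameters.
#' @return A list with \code{mcl} (the [mcl_cluster()] result) and
#'   \code{modules} (per cluster: members, dominant class).
#' @export
cluster_combined <- function(graph, params = mcl_params()) {
  stopifnot(inherits(graph, "vegnet_focal_graph"))
  ed <- graph$edges
  if (!nrow(ed)) stop("merged focal association graph is empty")
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$focal, to = ed$partner, weight = ed$weight),
    directed = FALSE)
  res <- mcl_cluster(g, params)
  class_of <- setNames(ed$class, ed$partner)
  modules <- lapply(res$clusters, function(cl) {
    cls <- class_of[intersect(cl, names(class_of))]
    dominant <- if (length(cls)) names(sort(-table(cls)))[1L] else NA_character_
    list(members = cl, dominant_class = dominant)
  })
  list(mcl = res, modules = modules)
}
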