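#' Extract species cliques from a partition
#'
#' A "clique" in this pipeline is a partition community reported by its
#' species members only (transect nodes are dropped).  Communities with
#' fewer than \code{min_species} species are discarded as noise; the rest
#' are ranked by species count (ties by smallest species code).  The hub
#' of each clique is its highest-degree species within the community
#' subgraph of the site network.
#'
#' @param partition A \code{vegnet_partition} of a bipartite site network.
#' @param graph The bipartite site network the partition was computed on.
#' @param meta Optional species metadata; adds per-species \code{status}
#'   and the clique's dominant invasive (an invasive hub's code, if any).
#' @param min_species Minimum species per clique (default 2).
#' @return A data frame with one row per clique member: columns
#'   \code{site}, \code{clique_rank}, \code{species_code}, \code{is_hub}
#'   and (with \code{meta}) \code{status}, \code{dominant_invasive}.
#' @export
extract_species_cliques <- function(partition, graph, meta = NULL,
                                    min_species = 2L) {
  stopifnot(inherits(partition, "vegnet_partition"))
  kind <- setNames(igraph::V(graph)$kind, igraph::V(graph)$name)
  site <- if (is.null(graph$site_id)) NA_character_ else graph$site_id
  cl <- lapply(partition$communities, function(comm) {
    sp <- sort(comm[kind[comm] == "species"])
    if (length(sp) < min_species) return(NULL)
    list(species = sp, community = comm)
  })
  cl <- Filter(Negate(is.null), cl)
  if (!length(cl)) {
    return(data.frame(site = character(), clique_rank = integer(),
                      species_code = character(), is_hub = logical(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-lengths(lapply(cl, `[[`, "species")),
               vapply(cl, function(x) x$species[1L], ""))
  cl <- cl[ord]
  rows <- lapply(seq_along(cl), function(i) {
    hubs <- identify_hubs(cl[[i]]$species, graph, cl[[i]]$community)
    data.frame(site = site, clique_rank = i,
               species_code = cl[[i]]$species,
               is_hub = cl[[i]]$species %in% hubs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    out$status <- meta$status[match(out$species_code, meta$code)]
    dom <- vapply(split(out, out$clique_rank), function(d) {
      inv <- d$species_code[d$is_hub & !is.na(d$status) &
                              d$status == "invasive"]
      if (length(inv)) inv[1L] else NA_character_
    }, "")
    out$dominant_invasive <- dom[as.character(out$clique_rank)]
  }
  rownames(out) <- NULL
  out
}

#' Identify the hub species of a clique
#'
#' The hub is the species with the highest degree in the site network
#' restricted to the clique's community.  All species tied at the
#' maximal degree are reported, in code order.
#'
#' @param clique Character vector of member species codes.
#' @param graph The bipartite site network.
#' @param community Optional full community (species + transects) to
#'   restrict the network to; defaults to the clique members and all
#'   their transect neighbours.
#' @return Character vector of hub species codes.
#' @export
identify_hubs <- function(clique, graph, community = NULL) {
  if (!length(clique)) stop("empty clique")
  if (is.null(community)) {
    nb <- unique(unlist(lapply(clique, function(v)
      igraph::neighbors(graph, v)$name)))
    community <- union(clique, nb)
  }
  sub <- igraph::induced_subgraph(graph, community)
  deg <- igraph::degree(sub)[clique]
  sort(names(deg)[deg == max(deg)])
}

#' Run community detection on every site of a survey
#'
#' Builds one bipartite network per site, partitions it and extracts
#' species cliques; the per-site results are stacked into one table.
#'
#' @param table A survey table.
#' @param meta Species metadata.
#' @param algorithm \code{"greedy_modularity"} (default) or
#'   \code{"mcode"}.
#' @param mcode MCODE parameters used when \code{algorithm = "mcode"}.
#' @param min_species Minimum species per clique.
#' @return A list with \code{cliques} (stacked data frame),
#'   \code{partitions} and \code{networks} (named per site).
#' @export
partition_all_sites <- function(table, meta = NULL,
                                algorithm = c("greedy_modularity", "mcode"),
                                mcode = mcode_params(), min_species = 2L) {
  algorithm <- match.arg(algorithm)
  sites <- sort(unique(table$site))
  networks <- list()
  partitions <- list()
  cliques <- list()
  for (s in sites) {
    g <- build_bipartite(to_abundance_matrix(table, s))
    g <- simplify_network2(g)
    part <- if (algorithm == "greedy_modularity")
      greedy_modularity_partition(g) else mcode_partition(g, mcode)
    networks[[s]] <- g
    partitions[[s]] <- part
    cliques[[s]] <- extract_species_cliques(part, g, meta = meta,
                                            min_species = min_species)
  }
  list(cliques = do.call(rbind, c(cliques, list(make.row.names = FALSE))),
       partitions = partitions, networks = networks)
}

# simplify while keeping graph attributes (igraph::simplify drops none,
# but as_undirected can; kept as a single point of truth)
simplify_network2 <- function(g) {
  sid <- g$site_id
  g <- simplify_network(g)
  g$site_id <- sid
  g
}

#' Write a clique table to CSV
#'
#' @param cliques Clique data frame from [extract_species_cliques()] or
#'   [partition_all_sites()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cliques <- function(cliques, path) {
  write.csv(cliques, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clique table from CSV
#'
#' @param path CSV with at least columns
#'   \code{site,clique_rank,species_code}.
#' @return The clique data frame.
#' @export
read_cliques <- function(path) {
  if (!file.exists(path)) stop("clique file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("site", "clique_rank", "species_code")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("clique table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  df
}
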