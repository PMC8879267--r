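#' Configuration for the synthetic survey generator
#'
#' The generator emulates a multi-site line-transect woodland survey:
#' each site's transects are divided among co-occurrence blocks, two
#' focal invasive species anchor one block each, and species occur on
#' transects of their own block with probability \code{p_in} and
#' elsewhere with probability \code{p_out} -- except across the two
#' focal blocks, where background occupancy is damped by the exclusion
#' strength \code{gamma} (at \code{gamma = 1} a focal-block species never
#' crosses to the rival focal's transects).  Counts for present species
#' are overdispersed (negative binomial), and each site draws a
#' dominance weight that tilts the two focals' abundances in opposite
#' directions, planting the site-level abundance anti-correlation.
#'
#' @param n_sites Number of sites (default 6).
#' @param transects_per_site Transects per site (default 15, i.e. about
#'   90 transects in all, the scale of a 94-transect survey).
#' @param n_native,n_invasive,n_introduced Species counts by status
#'   (defaults 45, 2, 3; the two invasives are the focal pair LC/PJ).
#' @param blocks_per_site Co-occurrence blocks per site (default 4: one
#'   per focal plus two native-anchored blocks, inside the 3-6 cliques
#'   per site seen in real fragments).
#' @param p_in Within-block occupancy probability (default 0.8).
#' @param p_out Background occupancy probability (default 0.05).
#' @param abundance_dispersion Negative-binomial size parameter for
#'   counts (default 1, strongly overdispersed).
#' @param exclusion_strength gamma in \[0, 1\] (default 1).
#' @param focal_dominance_range Range the per-site focal dominance
#'   weight w is drawn from (default c(0.2, 0.8)).
#' @param seed Master seed; per-site substreams are derived from it so
#'   adding sites never perturbs existing ones.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_sites = 6L, transects_per_site = 15L,
                             n_native = 45L, n_invasive = 2L,
                             n_introduced = 3L, blocks_per_site = 4L,
                             p_in = 0.8, p_out = 0.05,
                             abundance_dispersion = 1,
                             exclusion_strength = 1,
                             focal_dominance_range = c(0.2, 0.8),
                             seed = 1L) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            exclusion_strength >= 0, exclusion_strength <= 1,
            n_native >= 0, n_invasive >= 2, n_introduced >= 0,
            blocks_per_site >= 2, n_sites >= 1, transects_per_site >= 1,
            abundance_dispersion > 0,
            length(focal_dominance_range) == 2L)
  if (blocks_per_site > n_native + n_invasive + n_introduced)
    stop("more blocks than species: infeasible configuration")
  structure(as.list(environment()), class = "synthetic_config")
}

# Species codes: focals LC/PJ, further invasives IVx, introduced INx,
# natives Nxx -- all 2-4 uppercase letters, unique.
synthetic_species_metadata <- function(config) {
  pair2 <- function(i) paste0(LETTERS[(i - 1L) %/% 26L + 1L],
                              LETTERS[(i - 1L) %% 26L + 1L])
  inv <- c("LC", "PJ",
           if (config$n_invasive > 2L)
             paste0("IV", LETTERS[seq_len(config$n_invasive - 2L)]))
  intro <- if (config$n_introduced > 0L)
    paste0("IN", LETTERS[seq_len(config$n_introduced)]) else character()
  nat <- if (config$n_native > 0L)
    paste0("N", vapply(seq_len(config$n_native), pair2, "")) else character()
  data.frame(
    code = c(inv, intro, nat),
    scientific_name = c(
      if (length(inv) >= 1L) "Lantana synthetica",
      if (length(inv) >= 2L) "Prosopis synthetica",
      if (length(inv) > 2L) paste("Invasivus synthetic", seq_len(length(inv) - 2L)),
      if (length(intro)) paste("Introductus synthetic", seq_along(intro)),
      if (length(nat)) paste("Nativus synthetic", seq_along(nat))),
    status = c(rep("invasive", length(inv)),
               rep("introduced", length(intro)),
               rep("native", length(nat))),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-site survey
#'
#' See [synthetic_config()] for the generative model.  All randomness
#' flows from one master seed; the per-site substream seeds are drawn
#' first, so the output is fully reproducible and prefix-stable in the
#' number of sites.
#'
#' @param config A [synthetic_config()].
#' @return A list with \code{survey} (survey table), \code{meta}
#'   (species metadata) and \code{truth} (\code{SyntheticGroundTruth}:
#'   per-species block, per-site transect blocks, block anchors, focal
#'   dominance weights, realised occupancy matrices).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  meta <- synthetic_species_metadata(config)
  focal <- meta$code[meta$status == "invasive"][1:2]
  B <- config$blocks_per_site
  set.seed(config$seed)
  site_seeds <- sample.int(2147483646L, config$n_sites)
  # global block membership: focals anchor blocks 1 and 2; natives are
  # dealt round-robin over all blocks; introduced species live in the
  # native-anchored blocks (they are shared flora, not focal partners)
  species_block <- setNames(integer(nrow(meta)), meta$code)
  species_block[focal] <- 1:2
  other_inv <- setdiff(meta$code[meta$status == "invasive"], focal)
  if (length(other_inv))
    species_block[other_inv] <- rep(1:2, length.out = length(other_inv))
  natives <- meta$code[meta$status == "native"]
  species_block[natives] <- rep(seq_len(B), length.out = length(natives))
  intro <- meta$code[meta$status == "introduced"]
  if (length(intro)) {
    host <- if (B > 2L) seq(3L, B) else seq_len(B)
    species_block[intro] <- rep(host, length.out = length(intro))
  }
  anchors <- c(focal,
               vapply(seq_len(B)[-(1:2)], function(b)
                 sort(natives[species_block[natives] == b])[1L], ""))
  # per-species base abundance: invasives dominate, introduced are scarce
  mu_base <- setNames(numeric(nrow(meta)), meta$code)
  mu_base[meta$status == "invasive"] <- 25
  mu_base[meta$status == "introduced"] <- 2
  mu_base[natives] <- exp(rnorm(length(natives), log(5), 0.6))
  sites <- sprintf("S%02d", seq_len(config$n_sites))
  # each site is dominated by one focal or the other: w sits at an end of
  # the dominance range, balanced over sites and shuffled
  w_ends <- range(config$focal_dominance_range)
  w_site <- setNames(
    sample(rep(w_ends, length.out = config$n_sites)), sites)
  records <- list()
  occupancy <- list()
  transect_blocks <- list()
  for (i in seq_len(config$n_sites)) {
    set.seed(site_seeds[i])
    s <- sites[i]
    Tn <- config$transects_per_site
    tb <- sample(rep(seq_len(B), length.out = Tn))
    transects <- sprintf("%sT%02d", s, seq_len(Tn))
    names(tb) <- transects
    w <- w_site[s]
    # occupancy probabilities: species x transect
    sb <- species_block[meta$code]
    p <- matrix(config$p_out, nrow(meta), Tn,
                dimnames = list(meta$code, transects))
    conflict <- outer(sb, tb, function(bs, bt)
      (bs %in% 1:2) & (bt %in% 1:2) & bs != bt)
    p[conflict] <- config$p_out * (1 - config$exclusion_strength)
    own <- outer(sb, tb, `==`)
    p[own] <- config$p_in
    occ <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p),
                  dimnames = dimnames(p))
    # site-tilted focal means plant the abundance anti-correlation
    mu <- mu_base
    mu[focal[1L]] <- mu_base[focal[1L]] * 2 * w
    mu[focal[2L]] <- mu_base[focal[2L]] * 2 * (1 - w)
    idx <- which(occ == 1L, arr.ind = TRUE)
    if (nrow(idx)) {
      cnt <- 1L + rnbinom(nrow(idx), size = config$abundance_dispersion,
                          mu = pmax(mu[rownames(occ)[idx[, 1L]]] - 1, 0.1))
      records[[s]] <- data.frame(
        site = s, transect = transects[idx[, 2L]],
        species_code = rownames(occ)[idx[, 1L]],
        count = as.integer(cnt), stringsAsFactors = FALSE)
    }
    occupancy[[s]] <- occ
    transect_blocks[[s]] <- tb
  }
  survey <- as_survey_table(do.call(rbind, records), meta)
  truth <- structure(list(
    config = config, focal = focal, species_block = species_block,
    species_status = setNames(meta$status, meta$code),
    transect_blocks = transect_blocks, anchors = anchors,
    focal_dominance = w_site, occupancy = occupancy),
    class = "synthetic_truth")
  list(survey = survey, meta = meta, truth = truth)
}

#' Recovery metrics for a generated study
#'
#' Compares pipeline outputs against the planted ground truth:
#' clique-level exclusion of the two focals, precision/recall of the
#' planted exclusive-block native partners against the classified
#' exclusive modules, and the sign/significance of the focal abundance
#' correlation.
#'
#' @param truth The \code{synthetic_truth} from [generate_study()].
#' @param cliques Stacked clique table from [partition_all_sites()].
#' @param correlation A \code{vegnet_correlation} for the two focals.
#' @param focal_graph A \code{vegnet_focal_graph} for the two focals.
#' @return A list with \code{exclusion_per_site}, \code{exclusion_all},
#'   \code{precision}, \code{recall} (averaged over the two focals) and
#'   \code{correlation} summaries.
#' @export
recovery_metrics <- function(truth, cliques, correlation, focal_graph) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(focal_graph, "vegnet_focal_graph"),
            inherits(correlation, "vegnet_correlation"))
  if (!all(unique(cliques$species_code) %in% names(truth$species_block)))
    stop("clique table contains species absent from the ground truth")
  focal <- truth$focal
  excl <- site_exclusion_check(cliques, focal)
  # planted exclusive partners: the NATIVE members of each focal's block;
  # precision is likewise judged on native predictions only, so scarce
  # introduced/extra-invasive bystanders do not blur the planted signal
  natives <- names(truth$species_status)[truth$species_status == "native"]
  planted <- lapply(1:2, function(b)
    intersect(names(truth$species_block)[truth$species_block == b], natives))
  predicted <- list(
    intersect(focal_graph$partners$exclusive_focal1, natives),
    intersect(focal_graph$partners$exclusive_focal2, natives))
  pr <- vapply(1:2, function(k) {
    pred <- predicted[[k]]
    plant <- planted[[k]]
    hit <- length(intersect(pred, plant))
    c(precision = if (length(pred)) hit / length(pred) else NA_real_,
      recall = if (length(plant)) hit / length(plant) else NA_real_)
  }, c(precision = 0, recall = 0))
  list(exclusion_per_site = excl$per_site,
       exclusion_all = excl$global,
       precision = mean(pr["precision", ], na.rm = TRUE),
       recall = mean(pr["recall", ], na.rm = TRUE),
       correlation = list(r = correlation$r, p_value = correlation$p_value,
                          negative_significant =
                            correlation$r < 0 &
                            correlation$p_value < correlation$alpha))
}
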