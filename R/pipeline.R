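#' Pipeline configuration
#'
#' Describes one end-to-end run: either paths to a survey and species
#' metadata CSV, or a [synthetic_config()] to generate the study.
#'
#' @param survey Path to a survey CSV (ignored when \code{synthetic}
#'   given).
#' @param species Path to a species metadata CSV (ignored when
#'   \code{synthetic} given).
#' @param synthetic Optional [synthetic_config()].
#' @param focal Two focal species codes (default LC, PJ).
#' @param algorithm Partition algorithm, \code{"greedy_modularity"} or
#'   \code{"mcode"}.
#' @param mcode MCODE parameters.
#' @param mcl MCL parameters.
#' @param correlation_unit Sampling unit for the focal Pearson test.
#' @param out_dir Output directory for the bundle.
#' @param seed Seed for any stochastic stage (synthetic generation).
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(survey = NULL, species = NULL, synthetic = NULL,
                            focal = c("LC", "PJ"),
                            algorithm = c("greedy_modularity", "mcode"),
                            mcode = mcode_params(), mcl = mcl_params(),
                            correlation_unit = c("transect", "site"),
                            out_dir = "vegnet_out", seed = 1L) {
  algorithm <- match.arg(algorithm)
  correlation_unit <- match.arg(correlation_unit)
  if (is.null(synthetic) && (is.null(survey) || is.null(species)))
    stop("either survey+species paths or a synthetic config is required")
  stopifnot(length(focal) == 2L)
  structure(list(survey = survey, species = species, synthetic = synthetic,
                 focal = focal, algorithm = algorithm, mcode = mcode,
                 mcl = mcl, correlation_unit = correlation_unit,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Read or generate the survey; per site: abundance matrix, rank
#' abundance, rarefaction, bipartite network (SIF/GraphML), partition,
#' cliques and hubs; across sites: Bray-Curtis/UPGMA dendrogram, focal
#' Pearson test, focal superimposition with MCL modules.  All artifacts
#' are written to \code{config$out_dir} with deterministic content (a
#' fixed seed yields a byte-identical bundle), plus a manifest with the
#' config hash and seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress to standard error?
#' @return Invisibly, a list with the in-memory results (survey, meta,
#'   cliques, partitions, networks, correlation, focal graph, modules,
#'   recovery metrics when synthetic).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[vegnet] ", ...)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$synthetic)) {
      say("generating synthetic study")
      syn <- config$synthetic
      syn$seed <- config$seed
      study <- generate_study(syn)
      survey <- study$survey
      meta <- study$meta
      truth <- study$truth
    } else {
      say("reading survey")
      meta <- read_species_metadata(config$species)
      survey <- read_survey(config$survey, meta)
      truth <- NULL
    }
    if (!all(config$focal %in% meta$code))
      stop("focal code(s) missing from species metadata: ",
           paste(setdiff(config$focal, meta$code), collapse = ", "))
    write_survey(survey, file.path(out, "survey.csv"))
    write.csv(meta, file.path(out, "species.csv"), row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")

    stage <- "diversity statistics"
    say(stage)
    sites <- sort(unique(survey$site))
    ra <- do.call(rbind, lapply(sites, function(s) {
      am <- to_abundance_matrix(survey, s)
      cbind(site = s, rank_abundance(am, meta))
    }))
    write.csv(ra, file.path(out, "rank_abundance.csv"), row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
    rc <- do.call(rbind, lapply(sites, function(s) {
      am <- to_abundance_matrix(survey, s)
      sizes <- unique(round(seq(1, am$total, length.out = 25)))
      cbind(site = s, rarefaction_curve(am$species_totals, sizes))
    }))
    write.csv(rc, file.path(out, "rarefaction.csv"), row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
    if (length(sites) >= 2L) {
      bc <- bray_curtis_sites(survey)
      write.csv(as.matrix(bc), file.path(out, "bray_curtis.csv"),
                quote = FALSE, fileEncoding = "UTF-8")
      write_newick(upgma(bc), file.path(out, "dendrogram.nwk"))
    }

    stage <- "networks and partitioning"
    say(stage)
    parts <- partition_all_sites(survey, meta, algorithm = config$algorithm,
                                 mcode = config$mcode)
    for (s in sites) {
      write_sif(parts$networks[[s]], file.path(out, paste0(s, ".sif")))
      write_graphml(parts$networks[[s]],
                    file.path(out, paste0(s, ".graphml")))
    }
    write_cliques(parts$cliques, file.path(out, "cliques.csv"))
    part_dump <- lapply(parts$partitions, function(p)
      list(method = p$method, modularity = p$modularity,
           communities = p$communities))
    jsonlite::write_json(part_dump, file.path(out, "partitions.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    stage <- "focal correlation"
    say(stage)
    corr <- focal_correlation(survey, config$focal,
                              unit = config$correlation_unit)
    jsonlite::write_json(unclass(corr), file.path(out, "correlation.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "superimposition"
    say(stage)
    e1 <- extract_focal_edges(parts$cliques, config$focal[1L])
    e2 <- extract_focal_edges(parts$cliques, config$focal[2L])
    fg <- merge_and_classify(e1, e2, focal = config$focal, meta = meta)
    write.csv(fg$edges, file.path(out, "focal_associations.csv"),
              row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    modules <- if (nrow(fg$edges))
      cluster_combined(fg, config$mcl) else NULL
    jsonlite::write_json(
      list(module_strengths = fg$modules,
           mcl_modules = if (!is.null(modules))
             lapply(modules$modules, function(m)
               list(members = m$members, dominant_class = m$dominant_class))
           else list()),
      file.path(out, "modules.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)

    recovery <- NULL
    if (!is.null(truth)) {
      stage <- "recovery metrics"
      say(stage)
      recovery <- recovery_metrics(truth, parts$cliques, corr, fg)
    }

    stage <- "manifest"
    cfg_path <- file.path(out, "config.json")
    jsonlite::write_json(serialise_config(config), cfg_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest <- list(
      package = "vegnet",
      version = as.character(utils::packageVersion("vegnet")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      outputs = sort(setdiff(list.files(out), "manifest.json")))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    list(survey = survey, meta = meta, truth = truth,
         rank_abundance = ra, cliques = parts$cliques,
         partitions = parts$partitions, networks = parts$networks,
         correlation = corr, focal_graph = fg, modules = modules,
         recovery = recovery)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

serialise_config <- function(config) {
  list(survey = config$survey, species = config$species,
       synthetic = if (!is.null(config$synthetic))
         unclass(config$synthetic),
       focal = config$focal, algorithm = config$algorithm,
       mcode = unclass(config$mcode), mcl = unclass(config$mcl),
       correlation_unit = config$correlation_unit, seed = config$seed)
}

#' Run the pipeline in memory for a synthetic study
#'
#' Convenience wrapper used by the recovery experiments: generates a
#' study, partitions every site, runs the focal correlation and
#' superimposition, and returns the recovery metrics without touching
#' the filesystem.
#'
#' @param syn A [synthetic_config()].
#' @param algorithm Partition algorithm.
#' @param correlation_unit Sampling unit for the Pearson test.
#' @return A list like [run_pipeline()]'s, including \code{recovery}.
#' @export
run_synthetic_study <- function(syn,
                                algorithm = c("greedy_modularity", "mcode"),
                                correlation_unit = "transect") {
  algorithm <- match.arg(algorithm)
  study <- generate_study(syn)
  parts <- partition_all_sites(study$survey, study$meta,
                               algorithm = algorithm)
  corr <- focal_correlation(study$survey, study$truth$focal,
                            unit = correlation_unit)
  e1 <- extract_focal_edges2(parts$cliques, study$truth$focal[1L])
  e2 <- extract_focal_edges2(parts$cliques, study$truth$focal[2L])
  fg <- merge_and_classify(e1, e2, focal = study$truth$focal,
                           meta = study$meta)
  rec <- recovery_metrics(study$truth, parts$cliques, corr, fg)
  list(survey = study$survey, meta = study$meta, truth = study$truth,
       cliques = parts$cliques, partitions = parts$partitions,
       networks = parts$networks, correlation = corr, focal_graph = fg,
       recovery = rec)
}

# focal edges, tolerating a focal that fell out of every clique
extract_focal_edges2 <- function(cliques, focal) {
  if (!focal %in% unique(cliques$species_code))
    return(setNames(integer(), character()))
  extract_focal_edges(cliques, focal)
}
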