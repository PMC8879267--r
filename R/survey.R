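#' Read a species metadata table
#'
#' Species metadata maps each short code (2-4 uppercase letters) to a
#' scientific name and a status label: \code{native}, \code{invasive} or
#' \code{introduced}.
#'
#' @param path Path to a CSV file with columns
#'   \code{code,scientific_name,status}.
#' @return A data frame with columns \code{code}, \code{scientific_name},
#'   \code{status}.
#' @export
read_species_metadata <- function(path) {
  if (!file.exists(path)) stop("species metadata file not found: ", path)
  meta <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("code", "scientific_name", "status")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("species metadata is missing columns: ",
         paste(missing_cols, collapse = ", "))
  meta$scientific_name <- enc2utf8(meta$scientific_name)
  validate_species_metadata(meta)
  meta[need]
}

#' Validate species metadata
#'
#' Checks code uniqueness, code shape and the three-way status vocabulary.
#'
#' @param meta Data frame with columns \code{code}, \code{scientific_name},
#'   \code{status}.
#' @return The validated data frame, invisibly.
#' @export
validate_species_metadata <- function(meta) {
  if (anyDuplicated(meta$code))
    stop("duplicate species codes: ",
         paste(unique(meta$code[duplicated(meta$code)]), collapse = ", "))
  bad_status <- setdiff(unique(meta$status),
                        c("native", "invasive", "introduced"))
  if (length(bad_status))
    stop("unknown species status values: ",
         paste(bad_status, collapse = ", "),
         " (expected native/invasive/introduced)")
  bad_code <- meta$code[!grepl("^[A-Z]{2,4}$", meta$code)]
  if (length(bad_code))
    stop("species codes must be 2-4 uppercase letters; offending codes: ",
         paste(bad_code, collapse = ", "))
  invisible(meta)
}

#' Read a vegetation survey table
#'
#' Reads a CSV with columns
#' \code{site,transect,species_code,count[,gbh_cm,canopy_cover]} and
#' aggregates duplicate (site, transect, species) rows by summing counts
#' (field sheets for one transect are often split over several rows).
#'
#' @param path Path to the survey CSV.
#' @param meta Species metadata data frame (see
#'   [read_species_metadata()]); used to validate species codes.
#' @param allow_unknown If \code{TRUE}, rows whose species code is absent
#'   from \code{meta} are kept (with a warning) instead of raising an error.
#' @return A data frame of class \code{vegnet_survey} with one row per
#'   (site, transect, species) and integer \code{count}.
#' @export
read_survey <- function(path, meta, allow_unknown = FALSE) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("site", "transect", "species_code", "count")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("survey table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  as_survey_table(raw, meta, allow_unknown = allow_unknown)
}

#' Build a validated survey table from a raw data frame
#'
#' @inheritParams read_survey
#' @param records Data frame with at least
#'   \code{site,transect,species_code,count}.
#' @return A data frame of class \code{vegnet_survey}, aggregated over
#'   duplicate (site, transect, species) rows.
#' @export
as_survey_table <- function(records, meta = NULL, allow_unknown = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records)) {
    bad <- which(is.na(records$count) | records$count < 0 |
                   records$count != round(records$count))
    if (length(bad))
      stop("counts must be non-negative integers; offending row(s): ",
           paste(head(bad, 5L), collapse = ", "))
    if (!is.null(meta)) {
      unknown <- setdiff(unique(records$species_code), meta$code)
      if (length(unknown)) {
        msg <- paste0("unknown species code(s): ",
                      paste(unknown, collapse = ", "))
        if (allow_unknown) warning(msg) else stop(msg)
      }
    }
  }
  if (nrow(records)) {
    out <- stats::aggregate(count ~ site + transect + species_code,
                            data = records, FUN = sum)
    out$count <- as.integer(out$count)
    out <- out[order(out$site, out$transect, out$species_code),
               c("site", "transect", "species_code", "count")]
    rownames(out) <- NULL
  } else {
    out <- data.frame(site = character(), transect = character(),
                      species_code = character(), count = integer(),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("vegnet_survey", "data.frame")
  out
}

#' Write a survey table to CSV
#'
#' Output is sorted by site, transect and species code, so a read/write
#' round trip of an aggregated table is byte-stable.
#'
#' @param table A survey table.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_survey <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

# Transect node ids carry the site code as a prefix (e.g. "HK1") so that
# transect and species labels can never collide in one graph.
transect_node_id <- function(site, transect) {
  ifelse(startsWith(as.character(transect), as.character(site)),
         as.character(transect),
         paste0(site, transect))
}

#' Site-level abundance matrix
#'
#' Restricts a survey table to one site and tabulates transects (rows) by
#' species (columns).  Species never observed at the site are dropped from
#' the columns; transect rows keep the site-prefixed node id.
#'
#' @param table A survey table (see [read_survey()]).
#' @param site Site id present in \code{table}.
#' @return An object of class \code{vegnet_abundance}: a list with
#'   \code{site_id}, integer matrix \code{counts} (transects x species),
#'   per-species totals \code{species_totals} and grand total \code{total}.
#' @export
to_abundance_matrix <- function(table, site) {
  sites <- unique(table$site)
  if (!site %in% sites)
    stop("unknown site '", site, "'; available sites: ",
         paste(sort(sites), collapse = ", "))
  sub <- table[table$site == site, , drop = FALSE]
  tid <- transect_node_id(sub$site, sub$transect)
  transects <- sort(unique(tid))
  species <- sort(unique(sub$species_code))
  counts <- matrix(0L, length(transects), length(species),
                   dimnames = list(transects, species))
  counts[cbind(match(tid, transects), match(sub$species_code, species))] <-
    counts[cbind(match(tid, transects), match(sub$species_code, species))] +
    as.integer(sub$count)
  keep <- colSums(counts) > 0L
  counts <- counts[, keep, drop = FALSE]
  structure(list(site_id = site, counts = counts,
                 species_totals = colSums(counts), total = sum(counts)),
            class = "vegnet_abundance")
}

#' @export
print.vegnet_abundance <- function(x, ...) {
  cat("Abundance matrix for site", x$site_id, "-",
      nrow(x$counts), "transects x", ncol(x$counts), "species,",
      x$total, "individuals\n")
  invisible(x)
}
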