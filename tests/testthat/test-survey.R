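test_that("survey parsing aggregates duplicate rows and validates codes", {
  meta <- toy_meta()
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,transect,species_code,count",
               "HK,HK1,LC,5",
               "HK,HK1,PJ,2",
               "HK,HK2,LC,1",
               "HK,HK1,LC,5"), tmp)
  tab <- read_survey(tmp, meta)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$count[tab$transect == "HK1" & tab$species_code == "LC"], 10L)
  expect_setequal(unique(tab$transect), c("HK1", "HK2"))

  # header-only file gives an empty table
  writeLines("site,transect,species_code,count", tmp)
  expect_equal(nrow(read_survey(tmp, meta)), 0L)

  # negative counts and unknown codes are rejected
  writeLines(c("site,transect,species_code,count", "HK,HK1,LC,-2"), tmp)
  expect_error(read_survey(tmp, meta), "non-negative")
  writeLines(c("site,transect,species_code,count", "HK,HK1,QQQQ,2"), tmp)
  expect_error(read_survey(tmp, meta), "unknown species")
  expect_warning(read_survey(tmp, meta, allow_unknown = TRUE), "QQQQ")
})

test_that("survey CSV round trip is lossless for aggregated records", {
  tab <- toy_survey()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_survey(tab, tmp)
  back <- read_survey(tmp, toy_meta())
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("species metadata validation enforces codes and statuses", {
  meta <- toy_meta()
  expect_silent(validate_species_metadata(meta))
  bad <- rbind(meta, data.frame(code = "LC", scientific_name = "dup",
                                status = "native"))
  expect_error(validate_species_metadata(bad), "duplicate")
  bad2 <- meta
  bad2$status[1] <- "weedy"
  expect_error(validate_species_metadata(bad2), "status")
  bad3 <- meta
  bad3$code[1] <- "lc9"
  expect_error(validate_species_metadata(bad3), "uppercase")
})

test_that("abundance matrix restricts to the site and drops absent species", {
  meta <- toy_meta()
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,transect,species_code,count",
               "HK,HK1,LC,5",
               "HK,HK1,PJ,2",
               "HK,HK2,LC,1",
               "SV,SV1,AAA,7"), tmp)
  tab <- read_survey(tmp, meta)
  am <- to_abundance_matrix(tab, "HK")
  expect_equal(dim(am$counts), c(2L, 2L))
  expect_equal(am$total, 8L)
  expect_equal(unname(am$species_totals["LC"]), 6)
  # species seen only elsewhere is not a column here
  expect_false("AAA" %in% colnames(am$counts))
  # totals identity: matrix total equals the summed input counts
  expect_equal(am$total, sum(tab$count[tab$site == "HK"]))
  # single-record site
  am2 <- to_abundance_matrix(tab, "SV")
  expect_equal(dim(am2$counts), c(1L, 1L))
  expect_equal(am2$total, 7L)
  expect_error(to_abundance_matrix(tab, "XX"), "available sites")
})

test_that("transect node ids are site-prefixed without double prefixing", {
  meta <- toy_meta()
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,transect,species_code,count",
               "HK,1,LC,2", "HK,HK2,PJ,1"), tmp)
  am <- to_abundance_matrix(read_survey(tmp, meta), "HK")
  expect_setequal(rownames(am$counts), c("HK1", "HK2"))
})

test_that("SIF write is deterministic and read/write round-trips", {
  g <- build_bipartite(to_abundance_matrix(toy_survey(), "S1"))
  tmp <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, tmp)
  lines <- readLines(tmp)
  expect_equal(lines, sort(lines))
  expect_true(all(grepl("^\\S+\toccurs_in\t\\S+$", lines)))
  g2 <- read_sif(tmp)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  ed <- function(x) {
    e <- igraph::as_data_frame(x, what = "edges")
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  expect_equal(ed(g2), ed(g))

  # single edge formats exactly as specified
  m <- structure(list(site_id = "HK",
                      counts = matrix(1L, 1, 1,
                                      dimnames = list("HK1", "LC")),
                      species_totals = c(LC = 1L), total = 1L),
                 class = "vegnet_abundance")
  write_sif(build_bipartite(m), tmp)
  expect_equal(readLines(tmp), "HK1\toccurs_in\tLC")

  # empty network writes an empty file
  m$counts[1, 1] <- 0L
  write_sif(build_bipartite(m), tmp)
  expect_equal(length(readLines(tmp)), 0L)

  writeLines(c("HK1\toccurs_in\tLC", "broken line"), tmp)
  expect_error(read_sif(tmp), "line 2")
})
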