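#!/usr/bin/env Rscript
# Community-level statistics on the simulated survey: rank abundance per
# site, analytic rarefaction curves, Bray-Curtis dissimilarity between
# sites with a UPGMA dendrogram, and the focal Pearson exclusion test.

suppressMessages(library(vegnet))

meta <- read_species_metadata("results/species.csv")
survey <- read_survey("results/survey.csv", meta)
sites <- sort(unique(survey$site))

ra <- do.call(rbind, lapply(sites, function(s)
  cbind(site = s, rank_abundance(to_abundance_matrix(survey, s), meta))))
write.csv(ra, "results/rank_abundance.csv", row.names = FALSE, quote = FALSE)
top <- ra[ra$rank == 1, c("site", "species_code", "status",
                          "relative_abundance")]
cat("most abundant species per site:\n")
print(top, row.names = FALSE)

rc <- do.call(rbind, lapply(sites, function(s) {
  am <- to_abundance_matrix(survey, s)
  sizes <- unique(round(seq(1, am$total, length.out = 30)))
  cbind(site = s, rarefaction_curve(am$species_totals, sizes))
}))
write.csv(rc, "results/rarefaction.csv", row.names = FALSE, quote = FALSE)

bc <- bray_curtis_sites(survey)
write.csv(as.matrix(bc), "results/bray_curtis.csv", quote = FALSE)
write_newick(upgma(bc), "results/dendrogram.nwk")
cat("\nBray-Curtis range across site pairs:",
    paste(round(range(bc), 3), collapse = " - "), "\n")

corr_t <- focal_correlation(survey, c("LC", "PJ"), unit = "transect")
corr_s <- focal_correlation(survey, c("LC", "PJ"), unit = "site")
cat("\nfocal abundance correlation (transect pairs): ")
print(corr_t)
cat("focal abundance correlation (site pairs): ")
print(corr_s)
jsonlite::write_json(list(transect = unclass(corr_t),
                          site = unclass(corr_s)),
                     "results/correlation.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)
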