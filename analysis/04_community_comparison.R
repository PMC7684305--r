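#!/usr/bin/env Rscript
# Step 4: congruence between the microfossil census and the metabarcoding
# assemblages.
#
# The census table is aggregated (warm-advected rare species into WARM),
# the molecular planktonic table is CSS-normalized, both are compared on
# Bray-Curtis distances by PCoA, dispersion and permutation-ANOVA tests by
# site and hydrographic zone, and a Mantel test links the two distance
# structures. Spinose taxa are removed from the census side to mirror the
# primer dropout of the molecular data.

library(sedaforam)

out_dir <- "results/community"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

otu <- read_otu_table("results/pipeline/otu_table.tsv")
census <- read_census_table("results/simulated/census.tsv")
md <- read_metadata("results/simulated/metadata.tsv")

# molecular planktonic table: replicates summed, species as columns
counts <- otu$counts
mol <- t(rowsum(t(counts), sub("\\.rep[0-9]+$", "", colnames(counts))))
pl <- otu$annotation$habitat == "planktonic"
mol_pl <- t(mol[pl, , drop = FALSE])
colnames(mol_pl) <- otu$annotation$planktonic_taxon[pl]
mol_pl <- mol_pl[rowSums(mol_pl) > 0, , drop = FALSE]

# CSS-normalize the molecular table and save it
css <- css_normalize(mol_pl)
write_tsv(data.frame(sample = rownames(css$normalized),
                     round(css$normalized, 3), check.names = FALSE),
          file.path(out_dir, "molecular_css.tsv"))
cat("CSS factors: median", median(css$factors), "range",
    paste(range(css$factors), collapse = "-"), "\n")

# census: planktonic tests only, WARM aggregation
fossil <- census$counts[, colnames(census$counts) %in%
                          colnames(mol_pl) |
                          colnames(census$counts) %in%
                          c("Globigerina_bulloides",
                            "Turborotalita_quinqueloba",
                            warm_morphospecies), drop = FALSE]
fossil_warm <- aggregate_warm(fossil)
write_tsv(data.frame(sample = rownames(fossil_warm), fossil_warm,
                     check.names = FALSE),
          file.path(out_dir, "census_warm.tsv"))

spinose <- c("Globigerina_bulloides", "Turborotalita_quinqueloba")
cong <- congruence_report(fossil, mol_pl, md, spinose_taxa = spinose,
                         n_perm = 999, seed = 20201123)

coords <- function(src) data.frame(sample = cong$samples,
                                   src[["pcoa"]]$coordinates[, 1:2])
write_tsv(coords(cong$fossil), file.path(out_dir, "pcoa_census.tsv"))
write_tsv(coords(cong$molecular), file.path(out_dir, "pcoa_molecular.tsv"))

summary_tab <- data.frame(
  source = rep(c("census", "molecular"), each = 4),
  grouping = rep(c("site", "site", "zone", "zone"), 2),
  test = rep(c("dispersion", "permanova"), 4),
  statistic = c(cong$fossil$by_site$dispersion$statistic,
                cong$fossil$by_site$permanova$statistic,
                cong$fossil$by_zone$dispersion$statistic,
                cong$fossil$by_zone$permanova$statistic,
                cong$molecular$by_site$dispersion$statistic,
                cong$molecular$by_site$permanova$statistic,
                cong$molecular$by_zone$dispersion$statistic,
                cong$molecular$by_zone$permanova$statistic),
  p_value = c(cong$fossil$by_site$dispersion$p_value,
              cong$fossil$by_site$permanova$p_value,
              cong$fossil$by_zone$dispersion$p_value,
              cong$fossil$by_zone$permanova$p_value,
              cong$molecular$by_site$dispersion$p_value,
              cong$molecular$by_site$permanova$p_value,
              cong$molecular$by_zone$dispersion$p_value,
              cong$molecular$by_zone$permanova$p_value))
write_tsv(summary_tab, file.path(out_dir, "test_summary.tsv"))
write_tsv(cong$fossil$by_zone$dispersion$pairwise,
          file.path(out_dir, "census_zone_pairwise.tsv"))
write_tsv(cong$molecular$by_zone$dispersion$pairwise,
          file.path(out_dir, "molecular_zone_pairwise.tsv"))

cat("\nZone contrasts (permanova p):",
    "census =", cong$fossil$by_zone$permanova$p_value,
    "| molecular =", cong$molecular$by_zone$permanova$p_value, "\n")
cat("Mantel correlation census vs molecular: r =",
    round(cong$mantel$statistic, 3), "p =", cong$mantel$p_value, "\n")
cat("Reports written to", out_dir, "\n")
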