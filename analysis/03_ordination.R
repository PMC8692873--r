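#!/usr/bin/env Rscript
# Bray-Curtis PCoA at phylum and class level plus single-factor
# PERMANOVA (Adonis) for the compartment and species groupings.
suppressPackageStartupMessages(library(rhizonet))
dir.create("results/ordination", showWarnings = FALSE, recursive = TRUE)

fx <- read_fixture("results/fixture")
tab <- rarefy(fx$otu, "min", seed = 1)
for (rk in c("phylum", "class")) {
  rel <- aggregate_rank(tab, rk, relative = TRUE)
  d <- bray_curtis(rel)
  pc <- pcoa(d)
  cat(sprintf("%s PCoA: axis1 %.2f%%, axis2 %.2f%%\n", rk,
              100 * pc$proportion_explained[1],
              100 * pc$proportion_explained[2]))
  write.table(data.frame(sample_id = rownames(pc$coordinates),
                         pc$coordinates[, 1:2]),
              sprintf("results/ordination/pcoa_%s.tsv", rk), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (g in c("compartment", "species")) {
    pm <- permanova(d, tab$metadata[[g]], 999, seed = 1, grouping_name = g)
    cat(sprintf("  adonis %s: R2 = %.3f, p = %.3g\n", g, pm$R2, pm$p_value))
  }
}
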