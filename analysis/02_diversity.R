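#!/usr/bin/env Rscript
# Alpha diversity after rarefaction to the minimum library size, with
# compartment (Wilcoxon) and species (Kruskal-Wallis) comparisons, and
# the core-OTU set algebra behind the usual Venn summaries.
suppressPackageStartupMessages(library(rhizonet))
dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)

fx <- read_fixture("results/fixture")
tab <- rarefy(fx$otu, "min", seed = 1)
cat("rarefied to", min(rowSums(tab$counts)), "reads per sample\n")

div <- diversity_profile(tab)
write.table(div, "results/diversity/diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (idx in c("shannon", "richness", "evenness", "coverage")) {
  r <- compare_diversity(div, idx, "compartment")
  cat(sprintf("%-9s G vs T: medians %.3f / %.3f, p = %.3g\n", idx,
              r$group_medians[1], r$group_medians[2], r$p_value))
}

core <- core_otu_sets(tab, "species")
cat("common OTUs across all four species:",
    length(core$global_intersection), "\n")
comp <- core_otu_sets(tab, "compartment")
cat("OTUs shared by both compartments:",
    length(comp$global_intersection), "\n")
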