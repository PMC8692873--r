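#!/usr/bin/env Rscript
# Bipartite OTU-environment networks per compartment and linear
# regression of Shannon diversity on each soil factor.
suppressPackageStartupMessages(library(rhizonet))
dir.create("results/environment", showWarnings = FALSE, recursive = TRUE)

fx <- read_fixture("results/fixture")
tab <- rarefy(fx$otu, "min", seed = 1)
div <- diversity_profile(tab)
for (comp in c("G", "T")) {
  sub <- filter_abundant(subset_samples(tab, tab$metadata$compartment == comp))
  bip <- suppressWarnings(bipartite_network(sub, fx$env))
  cat(comp, "factor degrees: ")
  print(sort(bip$factor_degree, decreasing = TRUE))
  write.table(bip$edges, sprintf("results/environment/env_edges_%s.tsv", comp),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dsub <- div[div$compartment == comp, ]
  regs <- do.call(rbind, lapply(c("pH", "SWC", "TOC", "TN", "TP", "AP", "AK"),
    function(f) diversity_regression(dsub, fx$env, f)))
  write.table(regs, sprintf("results/environment/regressions_%s.tsv", comp),
              sep = "\t", quote = FALSE, row.names = FALSE)
  toc <- regs[regs$factor == "TOC", ]
  tn <- regs[regs$factor == "TN", ]
  cat(sprintf("  Shannon ~ TOC: slope %.3f, R2 = %.2f, p = %.4f | Shannon ~ TN: p = %.2f\n",
              toc$slope, toc$r_squared, toc$p_value, tn$p_value))
}
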