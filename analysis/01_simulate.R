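#!/usr/bin/env Rscript
# Generate the synthetic hazelnut root/rhizosphere study (24 samples:
# 2 compartments x 4 species x 3 replicates) with planted co-occurrence
# modules, hubs, connectors and a TOC-diversity association, and write
# it as a fixture for the downstream analysis steps.
suppressPackageStartupMessages(library(rhizonet))

ds <- generate_dataset(synthetic_config(seed = 1))
write_fixture(ds, "results/fixture")

cat("samples:", nrow(ds$otu$counts), " OTUs:", ncol(ds$otu$counts), "\n")
cat("library sizes:", paste(range(rowSums(ds$otu$counts)), collapse = "-"), "\n")
cat("planted: ", length(unique(ds$truth$module_assignment)), "modules,",
    length(ds$truth$hub_otus), "hubs,",
    length(ds$truth$connector_otus), "connectors,",
    length(ds$truth$toc_responders), "TOC responders\n")
cat("fixture written to results/fixture/\n")
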