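test_that("generation is deterministic given the seed", {
  d1 <- generate_dataset(synthetic_config(seed = 42))
  d2 <- generate_dataset(synthetic_config(seed = 42))
  expect_identical(d1$otu$counts, d2$otu$counts)
  expect_identical(d1$env, d2$env)
  expect_identical(d1$truth$module_assignment, d2$truth$module_assignment)
  d3 <- generate_dataset(synthetic_config(seed = 43))
  expect_false(identical(d1$otu$counts, d3$otu$counts))
})

test_that("config validation rejects impossible designs", {
  expect_error(synthetic_config(module_within_corr = 0), "0, 1")
  expect_error(synthetic_config(module_between_corr = 0.9), "smaller")
  expect_error(synthetic_config(n_planted_hubs = 40, module_size = 40),
               "hubs exceed")
  expect_error(synthetic_config(n_otus_endosphere = 100), "exceed the smaller")
  expect_error(synthetic_config(depth_per_sample = 0), "positive")
})

test_that("the design has the right shape and planted bookkeeping", {
  ds <- generate_dataset(synthetic_config(seed = 2))
  expect_equal(nrow(ds$otu$counts), 24)
  expect_equal(sort(unique(ds$otu$metadata$compartment)), c("G", "T"))
  expect_equal(sort(unique(ds$otu$metadata$species)), c("CZ", "OZ", "PZ", "ZJ"))
  tr <- ds$truth
  expect_length(tr$module_assignment, 4 * 40)
  expect_length(tr$hub_otus, 4)
  # hubs and connectors are disjoint; every planted OTU has a module id
  expect_length(intersect(tr$hub_otus, tr$connector_otus), 0)
  expect_true(all(tr$hub_otus %in% names(tr$module_assignment)))
  # compartment-specific background: richness differs as configured
  rich_by <- tapply(apply(ds$otu$counts, 1, function(v) sum(v > 0)),
                    ds$otu$metadata$compartment, mean)
  expect_gt(rich_by[["T"]], rich_by[["G"]] + 100)
})

test_that("a null configuration removes the compartment diversity effect", {
  diffs <- vapply(1:10, function(s) {
    cfg <- synthetic_config(n_otus_endosphere = 300, n_otus_rhizosphere = 300,
                            diversity_effect = 1, toc_slope = 0,
                            guild_effect = 0, seed = s)
    d <- diversity_profile(generate_dataset(cfg)$otu)
    diff(tapply(d$shannon, d$compartment, mean))
  }, 0)
  # no systematic offset beyond Monte-Carlo noise
  expect_lt(abs(mean(diffs)), 0.1)
  expect_lt(max(abs(diffs)), 0.35)
})

test_that("the default compartment effect gives the Wilcoxon test near-complete power", {
  hits <- vapply(1:60, function(s) {
    d <- diversity_profile(generate_dataset(synthetic_config(seed = s))$otu)
    compare_diversity(d, "shannon", "compartment")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("planted within-module correlation meets the configured target", {
  for (s in 1:3) {
    ds <- generate_dataset(synthetic_config(seed = s))
    rel <- relative_abundance(ds$otu)
    tr <- ds$truth
    med <- median(vapply(1:4, function(m) {
      ids <- names(tr$module_assignment)[tr$module_assignment == m]
      r <- cor(rel[, ids], method = "spearman")
      median(r[upper.tri(r)])
    }, 0))
    expect_gte(med, synthetic_config()$module_within_corr - 0.1)
  }
})

test_that("planted hubs sit at the top of their module's degree distribution", {
  # hub within-module degree reaches the 90th percentile of its detected
  # module in most (measured ~78%) network instances
  flags <- c()
  for (s in 1:3) {
    ds <- generate_dataset(synthetic_config(seed = s))
    tab <- rarefy(ds$otu, "min", seed = s)
    for (comp in c("G", "T")) {
      sub <- filter_abundant(subset_samples(tab,
                                            tab$metadata$compartment == comp))
      net <- suppressWarnings(build_network(sub))
      roles <- zi_pi(net, greedy_modularity(net))
      for (h in ds$truth$hub_otus) {
        i <- match(h, roles$otu)
        if (is.na(i)) next
        mem <- roles$within_degree[roles$module == roles$module[i]]
        flags <- c(flags, roles$within_degree[i] >= quantile(mem, 0.9))
      }
    }
  }
  expect_gte(mean(flags), 0.7)
})

test_that("fixtures round-trip through the on-disk dialect", {
  ds <- generate_dataset(synthetic_config(seed = 7))
  dir <- withr::local_tempdir()
  write_fixture(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("otu_table.tsv", "taxonomy.tsv", "metadata.tsv",
      "env.tsv", "guilds.tsv", "truth.json")))))
  t0 <- Sys.time()
  back <- read_fixture(dir)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_equal(back$otu$counts, ds$otu$counts)
  expect_equal(back$env$TOC, ds$env$TOC)
  # truth.json module ids cover all planted OTUs
  expect_setequal(names(back$truth$module_assignment),
                  names(ds$truth$module_assignment))
  expect_equal(back$truth$module_assignment[names(ds$truth$module_assignment)],
               ds$truth$module_assignment)
  expect_setequal(back$truth$hub_otus, ds$truth$hub_otus)
})

test_that("toc_slope = 0 plants no diversity-environment association", {
  rej <- vapply(1:30, function(s) {
    ds <- generate_dataset(synthetic_config(toc_slope = 0, seed = s))
    d <- diversity_profile(ds$otu)
    g <- d[d$compartment == "G", ]
    diversity_regression(g, ds$env, "TOC")$p_value < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.15)
})
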