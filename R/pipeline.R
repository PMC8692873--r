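#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the package
#' defaults: rarefaction to the minimum library size, the >0.005%
#' abundance rule, Spearman edges at |rho| >= 0.8 with unadjusted p < 0.05, Zi/Pi role thresholds 2.5 and 0.62, 999 PERMANOVA
#' permutations, BH correction for per-taxon tests.
#'
#' @param rarefy_depth "min" or an integer read depth.
#' @param abundance_threshold proportion for [filter_abundant()].
#' @param corr_method,min_abs_corr,alpha,p_adjust edge thresholds for
#'   both network stages.
#' @param zi_threshold,pi_threshold role thresholds.
#' @param n_permutations PERMANOVA permutations.
#' @param fdr_method correction for per-taxon difference tests.
#' @param top_n_taxa taxa per rank entering the per-taxon tests,
#'   selected by mean relative abundance.
#' @param rarefy_before_networks apply the rarefied table to network
#'   construction as well as diversity (default TRUE)?
#' @param seed master seed for rarefaction and permutation streams.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(rarefy_depth = "min",
                            abundance_threshold = 5e-5,
                            corr_method = "spearman",
                            min_abs_corr = 0.8,
                            alpha = 0.05,
                            p_adjust = "none",
                            zi_threshold = 2.5,
                            pi_threshold = 0.62,
                            n_permutations = 999,
                            fdr_method = "BH",
                            top_n_taxa = 15,
                            rarefy_before_networks = TRUE,
                            seed = 1) {
  cfg <- as.list(environment())
  if (zi_threshold <= 0 || pi_threshold <= 0) stop("role thresholds must be positive")
  if (abundance_threshold < 0) stop("abundance_threshold must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Per-taxon compartment difference tests at a taxonomic rank
#'
#' Selects the `top_n` taxa by mean relative abundance across all
#' samples, runs a two-sided Wilcoxon rank-sum test per taxon between
#' the two compartments, and adjusts the p-values across those taxa
#' (BH by default).
#'
#' @param table an [otu_table()].
#' @param rank taxonomic rank.
#' @param grouping metadata column with exactly two levels.
#' @param top_n number of taxa tested.
#' @param fdr_method passed to [stats::p.adjust()].
#' @return data.frame: taxon, mean abundances per group, statistic,
#'   p, p_adjusted.
#' @export
taxon_difference_tests <- function(table, rank = "phylum",
                                   grouping = "compartment", top_n = 15,
                                   fdr_method = "BH") {
  rel <- aggregate_rank(table, rank, relative = TRUE)
  keep <- order(colMeans(rel), decreasing = TRUE)[seq_len(min(top_n, ncol(rel)))]
  rel <- rel[, keep, drop = FALSE]
  g <- table$metadata[[grouping]]
  lv <- sort(unique(g))
  if (length(lv) != 2) stop("taxon_difference_tests expects 2 groups")
  rows <- lapply(colnames(rel), function(tx) {
    res <- wilcoxon_rank_sum(rel[g == lv[1], tx], rel[g == lv[2], tx])
    data.frame(taxon = tx,
               mean_1 = mean(rel[g == lv[1], tx]),
               mean_2 = mean(rel[g == lv[2], tx]),
               statistic = res$statistic, p = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", lv)
  out$p_adjusted <- stats::p.adjust(out$p, method = fdr_method)
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in order: rarefaction; alpha diversity and its group tests;
#' rank aggregation with per-taxon difference tests; Bray-Curtis PCoA
#' and single-factor PERMANOVA (compartment and species, at phylum and
#' class level); guild annotation and guild comparisons; per-compartment
#' abundance filtering, co-occurrence network construction, greedy
#' modularity, Zi-Pi role classification and shared keystones; bipartite
#' OTU-environment networks and Shannon-factor regressions per
#' compartment.  All tables are written under `outdir` together with a
#' `run.log` and a `summary.json`; the whole run is deterministic given
#' the config seed.
#'
#' @param dataset a `synthetic_dataset`, or a list with elements `otu`,
#'   `env`, `guilds` (e.g. from [read_fixture()]).
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  cat("rhizonet pipeline\n", file = logf)
  logline <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(n_samples = nrow(dataset$otu$counts),
                  n_otus = ncol(dataset$otu$counts))

  tab <- stage("rarefy", {
    r <- rarefy(dataset$otu, config$rarefy_depth, seed = config$seed)
    logline("rarefy: depth=", min(rowSums(r$counts)), " seed=", config$seed)
    r
  })
  summary$rarefaction_depth <- unname(min(rowSums(tab$counts)))

  div <- stage("diversity", {
    d <- diversity_profile(tab)
    utils::write.table(d, file.path(outdir, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    d
  })
  div_tests <- stage("diversity_tests", {
    idx <- c("shannon", "richness", "evenness", "coverage")
    rows <- lapply(idx, function(i) {
      r <- compare_diversity(div, i, "compartment")
      data.frame(index = i, grouping = "compartment", test = r$test_name,
                 statistic = r$statistic, p = r$p_value)
    })
    rows2 <- lapply(idx, function(i) {
      r <- compare_diversity(div, i, "species")
      data.frame(index = i, grouping = "species", test = r$test_name,
                 statistic = r$statistic, p = r$p_value)
    })
    t <- rbind(do.call(rbind, rows), do.call(rbind, rows2))
    utils::write.table(t, file.path(outdir, "diversity_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    t
  })
  summary$shannon_mean <- vapply(split(div$shannon, div$compartment), mean, 0)
  summary$shannon_p_compartment <-
    div_tests$p[div_tests$index == "shannon" &
                div_tests$grouping == "compartment"]
  logline("diversity: shannon G/T means ",
          paste(round(summary$shannon_mean, 3), collapse = "/"))

  taxon_tests <- stage("taxon_tests", {
    tt <- lapply(c("phylum", "class"), function(rk)
      cbind(rank = rk,
            taxon_difference_tests(tab, rk, "compartment",
                                   config$top_n_taxa, config$fdr_method)))
    tt <- do.call(rbind, tt)
    utils::write.table(tt, file.path(outdir, "taxon_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tt
  })

  ord <- stage("ordination", {
    res <- list()
    for (rk in c("phylum", "class")) {
      rel <- aggregate_rank(tab, rk, relative = TRUE)
      d <- bray_curtis(rel)
      pc <- pcoa(d)
      utils::write.table(
        data.frame(sample_id = rownames(pc$coordinates),
                   pc$coordinates[, 1:min(2, ncol(pc$coordinates)), drop = FALSE]),
        file.path(outdir, paste0("pcoa_", rk, ".tsv")), sep = "\t",
        quote = FALSE, row.names = FALSE)
      res[[rk]] <- list(
        pcoa = pc,
        permanova_compartment = permanova(d, tab$metadata$compartment,
                                          config$n_permutations,
                                          seed = config$seed,
                                          grouping_name = "compartment"),
        permanova_species = permanova(d, tab$metadata$species,
                                      config$n_permutations,
                                      seed = config$seed,
                                      grouping_name = "species"))
    }
    pm <- do.call(rbind, lapply(names(res), function(rk) {
      do.call(rbind, lapply(c("permanova_compartment", "permanova_species"),
        function(k) {
          x <- res[[rk]][[k]]
          data.frame(rank = rk, grouping = x$grouping_name, pseudo_F = x$pseudo_F,
                     R2 = x$R2, p = x$p_value, permutations = x$n_permutations)
        }))
    }))
    utils::write.table(pm, file.path(outdir, "permanova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })
  summary$pcoa_axis_pct <- lapply(ord, function(x)
    round(100 * x$pcoa$proportion_explained[1:2], 2))
  summary$permanova_R2 <- lapply(ord, function(x)
    c(compartment = x$permanova_compartment$R2,
      species = x$permanova_species$R2))
  logline("ordination: phylum axis1 ",
          summary$pcoa_axis_pct$phylum[1], "%")

  guilds <- stage("guilds", {
    prof <- assign_guilds(tab, dataset$guilds)
    utils::write.table(prof$assignments, file.path(outdir, "guild_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(prof$mode_abundance),
                 prof$mode_abundance, unassigned = prof$unassigned_mass,
                 check.names = FALSE),
      file.path(outdir, "guild_profile.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    cmp <- suppressMessages(
      compare_guilds(prof, tab$metadata, "compartment"))
    utils::write.table(cmp, file.path(outdir, "guild_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(profile = prof, tests = cmp)
  })
  summary$guild_status_counts <-
    as.list(table(guilds$profile$assignments$status))

  nets <- stage("networks", {
    net_tab <- if (config$rarefy_before_networks) tab else dataset$otu
    out <- list()
    for (comp in sort(unique(net_tab$metadata$compartment))) {
      sub <- subset_samples(net_tab, net_tab$metadata$compartment == comp)
      sub <- filter_abundant(sub, config$abundance_threshold)
      net <- suppressWarnings(
        build_network(sub, config$corr_method, config$min_abs_corr,
                      config$alpha, config$p_adjust))
      part <- greedy_modularity(net)
      roles <- classify_roles(zi_pi(net, part),
                              config$zi_threshold, config$pi_threshold)
      topo <- topology(net, part)
      write_network(net, roles, topo, outdir, paste0("network_", comp))
      logline("network ", comp, ": ", topo$n_nodes, " nodes, ",
              topo$n_edges, " edges, Q=", round(topo$modularity, 4))
      out[[comp]] <- list(net = net, partition = part, roles = roles,
                          topology = topo)
    }
    out
  })
  summary$networks <- lapply(nets, function(x) {
    tp <- x$topology
    list(n_nodes = tp$n_nodes, n_edges = tp$n_edges,
         positive_negative_ratio = round(tp$positive_negative_ratio, 4),
         average_degree = round(tp$average_degree, 4),
         average_clustering_coefficient =
           round(tp$average_clustering_coefficient, 4),
         modularity = round(tp$modularity, 6),
         n_modules = tp$n_modules,
         average_path_length = round(tp$average_path_length, 4),
         density = round(tp$density, 6),
         n_module_hubs = sum(x$roles$role == "module_hub"),
         n_connectors = sum(x$roles$role == "connector"),
         n_network_hubs = sum(x$roles$role == "network_hub"),
         n_keystones = length(attr(x$roles, "keystones")))
  })

  shared <- stage("shared_keystones", {
    if (length(nets) >= 2) {
      sk <- shared_keystones(lapply(nets, `[[`, "roles"))
      jsonlite::write_json(sk, file.path(outdir, "shared_keystones.json"),
                           auto_unbox = FALSE)
      sk
    } else NULL
  })
  if (!is.null(shared))
    summary$shared_keystones <- vapply(shared, length, 0L)

  envres <- stage("environment", {
    edges_all <- list(); degs <- list(); regs <- list()
    for (comp in names(nets)) {
      sub <- subset_samples(tab, tab$metadata$compartment == comp)
      sub <- filter_abundant(sub, config$abundance_threshold)
      bip <- suppressWarnings(
        bipartite_network(sub, dataset$env,
                          corr_method = config$corr_method,
                          min_abs_corr = config$min_abs_corr,
                          alpha = config$alpha, p_adjust = config$p_adjust))
      edges_all[[comp]] <- cbind(compartment = comp, bip$edges)
      degs[[comp]] <- bip$factor_degree
      dsub <- div[div$compartment == comp, ]
      regs[[comp]] <- do.call(rbind, lapply(ENV_FACTORS, function(f)
        cbind(compartment = comp,
              diversity_regression(dsub, dataset$env, f))))
      logline("env ", comp, ": top factor ",
              names(which.max(bip$factor_degree)))
    }
    ed <- do.call(rbind, edges_all)
    utils::write.table(ed, file.path(outdir, "env_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rg <- do.call(rbind, regs)
    utils::write.table(rg, file.path(outdir, "regressions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(factor_degree = degs, regressions = rg)
  })
  summary$env_factor_degree <- lapply(envres$factor_degree, as.list)
  summary$toc_regression <- lapply(names(envres$factor_degree), function(comp) {
    r <- envres$regressions
    r <- r[r$compartment == comp & r$factor == "TOC", ]
    list(slope = round(r$slope, 6), r_squared = round(r$r_squared, 6),
         p = round(r$p_value, 6))
  })
  names(summary$toc_regression) <- names(envres$factor_degree)

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  logline("done")
  invisible(summary)
}
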