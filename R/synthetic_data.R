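#' Configuration for the synthetic community generator
#'
#' Defines the 2-compartment x 4-species x 3-replicate study design and
#' the planted structure: correlated OTU modules with designated hub and
#' connector nodes, a compartment evenness effect, a symbiotroph
#' enrichment in root endospheres, and a TOC-diversity association.
#'
#' @param n_species_groups number of host species groups (default 4:
#'   PZ, CZ, OZ, ZJ).
#' @param n_replicates replicates per species x compartment (default 3).
#' @param compartments compartment labels; "G" = root endosphere,
#'   "T" = rhizosphere soil.
#' @param n_otus_endosphere,n_otus_rhizosphere total OTUs present in
#'   each compartment (planted OTUs included in both).
#' @param depth_per_sample nominal sequencing depth; realised library
#'   sizes vary uniformly within +/-15% so that rarefaction has work to do.
#' @param diversity_effect multiplicative evenness boost for rhizosphere
#'   samples (their lognormal rank-abundance spread is divided by it).
#' @param n_planted_modules number of planted co-occurrence modules.
#' @param module_size OTUs per module (hubs included).
#' @param module_within_corr target within-module correlation of latent
#'   log-abundances, in (0, 1].
#' @param module_between_corr target correlation between members of
#'   different modules (default 0).
#' @param n_planted_hubs hubs per module: members tied to the module
#'   factor almost noiselessly, so they correlate with every member.
#' @param n_planted_connectors OTUs each loading equally on three
#'   module factors, so their edges spread across modules.
#' @param n_toc_responders abundant OTUs whose log-abundance follows the
#'   soil-carbon latent variable negatively; they carry both the
#'   TOC-diversity association and the top bipartite degree of TOC.
#' @param responder_effect log-scale loading of responders on the
#'   soil-carbon latent.
#' @param toc_slope planted slope of Shannon (nats) on TOC (g/kg);
#'   0 plants no association.
#' @param toc_noise_frac sd of the TOC measurement noise as a fraction
#'   of the TOC signal sd.
#' @param noise_sd lognormal noise sd of ordinary OTUs.
#' @param base_sd lognormal rank-abundance spread (endosphere).
#' @param guild_effect log-scale boost of symbiotroph OTUs in
#'   endosphere samples.
#' @param seed integer seed; the full dataset is deterministic given it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species_groups = 4,
                             n_replicates = 3,
                             compartments = c("G", "T"),
                             n_otus_endosphere = 200,
                             n_otus_rhizosphere = 500,
                             depth_per_sample = 30000,
                             diversity_effect = 1.5,
                             n_planted_modules = 4,
                             module_size = 40,
                             module_within_corr = 0.8,
                             module_between_corr = 0,
                             n_planted_hubs = 1,
                             n_planted_connectors = 2,
                             n_toc_responders = 12,
                             responder_effect = 1.2,
                             toc_slope = 0.05,
                             toc_noise_frac = 0.15,
                             noise_sd = 0.5,
                             base_sd = 1.2,
                             guild_effect = 1.2,
                             seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_species_groups", "n_replicates", "n_otus_endosphere",
              "n_otus_rhizosphere", "n_planted_modules", "module_size")
  for (f in counts) if (cfg[[f]] < 1) stop(f, " must be >= 1")
  if (depth_per_sample <= 0) stop("depth_per_sample must be positive")
  if (!(module_within_corr > 0 && module_within_corr <= 1))
    stop("module_within_corr must lie in (0, 1]")
  if (module_between_corr >= module_within_corr)
    stop("module_between_corr must be smaller than module_within_corr")
  if (n_planted_hubs >= module_size)
    stop("planted hubs exceed module size")
  if (n_planted_modules < 3 && n_planted_connectors > 0)
    stop("connectors need >= 3 planted modules to span")
  n_planted <- n_planted_modules * module_size + n_planted_connectors +
    n_toc_responders
  if (n_planted > min(n_otus_endosphere, n_otus_rhizosphere))
    stop("planted OTUs (", n_planted, ") exceed the smaller compartment pool")
  if (diversity_effect <= 0 || noise_sd <= 0 || base_sd <= 0)
    stop("diversity_effect, noise_sd and base_sd must be positive")
  structure(cfg, class = "synthetic_config")
}

# fixed dummy lineage pool: genus, family, order, class, phylum.
# Trichoderma is deliberately absent from the guild reference, and the
# family-only / kingdom-only entries exercise the lineage parser.
synthetic_lineage_pool <- function() {
  g <- rbind(
    c("Tuber",        "Tuberaceae",          "Pezizales",         "Pezizomycetes",    "Ascomycota"),
    c("Inocybe",      "Inocybaceae",         "Agaricales",        "Agaricomycetes",   "Basidiomycota"),
    c("Sebacina",     "Sebacinaceae",        "Sebacinales",       "Agaricomycetes",   "Basidiomycota"),
    c("Russula",      "Russulaceae",         "Russulales",        "Agaricomycetes",   "Basidiomycota"),
    c("Fusarium",     "Nectriaceae",         "Hypocreales",       "Sordariomycetes",  "Ascomycota"),
    c("Trichoderma",  "Hypocreaceae",        "Hypocreales",       "Sordariomycetes",  "Ascomycota"),
    c("Chloridium",   "Chaetosphaeriaceae",  "Chaetosphaeriales", "Sordariomycetes",  "Ascomycota"),
    c("Acaulium",     "Microascaceae",       "Microascales",      "Sordariomycetes",  "Ascomycota"),
    c("Mortierella",  "Mortierellaceae",     "Mortierellales",    "Mortierellomycetes", "Mortierellomycota"),
    c("Alternaria",   "Pleosporaceae",       "Pleosporales",      "Dothideomycetes",  "Ascomycota"),
    c("Cladosporium", "Cladosporiaceae",     "Capnodiales",       "Dothideomycetes",  "Ascomycota"),
    c("Penicillium",  "Aspergillaceae",      "Eurotiales",        "Eurotiomycetes",   "Ascomycota"),
    c("Saitozyma",    "Trimorphomycetaceae", "Tremellales",       "Tremellomycetes",  "Basidiomycota"))
  colnames(g) <- c("genus", "family", "order", "class", "phylum")
  as.data.frame(g, stringsAsFactors = FALSE)
}

synthetic_guild_reference <- function() {
  ref <- rbind(
    c("Tuber",           "genus",  "Symbiotroph", "Ectomycorrhizal",                "Highly Probable"),
    c("Inocybe",         "genus",  "Symbiotroph", "Ectomycorrhizal",                "Highly Probable"),
    c("Sebacina",        "genus",  "Symbiotroph", "Ectomycorrhizal",                "Probable"),
    c("Russula",         "genus",  "Symbiotroph", "Ectomycorrhizal",                "Highly Probable"),
    c("Fusarium",        "genus",  "Pathotroph",  "Plant Pathogen",                 "Probable"),
    c("Chloridium",      "genus",  "Saprotroph",  "Undefined Saprotroph",           "Probable"),
    c("Acaulium",        "genus",  "Saprotroph",  "Undefined Saprotroph",           "Probable"),
    c("Mortierella",     "genus",  "Saprotroph",  "Undefined Saprotroph",           "Highly Probable"),
    c("Alternaria",      "genus",  "Pathotroph-Saprotroph", "Plant Pathogen|Wood Saprotroph", "Possible"),
    c("Cladosporium",    "genus",  "Saprotroph",  "Undefined Saprotroph",           "Possible"),
    c("Penicillium",     "genus",  "Saprotroph",  "Undefined Saprotroph",           "Possible"),
    c("Saitozyma",       "genus",  "Saprotroph",  "Undefined Saprotroph",           "Probable"),
    c("Melanommataceae", "family", "Saprotroph",  "Undefined Saprotroph",           "Possible"))
  ref <- as.data.frame(ref, stringsAsFactors = FALSE)
  names(ref) <- c("taxon", "level", "trophic_mode", "guild", "confidence")
  validate_guild_reference(ref)
}

#' Generate a synthetic paired root/rhizosphere fungal dataset
#'
#' Draws a full study dataset with known ground truth.  The latent model
#' works on log relative abundances: every sample gets one standard
#' normal factor per planted module; module members load on their factor
#' with a loading chosen so that the latent within-module correlation
#' equals `module_within_corr`; hubs follow the factor almost
#' noiselessly; connectors load equally on three module factors.  Counts
#' are multinomial draws at the sample's library size.  Rhizosphere
#' samples have a flatter rank-abundance curve (spread divided by
#' `diversity_effect`) and more OTUs, so both Shannon and richness
#' separate the compartments.  A soil-carbon latent variable suppresses
#' the abundant "responder" OTUs, which raises evenness, and TOC is
#' derived from realised Shannon so that within each compartment
#' Shannon ~ intercept + toc_slope * TOC + noise; TN and the remaining
#' factors carry no planted association.  Symbiotroph (ectomycorrhizal)
#' OTUs are boosted in endosphere samples.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset`: `otu` ([otu_table()]),
#'   `env` (per-sample soil chemistry), `guilds` (guild reference), and
#'   `truth` (module assignment, hub/connector/responder ids, expected
#'   per-sample Shannon, planted environmental slopes).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)

  species_pool <- c("PZ", "CZ", "OZ", "ZJ",
                    paste0("SP", seq_len(max(0, cfg$n_species_groups - 4)) + 4))
  species <- species_pool[seq_len(cfg$n_species_groups)]
  meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      species = species, compartment = cfg$compartments,
                      stringsAsFactors = FALSE)[, 3:1]
  meta$sample_id <- with(meta, paste(compartment, species, replicate, sep = "_"))
  n_samples <- nrow(meta)

  M <- cfg$n_planted_modules
  n_mod_otus <- M * cfg$module_size
  n_conn <- cfg$n_planted_connectors
  n_resp <- cfg$n_toc_responders
  n_bg_G <- cfg$n_otus_endosphere - n_mod_otus - n_conn - n_resp
  n_bg_T <- cfg$n_otus_rhizosphere - n_mod_otus - n_conn - n_resp
  n_otus <- n_mod_otus + n_conn + n_resp + n_bg_G + n_bg_T
  otu_ids <- sprintf("OTU%04d", seq_len(n_otus))

  idx_mod <- seq_len(n_mod_otus)
  module_of <- rep(seq_len(M), each = cfg$module_size)
  hub_mask <- logical(n_mod_otus)
  for (mm in seq_len(M))
    hub_mask[which(module_of == mm)[seq_len(cfg$n_planted_hubs)]] <- TRUE
  idx_conn <- n_mod_otus + seq_len(n_conn)
  idx_resp <- n_mod_otus + n_conn + seq_len(n_resp)
  idx_bg_G <- n_mod_otus + n_conn + n_resp + seq_len(n_bg_G)
  idx_bg_T <- n_mod_otus + n_conn + n_resp + n_bg_G + seq_len(n_bg_T)

  # connector j spans three consecutive modules (wrapping)
  conn_modules <- lapply(seq_len(n_conn), function(j)
    ((j - 1 + 0:2) %% M) + 1)

  # taxonomy: genus drawn from the fixed pool; a slice of OTUs is left
  # partly unresolved to exercise the parser and the guild fallback
  pool <- synthetic_lineage_pool()
  gi <- sample(nrow(pool), n_otus, replace = TRUE)
  lineage <- sprintf("k__Fungi;p__%s;c__%s;o__%s;f__%s;g__%s",
                     pool$phylum[gi], pool$class[gi], pool$order[gi],
                     pool$family[gi], pool$genus[gi])
  part_unres <- seq(5, n_otus, by = 23)   # family-level only (Melanommataceae)
  lineage[part_unres] <- "k__Fungi;p__Ascomycota;c__Dothideomycetes;o__Pleosporales;f__Melanommataceae"
  full_unres <- seq(11, n_otus, by = 29)  # kingdom only
  lineage[full_unres] <- "k__Fungi"
  taxonomy <- data.frame(otu_id = otu_ids, lineage = lineage,
                         stringsAsFactors = FALSE)
  taxonomy <- cbind(taxonomy, parse_lineage(taxonomy$lineage))
  symbiotroph <- taxonomy$genus %in% c("Tuber", "Inocybe", "Sebacina", "Russula")

  # per-OTU base abundance (lognormal rank-abundance); one draw, scaled
  # per compartment so identity is coherent across compartments
  zbase <- stats::rnorm(n_otus)
  base_sd_c <- c(G = cfg$base_sd, T = cfg$base_sd / cfg$diversity_effect)

  # The within-module correlation target is met jointly by two
  # components: a sample-level module factor (within-compartment
  # correlation) and a module compartment affinity (a mean shift between
  # compartments, shared by all members, which raises the correlation
  # measured across the full 24-sample design without touching the
  # within-compartment correlation structure).  The 0.10 split and the
  # 0.03 offset (compositional-closure / counting-noise compensation)
  # are one-time calibration constants at the default design; the
  # Spearman target is converted to the Pearson scale of the latent
  # Gaussians via 2 sin(pi rho / 6).
  # Within-module correlation is realised by two components: the
  # within-compartment latent factor (share w + 0.10, compensating the
  # attenuation that compositional closure, counting noise and the
  # rank-scale conversion impose on the observed Spearman correlation)
  # and a fixed module compartment affinity (a +/-0.5 log-unit habitat
  # preference shared by all members, which contributes to the
  # correlation measured across the full two-compartment design without
  # altering within-compartment structure).  Both constants were frozen
  # after a one-time calibration at the default design.
  w <- cfg$module_within_corr
  w_in <- max(0.3, min(0.95, w + 0.10))
  lambda <- cfg$noise_sd * sqrt(w_in / (1 - w_in))
  affinity <- 1.0
  favored <- rep(cfg$compartments, length.out = M)   # alternate module habitat
  b <- cfg$module_between_corr / w   # factor-level correlation shared across modules
  member_base_shift <- -1.3   # keeps module mass shares small (limits closure)
  hub_base_boost <- 0.8       # hubs are abundant members of their module
  responder_base <- 1.6       # responders sit near the top of the rank curve
  responder_noise <- 0.12     # responders track the carbon latent tightly

  # latent variables per sample.  The module factors and the soil-carbon
  # latent are orthogonalised within each compartment block: with only
  # 12 samples per compartment, iid draws would leave chance in-sample
  # collinearity (sd ~ 0.3) between factors, which shows up as spurious
  # between-module correlation and occasionally fuses two planted
  # modules; the planted effects are designed independent, so the
  # generator realises them as an orthogonal design.
  g0 <- stats::rnorm(n_samples)                       # shared factor (between-corr)
  lat <- matrix(stats::rnorm(n_samples * (M + 1)), n_samples, M + 1)
  for (comp in unique(meta$compartment)) {
    i <- which(meta$compartment == comp)
    if (length(i) > M + 1) {
      X <- scale(lat[i, , drop = FALSE], center = TRUE, scale = FALSE)
      Q <- qr.Q(qr(X))
      lat[i, ] <- scale(Q) * sign(colSums(Q * X))[col(Q)]
    }
  }
  gmat <- lat[, seq_len(M), drop = FALSE]
  if (b > 0) gmat <- sqrt(1 - b) * gmat + sqrt(b) * g0
  tcarbon <- lat[, M + 1]                             # soil-carbon latent

  depth <- round(cfg$depth_per_sample * stats::runif(n_samples, 0.85, 1.15))

  counts <- matrix(0, n_samples, n_otus,
                   dimnames = list(meta$sample_id, otu_ids))
  expected_shannon <- numeric(n_samples)
  carbon_shannon <- numeric(n_samples)  # Shannon predicted from the carbon latent alone
  for (s in seq_len(n_samples)) {
    comp <- meta$compartment[s]
    base <- zbase * base_sd_c[[comp]]
    base[idx_mod] <- base[idx_mod] + member_base_shift +
      ifelse(favored[module_of] == comp, affinity / 2, -affinity / 2)
    base[idx_mod[hub_mask]] <- base[idx_mod[hub_mask]] + hub_base_boost
    base[idx_resp] <- base[idx_resp] + responder_base
    if (comp == "G") base[symbiotroph] <- base[symbiotroph] + cfg$guild_effect
    present <- rep(TRUE, n_otus)
    present[if (comp == "G") idx_bg_T else idx_bg_G] <- FALSE

    eps <- stats::rnorm(n_otus)
    logx <- base
    # planted modules (hubs follow their factor almost noiselessly)
    memb <- idx_mod[!hub_mask]
    logx[memb] <- logx[memb] + lambda * gmat[s, module_of[!hub_mask]] +
      cfg$noise_sd * eps[memb]
    hubs <- idx_mod[hub_mask]
    logx[hubs] <- logx[hubs] + lambda * gmat[s, module_of[hub_mask]] +
      0.05 * eps[hubs]
    # connectors: equal loading on three module factors
    for (j in seq_len(n_conn)) {
      i <- idx_conn[j]
      logx[i] <- logx[i] + lambda / sqrt(3) * sum(gmat[s, conn_modules[[j]]]) +
        0.05 * eps[i]
    }
    # responders: abundant, suppressed by the soil-carbon latent
    logx[idx_resp] <- logx[idx_resp] - cfg$responder_effect * tcarbon[s] +
      responder_noise * eps[idx_resp]
    # background
    logx[c(idx_bg_G, idx_bg_T)] <- logx[c(idx_bg_G, idx_bg_T)] +
      cfg$noise_sd * eps[c(idx_bg_G, idx_bg_T)]

    p <- exp(logx) * present
    p <- p / sum(p)
    expected_shannon[s] <- -sum(p[p > 0] * log(p[p > 0]))
    counts[s, ] <- stats::rmultinom(1, depth[s], p)

    # carbon-only composition: module factors and noise at their mean
    logc <- base
    logc[idx_resp] <- logc[idx_resp] - cfg$responder_effect * tcarbon[s]
    q <- exp(logc) * present
    q <- q / sum(q)
    carbon_shannon[s] <- -sum(q[q > 0] * log(q[q > 0]))
  }

  # environment: TOC tracks realised (expected) Shannon within compartment
  env <- data.frame(sample_id = meta$sample_id,
                    pH  = round(stats::rnorm(n_samples, 6.2, 0.3), 2),
                    SWC = round(stats::rnorm(n_samples, 25, 4), 2),
                    TOC = NA_real_,
                    TN  = round(stats::rnorm(n_samples, 1.5, 0.15), 3),
                    TP  = round(stats::rnorm(n_samples, 0.8, 0.1), 3),
                    AP  = round(stats::rnorm(n_samples, 15, 3), 2),
                    AK  = round(stats::rnorm(n_samples, 120, 20), 1),
                    stringsAsFactors = FALSE)
  if (cfg$toc_slope != 0) {
    # TOC follows the carbon-predicted Shannon component, centred per
    # compartment, so that within each compartment
    # Shannon ~ intercept + toc_slope * TOC (+ noise)
    env$TOC <- 20
    for (comp in unique(meta$compartment)) {
      i <- meta$compartment == comp
      signal <- (carbon_shannon[i] - mean(carbon_shannon[i])) / cfg$toc_slope
      env$TOC[i] <- 20 + signal +
        stats::rnorm(sum(i), 0, cfg$toc_noise_frac * stats::sd(signal))
    }
  } else {
    env$TOC <- stats::rnorm(n_samples, 20, 3)
  }
  env$TOC <- round(env$TOC, 3)
  rownames(env) <- env$sample_id

  truth <- structure(list(
    module_assignment = stats::setNames(module_of, otu_ids[idx_mod]),
    hub_otus = otu_ids[idx_mod][hub_mask],
    connector_otus = otu_ids[idx_conn],
    connector_modules = stats::setNames(conn_modules, otu_ids[idx_conn]),
    toc_responders = otu_ids[idx_resp],
    symbiotroph_otus = otu_ids[symbiotroph],
    true_shannon = stats::setNames(expected_shannon, meta$sample_id),
    env_effect = c(TOC = cfg$toc_slope, TN = 0)),
    class = "ground_truth")

  structure(list(otu = otu_table(counts, meta, taxonomy),
                 env = env,
                 guilds = synthetic_guild_reference(),
                 truth = truth,
                 config = cfg),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to a fixture directory
#'
#' Emits `otu_table.tsv`, `taxonomy.tsv`, `metadata.tsv`, `env.tsv`,
#' `guilds.tsv` and `truth.json` in the package's on-disk dialects.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(dataset$otu, dir)
  utils::write.table(dataset$env, file.path(dir, "env.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$guilds, file.path(dir, "guilds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- dataset$truth
  jsonlite::write_json(
    list(module_assignment = as.list(tr$module_assignment),
         hub_otus = tr$hub_otus,
         connector_otus = tr$connector_otus,
         toc_responders = tr$toc_responders,
         symbiotroph_otus = tr$symbiotroph_otus,
         true_shannon = as.list(round(tr$true_shannon, 6)),
         env_effect = as.list(tr$env_effect)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#' @param dir fixture directory.
#' @return list with `otu`, `env`, `guilds`, `truth`.
#' @export
read_fixture <- function(dir) {
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  tr$module_assignment <- unlist(tr$module_assignment)
  tr$true_shannon <- unlist(tr$true_shannon)
  tr$env_effect <- unlist(tr$env_effect)
  class(tr) <- "ground_truth"
  list(otu = read_otu_table(file.path(dir, "otu_table.tsv"),
                            file.path(dir, "taxonomy.tsv"),
                            file.path(dir, "metadata.tsv")),
       env = read_env_table(file.path(dir, "env.tsv")),
       guilds = read_guild_reference(file.path(dir, "guilds.tsv")),
       truth = tr)
}

#' Score module and keystone recovery against the planted truth
#'
#' Compares a detected partition and classified roles with the ground
#' truth of the generating configuration: adjusted Rand index over the
#' planted module OTUs that made it into the network, the fraction of
#' planted hubs present that are classified module or network hubs, and
#' the fraction of planted connectors present classified connector.
#'
#' @param roles classified role table ([classify_roles()]) whose
#'   partition is in column `module`.
#' @param truth a `ground_truth`.
#' @return list: `ari`, `hub_recovery`, `connector_recovery`, `n_planted_in_net`.
#' @export
recovery_metrics <- function(roles, truth) {
  planted <- names(truth$module_assignment)
  present <- intersect(planted, roles$otu)
  ari <- if (length(present) < 2) NA_real_ else
    adjusted_rand_index(truth$module_assignment[present],
                        roles$module[match(present, roles$otu)])
  hubs_in <- intersect(truth$hub_otus, roles$otu)
  hub_rec <- if (!length(hubs_in)) NA_real_ else
    mean(roles$role[match(hubs_in, roles$otu)] %in% c("module_hub", "network_hub"))
  conn_in <- intersect(truth$connector_otus, roles$otu)
  conn_rec <- if (!length(conn_in)) NA_real_ else
    mean(roles$role[match(conn_in, roles$otu)] == "connector")
  list(ari = ari, hub_recovery = hub_rec, connector_recovery = conn_rec,
       n_planted_in_net = length(present))
}
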