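#' Pairwise correlation screen with vectorised p-values
#'
#' Correlation matrix over the columns of `x` plus two-sided p-values
#' from the t approximation t = r * sqrt((n-2)/(1-r^2)) with n-2 degrees
#' of freedom (applied to Pearson r or to Spearman rho via ranks).
#' Constant columns are dropped with a warning since their correlation
#' is undefined.
#'
#' @param x samples x variables numeric matrix.
#' @param method "spearman" or "pearson".
#' @return list with `r` (correlation matrix), `p` (p-value matrix),
#'   `dropped` (names of constant columns).
#' @keywords internal
cor_screen <- function(x, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  n <- nrow(x)
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped))
    warning("constant column(s) excluded from correlation screen: ",
            paste(dropped, collapse = ", "))
  x <- x[, sds > 0, drop = FALSE]
  r <- stats::cor(x, method = method)
  rc <- pmin(pmax(r, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rc) >= 1 - 1e-12] <- 0
  diag(p) <- NA
  list(r = r, p = p, dropped = dropped)
}

#' Build a signed co-occurrence network over abundant OTUs
#'
#' Computes pairwise correlations of per-sample relative abundances and
#' keeps an edge between two OTUs iff |rho| >= `min_abs_corr` AND the
#' multiplicity-adjusted p-value is < `alpha`.  The correlation sign is
#' retained as an edge attribute; OTUs left without any edge do not
#' appear as nodes (which is why reported node counts fall below OTU
#' counts).  The table should already be restricted to abundant OTUs
#' (see [filter_abundant()]).
#'
#' @param table an [otu_table()] with >= 4 samples.
#' @param corr_method "spearman" (default) or "pearson".
#' @param min_abs_corr minimum absolute correlation for an edge.
#' @param alpha significance level on the adjusted p-value.
#' @param p_adjust "none" (default: with 12-sample compartment
#'   networks the |rho| cut is the operative filter), "bh" or "bonferroni".
#' @return object of class `cooc_network`: `edges` (from, to, rho, p,
#'   p_adj, sign), `nodes` (otu, phylum, degree), `n_samples`, `params`.
#' @export
build_network <- function(table, corr_method = "spearman",
                          min_abs_corr = 0.8, alpha = 0.05,
                          p_adjust = c("none", "bh", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(table$counts) < 4)
    stop("build_network needs >= 4 samples")
  rel <- relative_abundance(table)
  scr <- cor_screen(rel, corr_method)
  r <- scr$r; p <- scr$p
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rho <- r[idx]; praw <- p[idx]
  padj <- stats::p.adjust(praw, method = c(bh = "BH", bonferroni = "bonferroni",
                                           none = "none")[[p_adjust]])
  keep <- abs(rho) >= min_abs_corr & padj < alpha
  edges <- data.frame(from = rownames(r)[idx[keep, 1]],
                      to = colnames(r)[idx[keep, 2]],
                      rho = rho[keep], p = praw[keep], p_adj = padj[keep],
                      sign = ifelse(rho[keep] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  node_ids <- sort(unique(c(edges$from, edges$to)))
  deg <- table(factor(c(edges$from, edges$to), levels = node_ids))
  phylum <- table$taxonomy$phylum[match(node_ids, table$taxonomy$otu_id)]
  nodes <- data.frame(otu = node_ids, phylum = phylum,
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, n_samples = nrow(rel),
                 params = list(corr_method = corr_method,
                               min_abs_corr = min_abs_corr,
                               alpha = alpha, p_adjust = p_adjust)),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#' @param net a `cooc_network`.
#' @return undirected [igraph::igraph] with edge attributes rho, p_adj, sign.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Greedy modularity optimisation (CNM agglomeration)
#'
#' Clauset-Newman-Moore community detection on the unsigned, unweighted
#' graph: start from singleton communities and repeatedly merge the pair
#' of connected communities with the largest modularity gain delta-Q
#' until no merge yields a positive gain.  Modularity is
#' Q = sum_s (e_ss - a_s^2) with e_ss the fraction of edges inside
#' community s and a_s its fraction of edge endpoints.  When two merges
#' tie on delta-Q, the pair whose (smallest-member) community labels are
#' lexicographically smallest is merged, making the partition
#' deterministic.  Module ids are relabelled 1, 2, ... by descending
#' module size.
#'
#' @param net a `cooc_network`, or a two-column edge data.frame/matrix.
#' @return object of class `module_partition`: `membership` (named
#'   integer vector), `Q`, `module_sizes`.
#' @export
greedy_modularity <- function(net) {
  edges <- if (inherits(net, "cooc_network")) net$edges[, c("from", "to")]
           else as.data.frame(net)[, 1:2]
  if (nrow(edges) == 0) stop("empty network")
  nodes <- sort(unique(c(as.character(edges[[1]]), as.character(edges[[2]]))))
  k <- length(nodes)
  m <- nrow(edges)
  ei <- match(as.character(edges[[1]]), nodes)
  ej <- match(as.character(edges[[2]]), nodes)
  if (any(ei == ej)) stop("self-loops are not allowed")

  # B[i,j] = m_ij/(2m) off-diagonal, B[i,i] = m_ii/m; row sums give a_i
  B <- matrix(0, k, k)
  for (e in seq_len(m)) {
    B[ei[e], ej[e]] <- B[ei[e], ej[e]] + 1 / (2 * m)
    B[ej[e], ei[e]] <- B[ej[e], ei[e]] + 1 / (2 * m)
  }
  active <- rep(TRUE, k)
  label <- seq_len(k)          # smallest original node index in the community
  comm <- seq_len(k)           # community id per node (index into B rows)

  repeat {
    act <- which(active)
    if (length(act) < 2) break
    Ba <- B[act, act, drop = FALSE]
    a <- rowSums(Ba)
    D <- 2 * (Ba - outer(a, a))
    D[Ba == 0] <- -Inf           # only connected pairs can be merged
    diag(D) <- -Inf
    best <- max(D)
    if (best <= 1e-15) break
    cand <- which(D >= best - 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lab1 <- pmin(label[act[cand[, 1]]], label[act[cand[, 2]]])
    lab2 <- pmax(label[act[cand[, 1]]], label[act[cand[, 2]]])
    pick <- order(lab1, lab2)[1]
    i <- act[cand[pick, 1]]; j <- act[cand[pick, 2]]
    # merge j into i
    B[i, ] <- B[i, ] + B[j, ]
    B[, i] <- B[, i] + B[, j]
    active[j] <- FALSE
    label[i] <- min(label[i], label[j])
    comm[comm == j] <- i
  }

  # relabel by descending size, ties by smallest original label
  sizes <- table(comm)
  ord <- order(-as.integer(sizes), label[as.integer(names(sizes))])
  newid <- stats::setNames(seq_along(ord), names(sizes)[ord])
  membership <- as.integer(newid[as.character(comm)])
  names(membership) <- nodes
  q <- modularity_q(edges, membership)
  structure(list(membership = membership, Q = q,
                 module_sizes = as.integer(table(membership))),
            class = "module_partition")
}

#' Recompute modularity Q of a partition from first principles
#'
#' Q = sum_s (m_ss/m - (deg_s/2m)^2) on the unsigned, unweighted graph.
#'
#' @param edges two-column edge data.frame (from, to).
#' @param membership named integer vector, module id per node.
#' @return modularity Q.
#' @export
modularity_q <- function(edges, membership) {
  edges <- as.data.frame(edges)[, 1:2]
  m <- nrow(edges)
  ci <- membership[as.character(edges[[1]])]
  cj <- membership[as.character(edges[[2]])]
  mods <- sort(unique(membership))
  q <- 0
  for (s in mods) {
    within <- sum(ci == s & cj == s) / m
    deg_s <- (sum(ci == s) + sum(cj == s)) / (2 * m)
    q <- q + within - deg_s^2
  }
  q
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' For node i in module s: Zi = (k_is - mean_s) / sd_s where k_is is the
#' number of i's edges inside s and mean/sd are taken over all members
#' of s; modules whose members all have equal within-degree (sd = 0)
#' give Zi = 0.  Pi = 1 - sum_t (k_it / k_i)^2 over all modules t, with
#' k_i the node's total degree: 0 when every edge stays inside one
#' module, approaching 1 when edges spread evenly across modules.
#'
#' @param net a `cooc_network` (or edge data.frame).
#' @param partition a `module_partition` covering all nodes.
#' @return data.frame: otu, module, degree, within_degree, zi, pi.
#' @export
zi_pi <- function(net, partition) {
  edges <- if (inherits(net, "cooc_network")) net$edges[, c("from", "to")]
           else as.data.frame(net)[, 1:2]
  memb <- partition$membership
  nodes <- names(memb)
  miss <- setdiff(unique(c(as.character(edges[[1]]), as.character(edges[[2]]))),
                  nodes)
  if (length(miss)) stop("partition does not cover node(s): ",
                         paste(miss, collapse = ", "))
  mods <- sort(unique(memb))
  # k[i, t]: edges of node i into module t
  kmat <- matrix(0L, length(nodes), length(mods),
                 dimnames = list(nodes, mods))
  ci <- as.character(edges[[1]]); cj <- as.character(edges[[2]])
  for (e in seq_len(nrow(edges))) {
    kmat[ci[e], as.character(memb[cj[e]])] <- kmat[ci[e], as.character(memb[cj[e]])] + 1L
    kmat[cj[e], as.character(memb[ci[e]])] <- kmat[cj[e], as.character(memb[ci[e]])] + 1L
  }
  ktot <- rowSums(kmat)
  kwithin <- kmat[cbind(seq_along(nodes), match(memb[nodes], mods))]
  zi <- numeric(length(nodes))
  for (s in mods) {
    members <- which(memb[nodes] == s)
    mu <- mean(kwithin[members])
    sdev <- stats::sd(kwithin[members])
    zi[members] <- if (length(members) < 2 || is.na(sdev) || sdev == 0) 0
                   else (kwithin[members] - mu) / sdev
  }
  pi <- 1 - rowSums((kmat / ktot)^2)
  data.frame(otu = nodes, module = unname(memb[nodes]),
             degree = unname(ktot), within_degree = unname(kwithin),
             zi = zi, pi = unname(pi), stringsAsFactors = FALSE)
}

#' Classify node roles from Zi-Pi and list keystone taxa
#'
#' Four roles from strict thresholds: module hubs (Zi > 2.5, Pi < 0.62),
#' connectors (Zi < 2.5, Pi > 0.62), network hubs (Zi > 2.5, Pi > 0.62)
#' and peripherals (the rest).  A node sitting exactly on a threshold
#' falls to the non-hub / non-connector side.  Keystone taxa are all
#' non-peripheral nodes.
#'
#' @param roles data.frame from [zi_pi()].
#' @param zi_threshold,pi_threshold role thresholds (defaults 2.5, 0.62).
#' @return the input data.frame with a `role` column added, plus a
#'   `keystones` attribute (character vector of keystone node ids).
#' @export
classify_roles <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  hi_z <- roles$zi > zi_threshold
  hi_p <- roles$pi > pi_threshold
  roles$role <- ifelse(hi_z & hi_p, "network_hub",
                ifelse(hi_z, "module_hub",
                ifelse(hi_p, "connector", "peripheral")))
  attr(roles, "keystones") <- roles$otu[roles$role != "peripheral"]
  roles
}

#' Keystone OTUs shared between networks
#'
#' Intersects keystone node ids across two or more analysed networks,
#' overall and within each role.
#'
#' @param role_tables named list of >= 2 classified role tables (from
#'   [classify_roles()]).
#' @return list with `overall` (OTUs keystone in every network) and one
#'   element per role (OTUs holding that same role in every network).
#' @export
shared_keystones <- function(role_tables) {
  if (length(role_tables) < 2) stop("need >= 2 networks")
  key_sets <- lapply(role_tables, function(r) r$otu[r$role != "peripheral"])
  out <- list(overall = Reduce(intersect, key_sets))
  for (role in c("module_hub", "connector", "network_hub")) {
    sets <- lapply(role_tables, function(r) r$otu[r$role == role])
    out[[role]] <- Reduce(intersect, sets)
  }
  out
}

#' Topology metrics of a co-occurrence network
#'
#' Standard descriptors: node and edge counts, positive:negative edge
#' ratio (Inf when no negative edges), average degree (connectivity),
#' mean local clustering coefficient (nodes of degree < 2 contribute 0),
#' modularity Q of the supplied partition, unweighted average shortest
#' path length over the largest connected component, and edge density.
#'
#' @param net a `cooc_network`.
#' @param partition optional `module_partition`; when missing,
#'   [greedy_modularity()] is run.
#' @return data.frame of class `network_topology` (one row).
#' @export
topology <- function(net, partition = NULL) {
  if (nrow(net$edges) == 0) stop("empty network")
  if (is.null(partition)) partition <- greedy_modularity(net)
  g <- as_igraph(net)
  npos <- sum(net$edges$sign == "positive")
  nneg <- sum(net$edges$sign == "negative")
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  out <- data.frame(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    positive_negative_ratio = if (nneg == 0) Inf else npos / nneg,
    average_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
    average_clustering_coefficient =
      igraph::transitivity(g, type = "localaverage", isolates = "zero"),
    modularity = partition$Q,
    n_modules = length(partition$module_sizes),
    average_path_length = igraph::mean_distance(giant, directed = FALSE),
    density = igraph::edge_density(g))
  class(out) <- c("network_topology", "data.frame")
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)   # both partitions trivial
  (nij - expected) / (maxi - expected)
}

#' Write network artefacts to disk
#'
#' Emits `edges.tsv` (source, target, rho, p_adj, sign), `nodes.tsv`
#' (otu, phylum, degree, module, zi, pi, role), `topology.tsv`, and a
#' GraphML file for Gephi interoperability.
#'
#' @param net a `cooc_network`.
#' @param roles classified role table from [classify_roles()].
#' @param topo topology row from [topology()].
#' @param dir output directory.
#' @param prefix file-name prefix (e.g. the compartment label).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, roles, topo, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_edges.tsv", "_nodes.tsv",
                                           "_topology.tsv", ".graphml")))
  ed <- net$edges
  names(ed)[1:2] <- c("source", "target")
  utils::write.table(ed, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- merge(net$nodes, roles, by = "otu", sort = TRUE)
  utils::write.table(nodes[, c("otu", "phylum", "degree.x", "module",
                               "zi", "pi", "role")],
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(topo, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  g <- as_igraph(net)
  ridx <- match(igraph::V(g)$name, roles$otu)
  igraph::V(g)$module <- roles$module[ridx]
  igraph::V(g)$zi <- roles$zi[ridx]
  igraph::V(g)$pi <- roles$pi[ridx]
  igraph::V(g)$role <- roles$role[ridx]
  igraph::write_graph(g, paths[4], format = "graphml")
  invisible(paths)
}
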