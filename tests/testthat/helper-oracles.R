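# Independent oracles used across the suite.  These deliberately use
# brute-force enumeration or first-principles formulas, not the code
# paths they check.

# Exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# choose(n1+n2, n1) assignments of the pooled ranks to group 1.
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  pooled <- sort(c(x, y))
  ws <- colSums(matrix(rank(pooled)[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings); Bell(8) = 4140 so exhaustive search stays cheap.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxblock) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (b in seq_len(maxblock + 1))
      grow(c(prefix, b), max(maxblock, b))
  }
  grow(integer(0), 0L)
  out
}

# Exhaustive maximum modularity over all partitions of a small graph.
oracle_max_modularity <- function(edges) {
  nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    memb <- stats::setNames(p, nodes)
    q <- modularity_q(edges, memb)
    if (q > best) best <- q
  }
  best
}

# First-principles Zi / Pi from an edge list and a membership vector.
oracle_zi_pi <- function(edges, memb) {
  nodes <- names(memb)
  adj <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(edges))) {
    adj[edges[e, 1], edges[e, 2]] <- 1L
    adj[edges[e, 2], edges[e, 1]] <- 1L
  }
  mods <- sort(unique(memb))
  zi <- pi <- numeric(length(nodes))
  kwithin <- sapply(nodes, function(v) sum(adj[v, names(memb)[memb == memb[v]]]))
  for (s in mods) {
    mem <- nodes[memb == s]
    mu <- mean(kwithin[mem]); sdv <- stats::sd(kwithin[mem])
    zi[match(mem, nodes)] <- if (length(mem) < 2 || is.na(sdv) || sdv == 0) 0
                             else (kwithin[mem] - mu) / sdv
  }
  for (i in seq_along(nodes)) {
    k <- sum(adj[i, ])
    kts <- sapply(mods, function(s) sum(adj[i, names(memb)[memb == s]]))
    pi[i] <- 1 - sum((kts / k)^2)
  }
  data.frame(otu = nodes, zi = zi, pi = pi, stringsAsFactors = FALSE)
}

# Random connected-ish undirected graph as an edge data.frame.
random_graph <- function(n, p = 0.35) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  data.frame(from = paste0("n", pairs[keep, 1]),
             to = paste0("n", pairs[keep, 2]), stringsAsFactors = FALSE)
}

# Minimal otu_table for hand-built count matrices.
tiny_table <- function(counts, lineages = NULL, compartment = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (is.null(compartment))
    compartment <- rep(c("G", "T"), length.out = nrow(counts))
  meta <- data.frame(sample_id = rownames(counts),
                     compartment = compartment,
                     species = rep(c("PZ", "CZ", "OZ", "ZJ"),
                                   length.out = nrow(counts)),
                     replicate = seq_len(nrow(counts)),
                     stringsAsFactors = FALSE)
  tax <- NULL
  if (!is.null(lineages)) {
    tax <- data.frame(otu_id = colnames(counts), lineage = lineages,
                      stringsAsFactors = FALSE)
    tax <- cbind(tax, parse_lineage(tax$lineage))
  }
  otu_table(counts, meta, tax)
}
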