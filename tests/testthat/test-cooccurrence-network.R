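test_that("build_network keeps monotone pairs with the right sign", {
  set.seed(8)
  a <- c(5, 9, 14, 22, 30, 41, 55, 70)
  counts <- cbind(A = a, B = 2 * a, C = rev(a) + 1,
                  D = rpois(8, 50), E = rpois(8, 50))
  counts <- counts + 1
  rownames(counts) <- paste0("S", 1:8)
  tab <- tiny_table(counts)
  # keep totals roughly constant so relative abundances stay monotone
  tab$counts <- cbind(tab$counts, filler = 500 - rowSums(tab$counts))
  tab <- tiny_table(tab$counts)
  net <- suppressWarnings(build_network(tab, min_abs_corr = 0.95,
                                        p_adjust = "none"))
  ek <- paste(net$edges$from, net$edges$to)
  ab <- net$edges[ek %in% c("A B", "B A"), ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$sign, "positive")
  expect_equal(ab$rho, 1, tolerance = 1e-12)
  ac <- net$edges[ek %in% c("A C", "C A"), ]
  expect_equal(ac$sign, "negative")
  expect_equal(ac$rho, -1, tolerance = 1e-12)
  # degree consistent with edge set; no self loops
  expect_false(any(net$edges$from == net$edges$to))
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(net$nodes$degree[match(names(deg), net$nodes$otu)]),
               as.integer(deg))
})

test_that("build_network refuses tiny designs and drops constant OTUs", {
  tab <- tiny_table(matrix(1:6, 3, 2))
  expect_error(build_network(tab), ">= 4 samples")
  m <- cbind(A = c(10, 20, 30, 40, 50, 60), B = c(12, 19, 33, 41, 48, 62),
             flat = rep(25, 6))
  m <- cbind(m, filler = 200 - rowSums(m))  # equal totals: flat stays constant
  rownames(m) <- paste0("S", 1:6)
  expect_warning(build_network(tiny_table(m), min_abs_corr = 0.9),
                 "constant column")
})

test_that("greedy modularity reproduces closed-form optima", {
  # two triangles joined by one bridge: Q = 2*(3/7 - (7/14)^2) = 5/14
  bridged <- data.frame(
    from = c("a1", "a1", "a2", "b1", "b1", "b2", "a1"),
    to   = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"))
  part <- greedy_modularity(bridged)
  expect_equal(part$Q, 5 / 14, tolerance = 1e-12)
  expect_equal(length(part$module_sizes), 2)
  memb <- part$membership
  expect_equal(memb[["a1"]], memb[["a2"]])
  expect_equal(memb[["b1"]], memb[["b3"]])
  expect_false(memb[["a1"]] == memb[["b1"]])

  # two disjoint triangles: Q = 0.5 exactly
  two <- data.frame(from = c("a1", "a1", "a2", "b1", "b1", "b2"),
                    to   = c("a2", "a3", "a3", "b2", "b3", "b3"))
  expect_equal(greedy_modularity(two)$Q, 0.5, tolerance = 1e-12)

  # complete graph: a single module, Q = 0
  k5 <- t(utils::combn(paste0("n", 1:5), 2))
  pk <- greedy_modularity(data.frame(from = k5[, 1], to = k5[, 2]))
  expect_equal(length(pk$module_sizes), 1)
  expect_equal(pk$Q, 0, tolerance = 1e-12)
})

test_that("reported Q equals recomputation from the partition, also via igraph", {
  set.seed(21)
  for (i in 1:10) {
    g <- random_graph(9, 0.35)
    part <- greedy_modularity(g)
    expect_equal(part$Q, modularity_q(g, part$membership), tolerance = 1e-12)
    ig <- igraph::graph_from_data_frame(g, directed = FALSE)
    expect_equal(part$Q,
                 igraph::modularity(ig, part$membership[igraph::V(ig)$name]),
                 tolerance = 1e-10)
  }
})

test_that("greedy Q never exceeds the exhaustive optimum on small graphs", {
  graphs <- list(
    two_cliques = data.frame(from = c("a1", "a1", "a2", "b1", "b1", "b2"),
                             to   = c("a2", "a3", "a3", "b2", "b3", "b3")),
    bridged = data.frame(from = c("a1", "a1", "a2", "b1", "b1", "b2", "a1"),
                         to   = c("a2", "a3", "a3", "b2", "b3", "b3", "b1")),
    star6 = data.frame(from = rep("h", 5), to = paste0("l", 1:5)),
    cycle7 = data.frame(from = paste0("c", 1:7),
                        to = paste0("c", c(2:7, 1))),
    k4 = { p <- t(utils::combn(paste0("k", 1:4), 2))
           data.frame(from = p[, 1], to = p[, 2]) })
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    qg <- greedy_modularity(g)$Q
    qmax <- oracle_max_modularity(g)
    expect_lte(qg, qmax + 1e-12)
    if (nm %in% c("two_cliques", "bridged"))
      expect_equal(qg, qmax, tolerance = 1e-12, label = nm)
  }
})

test_that("greedy modularity is deterministic under node relabelling ties", {
  g <- data.frame(from = c("x1", "x1", "x2", "y1", "y1", "y2"),
                  to   = c("x2", "x3", "x3", "y2", "y3", "y3"))
  p1 <- greedy_modularity(g)
  p2 <- greedy_modularity(g[sample(nrow(g)), ])
  expect_identical(p1$membership, p2$membership[names(p1$membership)])
})

test_that("zi-pi matches a brute-force implementation on random graphs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    g <- random_graph(n, 0.4)
    nodes <- sort(unique(c(g$from, g$to)))
    memb <- stats::setNames(sample(1:3, length(nodes), replace = TRUE), nodes)
    mine <- zi_pi(g, list(membership = memb))
    orac <- oracle_zi_pi(as.matrix(g), memb)
    expect_equal(mine$zi, orac$zi[match(mine$otu, orac$otu)], tolerance = 1e-12)
    expect_equal(mine$pi, orac$pi[match(mine$otu, orac$otu)], tolerance = 1e-12)
    # degree conservation across modules
    deg <- table(c(g$from, g$to))
    expect_equal(mine$degree, as.integer(deg[mine$otu]))
  }
})

test_that("zi-pi closed-form cases", {
  # all edges inside own module -> Pi = 0
  g <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"))
  memb <- c(a = 1, b = 1, c = 1)
  r <- zi_pi(g, list(membership = memb))
  expect_true(all(r$pi == 0))
  expect_true(all(r$zi == 0))   # equal within-degrees -> sd = 0 convention

  # degree-4 node with 2 edges into each of 2 modules -> Pi = 0.5
  g2 <- data.frame(from = rep("x", 4), to = c("m1", "m2", "n1", "n2"))
  memb2 <- c(x = 1, m1 = 1, m2 = 1, n1 = 2, n2 = 2)
  r2 <- zi_pi(g2, list(membership = memb2))
  expect_equal(r2$pi[r2$otu == "x"], 0.5, tolerance = 1e-12)

  # Zi within each module has mean 0, sd 1 when sd > 0
  set.seed(4)
  g3 <- random_graph(10, 0.5)
  p3 <- greedy_modularity(g3)
  r3 <- zi_pi(g3, p3)
  for (s in unique(r3$module)) {
    z <- r3$zi[r3$module == s]
    if (length(z) > 1 && any(z != 0)) {
      expect_equal(mean(z), 0, tolerance = 1e-10)
      expect_equal(sd(z), 1, tolerance = 1e-10)
    }
  }
})

test_that("role classification follows the strict Zi-Pi thresholds", {
  grid <- data.frame(
    otu = paste0("n", 1:7),
    module = 1, degree = 5, within_degree = 3,
    zi = c(3.0, 1.0, 3.0, 2.5, 2.5, 2.6, 0.0),
    pi = c(0.10, 0.70, 0.70, 0.62, 0.90, 0.62, 0.62))
  r <- classify_roles(grid)
  expect_equal(r$role,
               c("module_hub", "connector", "network_hub",
                 "peripheral",   # exactly on both thresholds
                 "connector",    # zi at threshold, pi above
                 "module_hub",   # zi above, pi at threshold
                 "peripheral"))
  expect_setequal(attr(r, "keystones"), r$otu[r$role != "peripheral"])
  # roles partition the nodes
  expect_true(all(table(r$otu) == 1))
})

test_that("topology metrics match hand-computed graphs", {
  tri <- structure(list(
    edges = data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                       rho = c(0.9, 0.9, -0.9), p = 0, p_adj = 0,
                       sign = c("positive", "positive", "negative")),
    nodes = data.frame(otu = c("a", "b", "c"), phylum = NA, degree = 2L),
    n_samples = 10, params = list()), class = "cooc_network")
  tp <- topology(tri)
  expect_equal(tp$average_clustering_coefficient, 1)
  expect_equal(tp$density, 1)
  expect_equal(tp$average_degree, 2)
  expect_equal(tp$positive_negative_ratio, 2)

  star <- structure(list(
    edges = data.frame(from = rep("h", 3), to = paste0("l", 1:3),
                       rho = 0.9, p = 0, p_adj = 0, sign = "positive"),
    nodes = data.frame(otu = c("h", paste0("l", 1:3)), phylum = NA,
                       degree = c(3L, 1L, 1L, 1L)),
    n_samples = 10, params = list()), class = "cooc_network")
  tps <- topology(star)
  expect_equal(tps$average_clustering_coefficient, 0)
  expect_equal(tps$average_path_length, 1.5)  # 3 pairs at 1, 3 at 2
  expect_equal(tps$positive_negative_ratio, Inf)

  # 6 positive + 2 negative edges -> ratio 3
  p8 <- t(utils::combn(paste0("v", 1:5), 2))[1:8, ]
  g8 <- data.frame(from = p8[, 1], to = p8[, 2], stringsAsFactors = FALSE)
  net8 <- structure(list(
    edges = cbind(g8, rho = c(rep(0.9, 6), rep(-0.9, 2)), p = 0, p_adj = 0,
                  sign = c(rep("positive", 6), rep("negative", 2))),
    nodes = data.frame(otu = sort(unique(unlist(g8))), phylum = NA,
                       degree = 1L),
    n_samples = 10, params = list()), class = "cooc_network")
  net8$nodes$degree <- as.integer(
    table(c(g8$from, g8$to))[net8$nodes$otu])
  expect_equal(topology(net8)$positive_negative_ratio, 3)
})

test_that("shared keystones intersect correctly across networks", {
  r1 <- data.frame(otu = c("a", "b", "c", "d"),
                   role = c("module_hub", "connector", "peripheral", "connector"))
  r2 <- data.frame(otu = c("a", "b", "c", "e"),
                   role = c("connector", "connector", "module_hub", "connector"))
  sk <- shared_keystones(list(G = r1, T = r2))
  expect_setequal(sk$overall, c("a", "b"))
  expect_equal(sk$connector, "b")
  expect_length(sk$module_hub, 0)
  # identical networks -> intersection is the full keystone set
  sk2 <- shared_keystones(list(r1, r1))
  expect_setequal(sk2$overall, c("a", "b", "d"))
  # disjoint keystone sets -> empty
  r3 <- data.frame(otu = c("x", "y"), role = c("module_hub", "connector"))
  expect_length(shared_keystones(list(r1, r3))$overall, 0)
  expect_error(shared_keystones(list(r1)), ">= 2")
})

test_that("adjusted Rand index agrees with mclust on random labelings", {
  skip_if_not_installed("mclust")
  set.seed(6)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("network writers emit readable edge, node and graphml files", {
  ds <- generate_dataset(synthetic_config(seed = 4))
  tab <- subset_samples(ds$otu, ds$otu$metadata$compartment == "G")
  net <- suppressWarnings(build_network(filter_abundant(tab)))
  part <- greedy_modularity(net)
  roles <- classify_roles(zi_pi(net, part))
  dir <- withr::local_tempdir()
  paths <- write_network(net, roles, topology(net, part), dir, "G")
  expect_true(all(file.exists(paths)))
  ed <- read.delim(paths[1])
  expect_equal(nrow(ed), nrow(net$edges))
  g <- igraph::read_graph(paths[4], format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_true("module" %in% igraph::vertex_attr_names(g))
})
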