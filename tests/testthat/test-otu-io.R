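test_that("otu_table validates counts and metadata, naming offenders", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("S1", "S2"), c("A", "B")))
  meta <- data.frame(sample_id = c("S1", "S2"), compartment = c("G", "T"),
                     species = "PZ", replicate = 1:2)
  expect_s3_class(otu_table(m, meta), "otu_table")

  bad <- m; bad[2, 1] <- -3
  expect_error(otu_table(bad, meta), "negative count.*S2.*A")
  bad <- m; bad[1, 2] <- 1.5
  expect_error(otu_table(bad, meta), "non-integer")
  expect_error(otu_table(m, meta[1, ]), "without metadata: S2")
  m2 <- m; colnames(m2) <- c("A", "A")
  expect_error(otu_table(m2, meta), "duplicate OTU")
})

test_that("lineage parser resolves ranks and labels unresolved ones from the parent", {
  lx <- parse_lineage("k__Fungi;p__Ascomycota;c__Pezizomycetes;o__Pezizales;f__Tuberaceae;g__Tuber;s__melanosporum")
  expect_equal(lx$phylum, "Ascomycota")
  expect_equal(lx$class, "Pezizomycetes")
  expect_equal(lx$genus, "Tuber")

  part <- parse_lineage("k__Fungi;p__Ascomycota;c__Dothideomycetes;o__Pleosporales;f__Melanommataceae")
  expect_equal(part$genus, "unclassified_f__Melanommataceae")
  expect_equal(part$species, "unclassified_f__Melanommataceae")

  bare <- parse_lineage("k__Fungi")
  expect_equal(bare$phylum, "unclassified_k__Fungi")

  # round-trip for any accepted lineage
  strs <- c("k__Fungi;p__Basidiomycota;c__Agaricomycetes",
            "k__Fungi",
            "k__Fungi;p__Ascomycota;c__Sordariomycetes;o__Hypocreales;f__Nectriaceae;g__Fusarium")
  expect_equal(format_lineage(parse_lineage(strs)), strs)
})

test_that("rarefy equalises depths, is deterministic, and matches hypergeometric moments", {
  set.seed(1)
  m <- matrix(rpois(40, 60), 4, 10,
              dimnames = list(paste0("S", 1:4), paste0("OTU", 1:10)))
  tab <- tiny_table(m)
  r1 <- rarefy(tab, "min", seed = 7)
  expect_true(all(rowSums(r1$counts) == min(rowSums(m))))
  expect_identical(colnames(r1$counts), colnames(m))  # zero columns kept
  r2 <- rarefy(tab, "min", seed = 7)
  expect_identical(r1$counts, r2$counts)

  one <- tiny_table(matrix(50, 1, 1, dimnames = list("S1", "OTU1")),
                    compartment = "G")
  expect_equal(unname(rarefy(one, 20)$counts[1, 1]), 20)

  expect_error(rarefy(tab, depth = 1e6), "exceeds")

  # two samples [30,10] and [20,20], depth 15 (< both totals):
  # sampling without replacement => hypergeometric mean and variance
  tt <- tiny_table(matrix(c(30, 10, 20, 20), 2, 2, byrow = TRUE,
                          dimnames = list(c("S1", "S2"), c("A", "B"))))
  draws <- vapply(1:1000, function(s) rarefy(tt, 15, seed = s)$counts[1, "A"], 0)
  mu <- 15 * 30 / 40
  v <- 15 * (30 / 40) * (10 / 40) * (40 - 15) / (40 - 1)
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / 1000))
  expect_lt(abs(var(draws) - v), 4 * v / sqrt(1000))
})

test_that("aggregate_rank sums by taxon label with unclassified fallback", {
  m <- matrix(c(3, 7, 5, 1, 2, 4), 2, 3,
              dimnames = list(c("S1", "S2"), c("O1", "O2", "O3")))
  lng <- c("k__Fungi;p__Ascomycota", "k__Fungi;p__Ascomycota", "k__Fungi")
  tab <- tiny_table(m, lineages = lng)
  agg <- aggregate_rank(tab, "phylum")
  expect_equal(agg[, "Ascomycota"], c(S1 = 3 + 5, S2 = 7 + 1))
  expect_equal(agg[, "unclassified_k__Fungi"], c(S1 = 2, S2 = 4))
  rel <- aggregate_rank(tab, "phylum", relative = TRUE)
  expect_equal(unname(rowSums(rel)), c(1, 1), tolerance = 1e-12)
  expect_error(aggregate_rank(tab, "clade"))
})

test_that("filter_abundant applies the strict >0.005% rule and is idempotent", {
  # grand total 100000; 5 reads = exactly 0.005% -> removed; 6 -> kept
  m <- matrix(c(99989, 5, 6), 1, 3,
              dimnames = list("S1", c("big", "at", "above")))
  tab <- tiny_table(m, compartment = "G")
  f <- filter_abundant(tab, 5e-5)
  expect_identical(colnames(f$counts), c("big", "above"))

  f0 <- filter_abundant(tab, 0)
  expect_identical(colnames(f0$counts), c("big", "at", "above"))
  zz <- tiny_table(cbind(m, none = 0), compartment = "G")
  expect_false("none" %in% colnames(filter_abundant(zz, 0)$counts))

  expect_identical(colnames(filter_abundant(f, 5e-5)$counts),
                   colnames(f$counts))
})

test_that("core OTU sets match exhaustive set algebra", {
  # 3 groups x hand-built membership
  m <- rbind(g1a = c(1, 1, 0, 0, 1), g1b = c(1, 0, 0, 0, 0),
             g2a = c(0, 1, 1, 0, 1), g2b = c(0, 1, 0, 0, 0),
             g3a = c(0, 0, 1, 1, 1), g3b = c(1, 0, 0, 1, 0))
  colnames(m) <- paste0("O", 1:5)
  tab <- tiny_table(m, compartment = c("A", "A", "B", "B", "C", "C"))
  cs <- core_otu_sets(tab, "compartment")
  sets <- list(A = c("O1", "O2", "O5"), B = c("O2", "O3", "O5"),
               C = c("O1", "O3", "O4", "O5"))
  expect_equal(cs$sets, sets)
  expect_equal(sort(cs$global_intersection), "O5")
  expect_equal(sort(cs$pairwise[["A&B"]]), c("O2", "O5"))
  expect_equal(sort(cs$pairwise[["A&C"]]), c("O1", "O5"))
  expect_equal(cs$exclusive$A, character(0))
  expect_equal(cs$exclusive$C, "O4")
  # union of exclusives + shared partitions the union
  shared <- setdiff(cs$union, unlist(cs$exclusive))
  expect_setequal(c(shared, unlist(cs$exclusive)), cs$union)
  expect_lte(length(cs$global_intersection), min(lengths(sets)))

  # disjoint and identical group compositions
  dd <- tiny_table(rbind(a = c(1, 0), b = c(0, 1)),
                   compartment = c("A", "B"))
  expect_length(core_otu_sets(dd, "compartment")$global_intersection, 0)
  ii <- tiny_table(rbind(a = c(1, 1), b = c(1, 1)),
                   compartment = c("A", "B"))
  ci <- core_otu_sets(ii, "compartment")
  expect_setequal(ci$global_intersection, ci$union)
  expect_error(core_otu_sets(tiny_table(m, compartment = rep("A", 6)),
                             "compartment"), "2 groups")
})

test_that("write then read round-trips counts, metadata and lineages", {
  ds <- generate_dataset(synthetic_config(seed = 11))
  dir <- withr::local_tempdir()
  write_otu_table(ds$otu, dir)
  back <- read_otu_table(file.path(dir, "otu_table.tsv"),
                         file.path(dir, "taxonomy.tsv"),
                         file.path(dir, "metadata.tsv"))
  expect_equal(back$counts, ds$otu$counts)
  expect_equal(back$metadata, ds$otu$metadata)
  expect_equal(back$taxonomy$lineage, ds$otu$taxonomy$lineage)
  expect_equal(back$taxonomy$genus, ds$otu$taxonomy$genus)
})
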