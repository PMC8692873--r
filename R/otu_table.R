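#' OTU count table with sample metadata and taxonomy
#'
#' The central container of the package: an integer count matrix
#' (samples x OTUs) together with per-sample metadata (compartment,
#' species, replicate) and one parsed taxonomy lineage per OTU.
#'
#' @param counts non-negative integer matrix, rows = samples, columns =
#'   OTUs; dimnames required.
#' @param metadata data.frame with columns `sample_id`, `compartment`,
#'   `species`, `replicate`; one row per sample.
#' @param taxonomy data.frame with columns `otu_id`, `lineage` plus the
#'   seven rank columns, as produced by [parse_lineage()].  OTUs absent
#'   from `taxonomy` receive an all-unclassified lineage.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, metadata, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)))
    stop("counts contain non-finite values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "double"   # integer-valued; double avoids overflow on sums

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "compartment", "species", "replicate")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata")
  absent <- setdiff(rownames(counts), metadata$sample_id)
  if (length(absent))
    stop("samples without metadata: ", paste(absent, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- metadata$sample_id

  otus <- colnames(counts)
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(otu_id = otus, lineage = "k__Fungi",
                           stringsAsFactors = FALSE)
    taxonomy <- cbind(taxonomy, parse_lineage(taxonomy$lineage))
  } else {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    unknown <- setdiff(taxonomy$otu_id, otus)
    if (length(unknown))
      warning(length(unknown), " taxonomy entries for OTUs absent from the count table ignored")
    taxonomy <- taxonomy[taxonomy$otu_id %in% otus, , drop = FALSE]
    missing_tax <- setdiff(otus, taxonomy$otu_id)
    if (length(missing_tax)) {
      filler <- data.frame(otu_id = missing_tax, lineage = "k__Fungi",
                           stringsAsFactors = FALSE)
      filler <- cbind(filler, parse_lineage(filler$lineage))
      taxonomy <- rbind(taxonomy[, names(filler)], filler)
    }
    taxonomy <- taxonomy[match(otus, taxonomy$otu_id), , drop = FALSE]
  }
  rownames(taxonomy) <- taxonomy$otu_id

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat("compartments:", paste(sort(unique(x$metadata$compartment)), collapse = ", "),
      "| species:", paste(sort(unique(x$metadata$species)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
TAX_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Parse QIIME-style taxonomy lineage strings
#'
#' Splits semicolon-delimited lineages with `k__`/`p__`/... rank prefixes
#' into seven rank columns.  Ranks that are absent, empty, or already
#' flagged unclassified are labelled `unclassified_<prefix><parent>`,
#' where `<parent>` is the deepest resolved taxon above them (e.g. a
#' lineage resolved to family Melanommataceae yields genus
#' `unclassified_f__Melanommataceae`).
#'
#' @param lineages character vector of lineage strings.
#' @return data.frame with the seven rank columns, one row per lineage.
#' @export
parse_lineage <- function(lineages) {
  out <- matrix(NA_character_, nrow = length(lineages), ncol = 7,
                dimnames = list(NULL, TAX_RANKS))
  for (i in seq_along(lineages)) {
    parts <- trimws(strsplit(lineages[i], ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    vals <- rep(NA_character_, 7)
    for (p in parts) {
      hit <- which(startsWith(p, TAX_PREFIXES))
      if (length(hit) == 1) {
        v <- substring(p, 4)
        if (nzchar(v) && !grepl("^unclassified", v, ignore.case = TRUE) &&
            !grepl("^unidentified", v, ignore.case = TRUE))
          vals[hit] <- v
      }
    }
    # fill unresolved ranks from the deepest resolved ancestor
    parent_lab <- "k__Fungi"   # ultimate fallback
    for (r in 1:7) {
      if (is.na(vals[r])) {
        vals[r] <- paste0("unclassified_", parent_lab)
      } else {
        parent_lab <- paste0(TAX_PREFIXES[r], vals[r])
      }
    }
    out[i, ] <- vals
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Format a parsed lineage back into a prefixed string
#'
#' Inverse of [parse_lineage()] for resolved ranks; unclassified slots are
#' omitted so that `format_lineage(parse_lineage(x))` reproduces any
#' well-formed input string.
#'
#' @param ranks data.frame as returned by [parse_lineage()].
#' @return character vector of lineage strings.
#' @export
format_lineage <- function(ranks) {
  apply(as.matrix(ranks), 1, function(v) {
    keep <- !startsWith(v, "unclassified_")
    paste0(TAX_PREFIXES[keep], v[keep], collapse = ";")
  })
}

#' Read an OTU table from TSV files
#'
#' Reads the three tab-delimited files of the package's on-disk dialect:
#' a count table (header `#OTU_ID` plus one column per sample, rows =
#' OTUs), a two-column taxonomy file (`otu_id`, semicolon lineage), and a
#' sample metadata file (`sample_id`, `compartment`, `species`,
#' `replicate`).  Lines starting with `#` are treated as comments except
#' for the count-table header itself.
#'
#' @param table_path,taxonomy_path,metadata_path file paths.
#' @return validated [otu_table()].
#' @export
read_otu_table <- function(table_path, taxonomy_path, metadata_path) {
  hdr <- readLines(table_path, n = 1)
  cn <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1]]
  tab <- utils::read.table(table_path, sep = "\t", skip = 1,
                           col.names = cn, header = FALSE,
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE, quote = "")
  otu_ids <- as.character(tab[[1]])
  counts <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(counts) <- otu_ids
  tax_raw <- utils::read.table(taxonomy_path, sep = "\t", header = TRUE,
                               comment.char = "", stringsAsFactors = FALSE,
                               quote = "")
  names(tax_raw)[1:2] <- c("otu_id", "lineage")
  taxonomy <- cbind(tax_raw[, 1:2], parse_lineage(tax_raw$lineage))
  metadata <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                                comment.char = "", stringsAsFactors = FALSE,
                                quote = "")
  otu_table(counts, metadata, taxonomy)
}

#' Write an OTU table to TSV files
#'
#' Counterpart of [read_otu_table()]; writes `otu_table.tsv`,
#' `taxonomy.tsv` and `metadata.tsv` into `dir`.
#'
#' @param table an [otu_table()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_otu_table <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("otu_table.tsv", "taxonomy.tsv", "metadata.tsv"))
  cnt <- t(table$counts)
  df <- data.frame(OTU_ID = rownames(cnt), cnt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- "#OTU_ID"
  utils::write.table(df, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$taxonomy[, c("otu_id", "lineage")], paths[2],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$metadata, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Subset an OTU table by samples
#'
#' @param table an [otu_table()].
#' @param samples sample ids, logical mask, or indices.
#' @param drop_empty_otus drop OTUs with zero counts in the subset?
#'   Default FALSE so OTU ids stay aligned across subsets.
#' @return an [otu_table()].
#' @export
subset_samples <- function(table, samples, drop_empty_otus = FALSE) {
  counts <- table$counts[samples, , drop = FALSE]
  if (drop_empty_otus) counts <- counts[, colSums(counts) > 0, drop = FALSE]
  otu_table(counts,
            table$metadata[rownames(counts), , drop = FALSE],
            table$taxonomy[table$taxonomy$otu_id %in% colnames(counts), ,
                           drop = FALSE])
}

#' Rarefy all samples to a common depth
#'
#' Subsamples each sample's reads without replacement (hypergeometric
#' draw, as in Mothur's sub.sample) to exactly `depth` reads, the
#' homogenisation step applied before diversity estimation.  OTUs left
#' with all-zero counts are retained as zero columns so OTU ids stay
#' aligned across sample subsets.
#'
#' @param table an [otu_table()].
#' @param depth target depth, or `"min"` for the minimum sample sum.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return rarefied [otu_table()].
#' @export
rarefy <- function(table, depth = "min", seed = 1) {
  totals <- rowSums(table$counts)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.numeric(depth)
  if (depth < 1) stop("depth must be >= 1")
  short <- totals < depth
  if (any(short))
    stop("depth ", depth, " exceeds the total reads of sample(s): ",
         paste(names(totals)[short], collapse = ", "))
  set.seed(seed)
  sub <- suppressWarnings(vegan::rrarefy(table$counts, depth))
  if (!identical(dim(sub), dim(table$counts))) sub <- t(sub)
  dimnames(sub) <- dimnames(table$counts)
  otu_table(sub, table$metadata, table$taxonomy)
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Sums OTU columns sharing the same label at `rank` (e.g. all
#' `p__Ascomycota` OTUs into one "Ascomycota" column).  Fully
#' unclassified OTUs collapse into the `unclassified_k__Fungi` column.
#'
#' @param table an [otu_table()].
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @param relative return relative abundances (rows sum to 1)?
#' @return matrix samples x taxa (counts or proportions).
#' @export
aggregate_rank <- function(table, rank, relative = FALSE) {
  rank <- match.arg(rank, TAX_RANKS)
  labels <- table$taxonomy[[rank]]
  agg <- t(rowsum(t(table$counts), group = labels))
  if (relative) agg <- agg / rowSums(agg)
  agg
}

#' Retain abundant OTUs
#'
#' Keeps OTUs whose share of the table's grand read total is strictly
#' greater than `threshold` (default 5e-5, i.e. the ">0.005%" abundance
#' rule); an OTU sitting exactly at the threshold is removed.  Column
#' order is preserved.  Idempotent: filtering a filtered table changes
#' nothing (the retained OTUs' shares only grow as the grand total
#' shrinks).
#'
#' @param table an [otu_table()].
#' @param threshold proportion of the grand total (fraction, not percent).
#' @return filtered [otu_table()].
#' @export
filter_abundant <- function(table, threshold = 5e-5) {
  grand <- sum(table$counts)
  if (grand == 0) stop("empty table: no reads")
  keep <- colSums(table$counts) / grand > threshold
  otu_table(table$counts[, keep, drop = FALSE], table$metadata,
            table$taxonomy[keep, , drop = FALSE])
}

#' Core-OTU presence sets and their intersections
#'
#' An OTU is "core" to a group when it is present (count > 0) in at least
#' one sample of that group.  Returns the per-group sets, the global
#' intersection (the shared core community), all pairwise intersections,
#' and the OTUs exclusive to each group, i.e. the set algebra a Venn
#' diagram displays.
#'
#' @param table an [otu_table()].
#' @param grouping metadata column name (e.g. "compartment" or "species").
#' @return list with elements `sets`, `global_intersection`, `pairwise`,
#'   `exclusive`, `union`; class `core_otu_sets`.
#' @export
core_otu_sets <- function(table, grouping) {
  g <- table$metadata[[grouping]]
  if (is.null(g)) stop("unknown metadata field: ", grouping)
  groups <- sort(unique(g))
  if (length(groups) < 2) stop("core_otu_sets needs at least 2 groups")
  sets <- lapply(groups, function(lv) {
    colnames(table$counts)[colSums(table$counts[g == lv, , drop = FALSE]) > 0]
  })
  names(sets) <- groups
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(p) intersect(sets[[p[1]]], sets[[p[2]]]))
  names(pairwise) <- vapply(pairs, paste, "", collapse = "&")
  uni <- Reduce(union, sets)
  exclusive <- lapply(groups, function(lv) {
    others <- Reduce(union, sets[setdiff(groups, lv)])
    setdiff(sets[[lv]], others)
  })
  names(exclusive) <- groups
  structure(list(sets = sets,
                 global_intersection = Reduce(intersect, sets),
                 pairwise = pairwise, exclusive = exclusive, union = uni),
            class = "core_otu_sets")
}

#' Relative abundances of an OTU table
#' @param table an [otu_table()].
#' @return matrix of per-sample proportions (rows sum to 1).
#' @export
relative_abundance <- function(table) {
  table$counts / rowSums(table$counts)
}
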