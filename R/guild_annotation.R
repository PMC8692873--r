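#' Read a FUNGuild-style reference table
#'
#' Five tab-delimited columns: `taxon`, `level` (taxonomic rank of the
#' record), `trophic_mode` (pathotroph / symbiotroph / saprotroph,
#' possibly compound like "Pathotroph-Saprotroph"), `guild` (possibly
#' "|"-delimited multi-guild), `confidence` (possible / probable /
#' highly probable).
#'
#' @param path TSV file.
#' @return data.frame of class `guild_reference`.
#' @export
read_guild_reference <- function(path) {
  ref <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           quote = "")
  names(ref)[1:5] <- c("taxon", "level", "trophic_mode", "guild", "confidence")
  validate_guild_reference(ref)
}

#' @keywords internal
validate_guild_reference <- function(ref) {
  if (nrow(ref) == 0) stop("empty guild reference")
  modes <- tolower(unlist(strsplit(ref$trophic_mode, "-", fixed = TRUE)))
  bad <- setdiff(unique(modes), c("pathotroph", "symbiotroph", "saprotroph"))
  if (length(bad))
    stop("unknown trophic mode token(s): ", paste(bad, collapse = ", "))
  class(ref) <- c("guild_reference", "data.frame")
  ref
}

#' Assign trophic modes and guilds to OTUs
#'
#' Each OTU is matched against the reference at the most specific
#' taxonomic rank carrying a record (species before genus before family,
#' up to kingdom); name comparison is case-insensitive and the first hit
#' wins.  Following the single-guild inclusion rule, OTUs whose matched
#' record lists two or more "|"-separated guilds are excluded from the
#' abundance profiles; OTUs with no match at any rank are counted as
#' unassigned.  Compound trophic modes on single-guild records (e.g.
#' "Pathotroph-Saprotroph") are kept under their compound label rather
#' than split, so no abundance is double-counted.
#'
#' @param table an [otu_table()].
#' @param ref a `guild_reference` (see [read_guild_reference()]).
#' @param min_confidence optional confidence floor ("possible" <
#'   "probable" < "highly probable"); records below it are ignored.
#'   Default NA: no confidence filtering.
#' @return list of class `guild_profile` with `assignments` (per-OTU
#'   table with a `status` of included / multi_guild / unassigned),
#'   `mode_abundance` and `guild_abundance` (samples x categories
#'   relative-abundance matrices over included OTUs), and
#'   `unassigned_mass` (per-sample relative abundance not assigned).
#' @export
assign_guilds <- function(table, ref, min_confidence = NA) {
  ref <- validate_guild_reference(as.data.frame(ref))
  if (!is.na(min_confidence)) {
    ord <- c("possible" = 1, "probable" = 2, "highly probable" = 3)
    keep <- ord[tolower(ref$confidence)] >= ord[[tolower(min_confidence)]]
    ref <- ref[keep, , drop = FALSE]
    if (nrow(ref) == 0) stop("no reference records at the requested confidence")
  }
  ref$level <- tolower(ref$level)
  ref_key <- paste(ref$level, tolower(ref$taxon))

  # ranks from most to least specific
  rank_order <- rev(TAX_RANKS)
  otus <- table$taxonomy$otu_id
  asg <- data.frame(otu_id = otus, matched_taxon = NA_character_,
                    matched_level = NA_character_,
                    trophic_mode = NA_character_, guild = NA_character_,
                    confidence = NA_character_,
                    status = "unassigned", stringsAsFactors = FALSE)
  for (i in seq_along(otus)) {
    for (r in rank_order) {
      lab <- table$taxonomy[[r]][i]
      if (startsWith(lab, "unclassified_")) next
      hit <- match(paste(r, tolower(lab)), ref_key)
      if (!is.na(hit)) {
        asg$matched_taxon[i] <- ref$taxon[hit]
        asg$matched_level[i] <- ref$level[hit]
        asg$trophic_mode[i]  <- ref$trophic_mode[hit]
        asg$guild[i]         <- ref$guild[hit]
        asg$confidence[i]    <- ref$confidence[hit]
        n_guilds <- length(strsplit(ref$guild[hit], "|", fixed = TRUE)[[1]])
        asg$status[i] <- if (n_guilds >= 2) "multi_guild" else "included"
        break
      }
    }
  }

  rel <- relative_abundance(table)
  inc <- asg$status == "included"
  agg_by <- function(labels) {
    if (!any(inc)) return(matrix(0, nrow(rel), 0, dimnames = list(rownames(rel), NULL)))
    t(rowsum(t(rel[, inc, drop = FALSE]), group = labels[inc]))
  }
  structure(list(assignments = asg,
                 mode_abundance = agg_by(asg$trophic_mode),
                 guild_abundance = agg_by(asg$guild),
                 unassigned_mass = rowSums(rel[, !inc, drop = FALSE])),
            class = "guild_profile")
}

#' Compare guild / trophic-mode abundances between groups
#'
#' For every trophic mode and guild, tests the per-sample relative
#' abundances between metadata groups: Wilcoxon rank-sum for two groups,
#' Kruskal-Wallis for more.  Categories absent from all samples are
#' skipped (recorded in the `skipped` attribute).
#'
#' @param profile a `guild_profile` from [assign_guilds()].
#' @param metadata the sample metadata of the profiled table.
#' @param grouping metadata column (default "compartment").
#' @param what "mode", "guild" or "both".
#' @return data.frame with category, type, statistic, p, group means.
#' @export
compare_guilds <- function(profile, metadata, grouping = "compartment",
                           what = c("both", "mode", "guild")) {
  what <- match.arg(what)
  mats <- list()
  if (what %in% c("both", "mode"))  mats$mode  <- profile$mode_abundance
  if (what %in% c("both", "guild")) mats$guild <- profile$guild_abundance
  g <- metadata[[grouping]]
  lv <- sort(unique(g))
  rows <- list(); skipped <- character()
  for (type in names(mats)) {
    m <- mats[[type]]
    for (cat in colnames(m)) {
      v <- m[, cat]
      if (all(v == 0)) { skipped <- c(skipped, cat); next }
      vals <- split(v, g)[lv]
      res <- if (length(lv) == 2)
        wilcoxon_rank_sum(vals[[1]], vals[[2]])
      else kruskal_wallis(vals)
      means <- vapply(vals, mean, 0)
      rows[[length(rows) + 1]] <- data.frame(
        category = cat, type = type, statistic = res$statistic,
        p_value = res$p_value,
        t(stats::setNames(means, paste0("mean_", lv))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    message("skipped categories absent from all samples: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
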