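#' Shannon diversity of a count vector
#'
#' H' = -sum p_i ln p_i over OTUs with nonzero counts, in natural-log
#' units (nats), the Mothur convention.
#'
#' @param counts non-negative numeric vector of per-OTU reads.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("shannon: sample has no reads")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Observed OTU richness
#' @param counts non-negative numeric vector of per-OTU reads.
#' @return number of OTUs with count > 0.
#' @export
richness <- function(counts) sum(counts > 0)

#' Pielou evenness
#'
#' J' = H' / ln S.  For a single-OTU sample (S = 1) the 0/0 ratio is
#' defined as 1: a one-taxon community is trivially even.
#'
#' @param counts non-negative numeric vector of per-OTU reads.
#' @return evenness in \[0, 1\].
#' @export
evenness <- function(counts) {
  s <- richness(counts)
  if (s == 0) stop("evenness: sample has no reads")
  if (s == 1) return(1)
  shannon(counts) / log(s)
}

#' Good's coverage
#'
#' 1 - F1/N where F1 is the number of singleton OTUs (count exactly 1)
#' and N the sample's total reads; the completeness-of-sampling index.
#'
#' @param counts non-negative numeric vector of per-OTU reads.
#' @return coverage in \[0, 1\].
#' @export
goods_coverage <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("goods_coverage: sample has no reads")
  1 - sum(counts == 1) / n
}

#' Per-sample alpha diversity profile
#'
#' @param table an [otu_table()].
#' @return data.frame with columns sample_id, shannon, richness,
#'   evenness, coverage, plus the sample metadata.
#' @export
diversity_profile <- function(table) {
  cnt <- table$counts
  out <- data.frame(
    sample_id = rownames(cnt),
    shannon   = apply(cnt, 1, shannon),
    richness  = apply(cnt, 1, richness),
    evenness  = apply(cnt, 1, evenness),
    coverage  = apply(cnt, 1, goods_coverage),
    stringsAsFactors = FALSE)
  cbind(out, table$metadata[out$sample_id,
                            c("compartment", "species", "replicate")])
}

#' Two-group Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test.  With `mode = "auto"` the exact
#' null distribution is used when both groups have at most 10
#' observations and the pooled data carry no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#' Exact mode refuses ties and falls back to the approximation.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param mode "auto", "exact" or "normal_approx".
#' @return list with `statistic` (W), `p_value`, `group_medians`,
#'   `test_name`, `mode_used`; class `group_test`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warning("constant pooled data; p set to 1")
    return(structure(list(statistic = length(x) * length(y) / 2, p_value = 1,
                          group_medians = c(stats::median(x), stats::median(y)),
                          test_name = "wilcoxon_rank_sum", mode_used = "degenerate"),
                     class = "group_test"))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- switch(mode,
                  auto = !ties && length(x) <= 10 && length(y) <= 10,
                  exact = !ties,
                  normal_approx = FALSE)
  if (mode == "exact" && ties)
    warning("ties present; falling back to normal approximation")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 group_medians = c(stats::median(x), stats::median(y)),
                 test_name = "wilcoxon_rank_sum",
                 mode_used = if (exact) "exact" else "normal_approx"),
            class = "group_test")
}

#' Kruskal-Wallis H test for three or more groups
#'
#' Tie-corrected H statistic referred to a chi-squared distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups list of >= 3 numeric vectors, each of length >= 2.
#' @return list with `statistic` (H), `p_value`, `df`, `group_medians`,
#'   `test_name`; class `group_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 3)
    stop("kruskal_wallis needs >= 3 groups; use wilcoxon_rank_sum for 2")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 observations")
  if (length(unique(unlist(groups))) == 1) {
    warning("constant pooled data; p set to 1")
    return(structure(list(statistic = 0, p_value = 1, df = length(groups) - 1,
                          group_medians = vapply(groups, stats::median, 0),
                          test_name = "kruskal_wallis"),
                     class = "group_test"))
  }
  kt <- stats::kruskal.test(groups)
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                 df = unname(kt$parameter),
                 group_medians = vapply(groups, stats::median, 0),
                 test_name = "kruskal_wallis"),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  invisible(x)
}

#' Compare an alpha-diversity index between metadata groups
#'
#' Dispatches to the Wilcoxon rank-sum test for two groups and the
#' Kruskal-Wallis H test for more.
#'
#' @param profile data.frame from [diversity_profile()].
#' @param index column name, e.g. "shannon".
#' @param grouping metadata column, e.g. "compartment".
#' @return a `group_test` with an added `groups` element.
#' @export
compare_diversity <- function(profile, index = "shannon",
                              grouping = "compartment") {
  g <- profile[[grouping]]
  lv <- sort(unique(g))
  vals <- split(profile[[index]], g)[lv]
  res <- if (length(lv) == 2) wilcoxon_rank_sum(vals[[1]], vals[[2]])
         else kruskal_wallis(vals)
  res$groups <- lv
  res
}
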