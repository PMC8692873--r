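#' Bray-Curtis dissimilarity matrix
#'
#' BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i) over OTUs, computed on
#' counts (or any abundance matrix): 0 for identical samples, 1 for
#' samples with disjoint support.
#'
#' @param x an [otu_table()] or a samples x taxa abundance matrix.
#' @return object of class `dist` with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  empty <- rowSums(m) == 0
  if (any(empty))
    stop("all-zero sample(s): ", paste(rownames(m)[empty], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the Gower-centred matrix -1/2 J D^2 J.
#' Coordinates are eigenvectors scaled by sqrt(lambda) for positive
#' eigenvalues; negative eigenvalues are reported but excluded from the
#' coordinates and from the proportion of variance explained.
#'
#' @param d a `dist` or square symmetric dissimilarity matrix.
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (descending, all of them), `proportion_explained` (over positive
#'   eigenvalues); class `pcoa_result`.
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("pcoa requires a symmetric dissimilarity matrix")
  n <- nrow(m)
  fit <- suppressWarnings(           # negative eigenvalues are expected
    stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = eig[pos] / sum(eig[pos])),
            class = "pcoa_result")
}

#' PERMANOVA (Adonis) for a single grouping factor
#'
#' Permutational partitioning of the dissimilarity matrix's sum of
#' squares by one grouping factor: pseudo-F = (SS_between/(k-1)) /
#' (SS_within/(n-k)), R^2 = SS_between/SS_total, and p = (1 + #{permuted
#' F >= observed F}) / (1 + n_permutations) under label permutation.
#' Thin deterministic wrapper around [vegan::adonis2()].
#'
#' @param d a `dist` or square dissimilarity matrix.
#' @param grouping factor or character vector, one label per sample.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed; the permutation stream is reproducible.
#' @return list with `pseudo_F`, `R2`, `p_value`, `n_permutations`,
#'   `grouping_name`, `ss` (between/within/total); class `permanova_result`.
#' @export
permanova <- function(d, grouping, n_permutations = 999, seed = 1,
                      grouping_name = deparse(substitute(grouping))) {
  m <- as.matrix(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != nrow(m))
    stop("grouping length does not match the distance matrix")
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("permanova needs >= 2 groups")
  if (any(sizes < 2))
    stop("group(s) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  set.seed(seed)
  df <- data.frame(g = grouping)
  fit <- vegan::adonis2(stats::as.dist(m) ~ g, data = df,
                        permutations = n_permutations)
  ss <- c(between = fit$SumOfSqs[1], within = fit$SumOfSqs[2],
          total = fit$SumOfSqs[3])
  structure(list(pseudo_F = fit$F[1],
                 R2 = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1],
                 n_permutations = n_permutations,
                 grouping_name = grouping_name,
                 ss = ss),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$grouping_name, x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}
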