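#' Read a per-sample soil chemistry table
#'
#' TSV with `sample_id` plus the seven factor columns pH, SWC, TOC, TN,
#' TP, AP, AK.
#'
#' @param path TSV file.
#' @return data.frame with rownames = sample ids.
#' @export
read_env_table <- function(path) {
  env <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           quote = "")
  rownames(env) <- env$sample_id
  env
}

ENV_FACTORS <- c("pH", "SWC", "TOC", "TN", "TP", "AP", "AK")

#' Bipartite OTU-environment correlation network
#'
#' Correlates each OTU's per-sample relative abundance with each
#' environmental factor and keeps an edge under the same thresholding
#' contract as [build_network()]: |rho| >= `min_abs_corr` and adjusted
#' p < `alpha` (adjustment over all OTU x factor tests).  The result is
#' bipartite by construction: no OTU-OTU or factor-factor edges.
#'
#' @param table an [otu_table()] restricted to abundant OTUs, >= 4 samples.
#' @param env environment data.frame (samples x factors); rows are
#'   matched to the table's samples by name.
#' @param factors factor columns to use (default the seven soil factors
#'   present in `env`).
#' @param corr_method,min_abs_corr,alpha,p_adjust as in [build_network()].
#' @return object of class `env_association`: `edges` (otu, factor, rho,
#'   p, p_adj, sign), `factor_degree`, `otu_degree`, `params`.
#' @export
bipartite_network <- function(table, env, factors = NULL,
                              corr_method = "spearman",
                              min_abs_corr = 0.8, alpha = 0.05,
                              p_adjust = c("none", "bh", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(table$counts) < 4) stop("bipartite_network needs >= 4 samples")
  if (is.null(factors)) factors <- intersect(ENV_FACTORS, colnames(env))
  emat <- as.matrix(env[rownames(table$counts), factors, drop = FALSE])
  if (any(is.na(emat))) stop("environment table lacks sample(s) of the OTU table")
  keepf <- apply(emat, 2, stats::sd) > 0
  if (any(!keepf))
    warning("constant factor(s) excluded: ",
            paste(factors[!keepf], collapse = ", "))
  emat <- emat[, keepf, drop = FALSE]
  rel <- relative_abundance(table)
  keepo <- apply(rel, 2, stats::sd) > 0
  rel <- rel[, keepo, drop = FALSE]
  n <- nrow(rel)
  if (corr_method == "spearman") {
    r <- stats::cor(apply(rel, 2, rank), apply(emat, 2, rank))
  } else {
    r <- stats::cor(rel, emat)
  }
  rc <- pmin(pmax(r, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rc) >= 1 - 1e-12] <- 0
  padj <- matrix(stats::p.adjust(p, method = c(bh = "BH",
                                               bonferroni = "bonferroni",
                                               none = "none")[[p_adjust]]),
                 nrow = nrow(p), dimnames = dimnames(p))
  keep <- which(abs(r) >= min_abs_corr & padj < alpha, arr.ind = TRUE)
  edges <- data.frame(otu = rownames(r)[keep[, 1]],
                      factor = colnames(r)[keep[, 2]],
                      rho = r[keep], p = p[keep], p_adj = padj[keep],
                      sign = ifelse(r[keep] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  factor_degree <- stats::setNames(
    as.integer(table(factor(edges$factor, levels = colnames(emat)))),
    colnames(emat))
  otu_degree <- table(edges$otu)
  structure(list(edges = edges, factor_degree = factor_degree,
                 otu_degree = otu_degree,
                 params = list(corr_method = corr_method,
                               min_abs_corr = min_abs_corr,
                               alpha = alpha, p_adjust = p_adjust)),
            class = "env_association")
}

#' @export
print.env_association <- function(x, ...) {
  cat(sprintf("env_association: %d OTU-factor edges\n", nrow(x$edges)))
  print(sort(x$factor_degree, decreasing = TRUE))
  invisible(x)
}

#' Ordinary least-squares regression of Shannon diversity on one factor
#'
#' Simple linear regression H = a + b * factor with the two-sided t-test
#' (n - 2 df) for the slope; R^2 equals the squared Pearson correlation
#' of the two variables.
#'
#' @param diversity data.frame from [diversity_profile()] (or any frame
#'   with `sample_id` and the response column).
#' @param env environment data.frame with rownames = sample ids.
#' @param factor factor column name, e.g. "TOC".
#' @param response response column (default "shannon").
#' @return one-row data.frame: factor, slope, intercept, r_squared,
#'   p_value, n.
#' @export
diversity_regression <- function(diversity, env, factor,
                                 response = "shannon") {
  x <- env[diversity$sample_id, factor]
  y <- diversity[[response]]
  if (length(y) < 3) stop("diversity_regression needs >= 3 samples")
  if (stats::sd(x) == 0) stop("zero-variance factor: ", factor)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(factor = factor,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = sm$r.squared,
             p_value = sm$coefficients[2, 4],
             n = length(y), stringsAsFactors = FALSE)
}
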