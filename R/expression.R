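#' Counts per million
#'
#' `cpm[g, s] = 1e6 * counts[g, s] / colsum[s]`.
#'
#' @param counts genes x samples non-negative matrix.
#' @return matrix of the same shape.
#' @export
cpm <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  libs <- colSums(counts)
  if (any(libs == 0)) stop("zero library size in column(s): ",
                           paste(which(libs == 0), collapse = ", "))
  sweep(counts, 2, libs, "/") * 1e6
}

#' Expression keep-filter on counts per million
#'
#' A gene is kept iff its CPM exceeds `min_cpm` (strictly) in at least
#' `min_samples` samples.
#'
#' @param cpm_matrix genes x samples CPM matrix (see [cpm()]).
#' @param min_cpm strict CPM threshold per sample.
#' @param min_samples minimum number of qualifying samples (inclusive).
#' @return named logical vector of kept genes.
#' @export
keep_filter <- function(cpm_matrix, min_cpm = 1, min_samples = 2) {
  rowSums(cpm_matrix > min_cpm) >= min_samples
}

#' Differential-expression gate
#'
#' Benjamini-Hochberg adjustment of the supplied p values, then a gene is
#' called differential iff its linear fold change exceeds `fc_threshold`
#' (strictly, in either direction) and its FDR is below `fdr_threshold`
#' (strictly). The p values and fold changes may come from any per-gene
#' test; see [ttest_per_gene()] for the simple two-sample test used on
#' synthetic cohorts.
#'
#' @param log2fc per-gene log2 fold change.
#' @param pvalues per-gene raw p values in `[0, 1]`.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param fdr_threshold FDR threshold; 0.01 by default, with 0.05 as the
#'   common relaxed alternative.
#' @return list with `de` (logical), `fdr` (BH-adjusted p values).
#' @export
de_gate <- function(log2fc, pvalues, fc_threshold = 1.5,
                    fdr_threshold = 0.01) {
  stopifnot(length(log2fc) == length(pvalues),
            all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  if (length(pvalues) == 0)
    return(list(de = logical(0), fdr = numeric(0)))
  fdr <- stats::p.adjust(pvalues, method = "BH")
  de <- abs(log2fc) > log2(fc_threshold) & fdr < fdr_threshold
  de[is.na(de)] <- FALSE
  list(de = de, fdr = fdr)
}

#' Per-gene two-sample test on log2 CPM
#'
#' Two-sample t test of `log2(CPM + 1)` per gene between two groups,
#' returning the inputs [de_gate()] expects. The pooled-variance form is
#' the default: with three samples per group the Welch degrees of freedom
#' collapse to ~2 and the test loses essentially all power, while equal
#' per-group variance is the correct model for replicate cohorts drawn
#' from a common dispersion.
#'
#' @param counts genes x samples count matrix.
#' @param groups two-level group labels per sample.
#' @param var_equal pooled (`TRUE`, default) or Welch (`FALSE`) variance.
#' @return data.frame with `gene`, `log2fc` (group 2 vs group 1), `p`.
#' @export
ttest_per_gene <- function(counts, groups, var_equal = TRUE) {
  glev <- unique(groups)
  stopifnot(length(glev) == 2)
  lc <- log2(cpm(counts) + 1)
  a <- lc[, groups == glev[1], drop = FALSE]
  b <- lc[, groups == glev[2], drop = FALSE]
  p <- vapply(seq_len(nrow(lc)), function(g) {
    if (stats::sd(a[g, ]) == 0 && stats::sd(b[g, ]) == 0) return(1)
    stats::t.test(b[g, ], a[g, ], var.equal = var_equal)$p.value
  }, numeric(1))
  data.frame(gene = rownames(counts), log2fc = rowMeans(b) - rowMeans(a),
             p = p, row.names = NULL)
}

#' Per-gene moderated test on log2 CPM
#'
#' Empirical-Bayes moderated t statistics (limma `lmFit` + `eBayes`) on
#' `log2(CPM + 1)`, the standard choice for small-replicate designs:
#' variance moderation recovers the power that a plain two-sample test
#' loses to its 4-df variance estimate at n = 3 per group.
#'
#' @inheritParams ttest_per_gene
#' @return data.frame with `gene`, `log2fc` (group 2 vs group 1), `p`.
#' @export
moderated_per_gene <- function(counts, groups) {
  glev <- unique(groups)
  stopifnot(length(glev) == 2)
  lc <- log2(cpm(counts) + 1)
  design <- stats::model.matrix(~ factor(groups, levels = glev))
  fit <- limma::eBayes(limma::lmFit(lc, design))
  data.frame(gene = rownames(counts), log2fc = fit$coefficients[, 2],
             p = fit$p.value[, 2], row.names = NULL)
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability `P(X >= k)` of observing at least the realized
#' overlap between a differential gene set and a pathway under random
#' draws from the gene universe.
#'
#' @param de_set character vector of differential genes.
#' @param pathway_set character vector of pathway genes.
#' @param universe character vector (or size) of the gene universe; both
#'   sets must be contained in it.
#' @return p value.
#' @examples
#' hypergeom_overlap(letters[1:5], letters[1:5], letters[1:10]) # 1/252
#' @export
hypergeom_overlap <- function(de_set, pathway_set, universe) {
  if (length(universe) == 1 && is.numeric(universe)) {
    n_u <- universe
    if (length(unique(de_set)) > n_u || length(unique(pathway_set)) > n_u)
      stop("sets exceed universe")
  } else {
    n_u <- length(unique(universe))
    if (!all(de_set %in% universe) || !all(pathway_set %in% universe))
      stop("sets exceed universe")
  }
  de_set <- unique(de_set); pathway_set <- unique(pathway_set)
  k <- length(intersect(de_set, pathway_set))
  stats::phyper(k - 1, length(pathway_set), n_u - length(pathway_set),
                length(de_set), lower.tail = FALSE)
}

#' Principal-component projection of log CPM
#'
#' Gene-centered (no scaling) decomposition of `log2(CPM + 1)`; samples
#' are projected onto the principal axes and genes are ranked by the
#' magnitude of their loading on each component ("contribution").
#'
#' @param log_cpm genes x samples matrix of log2 CPM values.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `loadings`
#'   (genes x components), `sdev`, `degenerate` flag (constant input).
#' @export
pca_project <- function(log_cpm, n_components = 2) {
  stopifnot(ncol(log_cpm) >= 2)
  centered <- log_cpm - rowMeans(log_cpm)
  if (all(abs(centered) < 1e-12)) {
    warning("constant matrix: principal components are degenerate")
    return(list(scores = matrix(0, ncol(log_cpm), n_components),
                loadings = matrix(0, nrow(log_cpm), n_components),
                sdev = rep(0, n_components), degenerate = TRUE))
  }
  pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       sdev = pc$sdev, degenerate = FALSE)
}

#' Rank genes by their contribution to a principal component
#'
#' @param pca result of [pca_project()].
#' @param component which component.
#' @param n number of top genes.
#' @return data.frame `gene`, `loading`, ordered by |loading|.
#' @export
top_loadings <- function(pca, component = 1, n = 25) {
  ld <- pca$loadings[, component]
  ord <- order(abs(ld), decreasing = TRUE)[seq_len(min(n, length(ld)))]
  data.frame(gene = names(ld)[ord], loading = ld[ord], row.names = NULL)
}
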