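#' Library-size-normalized log counts
#'
#' Simple per-cell size factors (total counts divided by their median)
#' followed by `log2(1 + x)`.
#'
#' @param counts genes x cells matrix (dense or sparse).
#' @return dense matrix of normalized log counts.
#' @export
normalized_logcounts <- function(counts) {
  lib <- Matrix::colSums(counts)
  stop_if(any(lib == 0), "cells with zero counts present")
  sf <- lib / stats::median(lib)
  x <- sweep(as.matrix(counts), 2L, sf, "/")
  log2(1 + x)
}

#' Aggregate counts per individual
#'
#' @param counts genes x cells matrix.
#' @param cell_to_individual per-cell individual labels.
#' @param method `"mean"` (mean of counts), `"mean_log"` (mean of
#'   `log2(1 + count)`), or `"sum"` (pseudobulk).
#' @return genes x individuals matrix with the method recorded in
#'   attribute `method`.
#' @export
aggregate_counts <- function(counts, cell_to_individual,
                             method = c("mean", "mean_log", "sum")) {
  method <- match.arg(method)
  stop_if(length(cell_to_individual) != ncol(counts),
          "every cell must be mapped to an individual")
  stop_if(anyNA(cell_to_individual), "unmapped cell (NA individual)")
  f <- factor(cell_to_individual, levels = unique(cell_to_individual))
  x <- if (method == "mean_log") log2(1 + as.matrix(counts))
       else as.matrix(counts)
  ind <- matrix(0, length(f), nlevels(f))
  ind[cbind(seq_along(f), as.integer(f))] <- 1
  sums <- x %*% ind
  n_per <- as.vector(table(f))
  out <- switch(method,
                sum = sums,
                sums %*% diag(1 / n_per, nrow = length(n_per)))
  out <- as.matrix(out)
  dimnames(out) <- list(rownames(counts), levels(f))
  attr(out, "method") <- method
  out
}

#' Percentage of expression variance explained by a factor
#'
#' One-way group-mean decomposition per gene: between-group sum of
#' squares over total sum of squares, times 100. Genes with zero total
#' variance return 0 by convention.
#'
#' @param logcounts genes x cells matrix of (log) expression.
#' @param factor_labels per-cell factor labels (>= 2 levels).
#' @return numeric vector, one percentage per gene.
#' @export
variance_explained <- function(logcounts, factor_labels) {
  f <- factor(factor_labels)
  stop_if(nlevels(f) < 2L, "factor needs at least 2 levels")
  x <- as.matrix(logcounts)
  gm <- rowMeans(x)
  tot <- rowSums((x - gm)^2)
  ind <- matrix(0, length(f), nlevels(f))
  ind[cbind(seq_along(f), as.integer(f))] <- 1
  n_per <- as.vector(table(f))
  grp_means <- (x %*% ind) %*% diag(1 / n_per, nrow = length(n_per))
  between <- as.vector(((grp_means - gm)^2) %*% n_per)
  out <- ifelse(tot == 0, 0, 100 * between / tot)
  names(out) <- rownames(x)
  out
}

#' Silhouette widths of cells under a clustering factor
#'
#' Standard silhouette widths on Euclidean distances between cells'
#' normalized log-count profiles, with the given labels (e.g. the
#' individual) as clusters. Cells in singleton clusters get width 0.
#'
#' @param logcounts genes x cells matrix.
#' @param cluster_labels per-cell cluster labels (>= 2 clusters).
#' @return numeric vector of per-cell widths in `[-1, 1]`.
#' @export
silhouette_widths <- function(logcounts, cluster_labels) {
  f <- factor(cluster_labels)
  stop_if(nlevels(f) < 2L, "need at least 2 clusters")
  d <- stats::dist(t(as.matrix(logcounts)))
  sil <- cluster::silhouette(as.integer(f), dist = d)
  widths <- if (is.matrix(sil)) sil[, "sil_width"]
            else rep(0, length(f)) # all-singleton degenerate case
  names(widths) <- colnames(logcounts)
  widths
}

#' Pseudobulk Wilcoxon differential expression test
#'
#' Sums counts per individual, then per gene runs a two-sided Wilcoxon
#' rank-sum test between the two condition cohorts and adjusts p-values
#' across genes with Benjamini-Hochberg.
#'
#' @param counts genes x cells matrix.
#' @param cell_to_individual per-cell individual labels.
#' @param condition_labels per-individual condition labels, named by
#'   individual (or in the order individuals first appear).
#' @return data.frame with `gene_id`, `stat` (rank-sum statistic),
#'   `lfc` (log2 fold change of pseudobulk means), `p`, `q`.
#' @export
de_test_pseudobulk <- function(counts, cell_to_individual,
                               condition_labels) {
  agg <- aggregate_counts(counts, cell_to_individual, method = "sum")
  inds <- colnames(agg)
  cond <- if (!is.null(names(condition_labels)))
    condition_labels[inds] else condition_labels
  stop_if(length(cond) != ncol(agg) || anyNA(cond),
          "need one condition label per individual")
  lv <- unique(cond)
  stop_if(length(lv) != 2L, "exactly two conditions required")
  a <- cond == lv[1L]; b <- cond == lv[2L]
  stop_if(sum(a) < 2L || sum(b) < 2L,
          "each condition needs at least 2 individuals")
  res <- apply(agg, 1L, function(x) {
    w <- suppressWarnings(stats::wilcox.test(x[a], x[b]))
    c(w$statistic, w$p.value)
  })
  p <- res[2L, ]
  lfc <- log2((rowMeans(agg[, a, drop = FALSE]) + 1) /
                (rowMeans(agg[, b, drop = FALSE]) + 1))
  data.frame(gene_id = rownames(agg), stat = res[1L, ], lfc = lfc,
             p = p, q = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-based inverse normal transform
#'
#' @param x numeric vector.
#' @return standard normal quantiles at `(rank - 0.5) / n` positions.
#' @export
inverse_normal_transform <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Simplified cis-eQTL mapping on aggregated expression
#'
#' Per gene: inverse-normal transform the aggregated expression across
#' individuals, regress it on the dosage of every SNP within
#' `window_bp` of the gene (ordinary least squares, optionally after
#' residualizing on covariates), record the top SNP by p-value, and
#' BH-adjust the top p-values across genes. Genes without a cis-SNP are
#' skipped and reported in attribute `skipped`.
#'
#' @param agg genes x individuals aggregated expression (see
#'   [aggregate_counts()]).
#' @param G a [genotype_matrix()] covering the aggregated individuals.
#' @param genes a [gene_annotation()] for the aggregated genes.
#' @param window_bp cis window half-width in bp.
#' @param covariates optional individuals x k numeric matrix of
#'   covariates regressed out of expression and dosage first.
#' @return data.frame with `gene_id`, `snp_id`, `beta`, `se`, `p`, `q`
#'   for each mapped gene; attribute `skipped` lists unmapped genes.
#' @export
map_eqtl_simple <- function(agg, G, genes, window_bp = 1e5,
                            covariates = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  inds <- colnames(agg)
  stop_if(!all(inds %in% G$sample_ids),
          "individuals missing from genotypes")
  n <- length(inds)
  if (n < 20L)
    warning("fewer than 20 individuals; eQTL mapping is underpowered")
  dos <- G$dosage[, inds, drop = FALSE]
  resid_on <- function(y, X) stats::lm.fit(cbind(1, X), y)$residuals
  rows <- vector("list", nrow(genes))
  skipped <- character(0)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    ai <- match(gid, rownames(agg))
    if (is.na(ai)) { skipped <- c(skipped, gid); next }
    cis <- which(G$chrom == genes$chrom[i] &
                   abs(G$pos - genes$pos[i]) <= window_bp)
    if (length(cis) == 0L) { skipped <- c(skipped, gid); next }
    if (stats::sd(agg[ai, ]) == 0) { skipped <- c(skipped, gid); next }
    y <- inverse_normal_transform(agg[ai, ])
    X <- t(dos[cis, , drop = FALSE])
    if (!is.null(covariates)) {
      y <- resid_on(y, covariates)
      X <- apply(X, 2L, resid_on, X = covariates)
    }
    sdx <- apply(X, 2L, stats::sd)
    ok <- sdx > 0
    if (!any(ok)) { skipped <- c(skipped, gid); next }
    r <- suppressWarnings(as.vector(stats::cor(y, X[, ok, drop = FALSE])))
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    top <- which.min(p)
    beta <- r[top] * stats::sd(y) / sdx[ok][top]
    se <- if (abs(tt[top]) > 0) abs(beta / tt[top]) else NA_real_
    rows[[i]] <- data.frame(gene_id = gid,
                            snp_id = G$snp_ids[cis[ok][top]],
                            beta = beta, se = se, p = p[top],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  stop_if(is.null(out), "no gene could be mapped")
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  if (length(skipped) > 0)
    message(sprintf("%d genes skipped (no cis-SNP or no aggregate)",
                    length(skipped)))
  attr(out, "skipped") <- skipped
  out
}

#' Score discoveries against the simulated truth
#'
#' @param truth_positive logical vector (named by gene) of ground-truth
#'   positives (e.g. eGene or DE status from the simulation key).
#' @param calls data.frame with `gene_id` and `q` columns (e.g. from
#'   [map_eqtl_simple()] or [de_test_pseudobulk()]).
#' @param q_threshold significance threshold on `q`.
#' @return an object of class `confusion_summary`: TP/TN/FP/FN counts,
#'   `tpr = TP/(TP+FN)` and `fdr = FP/(TP+FP)`; an undefined rate (zero
#'   denominator) is reported as 0 with flag `undefined_fdr`/
#'   `undefined_tpr`.
#' @export
score_discoveries <- function(truth_positive, calls, q_threshold = 0.05) {
  stop_if(is.null(names(truth_positive)), "truth must be named by gene")
  stop_if(!all(calls$gene_id %in% names(truth_positive)),
          "calls contain genes absent from the truth")
  sig_genes <- calls$gene_id[calls$q < q_threshold]
  tested <- calls$gene_id
  truth <- truth_positive[tested]
  called <- tested %in% sig_genes
  tp <- sum(truth & called); fp <- sum(!truth & called)
  fn <- sum(truth & !called); tn <- sum(!truth & !called)
  tpr <- if (tp + fn == 0) 0 else tp / (tp + fn)
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, tpr = tpr,
                 fdr = fdr, undefined_tpr = (tp + fn == 0),
                 undefined_fdr = (tp + fp == 0),
                 n_tests = length(tested),
                 q_threshold = q_threshold),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Confusion at q < %.3g over %d tests\n", x$q_threshold,
              x$n_tests))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  TPR %.3f%s  FDR %.3f%s\n", x$tpr,
              if (x$undefined_tpr) " (undefined, no positives)" else "",
              x$fdr,
              if (x$undefined_fdr) " (undefined, no calls)" else ""))
  invisible(x)
}

#' Down-sample cells per individual without replacement
#'
#' @param cells cell metadata with `individual` column.
#' @param n_per_individual target cells per individual (individuals
#'   with fewer cells keep all of them).
#' @param seed integer seed.
#' @return integer indices of the retained cells.
#' @export
downsample_cells <- function(cells, n_per_individual, seed = 1L) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_len(nrow(cells)), cells$individual),
                       function(ix) {
                         if (length(ix) <= n_per_individual) ix
                         else sort(sample(ix, n_per_individual))
                       }), use.names = FALSE)
  sort(idx)
}
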