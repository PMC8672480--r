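#' Estimate population-level parameters from an expression matrix
#'
#' Fits the population layer of the model to a genes x individuals
#' expression matrix (bulk RNA-seq or aggregated single-cell counts).
#' Lowly expressed genes (value below 0.1 in more than 50% of
#' individuals) are excluded. A gamma distribution is fit to the
#' surviving gene means, genes are partitioned into `n_bins` equal-count
#' bins by mean, and a gamma distribution is fit to the coefficient of
#' variation (sd/mean across individuals) within each bin, capturing the
#' mean-variance trend.
#'
#' @param expr numeric matrix, genes in rows, individuals in columns.
#' @param n_bins number of equal-count gene-mean bins.
#' @return a [pop_params()] object with fitted values and recorded bin
#'   edges.
#' @export
estimate_population_params <- function(expr, n_bins = 10L) {
  expr <- as.matrix(expr)
  stop_if(length(expr) == 0L, "empty expression matrix")
  stop_if(ncol(expr) < 2L, "need at least 2 individuals")
  n_bins <- as.integer(n_bins)

  low <- rowMeans(expr < 0.1) > 0.5
  expr <- expr[!low, , drop = FALSE]
  stop_if(nrow(expr) == 0L, "no expressed genes")
  stop_if(nrow(expr) < n_bins,
          sprintf("only %d genes survive filtering; need >= n_bins (%d)",
                  nrow(expr), n_bins))

  means <- rowMeans(expr)
  mean_fit <- fit_gamma(means)

  sds <- apply(expr, 1L, stats::sd)
  cv <- sds / means

  # equal-count bins by mean; ties broken by order of appearance
  r <- rank(means, ties.method = "first")
  bin <- ceiling(r * n_bins / length(r))
  edges <- numeric(n_bins + 1L)
  edges[1L] <- 0
  edges[n_bins + 1L] <- Inf
  if (n_bins > 1L) {
    for (k in seq_len(n_bins - 1L)) {
      edges[k + 1L] <- (max(means[bin == k]) + min(means[bin == k + 1L])) / 2
    }
  }
  stop_if(is.unsorted(edges, strictly = TRUE),
          "cannot form distinct equal-count bins (tied gene means)")

  cv_shape <- cv_rate <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    xk <- cv[bin == k & cv > 0]
    stop_if(length(xk) < 2L,
            sprintf("bin %d has fewer than 2 genes with positive cv", k))
    fk <- fit_gamma(xk)
    cv_shape[k] <- fk$shape
    cv_rate[k] <- fk$rate
  }

  pop_params(mean_shape = mean_fit$shape, mean_rate = mean_fit$rate,
             n_bins = n_bins, bin_edges = edges,
             cv_shape_per_bin = cv_shape, cv_rate_per_bin = cv_rate,
             similarity_scale = 1)
}

#' Estimate eQTL effect-size parameters from mapping summary statistics
#'
#' Fits a gamma distribution to the absolute values of per-gene top
#' eQTL effect sizes from an empirical mapping study. Negative effect
#' sizes are used in magnitude; the number of sign flips is reported as
#' attribute `n_sign_flipped` and in a message.
#'
#' @param betas numeric vector of effect sizes.
#' @return an [eqtl_params()] object with fitted `es_shape`/`es_rate`
#'   (other fields at defaults) and attribute `n_sign_flipped`.
#' @export
estimate_eqtl_params <- function(betas) {
  betas <- betas[is.finite(betas)]
  n_neg <- sum(betas < 0)
  x <- abs(betas)
  x <- x[x > 0]
  stop_if(length(x) < 10L,
          "need at least 10 finite non-zero effect sizes")
  stop_if(stats::var(x) == 0,
          "degenerate effect-size fit: all magnitudes identical")
  fit <- fit_gamma(x)
  if (n_neg > 0)
    message(sprintf("%d negative effect sizes used in magnitude", n_neg))
  out <- eqtl_params(es_shape = fit$shape, es_rate = fit$rate)
  attr(out, "n_sign_flipped") <- n_neg
  out
}

winsorize <- function(x, q = 0.1) {
  lim <- stats::quantile(x, c(q, 1 - q), names = FALSE)
  pmin(pmax(x, lim[1L]), lim[2L])
}

#' Estimate single-cell level parameters from a count matrix
#'
#' Fits the cell-level layer of the model to a genes x cells count
#' matrix from one individual:
#'
#' * log-normal library sizes from per-cell count totals;
#' * gamma gene means from winsorized (10% both tails) means of
#'   library-size-normalized counts, after removing expression outliers;
#' * outlier probability and log-normal factor parameters via an upper
#'   median-absolute-deviation rule (log2 ratio to the median mean
#'   exceeding 2 MADs above its median);
#' * common biological coefficient of variation and its degrees of
#'   freedom from an [edgeR::estimateDisp()] trended dispersion fit;
#' * logistic dropout midpoint/shape from a least-squares fit of
#'   per-gene zero proportion against log mean (kept disabled in the
#'   returned object; enable explicitly to simulate dropout).
#'
#' The winsorization fraction (0.1) and MAD multiplier (2) are fixed
#' constants of the procedure, overridable via arguments.
#'
#' @param counts numeric matrix of counts, genes x cells.
#' @param winsor_q winsorization fraction per tail for the gene-mean fit.
#' @param out_nmads MAD multiplier of the outlier rule.
#' @return an [sc_params()] object.
#' @export
estimate_sc_params <- function(counts, winsor_q = 0.1, out_nmads = 2) {
  counts <- as.matrix(counts)
  stop_if(ncol(counts) < 2L, "need at least 2 cells")
  stop_if(all(counts == 0), "all counts are zero")
  if (ncol(counts) < 100L)
    warning("fewer than 100 cells; single-cell parameter estimates may be unstable")

  lib <- colSums(counts)
  stop_if(any(lib == 0), "cells with zero total counts present; remove them")
  stop_if(stats::var(lib) == 0,
          "degenerate library-size fit: all cells have identical totals")
  lib_fit <- fit_lnorm(lib)

  norm <- t(t(counts) / lib * stats::median(lib))
  means <- rowMeans(norm)
  pos <- means > 0
  lfac <- log2(means[pos] / stats::median(means[pos]))
  thr <- stats::median(lfac) + out_nmads * stats::mad(lfac)
  out_idx <- which(pos)[lfac > thr]
  out_prob <- length(out_idx) / nrow(counts)
  if (length(out_idx) >= 2L) {
    fac <- means[out_idx] / stats::median(means[pos])
    of <- fit_lnorm(fac)
    out_loc <- of$meanlog
    out_scale <- of$sdlog
  } else {
    out_loc <- 4; out_scale <- 0.5 # defaults; too few outliers to fit
  }

  keep <- setdiff(which(pos), out_idx)
  stop_if(length(keep) < 2L, "too few non-outlier expressed genes")
  mean_fit <- fit_gamma(winsorize(means[keep], q = winsor_q))

  disp <- edgeR::estimateDisp(edgeR::DGEList(counts))
  bcv_common <- sqrt(disp$common.dispersion)
  bcv_df <- disp$prior.df[1L]
  if (!is.finite(bcv_df) || bcv_df <= 0) bcv_df <- Inf

  zero_prop <- rowMeans(counts == 0)
  drop_fit <- tryCatch({
    df <- data.frame(x = log(means[pos]), y = zero_prop[pos])
    fit <- stats::nls(y ~ 1 / (1 + exp(-k * (x - x0))), data = df,
                      start = list(x0 = stats::median(df$x), k = -1))
    as.list(stats::coef(fit))
  }, error = function(e) {
    warning("dropout logistic fit failed; keeping default dropout parameters")
    list(x0 = 0, k = -1)
  })

  sc_params(n_genes = nrow(counts),
            mean_shape = mean_fit$shape, mean_rate = mean_fit$rate,
            lib_loc = lib_fit$meanlog, lib_scale = lib_fit$sdlog,
            out_prob = out_prob, out_loc = out_loc, out_scale = out_scale,
            bcv_common = bcv_common, bcv_df = bcv_df,
            dropout_enabled = FALSE,
            dropout_mid = drop_fit$x0, dropout_shape = drop_fit$k)
}
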