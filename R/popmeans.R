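#' Construct a population-means tensor
#'
#' Expected gene means per individual, one slice per cell group. Slices
#' start identical and diverge as group-specific eQTL and DE effects
#' are applied.
#'
#' @param values genes x individuals matrix, or genes x individuals x
#'   groups array.
#' @param gene_ids,individual_ids identifiers.
#' @param groups cell-group names (one slice each).
#' @param conditions per-individual condition labels.
#' @return an object of class `pop_means`.
#' @export
pop_means <- function(values, gene_ids = NULL, individual_ids = NULL,
                      groups = "group1", conditions = NULL) {
  if (length(dim(values)) == 2L) {
    values <- array(rep(values, length(groups)),
                    dim = c(nrow(values), ncol(values), length(groups)))
  }
  stop_if(length(dim(values)) != 3L, "values must be 2- or 3-dimensional")
  stop_if(any(values < 0), "means must be non-negative")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(dim(values)[1]))
  if (is.null(individual_ids))
    individual_ids <- sprintf("sample%03d", seq_len(dim(values)[2]))
  if (is.null(conditions))
    conditions <- rep("condition1", dim(values)[2])
  stop_if(dim(values)[3] != length(groups), "one slice per group required")
  stop_if(length(conditions) != dim(values)[2],
          "one condition label per individual required")
  dimnames(values) <- list(gene_ids, individual_ids, groups)
  structure(list(values = values, gene_ids = gene_ids,
                 individual_ids = individual_ids, groups = groups,
                 conditions = as.character(conditions)),
            class = "pop_means")
}

#' @export
print.pop_means <- function(x, ...) {
  cat(sprintf("Population means: %d genes x %d individuals x %d group%s\n",
              length(x$gene_ids), length(x$individual_ids),
              length(x$groups), if (length(x$groups) == 1L) "" else "s"))
  invisible(x)
}

#' Sample population-wide base gene means
#'
#' Means are drawn from gamma(`mean_shape`, `mean_rate`) of the
#' population parameters. With probability `out_prob` (single-cell
#' parameters) a gene is flagged as an expression outlier and its mean
#' replaced by `median(means)` times a log-normal factor.
#'
#' @param pop a [pop_params()].
#' @param sc an [sc_params()] (outlier parameters).
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return list with `means`, `outlier_flag`, `outlier_factor`.
#' @export
sample_base_means <- function(pop, sc, n_genes, seed = 1L) {
  stop_if(n_genes < 1, "n_genes must be >= 1")
  set.seed(seed)
  lambda <- stats::rgamma(n_genes, shape = pop$mean_shape,
                          rate = pop$mean_rate)
  flag <- stats::runif(n_genes) < sc$out_prob
  fac <- rep(1, n_genes)
  if (any(flag)) {
    fac[flag] <- stats::rlnorm(sum(flag), sc$out_loc, sc$out_scale)
    lambda[flag] <- stats::median(lambda) * fac[flag]
  }
  list(means = lambda, outlier_flag = flag, outlier_factor = fac)
}

bin_of <- function(lambda, pop) {
  b <- findInterval(lambda, pop$bin_edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), pop$n_bins) # genes outside all bins use nearest bin
}

#' Sample per-gene coefficients of variation from the binned trend
#'
#' Each gene draws its across-individual coefficient of variation from
#' the gamma fit of its gene-mean bin, with the rate multiplied by the
#' similarity scale: larger `similarity_scale` shrinks the cv, making
#' individuals more alike.
#'
#' @param lambda base gene means.
#' @param pop a [pop_params()].
#' @param seed integer seed.
#' @return numeric vector of cv values, one per gene.
#' @export
sample_variances <- function(lambda, pop, seed = 1L) {
  set.seed(seed)
  b <- bin_of(lambda, pop)
  stats::rgamma(length(lambda), shape = pop$cv_shape_per_bin[b],
                rate = pop$cv_rate_per_bin[b] * pop$similarity_scale)
}

#' Sample baseline gene means per individual
#'
#' Draws `Normal(lambda_i, lambda_i * sigma_i)` per gene and
#' individual, where the second argument is the standard deviation
#' (sigma is a coefficient of variation, so `lambda * sigma` is an sd).
#' Negative draws are floored at 0.
#'
#' @param lambda base gene means.
#' @param sigma per-gene coefficients of variation.
#' @param individual_ids individual identifiers.
#' @param seed integer seed.
#' @return genes x individuals matrix of baseline means.
#' @export
sample_individual_means <- function(lambda, sigma, individual_ids,
                                    seed = 1L) {
  stop_if(length(lambda) != length(sigma), "lambda and sigma must align")
  set.seed(seed)
  n_ind <- length(individual_ids)
  m <- matrix(stats::rnorm(length(lambda) * n_ind, mean = lambda,
                           sd = lambda * sigma),
              nrow = length(lambda), ncol = n_ind,
              dimnames = list(names(lambda), individual_ids))
  pmax(m, 0)
}

#' Quantile normalize columns to a gamma target
#'
#' Replaces each column's values with the quantiles of
#' gamma(`mean_shape`, `mean_rate`) of the single-cell parameters at
#' plotting positions `(rank - 0.5) / n`, preserving within-column rank
#' order; ties share the average-rank quantile. Applied when population
#' parameters were estimated from bulk data, to move baseline means
#' onto the single-cell expression scale.
#'
#' @param means genes x individuals matrix.
#' @param sc an [sc_params()] providing the target gamma.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(means, sc) {
  means <- as.matrix(means)
  stop_if(nrow(means) < 2L, "need at least 2 genes")
  n <- nrow(means)
  out <- apply(means, 2L, function(col) {
    p <- (rank(col, ties.method = "average") - 0.5) / n
    stats::qgamma(p, shape = sc$mean_shape, rate = sc$mean_rate)
  })
  dimnames(out) <- dimnames(means)
  out
}

#' Apply eQTL effects to baseline means
#'
#' For each keyed eGene the baseline mean becomes
#' `lambda * (1 + G * beta)` where `G` is the individual's minor-allele
#' dosage at the assigned eSNP. Global effects hit every group slice
#' and individual; `group:<g>` effects only slice `g`; `condition:<c>`
#' effects only individuals of cohort `c` (all slices).
#'
#' @param pm a [pop_means()] (carries group and condition labels).
#' @param key an `eqtl_key` from [assign_eqtl()].
#' @param G a [genotype_matrix()] covering all simulated individuals.
#' @return the updated [pop_means()].
#' @export
apply_eqtl <- function(pm, key, G) {
  stopifnot(inherits(pm, "pop_means"), inherits(G, "genotype_matrix"))
  if (nrow(key) == 0L) return(pm)
  missing_ind <- setdiff(pm$individual_ids, G$sample_ids)
  stop_if(length(missing_ind) > 0L,
          "individuals missing from genotypes: ",
          paste(missing_ind, collapse = ", "))
  for (r in seq_len(nrow(key))) {
    gi <- match(key$gene_id[r], pm$gene_ids)
    stop_if(is.na(gi), "unknown gene in key: ", key$gene_id[r])
    si <- match(key$snp_id[r], G$snp_ids)
    stop_if(is.na(si), "eSNP missing from genotypes: ", key$snp_id[r])
    d <- G$dosage[si, pm$individual_ids]
    mult <- 1 + d * key$beta[r]
    spec <- key$specificity[r]
    if (spec == "global") {
      pm$values[gi, , ] <- pm$values[gi, , , drop = FALSE] *
        array(mult, dim = c(1, length(mult), length(pm$groups)))
    } else if (startsWith(spec, "group:")) {
      g <- sub("^group:", "", spec)
      stop_if(!g %in% pm$groups, "unknown group in key: ", g)
      pm$values[gi, , g] <- pm$values[gi, , g] * mult
    } else if (startsWith(spec, "condition:")) {
      cond <- sub("^condition:", "", spec)
      j <- pm$conditions == cond
      stop_if(!any(j), "unknown condition in key: ", cond)
      pm$values[gi, j, ] <- pm$values[gi, j, , drop = FALSE] *
        array(mult[j], dim = c(1, sum(j), length(pm$groups)))
    } else stop("unknown specificity label: ", spec, call. = FALSE)
  }
  pm
}

#' Apply differential-expression effects
#'
#' Per cell group (when more than one is simulated), genes are selected
#' with probability `de_prob` and their slice multiplied by a
#' log-normal factor, inverted with probability `de_down_prob`.
#' Condition effects work the same way but multiply the columns of the
#' cohort's individuals across all slices. Factors are returned for the
#' simulation key (1 for unaffected genes).
#'
#' @param pm a [pop_means()].
#' @param de a [de_params()].
#' @param seed integer seed.
#' @return list with the updated `pm`, `de_factors` (genes x groups)
#'   and `cde_factors` (genes x conditions).
#' @export
apply_de <- function(pm, de, seed = 1L) {
  set.seed(seed)
  n_genes <- length(pm$gene_ids)
  groups <- pm$groups
  conds <- unique(pm$conditions)
  de_fac <- matrix(1, n_genes, length(groups),
                   dimnames = list(pm$gene_ids, groups))
  cde_fac <- matrix(1, n_genes, length(conds),
                    dimnames = list(pm$gene_ids, conds))
  rec <- function(x, k) rep(x, length.out = k)
  if (length(groups) > 1L) {
    prob <- rec(de$de_prob, length(groups))
    down <- rec(de$de_down_prob, length(groups))
    loc <- rec(de$de_loc, length(groups))
    scl <- rec(de$de_scale, length(groups))
    for (g in seq_along(groups)) {
      hit <- stats::runif(n_genes) < prob[g]
      f <- stats::rlnorm(sum(hit), loc[g], scl[g])
      f <- ifelse(stats::runif(sum(hit)) < down[g], 1 / f, f)
      de_fac[hit, g] <- f
      pm$values[, , g] <- pm$values[, , g] * de_fac[, g]
    }
  }
  if (length(conds) > 1L) {
    prob <- rec(de$cde_prob, length(conds))
    down <- rec(de$cde_down_prob, length(conds))
    loc <- rec(de$cde_loc, length(conds))
    scl <- rec(de$cde_scale, length(conds))
    for (cc in seq_along(conds)) {
      hit <- stats::runif(n_genes) < prob[cc]
      f <- stats::rlnorm(sum(hit), loc[cc], scl[cc])
      f <- ifelse(stats::runif(sum(hit)) < down[cc], 1 / f, f)
      cde_fac[hit, cc] <- f
      j <- pm$conditions == conds[cc]
      pm$values[, j, ] <- pm$values[, j, , drop = FALSE] *
        array(cde_fac[, cc], dim = c(n_genes, sum(j), length(groups)))
    }
  }
  list(pm = pm, de_factors = de_fac, cde_factors = cde_fac)
}

#' Use an empirical matrix as baseline means (replication mode)
#'
#' Skips the sampling of base means, variances and per-individual
#' means; the supplied genes x individuals matrix is used directly as
#' the baseline. When flagged as bulk-derived it is quantile normalized
#' to the single-cell gamma target at simulation time. A warning is
#' emitted if eQTL effects are also requested, since simulated effects
#' may compound with effects already present in the data.
#'
#' @param mat strictly non-negative genes x individuals matrix with
#'   gene and individual ids as dimnames.
#' @param bulk logical; `TRUE` if the matrix is bulk-derived and should
#'   be quantile normalized.
#' @return the matrix, annotated with class `empirical_means`.
#' @export
use_empirical_means <- function(mat, bulk = TRUE) {
  mat <- as.matrix(mat)
  stop_if(any(mat < 0), "empirical means must be non-negative")
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("gene%05d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("sample%03d", seq_len(ncol(mat)))
  structure(mat, bulk = isTRUE(bulk), class = c("empirical_means", "matrix"))
}
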