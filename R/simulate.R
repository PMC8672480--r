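#' Simulate a population-scale single-cell RNA-seq dataset
#'
#' Runs the full pipeline: genotype preparation, eQTL assignment,
#' population-mean simulation (base means with outliers, binned-cv
#' variances, per-individual baseline means, optional quantile
#' normalization to the single-cell gamma, eQTL / group-DE /
#' condition-DE effects) and cell-level count simulation (batch design,
#' batch factors, library sizes, BCV-inflated gamma-Poisson sampling,
#' optional dropout). Every stochastic stage draws from its own
#' substream of the master seed, so the returned key together with the
#' genotypes and parameters is sufficient to recreate the simulation
#' bit for bit.
#'
#' @param params a [parameter_set()].
#' @param genotypes optional [genotype_matrix()]; simulated when `NULL`
#'   (10 SNPs per gene, unstructured).
#' @param annotation optional [gene_annotation()]; simulated when
#'   `NULL`.
#' @param empirical_means optional [use_empirical_means()] matrix for
#'   replication mode: the matrix is used as the baseline means and the
#'   sampling of base means/variances/individual means is skipped.
#' @param quantile_norm apply quantile normalization of baseline means
#'   to gamma(`mean_shape`, `mean_rate`) of the single-cell parameters.
#'   Default: `TRUE` for sampled means (population defaults are
#'   bulk-derived) and the `bulk` flag of `empirical_means` in
#'   replication mode.
#' @param keep_intermediates keep the dense cell-level expected means
#'   in the result (memory heavy).
#' @param verbose log one line per pipeline stage.
#' @return an object of class `count_bundle`: sparse integer `counts`
#'   (genes x cells), `cells` metadata (individual, batch, group,
#'   condition), the ground-truth `key` ([sim_key]), `genotypes`,
#'   `annotation`, `params`, per-batch factors and per-cell library
#'   sizes.
#' @export
simulate_population <- function(params, genotypes = NULL,
                                annotation = NULL,
                                empirical_means = NULL,
                                quantile_norm = NULL,
                                keep_intermediates = FALSE,
                                verbose = FALSE) {
  stopifnot(inherits(params, "parameter_set"))
  sc <- params$sc; pop <- params$pop; eqtl <- params$eqtl
  de <- params$de; design <- params$design
  master <- design$master_seed
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  replication <- !is.null(empirical_means)
  if (replication) {
    stopifnot(inherits(empirical_means, "empirical_means"))
    n_genes <- nrow(empirical_means)
    n_ind <- ncol(empirical_means)
    ind_ids <- colnames(empirical_means)
    gene_ids <- rownames(empirical_means)
    if (eqtl$eqtl_prob > 0)
      warning("adding simulated eQTL effects in replication mode may compound with effects already present in the empirical means")
  } else {
    n_genes <- sc$n_genes
    n_ind <- design$n_individuals
    ind_ids <- NULL
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  }

  genotypes <- stage("genotypes", {
    if (is.null(genotypes)) {
      G <- simulate_genotypes(
        n_snps = 10L * n_genes, n_individuals = n_ind,
        maf_range = c(eqtl$maf_min, eqtl$maf_max),
        seed = substream_seed(master, "genotypes"))
      if (!is.null(ind_ids)) {
        colnames(G$dosage) <- ind_ids
        G$sample_ids <- ind_ids
      }
      G
    } else {
      stopifnot(inherits(genotypes, "genotype_matrix"))
      G <- filter_genotypes(genotypes, maf_min = 0, max_missing = 0)
      if (is.null(ind_ids)) {
        stop_if(ncol(G$dosage) < n_ind,
                sprintf("genotypes cover %d individuals; %d requested",
                        ncol(G$dosage), n_ind))
        G$dosage <- G$dosage[, seq_len(n_ind), drop = FALSE]
        G$sample_ids <- G$sample_ids[seq_len(n_ind)]
      } else {
        stop_if(!all(ind_ids %in% G$sample_ids),
                "genotypes are missing individuals of the empirical matrix")
        G$dosage <- G$dosage[, ind_ids, drop = FALSE]
        G$sample_ids <- ind_ids
      }
      af <- rowMeans(G$dosage) / 2
      G$maf <- pmin(af, 1 - af)
      G
    }
  })
  if (is.null(ind_ids)) ind_ids <- genotypes$sample_ids
  say("genotypes: %d SNPs x %d individuals", nrow(genotypes$dosage), n_ind)

  annotation <- stage("annotation", {
    if (is.null(annotation)) {
      ann <- simulate_gene_annotation(
        n_genes, chrom_length = max(genotypes$pos),
        seed = substream_seed(master, "annotation"),
        chrom = genotypes$chrom[1L])
      ann$gene_id <- gene_ids
      ann
    } else {
      stop_if(nrow(annotation) < n_genes,
              "annotation covers fewer genes than simulated")
      ann <- annotation[seq_len(n_genes), , drop = FALSE]
      if (replication) ann$gene_id <- gene_ids # align to empirical rows
      ann
    }
  })
  gene_ids <- annotation$gene_id

  groups <- sprintf("group%d", seq_along(design$group_probs))
  cond_labels <- sprintf("condition%d", seq_along(design$condition_probs))
  conditions <- with_substream(master, "conditions",
    allocate_conditions(n_ind, design$condition_probs, cond_labels))
  names(conditions) <- ind_ids

  # population-mean layer
  if (replication) {
    base_mean <- rowMeans(empirical_means)
    out_flag <- rep(FALSE, n_genes)
    out_fac <- rep(1, n_genes)
    cv <- rep(NA_real_, n_genes)
    baseline <- unclass(empirical_means)
    attr(baseline, "bulk") <- NULL
    class(baseline) <- NULL
    dimnames(baseline) <- list(gene_ids, ind_ids)
    if (is.null(quantile_norm))
      quantile_norm <- isTRUE(attr(empirical_means, "bulk"))
  } else {
    bm <- stage("base_means", sample_base_means(
      pop, sc, n_genes, seed = substream_seed(master, "base_means")))
    base_mean <- bm$means
    out_flag <- bm$outlier_flag
    out_fac <- bm$outlier_factor
    cv <- stage("variances", sample_variances(
      base_mean, pop, seed = substream_seed(master, "variances")))
    baseline <- stage("individual_means", sample_individual_means(
      base_mean, cv, ind_ids,
      seed = substream_seed(master, "individual_means")))
    rownames(baseline) <- gene_ids
    if (is.null(quantile_norm)) quantile_norm <- TRUE
  }
  if (quantile_norm)
    baseline <- stage("quantile_norm", quantile_normalize(baseline, sc))
  say("baseline means: %d genes x %d individuals (qn: %s)",
      n_genes, n_ind, quantile_norm)

  key <- stage("eqtl", assign_eqtl(
    annotation, genotypes, eqtl, groups = groups,
    conditions = cond_labels, seed = substream_seed(master, "eqtl")))
  say("eQTL: %d eGenes assigned", nrow(key))

  pm <- pop_means(baseline, gene_ids = gene_ids, individual_ids = ind_ids,
                  groups = groups, conditions = unname(conditions[ind_ids]))
  pm <- stage("eqtl", apply_eqtl(pm, key, genotypes))
  deres <- stage("de", apply_de(pm, de, seed = substream_seed(master, "de")))
  pm <- deres$pm

  # cell layer
  cd <- stage("design", build_design(
    design, ind_ids, seed = substream_seed(master, "design"),
    conditions = conditions))
  cells <- cd$cells
  n_cells <- nrow(cells)
  say("design: %d cells, %d batches", n_cells, length(cd$batch_members))

  bf <- with_substream(master, "batch_factors",
    sample_batch_factors(n_genes, design$batch_loc, design$batch_scale))
  rownames(bf) <- gene_ids
  libs <- with_substream(master, "library_sizes",
    stats::rlnorm(n_cells, sc$lib_loc, sc$lib_scale))
  chisq <- with_substream(master, "bcv", draw_bcv_chisq(n_genes, sc))

  block_size <- max(1L, 2000000L %/% n_genes)
  starts <- seq(1L, n_cells, by = block_size)
  counts <- matrix(0L, n_genes, n_cells,
                   dimnames = list(gene_ids, cells$cell_id))
  keep_mu <- if (keep_intermediates)
    matrix(0, n_genes, n_cells, dimnames = dimnames(counts)) else NULL
  set.seed(substream_seed(master, "counts"))
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, n_cells)
    mu <- compute_cell_means(pm, cells[idx, , drop = FALSE], bf, libs[idx])
    counts[, idx] <- sample_counts_block(mu, sc, chisq)
    if (keep_intermediates) keep_mu[, idx] <- mu
  }
  if (sc$dropout_enabled) {
    set.seed(substream_seed(master, "dropout"))
    for (s in starts) {
      idx <- s:min(s + block_size - 1L, n_cells)
      mu <- if (keep_intermediates) keep_mu[, idx, drop = FALSE]
            else compute_cell_means(pm, cells[idx, , drop = FALSE], bf,
                                    libs[idx])
      counts[, idx] <- dropout_block(counts[, idx, drop = FALSE], mu, sc)
    }
  }
  say("counts: %.1f%% zeros", 100 * mean(counts == 0))

  key_full <- build_sim_key(gene_ids, annotation, base_mean, out_flag,
                            out_fac, cv, key, deres, cd, baseline)
  structure(list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "CsparseMatrix"),
                 cells = cells, key = key_full, params = params,
                 genotypes = genotypes, annotation = annotation,
                 batch_factors = bf, lib_sizes = libs,
                 cell_means = keep_mu),
            class = "count_bundle")
}

#' @rdname simulate_population
#' @param G,genes aliases of `genotypes` and `annotation`.
#' @export
simulate_counts <- function(params, G = NULL, genes = NULL, ...)
  simulate_population(params, genotypes = G, annotation = genes, ...)

build_sim_key <- function(gene_ids, annotation, base_mean, out_flag,
                          out_fac, cv, eqtl_key, deres, cd, baseline) {
  genes <- data.frame(gene_id = gene_ids,
                      chrom = annotation$chrom, pos = annotation$pos,
                      base_mean = base_mean, outlier_flag = out_flag,
                      outlier_factor = out_fac, cv = cv,
                      stringsAsFactors = FALSE)
  i <- match(gene_ids, eqtl_key$gene_id)
  genes$snp_id <- eqtl_key$snp_id[i]
  genes$beta <- eqtl_key$beta[i]
  genes$specificity <- eqtl_key$specificity[i]
  genes$coreg_partner <- eqtl_key$coreg_partner[i]
  de_fac <- deres$de_factors
  colnames(de_fac) <- paste0("de_factor_", colnames(de_fac))
  cde_fac <- deres$cde_factors
  colnames(cde_fac) <- paste0("cde_factor_", colnames(cde_fac))
  genes <- cbind(genes, as.data.frame(de_fac), as.data.frame(cde_fac))
  rownames(genes) <- NULL
  structure(list(genes = genes, individuals = cd$individuals,
                 baseline_means = baseline),
            class = "sim_key")
}

#' @export
print.sim_key <- function(x, ...) {
  cat(sprintf("Simulation key: %d genes, %d individuals, %d eGenes\n",
              nrow(x$genes), nrow(x$individuals),
              sum(!is.na(x$genes$snp_id))))
  invisible(x)
}

#' @export
print.count_bundle <- function(x, ...) {
  cat(sprintf("Simulated counts: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  individuals: %d  batches: %d  groups: %d  conditions: %d\n",
              length(unique(x$cells$individual)),
              length(unique(x$cells$batch)),
              length(unique(x$cells$group)),
              length(unique(x$cells$condition))))
  cat(sprintf("  eGenes: %d  sparsity: %.1f%% zeros\n",
              sum(!is.na(x$key$genes$snp_id)),
              100 * (1 - Matrix::nnzero(x$counts) / length(x$counts))))
  invisible(x)
}

#' @export
summary.count_bundle <- function(object, ...) {
  print(object)
  cat(sprintf("  median library size: %.0f\n",
              stats::median(Matrix::colSums(object$counts))))
  cat(sprintf("  mean counts per gene: %.2f\n",
              mean(Matrix::rowMeans(object$counts))))
  invisible(object)
}
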