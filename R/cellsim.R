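#' Allocate individuals, cells, groups and conditions to a design
#'
#' Individuals are allocated to batches of exactly `batch_size`
#' distinct individuals. When the total slots
#' (`n_batches * batch_size`) exceed the number of individuals, the
#' extra slots are filled by technical replicates chosen uniformly
#' among the least-replicated individuals, so every individual appears
#' in at least one batch. Cells within a batch are split evenly across
#' its individuals (remainders go to randomly chosen members), groups
#' are drawn per cell from `group_probs`, and conditions per individual
#' by largest-remainder allocation of `condition_probs`.
#'
#' @param design a [design_params()].
#' @param individual_ids individual identifiers (length
#'   `n_individuals`).
#' @param seed integer seed.
#' @param conditions optional pre-assigned per-individual condition
#'   labels; drawn from `condition_probs` when `NULL`.
#' @return an object of class `cell_design`: list with `cells` (one row
#'   per cell: `cell_id`, `individual`, `batch`, `group`, `condition`),
#'   `individuals` (per-individual condition), and `batch_members`.
#' @export
build_design <- function(design, individual_ids, seed = 1L,
                         conditions = NULL) {
  stopifnot(inherits(design, "design_params"))
  n_ind <- length(individual_ids)
  stop_if(design$batch_size > n_ind,
          "batch_size exceeds the number of individuals")
  set.seed(seed)

  n_batches <- length(design$batch_n_cells)
  batches <- sprintf("batch%d", seq_len(n_batches))
  groups <- sprintf("group%d", seq_along(design$group_probs))
  conds <- sprintf("condition%d", seq_along(design$condition_probs))

  if (is.null(conditions))
    conditions <- allocate_conditions(n_ind, design$condition_probs, conds)
  names(conditions) <- individual_ids

  # batch membership: fill each batch with the least-assigned individuals
  times_used <- stats::setNames(integer(n_ind), individual_ids)
  batch_members <- vector("list", n_batches)
  names(batch_members) <- batches
  for (b in seq_len(n_batches)) {
    chosen <- character(0)
    while (length(chosen) < design$batch_size) {
      avail <- setdiff(individual_ids, chosen)
      lvl <- min(times_used[avail])
      pool <- avail[times_used[avail] == lvl]
      take <- min(design$batch_size - length(chosen), length(pool))
      chosen <- c(chosen, if (length(pool) == 1L) pool
                  else sample(pool, take))
    }
    batch_members[[b]] <- sort(chosen)
    times_used[chosen] <- times_used[chosen] + 1L
  }
  stop_if(any(times_used == 0L) && n_batches * design$batch_size >= n_ind,
          "internal error: individual left out of all batches")

  cell_rows <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    members <- batch_members[[b]]
    n_cells <- design$batch_n_cells[b]
    base <- n_cells %/% length(members)
    per <- rep(base, length(members))
    extra <- n_cells - base * length(members)
    if (extra > 0L)
      per[sample.int(length(members), extra)] <- base + 1L
    cell_rows[[b]] <- data.frame(
      individual = rep(members, per),
      batch = batches[b], stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cell_rows)
  cells$group <- sample(groups, nrow(cells), replace = TRUE,
                        prob = design$group_probs)
  cells$condition <- unname(conditions[cells$individual])
  cells$cell_id <- sprintf("cell%06d", seq_len(nrow(cells)))
  cells <- cells[, c("cell_id", "individual", "batch", "group",
                     "condition")]
  structure(list(cells = cells,
                 individuals = data.frame(individual = individual_ids,
                                          condition = unname(conditions),
                                          stringsAsFactors = FALSE),
                 batch_members = batch_members,
                 groups = groups, conditions = conds),
            class = "cell_design")
}

# largest-remainder apportionment of n individuals over cohorts, then a
# random permutation decides who lands where
allocate_conditions <- function(n, probs, labels) {
  quota <- n * probs
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    extra <- order(frac, stats::runif(length(probs)), decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(labels, times = base))
}

#' Sample multiplicative batch factors
#'
#' One log-normal factor per gene per batch, made bidirectional by
#' replacing the factor with its reciprocal with probability 0.5.
#'
#' @param n_genes number of genes.
#' @param batch_loc,batch_scale per-batch log-normal location/scale.
#' @param seed integer seed.
#' @return genes x batches matrix of factors.
#' @export
sample_batch_factors <- function(n_genes, batch_loc, batch_scale,
                                 seed = 1L) {
  stop_if(length(batch_loc) != length(batch_scale),
          "need one (loc, scale) pair per batch")
  set.seed(seed)
  n_b <- length(batch_loc)
  f <- matrix(1, n_genes, n_b,
              dimnames = list(NULL, sprintf("batch%d", seq_len(n_b))))
  for (b in seq_len(n_b)) {
    fac <- stats::rlnorm(n_genes, batch_loc[b], batch_scale[b])
    flip <- stats::runif(n_genes) < 0.5
    f[, b] <- ifelse(flip, 1 / fac, fac)
  }
  f
}

#' Sample expected library sizes
#'
#' @param n_cells number of cells.
#' @param sc an [sc_params()] (log-normal `lib_loc`, `lib_scale`).
#' @param seed integer seed.
#' @return numeric vector of expected per-cell totals.
#' @export
sample_library_sizes <- function(n_cells, sc, seed = 1L) {
  set.seed(seed)
  stats::rlnorm(n_cells, sc$lib_loc, sc$lib_scale)
}

#' Compute cell-level expected means
#'
#' For cell `c` of individual `j`, group `g`, batch `b`, the expected
#' mean of gene `i` is `popmeans[i, j, g] * batch_factor[i, b]`, with
#' each cell's column then rescaled to sum to its expected library
#' size (so per-individual scale is absorbed by the library size).
#'
#' @param pm a [pop_means()].
#' @param cells data.frame with columns `individual`, `batch`, `group`
#'   (one row per cell, as in [build_design()]`$cells`).
#' @param batch_factors genes x batches matrix.
#' @param lib_sizes per-cell expected totals.
#' @return genes x cells matrix of expected means.
#' @export
compute_cell_means <- function(pm, cells, batch_factors, lib_sizes) {
  stopifnot(inherits(pm, "pop_means"))
  ji <- match(cells$individual, pm$individual_ids)
  gi <- match(cells$group, pm$groups)
  bi <- match(cells$batch, colnames(batch_factors))
  stop_if(anyNA(ji) || anyNA(gi) || anyNA(bi),
          "cells reference unknown individual, group or batch")
  n_ind <- length(pm$individual_ids)
  flat <- matrix(pm$values, nrow = dim(pm$values)[1]) # genes x (ind*group)
  mu <- flat[, ji + (gi - 1L) * n_ind, drop = FALSE]
  mu <- mu * batch_factors[, bi, drop = FALSE]
  tot <- colSums(mu)
  stop_if(any(tot == 0), "a cell has zero total expected mean")
  mu <- sweep(mu, 2L, lib_sizes / tot, "*")
  dimnames(mu) <- list(pm$gene_ids,
                       if (!is.null(cells$cell_id)) cells$cell_id else NULL)
  mu
}

#' Sample over-dispersed counts from expected means
#'
#' Implements gamma-Poisson sampling with BCV inflation: per gene `i`
#' and cell `c`, `B = (bcv_common + 1/sqrt(mu)) * sqrt(bcv_df / chi_i)`
#' with one chi-square(`bcv_df`) draw per gene, a trended mean
#' `mu' ~ gamma(shape = 1/B^2, scale = mu * B^2)`, and the count
#' `~ Poisson(mu')`. Entries with zero mean always yield zero counts.
#'
#' @param cell_means genes x cells matrix of expected means.
#' @param sc an [sc_params()].
#' @param seed integer seed.
#' @param chisq optional per-gene chi-square(`bcv_df`) draws, to share
#'   the gene-level dispersion across blocks of cells; drawn internally
#'   when `NULL`.
#' @return genes x cells integer matrix of counts.
#' @export
sample_counts <- function(cell_means, sc, seed = 1L, chisq = NULL) {
  set.seed(seed)
  if (is.null(chisq)) chisq <- draw_bcv_chisq(nrow(cell_means), sc)
  sample_counts_block(cell_means, sc, chisq)
}

draw_bcv_chisq <- function(n_genes, sc) {
  if (is.finite(sc$bcv_df)) stats::rchisq(n_genes, df = sc$bcv_df)
  else rep(1, n_genes) # df -> Inf limit: chi/df -> 1
}

# block kernel: no seeding, draws from the current RNG state
sample_counts_block <- function(mu, sc, chisq) {
  n_g <- nrow(mu); n_c <- ncol(mu)
  infl <- if (is.finite(sc$bcv_df)) sqrt(sc$bcv_df / chisq)
          else rep(1, n_g)
  B <- (sc$bcv_common + 1 / sqrt(mu)) * infl
  zero <- mu == 0
  B[zero] <- 1 # placeholder, overwritten below
  shape <- 1 / B^2
  trended <- matrix(stats::rgamma(n_g * n_c, shape = shape,
                                  scale = mu * B^2),
                    nrow = n_g)
  trended[zero] <- 0
  counts <- matrix(stats::rpois(n_g * n_c, trended), nrow = n_g)
  dimnames(counts) <- dimnames(mu)
  counts
}

#' Apply logistic dropout to counts
#'
#' Each entry is zeroed with probability
#' `1 / (1 + exp(-dropout_shape * (ln mu - dropout_mid)))`; with the
#' default negative shape the keeping probability rises logistically
#' with the log mean. Existing zeros stay zero. Identity when dropout
#' is disabled.
#'
#' @param counts genes x cells integer matrix.
#' @param cell_means the expected means the counts were drawn from.
#' @param sc an [sc_params()].
#' @param seed integer seed.
#' @return the thinned count matrix.
#' @export
apply_dropout <- function(counts, cell_means, sc, seed = 1L) {
  if (!sc$dropout_enabled) return(counts)
  set.seed(seed)
  dropout_block(counts, cell_means, sc)
}

dropout_block <- function(counts, mu, sc) {
  p_drop <- 1 / (1 + exp(-sc$dropout_shape * (log(mu) - sc$dropout_mid)))
  keep <- matrix(stats::runif(length(counts)) >= p_drop,
                 nrow = nrow(counts))
  counts * keep
}
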