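#' @title Model parameter objects
#'
#' @description The simulation is controlled by five parameter families,
#' each a validated S3 object, collected in a [parameter_set()]:
#'
#' * [sc_params()] — single-cell level: gamma distribution of gene means
#'   (`mean_shape`, `mean_rate`), log-normal library sizes, expression
#'   outliers, biological coefficient of variation (BCV) and optional
#'   logistic dropout.
#' * [pop_params()] — population level: gamma distribution of
#'   population-wide gene means and a binned mean-variance trend (one
#'   gamma fit of the coefficient of variation per gene-mean bin), plus
#'   the similarity scale multiplier applied to the cv rate.
#' * [eqtl_params()] — eQTL effects: gamma distribution of effect sizes,
#'   fraction of genes made eGenes, eSNP minor-allele-frequency and
#'   distance constraints, co-regulation and specificity proportions.
#' * [de_params()] — differential-expression scaling factors between
#'   cell groups and between condition cohorts.
#' * [design_params()] — experimental design: individuals, cells, batch
#'   structure, cell-group and condition-cohort proportions, master seed.
#'
#' @name scpopsim-params
NULL

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  stop_if(any(!is.finite(x) | x < 0 | x > 1),
          sprintf("'%s' must be in [0, 1]", name))
}

check_pos <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  stop_if(bad, sprintf("'%s' must be %s", name,
                       if (strict) "> 0" else ">= 0"))
}

#' Single-cell level parameters
#'
#' @param n_genes number of genes to simulate.
#' @param mean_shape,mean_rate gamma shape/rate of the single-cell gene
#'   mean distribution (the quantile-normalization target).
#' @param lib_loc,lib_scale location/scale (log scale) of the log-normal
#'   expected library size per cell.
#' @param out_prob probability that a gene is an expression outlier.
#' @param out_loc,out_scale log-normal location/scale of outlier factors
#'   (a flagged gene's mean becomes `median(means) * factor`).
#' @param bcv_common common biological coefficient of variation.
#' @param bcv_df degrees of freedom of the chi-square BCV inflation
#'   (may be `Inf` for no trend noise).
#' @param dropout_enabled logical; apply logistic dropout after count
#'   sampling.
#' @param dropout_mid,dropout_shape midpoint (on the natural-log mean
#'   scale) and shape of the dropout logistic; with the default negative
#'   shape, higher-mean entries are kept more often.
#' @return an object of class `sc_params`.
#' @export
sc_params <- function(n_genes = 1000L,
                      mean_shape = 0.6, mean_rate = 0.3,
                      lib_loc = 11, lib_scale = 0.2,
                      out_prob = 0.05, out_loc = 4, out_scale = 0.5,
                      bcv_common = 0.1, bcv_df = 60,
                      dropout_enabled = FALSE,
                      dropout_mid = 0, dropout_shape = -1) {
  n_genes <- as.integer(n_genes)
  stop_if(n_genes < 1L, "'n_genes' must be >= 1")
  check_pos(c(mean_shape, mean_rate), "mean_shape/mean_rate")
  check_pos(lib_scale, "lib_scale", strict = FALSE)
  check_prob(out_prob, "out_prob")
  check_pos(out_scale, "out_scale", strict = FALSE)
  check_pos(bcv_common, "bcv_common", strict = FALSE)
  stop_if(!(is.numeric(bcv_df) && bcv_df > 0), "'bcv_df' must be > 0")
  p <- list(n_genes = n_genes, mean_shape = as.numeric(mean_shape),
            mean_rate = as.numeric(mean_rate),
            lib_loc = as.numeric(lib_loc),
            lib_scale = as.numeric(lib_scale),
            out_prob = as.numeric(out_prob),
            out_loc = as.numeric(out_loc),
            out_scale = as.numeric(out_scale),
            bcv_common = as.numeric(bcv_common),
            bcv_df = as.numeric(bcv_df),
            dropout_enabled = isTRUE(dropout_enabled),
            dropout_mid = as.numeric(dropout_mid),
            dropout_shape = as.numeric(dropout_shape))
  structure(p, class = "sc_params")
}

# Embedded population defaults. The bin edges are the deciles of the
# default population-mean gamma; the per-bin cv gammas encode a
# decreasing mean-variance trend (mean cv 0.40 in the lowest-expression
# bin down to 0.15 in the highest, tightening with expression), the
# regime seen after low-expression filtering in population-scale
# reference panels.
.default_bin_edges <- c(0, 0.102405, 0.78974, 2.631198, 6.26522,
                        12.526053, 22.693613, 39.093123, 66.949111,
                        123.263292, Inf)
.default_cv_shape <- c(6, 8, 10, 12, 14, 16, 18, 20, 22, 24)
.default_cv_rate <- .default_cv_shape /
  c(0.4, 0.34, 0.29, 0.26, 0.23, 0.21, 0.19, 0.17, 0.16, 0.15)

#' Population level parameters
#'
#' @param mean_shape,mean_rate gamma shape/rate of population-wide gene
#'   means.
#' @param n_bins number of equal-count gene-mean bins for the
#'   mean-variance trend.
#' @param bin_edges ordered bin boundaries (length `n_bins + 1`).
#' @param cv_shape_per_bin,cv_rate_per_bin gamma shape/rate of the
#'   coefficient of variation in each bin (length `n_bins`).
#' @param similarity_scale multiplier applied to the cv gamma rate;
#'   values > 1 shrink between-individual variability (individuals more
#'   similar), values < 1 inflate it.
#' @return an object of class `pop_params`.
#' @export
pop_params <- function(mean_shape = 0.34, mean_rate = 0.008,
                       n_bins = 10L,
                       bin_edges = NULL,
                       cv_shape_per_bin = NULL,
                       cv_rate_per_bin = NULL,
                       similarity_scale = 1) {
  n_bins <- as.integer(n_bins)
  stop_if(n_bins < 1L, "'n_bins' must be >= 1")
  if (is.null(bin_edges) && n_bins == 10L) bin_edges <- .default_bin_edges
  if (is.null(cv_shape_per_bin) && n_bins == 10L)
    cv_shape_per_bin <- .default_cv_shape
  if (is.null(cv_rate_per_bin) && n_bins == 10L)
    cv_rate_per_bin <- .default_cv_rate
  stop_if(is.null(bin_edges) || is.null(cv_shape_per_bin) ||
            is.null(cv_rate_per_bin),
          "bin_edges and per-bin cv parameters are required when n_bins != 10")
  check_pos(c(mean_shape, mean_rate), "mean_shape/mean_rate")
  stop_if(length(bin_edges) != n_bins + 1L,
          "'bin_edges' must have length n_bins + 1")
  stop_if(is.unsorted(bin_edges, strictly = TRUE),
          "'bin_edges' must be strictly increasing")
  stop_if(length(cv_shape_per_bin) != n_bins ||
            length(cv_rate_per_bin) != n_bins,
          "per-bin cv parameters must have length n_bins")
  check_pos(cv_shape_per_bin, "cv_shape_per_bin")
  check_pos(cv_rate_per_bin, "cv_rate_per_bin")
  check_pos(similarity_scale, "similarity_scale")
  structure(list(mean_shape = as.numeric(mean_shape),
                 mean_rate = as.numeric(mean_rate),
                 n_bins = n_bins, bin_edges = as.numeric(bin_edges),
                 cv_shape_per_bin = as.numeric(cv_shape_per_bin),
                 cv_rate_per_bin = as.numeric(cv_rate_per_bin),
                 similarity_scale = as.numeric(similarity_scale)),
            class = "pop_params")
}

#' eQTL effect parameters
#'
#' @param es_shape,es_rate gamma shape/rate of eQTL effect sizes.
#' @param eqtl_prob fraction of genes assigned an eQTL (eGenes).
#' @param maf_min,maf_max minor-allele-frequency bounds for eligible
#'   eSNPs.
#' @param dist_max maximum eGene-eSNP distance in bp.
#' @param coreg_prop fraction of eGenes sharing an eSNP with another
#'   eGene (co-regulation).
#' @param group_specific_prop fraction of eQTL effects applied to a
#'   single cell group only (used when more than one group is simulated).
#' @param condition_specific_prop fraction applied to a single condition
#'   cohort only (used when more than one cohort is simulated).
#' @param sign_flip_prob probability of negating a sampled effect size;
#'   the model's effects are positive, this extension allows
#'   bidirectional effects and defaults to 0.
#' @return an object of class `eqtl_params`.
#' @export
eqtl_params <- function(es_shape = 3.6, es_rate = 12,
                        eqtl_prob = 0.5,
                        maf_min = 0.05, maf_max = 0.5,
                        dist_max = 1e6,
                        coreg_prop = 0,
                        group_specific_prop = 0.2,
                        condition_specific_prop = 0.2,
                        sign_flip_prob = 0) {
  check_pos(c(es_shape, es_rate), "es_shape/es_rate")
  check_prob(c(eqtl_prob, coreg_prop, group_specific_prop,
               condition_specific_prop, sign_flip_prob),
             "eqtl proportions")
  stop_if(!(maf_min > 0 && maf_min < maf_max && maf_max <= 0.5),
          "need 0 < maf_min < maf_max <= 0.5")
  check_pos(dist_max, "dist_max")
  structure(lapply(list(es_shape = es_shape, es_rate = es_rate,
                        eqtl_prob = eqtl_prob, maf_min = maf_min,
                        maf_max = maf_max, dist_max = dist_max,
                        coreg_prop = coreg_prop,
                        group_specific_prop = group_specific_prop,
                        condition_specific_prop = condition_specific_prop,
                        sign_flip_prob = sign_flip_prob), as.numeric),
            class = "eqtl_params")
}

#' Differential-expression parameters
#'
#' Group-level (`de_*`) parameters control DE between cell groups;
#' condition-level (`cde_*`) parameters control DE between condition
#' cohorts. Each may be a scalar (shared) or a vector with one entry per
#' group/cohort.
#'
#' @param de_prob,de_down_prob,de_loc,de_scale per-group probability of
#'   DE, probability a DE factor is inverted (down-regulation), and
#'   log-normal location/scale of the factors.
#' @param cde_prob,cde_down_prob,cde_loc,cde_scale the same, per
#'   condition cohort.
#' @return an object of class `de_params`.
#' @export
de_params <- function(de_prob = 0.1, de_down_prob = 0.5,
                      de_loc = 0.1, de_scale = 0.4,
                      cde_prob = 0.1, cde_down_prob = 0.5,
                      cde_loc = 0.1, cde_scale = 0.4) {
  check_prob(c(de_prob, de_down_prob, cde_prob, cde_down_prob),
             "de/cde probabilities")
  check_pos(c(de_scale, cde_scale), "de_scale/cde_scale", strict = FALSE)
  structure(lapply(list(de_prob = de_prob, de_down_prob = de_down_prob,
                        de_loc = de_loc, de_scale = de_scale,
                        cde_prob = cde_prob,
                        cde_down_prob = cde_down_prob,
                        cde_loc = cde_loc, cde_scale = cde_scale),
                   as.numeric),
            class = "de_params")
}

#' Experimental design parameters
#'
#' @param n_individuals number of individuals.
#' @param cells_per_individual expected cells per individual (used to
#'   size the default single batch when `batch_n_cells` is `NULL`).
#' @param batch_n_cells integer vector of cells per batch; its length is
#'   the number of batches. `NULL` means one batch holding
#'   `n_individuals * cells_per_individual` cells.
#' @param batch_size number of distinct individuals per batch; when
#'   total batch slots exceed `n_individuals`, some individuals appear
#'   in more than one batch as technical replicates.
#' @param batch_loc,batch_scale per-batch log-normal location/scale of
#'   multiplicative batch factors (recycled across batches).
#' @param group_probs cell-group membership probabilities (sum to 1).
#' @param condition_probs condition-cohort proportions over individuals
#'   (sum to 1).
#' @param master_seed master seed; all pipeline substreams derive from
#'   it (see [substream_seed()]).
#' @return an object of class `design_params`.
#' @export
design_params <- function(n_individuals = 6L,
                          cells_per_individual = 100L,
                          batch_n_cells = NULL,
                          batch_size = NULL,
                          batch_loc = 0.1, batch_scale = 0.1,
                          group_probs = 1,
                          condition_probs = 1,
                          master_seed = 1L) {
  n_individuals <- as.integer(n_individuals)
  stop_if(n_individuals < 1L, "'n_individuals' must be >= 1")
  auto_cells <- is.null(batch_n_cells)
  if (auto_cells)
    batch_n_cells <- n_individuals * as.integer(cells_per_individual)
  batch_n_cells <- as.integer(batch_n_cells)
  check_pos(batch_n_cells, "batch_n_cells")
  auto_size <- is.null(batch_size)
  if (auto_size) batch_size <- n_individuals
  batch_size <- as.integer(batch_size)
  stop_if(batch_size < 1L || batch_size > n_individuals,
          "'batch_size' must be in [1, n_individuals]")
  check_prob(group_probs, "group_probs")
  check_prob(condition_probs, "condition_probs")
  stop_if(abs(sum(group_probs) - 1) > 1e-8, "'group_probs' must sum to 1")
  stop_if(abs(sum(condition_probs) - 1) > 1e-8,
          "'condition_probs' must sum to 1")
  n_batches <- length(batch_n_cells)
  check_pos(rep(batch_scale, length.out = n_batches), "batch_scale",
            strict = FALSE)
  structure(list(n_individuals = n_individuals,
                 cells_per_individual = as.integer(cells_per_individual),
                 batch_n_cells = batch_n_cells, batch_size = batch_size,
                 batch_loc = as.numeric(rep(batch_loc,
                                            length.out = n_batches)),
                 batch_scale = as.numeric(rep(batch_scale,
                                              length.out = n_batches)),
                 group_probs = as.numeric(group_probs),
                 condition_probs = as.numeric(condition_probs),
                 master_seed = as.integer(master_seed),
                 .auto_batch_n_cells = auto_cells,
                 .auto_batch_size = auto_size),
            class = "design_params")
}

#' Assemble a full parameter set
#'
#' @param sc,pop,eqtl,de,design the five parameter families; defaults
#'   are used for any omitted family.
#' @return an object of class `parameter_set`.
#' @seealso [default_params()], [write_params()], [read_params()]
#' @export
parameter_set <- function(sc = sc_params(), pop = pop_params(),
                          eqtl = eqtl_params(), de = de_params(),
                          design = design_params()) {
  stopifnot(inherits(sc, "sc_params"), inherits(pop, "pop_params"),
            inherits(eqtl, "eqtl_params"), inherits(de, "de_params"),
            inherits(design, "design_params"))
  structure(list(sc = sc, pop = pop, eqtl = eqtl, de = de,
                 design = design),
            class = "parameter_set")
}

#' Default parameter set
#'
#' Returns the embedded default constants: splat-style single-cell
#' parameters, a population mean-variance trend with 10 decile bins, an
#' effect-size gamma with mean 0.3, and a minimal six-individual
#' single-batch design. Deterministic; calling it twice gives identical
#' objects.
#'
#' @return a `parameter_set`.
#' @export
default_params <- function() parameter_set()

#' Update a parameter set with named overrides
#'
#' Overrides are given as a nested list, e.g.
#' `list(eqtl = list(eqtl_prob = 0.7))`. Unknown family or field names
#' are an error.
#'
#' @param params a `parameter_set`.
#' @param overrides nested named list of overrides.
#' @return the updated, re-validated `parameter_set`.
#' @export
update_params <- function(params, overrides) {
  stopifnot(inherits(params, "parameter_set"))
  if (is.null(overrides) || length(overrides) == 0L) return(params)
  ctors <- list(sc = sc_params, pop = pop_params, eqtl = eqtl_params,
                de = de_params, design = design_params)
  bad <- setdiff(names(overrides), names(ctors))
  stop_if(length(bad) > 0,
          "unknown parameter family: ", paste(bad, collapse = ", "))
  for (fam in names(overrides)) {
    cur <- unclass(params[[fam]])
    ov <- overrides[[fam]]
    unknown <- setdiff(names(ov), names(cur))
    stop_if(length(unknown) > 0,
            sprintf("unknown %s parameter: %s", fam,
                    paste(unknown, collapse = ", ")))
    cur[names(ov)] <- ov
    if (fam == "design") {
      # batch defaults derived from n_individuals/cells_per_individual
      # are re-derived unless set explicitly
      if (isTRUE(cur$.auto_batch_n_cells) &&
            !"batch_n_cells" %in% names(ov))
        cur$batch_n_cells <- NULL
      if (isTRUE(cur$.auto_batch_size) && !"batch_size" %in% names(ov))
        cur$batch_size <- NULL
    }
    cur <- cur[!startsWith(names(cur), ".")]
    params[[fam]] <- do.call(ctors[[fam]], cur)
  }
  params
}

#' @export
print.parameter_set <- function(x, ...) {
  d <- x$design
  cat("Parameter set for population-scale scRNA-seq simulation\n")
  cat(sprintf("  genes: %d  individuals: %d  batches: %d  groups: %d  conditions: %d\n",
              x$sc$n_genes, d$n_individuals, length(d$batch_n_cells),
              length(d$group_probs), length(d$condition_probs)))
  cat(sprintf("  pop means ~ gamma(%.3g, %.3g); %d cv bins; similarity scale %.3g\n",
              x$pop$mean_shape, x$pop$mean_rate, x$pop$n_bins,
              x$pop$similarity_scale))
  cat(sprintf("  eQTL: prob %.3g, effects ~ gamma(%.3g, %.3g), MAF [%.3g, %.3g], window %g bp, coreg %.3g\n",
              x$eqtl$eqtl_prob, x$eqtl$es_shape, x$eqtl$es_rate,
              x$eqtl$maf_min, x$eqtl$maf_max, x$eqtl$dist_max,
              x$eqtl$coreg_prop))
  cat(sprintf("  master seed: %d\n", d$master_seed))
  invisible(x)
}

#' @export
print.sc_params <- function(x, ...) {
  cat("Single-cell parameters:\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

params_to_list <- function(params) {
  lapply(unclass(params), function(fam) {
    l <- unclass(fam)
    l <- l[!startsWith(names(l), ".")] # drop internal bookkeeping
    l[order(names(l))] # canonical key order
  })
}

list_to_params <- function(x) {
  ctors <- list(sc = sc_params, pop = pop_params, eqtl = eqtl_params,
                de = de_params, design = design_params)
  stop_if(!all(sort(names(x)) == sort(names(ctors))),
          "parameter file must contain families sc, pop, eqtl, de, design")
  fams <- lapply(names(ctors), function(fam) {
    vals <- x[[fam]]
    # JSON may force numeric vectors containing Inf to strings
    vals <- lapply(vals, function(v) {
      if (is.character(v)) {
        nv <- suppressWarnings(as.numeric(v))
        if (!anyNA(nv)) v <- nv
      }
      v
    })
    do.call(ctors[[fam]], vals)
  })
  names(fams) <- names(ctors)
  do.call(parameter_set, fams)
}

#' Write / read a parameter set
#'
#' Serializes to JSON (default, canonical key order, full numeric
#' precision) or YAML, chosen by file extension. The round trip is
#' lossless.
#'
#' @param params a `parameter_set`.
#' @param path output file, extension `.json`, `.yaml` or `.yml`.
#' @return `write_params` returns `path` invisibly; `read_params`
#'   returns a `parameter_set`.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  x <- params_to_list(params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 17)
  } else {
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                             pretty = TRUE, na = "string")
    writeLines(gsub('"Inf"', '"Inf"', json), path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::fromJSON(path, simplifyVector = TRUE)
  list_to_params(x)
}
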