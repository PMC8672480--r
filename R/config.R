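#' Build and validate a run configuration
#'
#' A configuration is a named list (or a YAML file holding one) with:
#'
#' * `paths`: optional input files — `genotypes` (VCF), `annotation`
#'   (TSV), `population_expr` (genes x individuals TSV), `sc_counts`
#'   (genes x cells TSV), `eqtl_betas` (single-column TSV of effect
#'   sizes), `empirical_means` (TSV, replication mode), and `bundle`
#'   (a simulated output directory, for evaluation).
#' * `params`: nested parameter overrides, e.g.
#'   `params: {eqtl: {eqtl_prob: 0.7}}`.
#' * `seed`: overrides the design master seed.
#' * `out`: output directory.
#' * flags: `replication`, `dropout`, `keep_intermediates`,
#'   `quantile_norm`; `cells_grid` for evaluation down-sampling.
#'
#' Referenced paths must exist; unknown parameter overrides are
#' rejected by name.
#'
#' @param config a named list or path to a YAML file.
#' @return a validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("paths", "params", "seed", "out", "replication", "dropout",
             "keep_intermediates", "quantile_norm", "cells_grid",
             "q_threshold", "window_bp")
  bad <- setdiff(names(config), known)
  stop_if(length(bad) > 0,
          "unknown config key: ", paste(bad, collapse = ", "))
  paths <- config$paths
  known_paths <- c("genotypes", "annotation", "population_expr",
                   "sc_counts", "eqtl_betas", "empirical_means", "bundle")
  badp <- setdiff(names(paths), known_paths)
  stop_if(length(badp) > 0,
          "unknown config path key: ", paste(badp, collapse = ", "))
  for (p in names(paths))
    stop_if(!file.exists(paths[[p]]),
            sprintf("config path '%s' does not exist: %s", p, paths[[p]]))
  # type-check overrides against the parameter schema immediately
  if (!is.null(config$params))
    invisible(update_params(default_params(), config$params))
  structure(config, class = c("run_config", "list"))
}

resolve_params <- function(config) {
  params <- update_params(default_params(), config$params)
  if (!is.null(config$seed))
    params <- update_params(params,
                            list(design = list(master_seed = config$seed)))
  if (isTRUE(config$dropout))
    params <- update_params(params,
                            list(sc = list(dropout_enabled = TRUE)))
  params
}

log_stage <- function(fmt, ...) message(sprintf(fmt, ...))

#' Estimate parameters from reference data named in a config
#'
#' Estimates each parameter family for which a reference file is
#' supplied (`population_expr` for the population family, `sc_counts`
#' for the single-cell family, `eqtl_betas` for the eQTL effect-size
#' family) and keeps defaults for the rest, logging which families were
#' estimated versus defaulted. Writes `params.json` to `out`.
#'
#' @param config a [run_config()] (or list/YAML path coercible to one).
#' @return the estimated [parameter_set()], invisibly; side effect:
#'   `params.json` in `config$out`.
#' @export
cmd_estimate <- function(config) {
  config <- run_config(unclass(config))
  paths <- config$paths
  stop_if(is.null(paths$population_expr) && is.null(paths$sc_counts) &&
            is.null(paths$eqtl_betas),
          "cmd_estimate needs at least one reference matrix")
  params <- default_params()
  estimated <- character(0)
  if (!is.null(paths$sc_counts)) {
    params$sc <- estimate_sc_params(read_matrix_tsv(paths$sc_counts))
    estimated <- c(estimated, "sc")
  }
  if (!is.null(paths$population_expr)) {
    nb <- if (!is.null(config$params$pop$n_bins))
      config$params$pop$n_bins else 10L
    params$pop <- estimate_population_params(
      read_matrix_tsv(paths$population_expr), n_bins = nb)
    estimated <- c(estimated, "pop")
  }
  if (!is.null(paths$eqtl_betas)) {
    betas <- utils::read.delim(paths$eqtl_betas)[[1L]]
    params$eqtl <- estimate_eqtl_params(betas)
    estimated <- c(estimated, "eqtl")
  }
  params <- update_params(params, config$params)
  defaulted <- setdiff(c("sc", "pop", "eqtl", "de", "design"), estimated)
  log_stage("estimated families: %s; defaulted: %s",
            paste(estimated, collapse = ", "),
            paste(defaulted, collapse = ", "))
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    write_params(params, file.path(config$out, "params.json"))
  }
  invisible(params)
}

#' Run a simulation from a config and write an output directory
#'
#' Resolves parameters (defaults + overrides + seed), loads or
#' simulates genotypes and annotation, runs [simulate_population()] and
#' writes the bundle plus a copy of the resolved configuration
#' (`config.yaml`) to `config$out`.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly.
#' @export
cmd_simulate <- function(config) {
  config <- run_config(unclass(config))
  stop_if(is.null(config$out), "cmd_simulate needs an 'out' directory")
  params <- resolve_params(config)
  paths <- config$paths
  G <- if (!is.null(paths$genotypes)) read_vcf(paths$genotypes) else NULL
  ann <- if (!is.null(paths$annotation))
    read_gene_annotation(paths$annotation) else NULL
  emp <- NULL
  if (isTRUE(config$replication)) {
    stop_if(is.null(paths$empirical_means),
            "replication mode needs paths$empirical_means")
    emp <- use_empirical_means(read_matrix_tsv(paths$empirical_means))
  }
  t0 <- proc.time()[["elapsed"]]
  bundle <- simulate_population(
    params, genotypes = G, annotation = ann, empirical_means = emp,
    quantile_norm = config$quantile_norm,
    keep_intermediates = isTRUE(config$keep_intermediates))
  log_stage("simulate: seed %d, %d genes x %d cells in %.1fs",
            params$design$master_seed, nrow(bundle$counts),
            ncol(bundle$counts), proc.time()[["elapsed"]] - t0)
  write_count_bundle(bundle, config$out)
  yaml::write_yaml(resolved_config_list(config, params),
                   file.path(config$out, "config.yaml"))
  invisible(config$out)
}

resolved_config_list <- function(config, params) {
  out <- unclass(config)
  out$resolved_params <- params_to_list(params)
  lapply(out, function(x) if (is.list(x)) x else unclass(x))
}

#' Evaluate a simulated bundle across a cells-per-individual grid
#'
#' For each grid value, cells are down-sampled without replacement per
#' individual; differential expression between the two condition
#' cohorts (pseudobulk Wilcoxon) is run when two cohorts exist, and
#' simplified cis-eQTL mapping ([map_eqtl_simple()]) is always run.
#' Results (`de_results.tsv`, `eqtl_results.tsv`) and a
#' `confusion.tsv` with one row per grid value and analysis are written
#' to `config$out`.
#'
#' @param config a [run_config()] with `paths$bundle` set.
#' @return data.frame of confusion rows, invisibly.
#' @export
cmd_evaluate <- function(config) {
  config <- run_config(unclass(config))
  stop_if(is.null(config$paths$bundle),
          "cmd_evaluate needs paths$bundle (a simulated output directory)")
  stop_if(is.null(config$out), "cmd_evaluate needs an 'out' directory")
  b <- read_count_bundle(config$paths$bundle)
  grid <- config$cells_grid
  if (is.null(grid)) grid <- c(10L, 80L, 500L)
  qthr <- if (is.null(config$q_threshold)) 0.05 else config$q_threshold
  window <- if (is.null(config$window_bp)) 1e5 else config$window_bp
  seed <- if (is.null(config$seed)) 1L else config$seed
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  truth_eqtl <- stats::setNames(!is.na(b$key$genes$snp_id),
                                b$key$genes$gene_id)
  conds <- b$key$individuals$condition
  two_cohorts <- length(unique(conds)) == 2L
  cde_cols <- grep("^cde_factor_", names(b$key$genes))
  truth_de <- stats::setNames(
    apply(b$key$genes[, cde_cols, drop = FALSE], 1L,
          function(x) any(x != 1)), b$key$genes$gene_id)

  conf_rows <- list()
  de_all <- list(); eq_all <- list()
  for (n_cells in grid) {
    idx <- downsample_cells(b$cells, n_cells,
                            seed = substream_seed(seed, paste0("ds", n_cells)))
    cnt <- b$counts[, idx, drop = FALSE]
    meta <- b$cells[idx, , drop = FALSE]
    if (two_cohorts) {
      cond_by_ind <- stats::setNames(b$key$individuals$condition,
                                     b$key$individuals$individual)
      de <- de_test_pseudobulk(cnt, meta$individual, cond_by_ind)
      cs <- score_discoveries(truth_de, de, qthr)
      de$cells_per_individual <- n_cells
      de_all[[as.character(n_cells)]] <- de
      conf_rows[[length(conf_rows) + 1L]] <-
        data.frame(analysis = "de", cells_per_individual = n_cells,
                   TP = cs$TP, FP = cs$FP, FN = cs$FN, TN = cs$TN,
                   tpr = cs$tpr, fdr = cs$fdr)
    }
    agg <- aggregate_counts(cnt, meta$individual, method = "mean")
    eq <- map_eqtl_simple(agg, b$genotypes, b$annotation,
                          window_bp = window)
    cs <- score_discoveries(truth_eqtl, eq, qthr)
    eq$cells_per_individual <- n_cells
    eq_all[[as.character(n_cells)]] <- eq
    conf_rows[[length(conf_rows) + 1L]] <-
      data.frame(analysis = "eqtl", cells_per_individual = n_cells,
                 TP = cs$TP, FP = cs$FP, FN = cs$FN, TN = cs$TN,
                 tpr = cs$tpr, fdr = cs$fdr)
    log_stage("evaluate: %d cells/individual done", n_cells)
  }
  confusion <- do.call(rbind, conf_rows)
  write_tsv(confusion, file.path(config$out, "confusion.tsv"))
  if (length(de_all) > 0)
    write_tsv(do.call(rbind, de_all), file.path(config$out,
                                                "de_results.tsv"))
  write_tsv(do.call(rbind, eq_all), file.path(config$out,
                                              "eqtl_results.tsv"))
  invisible(confusion)
}
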