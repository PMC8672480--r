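#' Read / write an expression matrix as TSV
#'
#' Genes in rows, a header row of individual or cell IDs, gene IDs in
#' the first column.
#'
#' @param path TSV file.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_matrix_tsv
#' @param mat numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Matrix Market count matrix with row/column TSVs
#'
#' Expects `<prefix>.mtx` plus `<prefix>_rows.tsv` and
#' `<prefix>_cols.tsv` holding the row and column identifiers (one per
#' line, no header).
#'
#' @param prefix path prefix.
#' @return a sparse matrix with dimnames.
#' @export
read_matrix_mtx <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  rn <- readLines(paste0(prefix, "_rows.tsv"))
  cn <- readLines(paste0(prefix, "_cols.tsv"))
  dimnames(m) <- list(rn, cn)
  methods::as(m, "CsparseMatrix")
}

write_matrix_mtx <- function(mat, prefix) {
  Matrix::writeMM(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                              "generalMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(mat), paste0(prefix, "_rows.tsv"))
  writeLines(colnames(mat), paste0(prefix, "_cols.tsv"))
  invisible(prefix)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export / import the simulation key
#'
#' Writes `key.tsv` (per-gene ground truth), `key_individuals.tsv`
#' (per-individual condition) and `key_means.tsv` (baseline means) into
#' a directory; `read_sim_key` reconstructs the [sim_key] object.
#'
#' @param key a `sim_key`.
#' @param dir output directory (created if missing).
#' @return the directory (write) or a `sim_key` (read), invisibly for
#'   the writer.
#' @export
write_sim_key <- function(key, dir) {
  stopifnot(inherits(key, "sim_key"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(key$genes, file.path(dir, "key.tsv"))
  write_tsv(key$individuals, file.path(dir, "key_individuals.tsv"))
  write_matrix_tsv(key$baseline_means, file.path(dir, "key_means.tsv"))
  invisible(dir)
}

#' @rdname write_sim_key
#' @export
read_sim_key <- function(dir) {
  genes <- utils::read.delim(file.path(dir, "key.tsv"),
                             stringsAsFactors = FALSE)
  individuals <- utils::read.delim(file.path(dir, "key_individuals.tsv"),
                                   stringsAsFactors = FALSE)
  means <- read_matrix_tsv(file.path(dir, "key_means.tsv"))
  genes$snp_id <- as.character(genes$snp_id)
  genes$specificity <- as.character(genes$specificity)
  genes$coreg_partner <- as.character(genes$coreg_partner)
  structure(list(genes = genes, individuals = individuals,
                 baseline_means = means),
            class = "sim_key")
}

#' Write a simulated bundle to an output directory
#'
#' Writes sparse counts (`counts.mtx` with row/col TSVs), `genes.tsv`
#' (annotation), `cells.tsv` (cell metadata), the simulation key
#' ([write_sim_key()]), `genotypes.tsv` (dosages with SNP metadata) and
#' `params.json`.
#'
#' @param bundle a `count_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_count_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "count_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_mtx(bundle$counts, file.path(dir, "counts"))
  write_tsv(bundle$annotation, file.path(dir, "genes.tsv"))
  write_tsv(bundle$cells, file.path(dir, "cells.tsv"))
  write_sim_key(bundle$key, dir)
  G <- bundle$genotypes
  gdf <- data.frame(snp_id = G$snp_ids, chrom = G$chrom, pos = G$pos,
                    as.data.frame(G$dosage, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(gdf, file.path(dir, "genotypes.tsv"))
  write_params(bundle$params, file.path(dir, "params.json"))
  invisible(dir)
}

#' Read a simulated bundle from a directory
#'
#' @param dir a directory written by [write_count_bundle()].
#' @return a list with `counts`, `cells`, `key`, `genotypes`,
#'   `annotation`, `params`.
#' @export
read_count_bundle <- function(dir) {
  stop_if(!file.exists(file.path(dir, "key.tsv")),
          "missing simulation key (key.tsv) in ", dir)
  counts <- read_matrix_mtx(file.path(dir, "counts"))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  key <- read_sim_key(dir)
  gdf <- utils::read.delim(file.path(dir, "genotypes.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  G <- genotype_matrix(as.matrix(gdf[, -(1:3), drop = FALSE]),
                       chrom = gdf$chrom, pos = gdf$pos,
                       snp_ids = gdf$snp_id)
  annotation <- read_gene_annotation(file.path(dir, "genes.tsv"))
  params <- read_params(file.path(dir, "params.json"))
  list(counts = counts, cells = cells, key = key, genotypes = G,
       annotation = annotation, params = params)
}

#' Re-validate an output directory against the key invariants
#'
#' Checks, from the files alone, that count dimensions match the
#' metadata, dosages are in 0/1/2, every keyed eSNP satisfies the MAF
#' bounds and the distance constraint of the parameter file, and betas
#' of keyed eGenes are positive (unless sign flips were enabled).
#'
#' @param dir a bundle directory.
#' @return `TRUE` invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_output_dir <- function(dir) {
  b <- read_count_bundle(dir)
  stop_if(ncol(b$counts) != nrow(b$cells),
          "counts columns do not match cell metadata")
  stop_if(nrow(b$counts) != nrow(b$key$genes),
          "counts rows do not match key")
  stop_if(!all(b$genotypes$dosage %in% c(0, 1, 2)),
          "dosages outside 0/1/2")
  eq <- b$key$genes[!is.na(b$key$genes$snp_id), , drop = FALSE]
  if (nrow(eq) > 0) {
    si <- match(eq$snp_id, b$genotypes$snp_ids)
    stop_if(anyNA(si), "keyed eSNP missing from genotypes")
    ep <- b$params$eqtl
    stop_if(any(b$genotypes$maf[si] < ep$maf_min - 1e-9 |
                  b$genotypes$maf[si] > ep$maf_max + 1e-9),
            "keyed eSNP violates MAF bounds")
    gi <- match(eq$gene_id, b$annotation$gene_id)
    dist <- abs(b$genotypes$pos[si] - b$annotation$pos[gi])
    stop_if(any(dist > ep$dist_max |
                  b$genotypes$chrom[si] != b$annotation$chrom[gi]),
            "keyed eSNP violates the distance constraint")
    if (ep$sign_flip_prob == 0)
      stop_if(any(eq$beta <= 0), "non-positive eQTL beta in key")
  }
  invisible(TRUE)
}
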