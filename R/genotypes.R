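#' Construct a genotype dosage matrix
#'
#' Holds minor-allele dosages (0/1/2) for SNPs x individuals. Minor
#' allele frequencies are always recomputed from the dosages, never
#' trusted from input; columns whose alternate-allele frequency exceeds
#' 0.5 are expected to have been flipped by the reader.
#'
#' @param dosage integer matrix SNPs x individuals with values 0/1/2.
#' @param chrom per-SNP chromosome.
#' @param pos per-SNP 1-based position (bp).
#' @param snp_ids,sample_ids identifiers; defaults derived from
#'   dimnames or generated.
#' @return an object of class `genotype_matrix` with fields `dosage`,
#'   `snp_ids`, `chrom`, `pos`, `sample_ids`, `maf`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, snp_ids = NULL,
                            sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  stop_if(!all(dosage %in% c(0, 1, 2)), "dosages must be 0, 1 or 2")
  n_snp <- nrow(dosage)
  stop_if(length(chrom) != n_snp || length(pos) != n_snp,
          "chrom/pos must have one entry per SNP")
  stop_if(any(pos < 1), "positions must be 1-based (>= 1)")
  if (is.null(snp_ids)) snp_ids <- rownames(dosage)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%06d", seq_len(n_snp))
  if (is.null(sample_ids)) sample_ids <- colnames(dosage)
  if (is.null(sample_ids))
    sample_ids <- sprintf("sample%03d", seq_len(ncol(dosage)))
  dimnames(dosage) <- list(snp_ids, sample_ids)
  af <- rowMeans(dosage) / 2
  maf <- pmin(af, 1 - af)
  structure(list(dosage = dosage, snp_ids = snp_ids,
                 chrom = as.character(chrom), pos = as.integer(pos),
                 sample_ids = sample_ids, maf = maf),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d SNPs x %d individuals (%d chromosome%s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1L) "" else "s"))
  cat(sprintf("  MAF range: %.4f - %.4f\n", min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read genotypes from a VCF file
#'
#' Keeps biallelic SNP records with complete GT fields; multiallelic
#' records and records with any missing genotype are dropped with a
#' message reporting the counts. Dosages count copies of the minor
#' allele: when the alternate allele frequency exceeds 0.5, the dosage
#' is flipped to `2 - alt dosage`.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_multi <- sum(!bi)
  v <- v[bi, ]
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                 error = function(e) NULL)
  stop_if(is.null(gt) || all(is.na(gt)), "VCF has no GT field")
  alt_count <- function(g) {
    ifelse(is.na(g), NA_integer_,
           lengths(regmatches(g, gregexpr("1", g))))
  }
  dos <- apply(gt, 2L, alt_count)
  dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  complete <- rowSums(is.na(dos)) == 0L
  n_missing <- sum(!complete)
  if (n_multi > 0 || n_missing > 0)
    message(sprintf("dropped %d multiallelic and %d missing-GT records",
                    n_multi, n_missing))
  dos <- dos[complete, , drop = FALSE]
  stop_if(nrow(dos) == 0L, "zero SNPs after parsing VCF")
  fix <- vcfR::getFIX(v)[complete, , drop = FALSE]
  af <- rowMeans(dos) / 2
  flip <- af > 0.5
  dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  genotype_matrix(dos, chrom = fix[, "CHROM"],
                  pos = as.integer(fix[, "POS"]), snp_ids = ids)
}

#' Filter SNPs by minor allele frequency and missingness
#'
#' Keeps SNPs with recomputed MAF strictly greater than `maf_min`
#' (a SNP at exactly the threshold is removed) and a missing-dosage
#' fraction at most `max_missing`. SNP order is preserved.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param max_missing maximum tolerated fraction of missing dosages.
#' @return the filtered [genotype_matrix()].
#' @export
filter_genotypes <- function(G, maf_min = 0.05, max_missing = 0) {
  stopifnot(inherits(G, "genotype_matrix"))
  miss <- rowMeans(is.na(G$dosage))
  keep <- G$maf > maf_min & miss <= max_missing
  stop_if(!any(keep), "all SNPs removed by filtering")
  genotype_matrix(G$dosage[keep, , drop = FALSE],
                  chrom = G$chrom[keep], pos = G$pos[keep],
                  snp_ids = G$snp_ids[keep], sample_ids = G$sample_ids)
}

#' Simulate unstructured genotype dosages
#'
#' Each SNP gets an allele frequency drawn uniformly from `maf_range`
#' and independent per-individual dosages from Binomial(2, freq);
#' positions are uniform over `[1, chrom_length]` and sorted. There is
#' no linkage or population structure. SNPs that come out monomorphic
#' are redrawn.
#'
#' @param n_snps,n_individuals dimensions.
#' @param maf_range length-2 vector within (0, 0.5].
#' @param chrom_length chromosome length in bp.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_snps, n_individuals,
                               maf_range = c(0.05, 0.5),
                               chrom_length = 5e7, seed = 1L,
                               chrom = "chr1") {
  stop_if(n_individuals < 2, "need at least 2 individuals")
  stop_if(!(maf_range[1] > 0 && maf_range[2] <= 0.5 &&
              maf_range[1] <= maf_range[2]),
          "maf_range must lie within (0, 0.5]")
  set.seed(seed)
  freq <- stats::runif(n_snps, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n_snps * n_individuals, 2L, rep(freq, n_individuals)),
                nrow = n_snps)
  mono <- which(rowSums(dos) %in% c(0L, 2L * n_individuals))
  tries <- 0L
  while (length(mono) > 0L && tries < 100L) {
    dos[mono, ] <- stats::rbinom(length(mono) * n_individuals, 2L,
                                 rep(freq[mono], n_individuals))
    mono <- mono[rowSums(dos[mono, , drop = FALSE]) %in%
                   c(0L, 2L * n_individuals)]
    tries <- tries + 1L
  }
  stop_if(length(mono) > 0L, "could not draw polymorphic dosages; increase n_individuals")
  pos <- sort(sample.int(chrom_length, n_snps, replace = FALSE))
  genotype_matrix(dos, chrom = rep(chrom, n_snps), pos = pos)
}

#' Construct a gene annotation table
#'
#' @param gene_ids unique gene identifiers.
#' @param chrom per-gene chromosome.
#' @param pos per-gene 1-based anchor position (TSS or midpoint, at the
#'   user's choice).
#' @return a `data.frame` with class `gene_annotation`.
#' @export
gene_annotation <- function(gene_ids, chrom, pos) {
  stop_if(anyDuplicated(gene_ids) > 0, "gene ids must be unique")
  stop_if(any(pos < 1), "gene positions must be >= 1")
  structure(data.frame(gene_id = as.character(gene_ids),
                       chrom = as.character(chrom), pos = as.integer(pos),
                       stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

#' Simulate a gene annotation with uniformly placed genes
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return a [gene_annotation()].
#' @export
simulate_gene_annotation <- function(n_genes, chrom_length = 5e7,
                                     seed = 1L, chrom = "chr1") {
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_genes, replace = FALSE))
  gene_annotation(sprintf("gene%05d", seq_len(n_genes)),
                  chrom = rep(chrom, n_genes), pos = pos)
}

#' Read a gene annotation TSV (columns gene_id, chrom, pos)
#'
#' @param path TSV path with a header.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if(!all(c("gene_id", "chrom", "pos") %in% names(tab)),
          "annotation needs columns gene_id, chrom, pos")
  gene_annotation(tab$gene_id, tab$chrom, tab$pos)
}

#' Assign eSNPs and effect sizes to eGenes
#'
#' Chooses `round(eqtl_prob * n_genes)` eGenes uniformly among genes
#' with at least one eligible eSNP (same chromosome, distance at most
#' `dist_max`, MAF within `[maf_min, maf_max]`), assigns each a
#' uniformly chosen eligible eSNP, and samples effect sizes from
#' gamma(`es_shape`, `es_rate`). eSNPs of non-co-regulated eGenes are
#' drawn without replacement, so an eSNP is shared only through
#' co-regulation: `round(coreg_prop * n_eGenes)` eGenes (rounded down
#' to an even count) are arranged in disjoint pairs whose second member
#' inherits the first member's eSNP, which must satisfy the second
#' gene's own distance constraint. Specificity labels (`global`,
#' `group:<g>`, `condition:<c>`) are drawn per the specificity
#' proportions when more than one group/condition is present.
#'
#' @param genes a [gene_annotation()].
#' @param G a [genotype_matrix()].
#' @param params an [eqtl_params()].
#' @param groups character vector of cell-group names.
#' @param conditions character vector of condition-cohort names.
#' @param seed integer seed.
#' @return a `data.frame` (class `eqtl_key`) with one row per eGene:
#'   `gene_id`, `snp_id`, `beta`, `specificity`, `coreg_partner`.
#' @export
assign_eqtl <- function(genes, G, params = eqtl_params(),
                        groups = "group1", conditions = "condition1",
                        seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  set.seed(seed)

  snp_ok <- G$maf >= params$maf_min & G$maf <= params$maf_max
  # eligible SNP index set per gene (SNPs sorted by position per chrom)
  eligible <- lapply(seq_len(nrow(genes)), function(i) {
    which(snp_ok & G$chrom == genes$chrom[i] &
            abs(G$pos - genes$pos[i]) <= params$dist_max)
  })
  n_elig <- sum(lengths(eligible) > 0L)
  n_egenes <- round(params$eqtl_prob * nrow(genes))
  if (n_egenes == 0L)
    return(empty_eqtl_key())
  if (n_elig < nrow(genes))
    warning(sprintf("%d genes have no eligible eSNP and cannot be eGenes",
                    nrow(genes) - n_elig))
  stop_if(n_elig < n_egenes,
          sprintf("only %d genes have an eligible eSNP; %d eGenes requested",
                  n_elig, n_egenes))

  egenes <- sample(which(lengths(eligible) > 0L), n_egenes)

  # co-regulated pairs share the first member's eSNP
  n_coreg <- round(params$coreg_prop * n_egenes)
  n_coreg <- n_coreg - n_coreg %% 2L
  snp_id <- character(n_egenes)
  partner <- rep(NA_character_, n_egenes)
  paired <- logical(n_egenes)
  if (n_coreg > 0L) {
    pool <- sample(seq_len(n_egenes)) # order in which to attempt pairing
    n_pairs_needed <- n_coreg %/% 2L
    n_pairs <- 0L
    i <- 1L
    while (n_pairs < n_pairs_needed && i <= length(pool)) {
      a <- pool[i]
      if (!paired[a]) {
        ea <- eligible[[egenes[a]]]
        cands <- pool[!paired[pool] & pool != a]
        for (b in sample_keep(cands)) {
          shared <- intersect(ea, eligible[[egenes[b]]])
          if (length(shared) > 0L) {
            s <- shared[sample.int(length(shared), 1L)]
            snp_id[a] <- snp_id[b] <- G$snp_ids[s]
            partner[a] <- genes$gene_id[egenes[b]]
            partner[b] <- genes$gene_id[egenes[a]]
            paired[a] <- paired[b] <- TRUE
            n_pairs <- n_pairs + 1L
            break
          }
        }
      }
      i <- i + 1L
    }
    stop_if(n_pairs < n_pairs_needed,
            sprintf("could only form %d of %d co-regulated pairs; widen dist_max or densify SNPs",
                    n_pairs, n_pairs_needed))
  }

  # remaining eGenes draw eSNPs without replacement
  used <- match(snp_id[paired], G$snp_ids)
  for (a in which(!paired)) {
    free <- setdiff(eligible[[egenes[a]]], used)
    stop_if(length(free) == 0L,
            sprintf("gene %s: all eligible eSNPs already used",
                    genes$gene_id[egenes[a]]))
    s <- free[sample.int(length(free), 1L)]
    snp_id[a] <- G$snp_ids[s]
    used <- c(used, s)
  }

  beta <- stats::rgamma(n_egenes, shape = params$es_shape,
                        rate = params$es_rate)
  if (params$sign_flip_prob > 0)
    beta <- beta * ifelse(stats::runif(n_egenes) < params$sign_flip_prob,
                          -1, 1)

  specificity <- rep("global", n_egenes)
  if (length(groups) > 1L && params$group_specific_prop > 0) {
    pick <- stats::runif(n_egenes) < params$group_specific_prop
    specificity[pick] <- paste0("group:",
                                sample(groups, sum(pick), replace = TRUE))
  }
  if (length(conditions) > 1L && params$condition_specific_prop > 0) {
    pick <- specificity == "global" &
      stats::runif(n_egenes) < params$condition_specific_prop
    specificity[pick] <- paste0("condition:",
                                sample(conditions, sum(pick),
                                       replace = TRUE))
  }

  key <- data.frame(gene_id = genes$gene_id[egenes], snp_id = snp_id,
                    beta = beta, specificity = specificity,
                    coreg_partner = partner, stringsAsFactors = FALSE)
  key <- key[order(match(key$gene_id, genes$gene_id)), , drop = FALSE]
  rownames(key) <- NULL
  class(key) <- c("eqtl_key", "data.frame")
  key
}

empty_eqtl_key <- function() {
  structure(data.frame(gene_id = character(), snp_id = character(),
                       beta = numeric(), specificity = character(),
                       coreg_partner = character(),
                       stringsAsFactors = FALSE),
            class = c("eqtl_key", "data.frame"))
}

# sample() with the length-1 surprise removed
sample_keep <- function(x) if (length(x) <= 1L) x else sample(x)
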