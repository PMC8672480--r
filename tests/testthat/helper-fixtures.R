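# Shared fixture builders: everything is generated in code at test time.

# five handwritten VCF records over 4 samples: one triallelic (dropped),
# one with a missing GT (dropped), one whose ALT is the major allele
# (dosage flipped)
write_vcf_fixture <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/1", "0/0", sep = "\t"),
    paste("chr1", "300", "rs3", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "0/0", "1/1", sep = "\t"),
    paste("chr1", "400", "rs4", "T", "C", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/1", "1/1", sep = "\t"),
    paste("chr1", "500", "rs5", "A", "C", ".", "PASS", ".", "GT",
          "0/1", "./.", "0/0", "0/1", sep = "\t"))
  writeLines(lines, path)
  path
}

# a small genotype panel with known positions for assignment tests
toy_genotypes <- function(n_snps = 200, n_ind = 20, seed = 11,
                          chrom_length = 2e6) {
  simulate_genotypes(n_snps, n_ind, maf_range = c(0.1, 0.5),
                     chrom_length = chrom_length, seed = seed)
}

toy_annotation <- function(n_genes = 20, seed = 12, chrom_length = 2e6) {
  simulate_gene_annotation(n_genes, chrom_length = chrom_length,
                           seed = seed)
}

small_params <- function(n_genes = 200L, n_ind = 6L, cells = 30L,
                         seed = 5L, ...) {
  update_params(default_params(), utils::modifyList(
    list(sc = list(n_genes = n_genes),
         design = list(n_individuals = n_ind,
                       cells_per_individual = cells,
                       master_seed = seed)),
    list(...)))
}
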