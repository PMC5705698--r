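# Small hand-built fixtures shared across test files.

mk_sumstats <- function(ids, pos, p, chrom = "1") {
  data.table::data.table(
    snp_id = ids, chrom = chrom, pos = as.integer(pos),
    effect_allele = "G", other_allele = "A", p = p,
    beta = NA_real_, se = NA_real_, n = NA_integer_)
}

mk_panel <- function(ids, pos, maf = 0.3, chrom = "1") {
  data.table::data.table(
    snp_id = ids, chrom = chrom, pos = as.integer(pos),
    ref_allele = "A", alt_allele = "G",
    maf = rep_len(maf, length(ids)))
}

mk_ld <- function(a, b, r2) {
  ld_store(data.table::data.table(snp_a = a, snp_b = b, r2 = r2))
}

empty_ld <- function() {
  ld_store(data.table::data.table(snp_a = character(0),
                                  snp_b = character(0), r2 = numeric(0)))
}

# one-exon-list gene model row
mk_gene <- function(gene_id, start, end, strand = "+",
                    gene_type = "protein_coding", chrom = "1",
                    exon_start = NULL, exon_end = NULL,
                    symbol = gene_id) {
  gm <- data.table::data.table(
    gene_id = gene_id, symbol = symbol, gene_type = gene_type,
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand,
    exon_start = list(as.integer(if (is.null(exon_start)) start else exon_start)),
    exon_end = list(as.integer(if (is.null(exon_end)) end else exon_end)))
  validate_gene_models(gm)
  gm
}

mk_genes <- function(...) {
  gm <- data.table::rbindlist(list(...))
  validate_gene_models(gm)
  gm
}

mk_snps <- function(ids, pos, chrom = "1") {
  data.table::data.table(snp_id = ids, chrom = chrom, pos = as.integer(pos))
}

# expression object from a genes x samples matrix and a tissue factor
mk_expr <- function(mat, tissues_per_sample) {
  structure(list(mat = mat,
                 tissue_of = stats::setNames(tissues_per_sample,
                                             colnames(mat))),
            class = "pg_expr")
}

# random null expression fixture with a balanced tissue design
mk_tissue_mat <- function(n_genes, samples_per_tissue, tissues,
                          mean = 2, sd = 0.5) {
  n_s <- samples_per_tissue * length(tissues)
  samples <- paste0(rep(tissues, each = samples_per_tissue), "_",
                    seq_len(n_s))
  m <- matrix(pmax(2^stats::rnorm(n_genes * n_s, mean, sd) - 1, 0),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  mk_expr(m, rep(tissues, each = samples_per_tissue))
}
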