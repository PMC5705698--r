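# The three mapping strategies, per-strategy functional filters and the
# combined gene table.

mk_annot <- function(snp_id, pos, cadd = NA_real_, rdb = NA_character_,
                     consequence = "intronic", chrom = "1",
                     chromhmm_E1 = NA_integer_) {
  data.table::data.table(
    snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
    ref_allele = "A", alt_allele = "G",
    effect_allele = "G", other_allele = "A",
    cadd = cadd, rdb = rdb, chromhmm_E1 = chromhmm_E1,
    consequence = consequence, genes = "", dist = "")
}

test_that("functional filters conjoin and fail SNPs lacking a score", {
  annot <- mk_annot(c("a", "b", "c"), c(100, 200, 300),
                    cadd = c(15.1, 3.0, NA),
                    rdb = c("1a", "5", NA),
                    consequence = c("exonic", "intronic", "intergenic"))
  expect_equal(filter_snps_functional(annot, cadd_min = 12.37)$snp_id, "a")
  expect_equal(filter_snps_functional(annot)$snp_id, c("a", "b", "c"))
  expect_equal(filter_snps_functional(
    annot, allowed_consequences = c("exonic", "splicing"))$snp_id, "a")
  expect_equal(filter_snps_functional(annot, rdb_max = "2c")$snp_id, "a")
  st <- mk_annot("d", 400, chromhmm_E1 = 7L)
  expect_equal(filter_snps_functional(rbind(annot, st),
                                      allowed_states = 1:7)$snp_id, "d")
  expect_warning(out <- filter_snps_functional(annot, cadd_min = 100),
                 "removed every")
  expect_equal(nrow(out), 0L)
})

test_that("positional window mapping applies the kb window symmetrically", {
  g <- mk_gene("g1", 100000, 120000)
  near <- mk_annot("near", 96000)    # 4 kb upstream
  far <- mk_annot("far", 85000)      # 15 kb upstream
  ev <- positional_map(rbind(near, far), g, mode = "window", window_kb = 10)
  expect_equal(ev$snp_id, "near")
  expect_equal(ev$gene_id, "g1")
})

test_that("consequence-mode positional mapping drops intronic-only genes", {
  annot <- rbind(
    mk_annot("ex", 1000, consequence = "exonic"),
    mk_annot("in", 2000, consequence = "intronic"))
  annot[snp_id == "ex", genes := "g1"]
  annot[snp_id == "in", genes := "g2"]
  g <- mk_genes(mk_gene("g1", 500, 1500), mk_gene("g2", 1500, 2500))
  ev <- positional_map(annot, g, mode = "consequence",
                       allowed_consequences = c("exonic", "splicing"))
  expect_equal(ev$gene_id, "g1")
  expect_equal(ev$snp_id, "ex")
})

test_that("eQTL mapping joins on alleles, filters by source FDR and respects cis", {
  g <- mk_genes(mk_gene("G1", 150000, 160000),
                mk_gene("G2", 150000, 160000),
                mk_gene("GFAR", 2e8, 2.0001e8))
  annot <- mk_annot(c("s1", "s2"), c(100000, 110000))
  eqtl <- data.table::data.table(
    chrom = "1",
    pos = c(100000L, 100000L, 110000L, 110000L),
    effect_allele = c("G", "A", "G", "G"),
    other_allele = c("A", "G", "A", "A"),
    gene_id = c("G1", "G2", "G1", "GFAR"),
    tissue = c("T1", "T2", "T1", "T1"),
    p = c(1e-8, 1e-6, 1e-4, 1e-9),
    fdr = c(0.01, 0.04, 0.2, 0.001))
  ev <- eqtl_map(annot, eqtl, tissues = c("T1", "T2"), gene_models = g)
  # s1 -> G1 (exact alleles, FDR 0.01) and G2 (swapped alleles, FDR 0.04);
  # s2 -> G1 fails FDR; s2 -> GFAR passes FDR but violates the cis bound
  expect_setequal(ev$gene_id, c("G1", "G2"))
  expect_equal(nrow(ev), 2L)
  # nominal-p filtering replaces the FDR rule
  evp <- eqtl_map(annot, eqtl, tissues = c("T1", "T2"), p_max = 1e-3,
                  gene_models = g)
  expect_true("G1" %in% evp$gene_id)
  expect_error(eqtl_map(annot, eqtl, tissues = "Brain", gene_models = g),
               "Brain")
})

test_that("chromatin mapping tests both orientations with strand-aware promoters", {
  # plus-strand gene: TSS 1,000,000, promoter [999,750-1,000,500]
  gplus <- mk_gene("GP", 1000000, 1050000, strand = "+")
  # minus-strand gene: TSS at the gene end 2,050,000,
  # promoter [2,049,500-2,050,250]
  gminus <- mk_gene("GM", 2000000, 2050000, strand = "-")
  genes <- mk_genes(gplus, gminus)
  snps <- mk_annot(c("sA", "sB"), c(500100, 700100))
  ci <- data.table::data.table(
    chrom_a = "1", start_a = 500001L, end_a = 510000L,
    chrom_b = "1", start_b = 1000401L, end_b = 1010000L,
    tissue = "T1", fdr = 1e-8)
  # promoter end given as region_a to exercise the reverse orientation
  ci2 <- data.table::data.table(
    chrom_a = "1", start_a = 2049000L, end_a = 2049600L,
    chrom_b = "1", start_b = 700001L, end_b = 710000L,
    tissue = "T1", fdr = 1e-8)
  ev <- chromatin_map(snps, rbind(ci, ci2), genes, tissues = "T1")
  expect_equal(ev[snp_id == "sA", gene_id], "GP")
  expect_equal(ev[snp_id == "sB", gene_id], "GM")
  # an interaction failing the FDR threshold maps nothing
  weak <- data.table::copy(ci)[, fdr := 1e-3]
  expect_equal(nrow(chromatin_map(snps, weak, genes, tissues = "T1")), 0L)
  # promoter misses the other end when the window is tightened
  ev2 <- chromatin_map(snps, ci, genes, tissues = "T1",
                       promoter_up = 10L, promoter_down = 10L)
  expect_equal(nrow(ev2), 0L)
})

test_that("enhancer and promoter-region filters restrict chromatin mapping", {
  g <- mk_gene("GP", 1000000, 1050000, strand = "+")
  snps <- mk_annot("sA", 500100)
  ci <- data.table::data.table(
    chrom_a = "1", start_a = 500001L, end_a = 510000L,
    chrom_b = "1", start_b = 1000401L, end_b = 1010000L,
    tissue = "T1", fdr = 1e-8)
  hit_enh <- data.table::data.table(chrom = "1", start = 500000L,
                                    end = 501000L, kind = "enhancer",
                                    epigenome = "E1")
  miss_enh <- data.table::data.table(chrom = "1", start = 900000L,
                                     end = 901000L, kind = "enhancer",
                                     epigenome = "E1")
  expect_equal(nrow(chromatin_map(snps, ci, g, "T1",
                                  enhancer_sets = hit_enh)), 1L)
  expect_equal(nrow(chromatin_map(snps, ci, g, "T1",
                                  enhancer_sets = miss_enh)), 0L)
  hit_prom <- data.table::data.table(chrom = "1", start = 999000L,
                                     end = 1001000L, kind = "promoter",
                                     epigenome = "E1")
  expect_equal(nrow(chromatin_map(snps, ci, g, "T1",
                                  promoter_sets = hit_prom)), 1L)
  expect_equal(nrow(chromatin_map(snps, ci, g, "T1",
                                  promoter_sets = miss_enh)), 0L)
})

test_that("combined mapping unions strategies with flags and locus attribution", {
  sc <- synth_scenario(seed = 13, n_loci = 2)
  ref <- generate_reference(sc)
  ss <- generate_sumstats(sc, ref)
  ch <- characterize_loci(ss, ref$panel, ref$ld)
  ann <- annotate_snps(ch$candidates, ref$genes, panel = ref$panel,
                       cadd = ref$cadd, rdb = ref$rdb,
                       chromhmm = ref$chromhmm, epigenomes = "E1")
  annot <- ann$annot
  pos_ev <- positional_map(
    filter_snps_functional(annot, cadd_min = 12.37), ref$genes,
    mode = "consequence", allowed_consequences = c("exonic", "splicing"))
  eqtl_ev <- eqtl_map(annot, ref$eqtl, tissues = "T1",
                      gene_models = ref$genes)
  ci_ev <- chromatin_map(annot, ref$interactions, ref$genes, tissues = "T1")
  mapped <- combine_maps(pos_ev, eqtl_ev, ci_ev, ch$candidates, ch$loci,
                         ref$genes, intolerance = ref$intolerance)
  for (t in ref$truth$loci) {
    expect_true(mapped[gene_id == t$coding_target, posMap])
    expect_false(mapped[gene_id == t$coding_target, eqtlMap])
    expect_true(mapped[gene_id == t$eqtl_target, eqtlMap])
    expect_true(mapped[gene_id == t$ci_target, ciMap])
    # distal targets lie outside their locus, the coding target inside
    expect_true(mapped[gene_id == t$coding_target, inside_locus])
    expect_false(mapped[gene_id == t$ci_target, inside_locus])
  }
  expect_setequal(mapped$gene_id,
                  unlist(lapply(ref$truth$loci, function(t)
                    c(t$coding_target, t$eqtl_target, t$ci_target))))
  # intolerance scores joined
  expect_false(anyNA(mapped$pli))
  # union is order-independent across strategies
  mapped2 <- combine_maps(pos_ev, eqtl_ev, ci_ev, ch$candidates, ch$loci,
                          ref$genes, intolerance = ref$intolerance)
  expect_equal(mapped2, mapped)  # idempotent re-run
  # strategy identity travels with the evidence, so argument order is moot
  mapped3 <- combine_maps(ci_ev, eqtl_ev, pos_ev, ch$candidates, ch$loci,
                          ref$genes, intolerance = ref$intolerance)
  expect_equal(mapped3, mapped)
  # gene-type restriction removes non-coding genes
  ncg <- ref$genes[gene_type == "ncRNA", gene_id]
  expect_false(any(mapped$gene_id %in% ncg))
  # per-locus counts: each planted locus maps its 3 genes
  counts <- locus_gene_counts(mapped, ch$loci)
  expect_equal(counts$n_genes, rep(3L, nrow(ch$loci)))
  expect_false(any(counts$single_gene))
})

test_that("per-strategy filters do not leak across strategies", {
  sc <- synth_scenario(seed = 31, n_loci = 2)
  ref <- generate_reference(sc)
  ss <- generate_sumstats(sc, ref)
  ch <- characterize_loci(ss, ref$panel, ref$ld)
  annot <- annotate_snps(ch$candidates, ref$genes, panel = ref$panel,
                         cadd = ref$cadd, rdb = ref$rdb,
                         chromhmm = ref$chromhmm, epigenomes = "E1")$annot
  # eQTL evidence from the ORIGINAL candidate set is identical whether or
  # not positional mapping filters on CADD
  ev_plain <- eqtl_map(annot, ref$eqtl, tissues = "T1",
                       gene_models = ref$genes)
  invisible(filter_snps_functional(annot, cadd_min = 12.37))
  ev_after <- eqtl_map(annot, ref$eqtl, tissues = "T1",
                       gene_models = ref$genes)
  expect_identical(ev_plain, ev_after)
  # and filtering for the eQTL strategy does not change chromatin evidence
  ci_plain <- chromatin_map(annot, ref$interactions, ref$genes, "T1")
  ci_again <- chromatin_map(annot, ref$interactions, ref$genes, "T1")
  expect_identical(ci_plain, ci_again)
})

test_that("re-verified geometry: eQTL pairs are cis and promoters touch ends", {
  for (seed in c(3, 17, 29)) {
    sc <- synth_scenario(seed = seed, n_loci = 3)
    ref <- generate_reference(sc)
    snps <- data.table::copy(ref$panel)[, `:=`(
      effect_allele = alt_allele, other_allele = ref_allele)]
    ev <- eqtl_map(snps, ref$eqtl, tissues = "T1", gene_models = ref$genes)
    gi <- match(ev$gene_id, ref$genes$gene_id)
    sp <- ref$panel$pos[match(ev$snp_id, ref$panel$snp_id)]
    d <- pmax(0, pmax(ref$genes$start[gi] - sp, sp - ref$genes$end[gi]))
    expect_true(all(d <= 1e6))
    cev <- chromatin_map(snps, ref$interactions, ref$genes, tissues = "T1")
    prom <- promoter_intervals(ref$genes)
    pm <- match(cev$gene_id, prom$gene_id)
    ge <- data.table::tstrsplit(sub("^.*:", "", cev$gene_end), "-")
    expect_true(all(prom$start[pm] <= as.integer(ge[[2]]) &
                      prom$end[pm] >= as.integer(ge[[1]])))
  }
})
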