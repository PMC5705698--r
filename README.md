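# postgwas

Offline post-GWAS functional annotation and gene prioritization for R.

A genome-wide association study ends with a table of SNP p-values; the
biology starts with genes.  In between sit linkage disequilibrium (LD),
which smears signal across correlated variants, and the fact that most
associated SNPs are non-coding.  `postgwas` closes that gap as a
scriptable, fully offline pipeline for statistical geneticists: it takes
GWAS summary statistics plus user-supplied reference tables and produces
characterized genomic risk loci, functionally annotated candidate SNPs,
genes prioritized through three independent mapping strategies, and
tissue/pathway enrichment for the resulting gene list.  No web service, no
downloads at run time, byte-deterministic outputs.

## What it computes

**Risk loci (snp2gene step 1).** Greedy LD clumping of genome-wide
significant SNPs (p < 5×10⁻⁸, pairwise r² < 0.6) yields *independent
significant SNPs*; a second pass at r² < 0.1 yields *lead SNPs*.
*Candidate SNPs* are all reference-panel variants with r² ≥ 0.6 to an
independent significant SNP — including proxies absent from the GWAS
input — filtered at MAF ≥ 0.01.  LD blocks closer than 250 kb merge into
one *genomic risk locus*.

**SNP annotation (step 2).** Each candidate gets a positional consequence
(exonic / splicing / intronic / ncRNA / up-/downstream / intergenic with
the two flanking genes), CADD deleteriousness, RegulomeDB category,
per-epigenome 15-state chromatin state (200-bp bins), and GWAS-catalog
matches by position.

**Gene mapping (step 3).** Three strategies with independent per-strategy
SNP filters: positional (gene body ± 10 kb, or selected consequences such
as exonic/splicing with CADD ≥ 12.37 for deleterious-coding mapping),
cis-eQTL (source FDR ≤ 0.05, ≤ 1 Mb), and chromatin interaction (Hi-C
pairs at FDR ≤ 10⁻⁶; SNP on one end, strand-aware promoter
[TSS−250, TSS+500] on the other; optional enhancer/promoter-region
filters).  Evidence is combined as a set union with per-strategy flags,
pLI/ncRVIS intolerance scores and an inside-locus indicator.

**Gene-to-function (gene2func).** Tissue expression summaries
(winsorized log₂(RPKM+1) means; within-gene centered values), tissue
differentially-expressed gene (DEG) sets from pooled-variance t-tests
(Bonferroni p < 0.05, |log₂FC| ≥ 0.58, signed up/down sets), and
hypergeometric enrichment

&nbsp;&nbsp;&nbsp;&nbsp;p = Σᵢ₌ₖ^min(n,K) C(K,i)·C(N−K,n−i) / C(N,n)

against GMT gene-set collections and the DEG sets, with
Benjamini–Hochberg adjustment per data source.

A seeded synthetic-fixture generator (`synth_scenario()`,
`write_scenario()`) plants association blocks, causal coding SNPs, eQTL
targets, interaction targets and tissue effects, so the whole pipeline is
testable end-to-end against known truth.

## Worked example

Generate a three-locus synthetic study and run both flows:

```r
library(postgwas)
sc <- synth_scenario(seed = 7, n_loci = 3)
d <- tempfile(); write_scenario(sc, d)           # inputs + config.yaml + manifest
res <- run_snp2gene(file.path(d, "config.yaml"), out_dir = "out_s2g")
res$loci[, .(locus_id, chrom, start, end, top_snp, top_p, n_candidates)]
#>    locus_id  chrom   start     end top_snp       top_p n_candidates
#> 1:        1      1 1005000 1070000  rs1008 2.15905e-11           14
#> 2:        2      1 2275000 2340000  rs2008 9.55964e-11           14
#> 3:        3      1 3545000 3610000  rs3008 3.16851e-12           14
```

Three loci, each led by its planted causal SNP (`top_snp`, smallest p in
the locus), spanning the positional range of the 14 candidate SNPs that
survive the MAF filter.  The mapped-gene table shows which strategy
implicated each gene and whether the gene lies inside its locus:

```r
res$mapped[, .(gene_id, posMap, eqtlMap, ciMap, inside_locus, loci)]
#>           gene_id posMap eqtlMap  ciMap inside_locus   loci
#> 1: GENE_L1_CODING   TRUE   FALSE  FALSE         TRUE      1
#> 2:   GENE_L1_EQTL  FALSE    TRUE  FALSE        FALSE      1
#> 3:     GENE_L1_CI  FALSE   FALSE   TRUE        FALSE      1
#> ...                                        (9 genes, 3 per locus)
```

The coding gene is hit by a deleterious exonic SNP inside the locus; the
eQTL and interaction targets sit hundreds of kb outside it — exactly the
genes a proximity-only analysis would miss.  Chaining into gene2func:

```r
g2 <- run_gene2func(file.path(d, "config.yaml"), res$mapped$gene_id,
                    out_dir = "out_g2f")
g2$gs_enrichment$report[, .(set_name, N, K, n, k, p, adj_p)]
#>                  set_name     N     K     n     k            p        adj_p
#> 1:   PLANTED_EQTL_TARGETS    42     3     9     3 7.317073e-03 1.951220e-02
#> 2: PLANTED_CODING_TARGETS    42     3     9     3 7.317073e-03 1.951220e-02
#> 3:            PLANTED_ALL    42     9     9     9 2.242696e-09 1.794157e-08
```

Against the 42-gene protein-coding background, the 9 mapped genes overlap
the planted 9-gene set completely (k = n = K = 9, hypergeometric
p ≈ 2.2×10⁻⁹); random distractor sets do not reach the report (adjusted
p ≤ 0.05 and overlap ≥ 2).  The DEG-up enrichment likewise points to the
planted tissue T1.

Both runs write tab-separated tables (`GenomicRiskLoci.txt`,
`IndSigSNPs.txt`, `leadSNPs.txt`, `snps.txt`, `annot.txt`, `genes.txt`,
`eqtl.txt`, `ci.txt`; `gtex_summary.txt`, `deg.txt`,
`DEG_enrichment.txt`, `GS_enrichment.txt`) plus a `run_log.json` with
parameters, input checksums and filtered-row counts.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/postgwas.R simulate --seed 7 --out sim
Rscript inst/cli/postgwas.R snp2gene --config sim/config.yaml --out out_s2g
Rscript inst/cli/postgwas.R gene2func --config sim/config.yaml --genes genes.txt --out out_g2f
```

## Documentation

The methods vignette (`vignettes/postgwas-methods.Rmd`) describes the
model, the parameters with their defaults and rationale, what the
synthetic generator does and does not emulate, numerical edge cases, and
known limitations.
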