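---
title: "Methods: risk-locus characterization, gene mapping and gene-to-function analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-locus characterization, gene mapping and gene-to-function analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postgwas)
```

# The problem

A genome-wide association study (GWAS) reports a p-value per tested SNP, but
linkage disequilibrium (LD) smears association signal across correlated
variants, and most associated SNPs are non-coding.  Going from "a region of
low p-values" to "a short list of plausibly causal genes" requires three
ingredients: a disciplined definition of the associated region (the genomic
risk locus), functional annotation of every correlated variant in it, and
explicit SNP-to-gene links that do not rely on proximity alone.  `postgwas`
implements that workflow offline: all reference information (LD, gene
models, variant scores, cis-eQTLs, Hi-C interactions, expression, gene
sets) arrives as user-supplied tables, and every step is a deterministic
function of inputs plus a validated configuration.

# Risk-locus characterization

Let $p_i$ be the GWAS p-value of SNP $i$ and $r^2_{ij}$ the squared allelic
correlation between SNPs $i$ and $j$ in the reference panel.  The LD store
holds pre-computed pairs (as emitted by PLINK-style pipelines, with a
storage floor of $r^2 \ge 0.05$ and a 1 Mb distance cap); absent pairs are
treated as $r^2 = 0$ and self-LD is implicitly 1.

1. **Independent significant SNPs.** SNPs with $p < 5\times10^{-8}$ that are
   present in the panel are visited in ascending $p$; a SNP is selected iff
   its $r^2$ with every previously selected SNP is below 0.6.  This is the
   standard greedy clumping semantics: independence is enforced against the
   already-selected set, not as a maximum-independent-set problem, which
   keeps the procedure deterministic and matches common clumping tools.
   Ties in $p$ are broken by chromosome, position, then SNP id.  SNPs
   absent from the panel are excluded from LD-dependent steps with a logged
   count, because silently assuming $r^2 = 0$ for them would corrupt
   clumping.
2. **Candidate SNPs.** Every panel variant with $r^2 \ge 0.6$ to at least
   one independent significant SNP, including variants absent from the
   GWAS input; those keep a missing p-value and are flagged
   *non-GWAS-tagged*.  A minor-allele-frequency filter (default
   $\ge 0.01$) applies to candidates only and never removes an independent
   significant SNP.
3. **Lead SNPs.** A second greedy pass over the independent significant
   SNPs at $r^2 < 0.1$; every non-lead is assigned to the first selected
   lead it is correlated with at $r^2 \ge 0.1$.
4. **Risk loci.** Each independent significant SNP spans an LD block, the
   positional range of its candidate SNPs.  Blocks on a chromosome are
   merged left-to-right, transitively, while the gap between the next
   block's left edge and the running right edge is *strictly less than*
   250 kb; a gap of exactly 250,000 bp does not merge (literal reading of
   "closer than 250 kb").  Locus boundaries come from candidate-SNP
   positions, not from gene spans or padding.  Candidates are assigned to
   the locus of their best-correlated independent significant SNP (ties to
   the smaller p), so a candidate correlated with two unmerged loci is
   assigned once rather than duplicated.

Users may force pre-defined lead SNPs (they are selected unconditionally
before the greedy pass; a forced SNP without genome-wide significance is
kept with a warning, since upstream studies sometimes report leads from
combined analyses that the supplied discovery-phase input cannot
reproduce) and may restrict the whole analysis to pre-defined regions.

# SNP annotation

Candidate SNPs receive a positional consequence from a simplified
gene-based classifier with precedence splicing > exonic > intronic >
upstream/downstream > intergenic; non-protein-coding genes yield
`ncRNA_exonic` / `ncRNA_intronic`.  Splicing means "inside the intron,
within 2 bp of an exon–intron boundary" (`splice_bp = 2`); flanks are
strand-aware with `flank_bp = 1000`.  Both follow the conventions of
widely used variant annotators and are parameters.  Codon-level exonic
subclasses (missense, stop-gain) require CDS and codon logic that is out
of scope here; an optional per-variant override table can inject such
calls from an external annotator, and "deleterious coding" filtering is
expressed as consequence ∈ {exonic, splicing} ∧ CADD ≥ threshold.  UTR
classes would require CDS bounds the gene models do not carry, so exonic
is reported in their place.  A SNP overlapping several genes is annotated
to all of them with the highest-precedence consequence; intergenic SNPs
carry the two closest flanking genes with distances.

CADD scores join by chromosome, position and alleles — exact or swapped
(ref, alt) orientation; strand flips are not attempted because they are
error-prone without allele-frequency evidence.  RegulomeDB categories join
by position and use the ordered vocabulary `1a` … `7` (filtering keeps
categories at or before a threshold).  Chromatin states (1–15) join per
epigenome by containment in fixed 200-bp bins, the segmentation
convention of ChromHMM.  All score joins are left joins: missing entries
are expected, never errors, and the candidate set cardinality is
preserved.  GWAS-catalog matches are exact on (chromosome, position).

# Gene mapping

Three strategies run independently; each applies its own functional SNP
filter (CADD threshold, RegulomeDB category, chromatin-state set,
consequence set) to the *original* candidate set, so a filter configured
for one strategy can never change another strategy's evidence.

* **Positional** — window mode maps a SNP to genes whose span ±10 kb
  (default) contains it; consequence mode maps a SNP to its annotated
  gene(s) only when its consequence is in the selected set, so a gene
  containing only intronic candidates is not prioritized under an
  exonic/splicing restriction.
* **cis-eQTL** — candidates join significant SNP–gene pairs per selected
  tissue, filtered by the source-provided FDR (default ≤ 0.05) or
  optionally a nominal p-value.  The FDR column is used verbatim — it was
  computed by the source on its full test set, and recomputing it on a
  subset would be wrong.  The cis bound (≤ 1 Mb from SNP to gene body) is
  re-enforced against the gene models.
* **Chromatin interaction** — interactions per selected tissue are
  pre-filtered at FDR ≤ 1e-6 (default) and considered in both
  orientations: a SNP overlapping one end maps to genes whose promoter
  overlaps the other end.  The promoter is 250 bp upstream to 500 bp
  downstream of the TSS, mirrored on the minus strand
  ($[\mathrm{TSS}-500, \mathrm{TSS}+250]$) — the only coherent reading of
  an up/downstream window around a strand-aware TSS.  Optional filters
  require the SNP end to fall in predicted enhancer regions and the gene
  promoter to overlap predicted promoter regions of selected epigenomes.
  There is no distance bound and trans-chromosomal records are honored;
  promoter–promoter configurations (the SNP end itself inside the mapped
  gene's promoter) are allowed and flagged rather than dropped, since the
  data cannot distinguish direction.

Interval overlap is everywhere "≥ 1 shared base" on closed 1-based
intervals; BED/BEDPE input is converted on ingest so exactly one
coordinate convention exists internally.  The combined gene table is the
set union over strategies with per-strategy flags and supporting SNPs —
idempotent and order-independent — restricted by default to
protein-coding genes, with loss-of-function-intolerance (pLI) and ncRVIS
scores joined and an `inside_locus` indicator (eQTL and interaction
evidence regularly implicates genes outside the locus).  Per-locus mapped
gene counts support the "single prioritized gene" summary.

# Gene-to-function analysis

Expression input is a samples × genes RPKM matrix with a sample→tissue
map.  Genes are kept when their mean raw RPKM reaches 1 in at least one
tissue.  Two summaries are computed per gene and tissue: the tissue mean
of $\log_2(\min(\mathrm{RPKM}, 50) + 1)$ (winsorization caps outlier
samples so values compare across genes) and the same value centered to
zero mean across tissues within the gene (comparable across tissues;
centered values sum to zero per gene by construction).

Tissue differentially-expressed gene (DEG) sets use a two-sided
pooled-variance Student t-test per gene and tissue on per-sample
$\log_2(\mathrm{RPKM}+1)$ values, target tissue versus all other samples
pooled, $df = n_1 + n_2 - 2$.  Design choices worth stating explicitly:

* the test is the pooled-variance Student test (Welch is available behind
  a flag);
* the t-test input is *not* winsorized — winsorization belongs to the
  heatmap summaries, and 0.58 ≈ $\log_2 1.5$ is interpreted on the raw
  log scale; a flag exposes the winsorized alternative;
* the log fold change is the difference of group means on the log2 scale;
* Bonferroni correction spans *all* (gene × tissue) tests performed — the
  conservative scope — and is parameterizable per tissue;
* a gene joins a tissue's DEG set when corrected $p < 0.05$ and
  $|\mathrm{lfc}| \ge 0.58$; up/down sets split by the sign of $t$, and
  the two-sided set is exactly their union;
* degenerate inputs: zero pooled variance with equal means gives $p = 1$
  (no call); zero variance with unequal means is a perfect separation and
  is reported at the smallest representable p rather than NaN.

Enrichment of a gene list against gene-set collections and against the
DEG sets uses the hypergeometric upper tail
$p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
computed through the distribution's stable tail implementation.  Input
genes and sets are intersected with the background *before* $N, K, n, k$
are computed; genes outside the background are dropped with a logged
count.  The default background is the protein-coding universe of the
loaded gene models; custom backgrounds are accepted and used verbatim.
Benjamini–Hochberg adjustment runs within each data source independently
(so identical raw p-values in different sources may receive different
adjusted values), and the reported subset keeps adjusted $p \le 0.05$
with overlap $k \ge 2$ — a consequence is that singleton sets ($K = 1$)
can never be reported, which we accept as the cost of the overlap rule.
The full unfiltered table is always written alongside the report.

# The synthetic-fixture generator

All tests and the acceptance script run on generated data with planted
truth; nothing is downloaded.  A scenario plants $k$ association blocks
on one synthetic chromosome, separated by more than 1 Mb so no
cross-block LD pair exists at the storage floor.  Within a block of 15
SNPs spaced 5 kb apart, LD decays linearly,
$r^2(d) = \max(0, 0.95 - d \cdot \mathrm{rate})$ with rate $10^{-6}$ per
bp by default, so the whole block stays above $r^2 = 0.6$ with its
central causal SNP and clumps to a single independent significant SNP.
The causal SNP draws $-\log_{10} p$ uniformly in $[9.5, 12]$ (comfortably
genome-wide significant); neighbors are interpolated toward the null in
proportion to their $r^2$ and are always strictly weaker than the causal
SNP; unlinked null SNPs draw $p \sim U(0,1)$.  Ten percent of non-causal
block SNPs are omitted from the summary statistics by default to exercise
non-GWAS-tagged proxies, and one block SNP carries MAF 0.005 to exercise
the frequency filter.

Per locus the generator plants one gene with an exonic causal SNP whose
CADD score lies above the 12.37 deleteriousness threshold (every other
SNP stays below it), one distal cis-eQTL target at FDR 0.01 (plus a
distractor record failing the FDR filter), and one distal gene whose
promoter overlaps one end of a significant interaction whose other end
covers the block (plus an interaction failing the FDR threshold).
Expression is i.i.d. Normal(2, 0.5) on the log2 scale over 4 tissues × 20
samples, with the planted tissue-specific genes shifted by lfc 2.0 in one
tissue; with these sizes the planted effect is recovered essentially
always, which is the point — the generator validates bookkeeping and
thresholds, not statistical power at realistic noise.  Gene-set
collections contain the planted groups plus random distractor sets.  One
integer seed drives every draw, so scenario directories are
byte-reproducible.

What the generator does *not* emulate: realistic coalescent LD (decay is
linear, not population-genetic), realistic effect-size architecture,
overlapping genes at real densities, multi-chromosome layouts by default,
and source-realistic FDR landscapes.  Passing tests therefore demonstrate
correctness of the algorithms and their thresholds on known structure,
not calibration on real GWAS data.

# Problem sizes and determinism

The test suite checks the clumping pair (independent significant + lead
selection) against an exhaustive first-principles oracle on 1,000 random
LD matrices of up to 12 significant SNPs; planted-locus recovery over 100
seeded scenarios with 1, 3 or 5 blocks plus randomized 249,999 bp /
250,000 bp merge-boundary cases; hypergeometric p-values against complete
enumeration of all backgrounds up to $N = 12$; DEG statistics against
`stats::t.test` on 1,000 random gene×tissue draws, a 200-replicate global
null for the Bonferroni family-wise bound, and 100 seeded planted-effect
recoveries; and mapping geometry (cis bound, promoter/end overlap) post
hoc on 100 random fixtures.  These sizes give the properties room to fail
while keeping the default suite in the low minutes on one CPU.

Every pipeline run writes a JSON run log with the effective parameters,
input MD5 checksums and filtered-row counts; identical inputs and config
produce byte-identical tables.  An external gene-based/gene-set analysis
tool (MAGMA) can be attached as an optional subprocess when a binary path
is configured; an absent binary skips that stage with a notice.

# Known limitations

No conditional/joint analysis or fine-mapping (clumping is marginal); no
on-the-fly $r^2$ from genotypes (LD arrives pre-computed); SNVs only, no
indels; no transcript-level consequences or UTR calls without CDS; no
colocalization statistics for eQTL evidence; interaction data arrive
pre-called with FDR, no contact-matrix normalization; rsID version
migration and assembly liftover are assumed done upstream.
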