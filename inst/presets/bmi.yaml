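# Parameter preset for a body-mass-index GWAS application: positional
# mapping restricted to deleterious coding SNPs (exonic/splicing with
# CADD >= 12.37), eQTL mapping at source FDR <= 0.05 across all 44 GTEx
# tissue types carrying cis-eQTLs, chromatin-interaction mapping at
# FDR < 1e-6 in 14 Hi-C tissue types.  Supply the tissue labels exactly as
# they appear in your eQTL / interaction tables; `eqtl_tissues: all` uses
# every tissue present in the eQTL store.
params:
  p_sig: 5.0e-8
  r2_ind: 0.6
  r2_lead: 0.1
  merge_kb: 250
  maf_min: 0.01
  eqtl_fdr_max: 0.05
  ci_fdr_max: 1.0e-6
strategies:
  positional:
    enabled: true
    mode: consequence
    allowed_consequences: [exonic, splicing]
    cadd_min: 12.37
  eqtl:
    enabled: true
  chromatin:
    enabled: true
eqtl_tissues: all
ci_tissues:
  - Adrenal
  - Aorta
  - Bladder
  - Dorsolateral_Prefrontal_Cortex
  - Hippocampus
  - Left_Ventricle
  - Liver
  - Lung
  - Ovary
  - Pancreas
  - Psoas
  - Right_Ventricle
  - Small_Bowel
  - Spleen
gene_types: [protein_coding]
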