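# Parameter preset for a Crohn's disease GWAS application: deleterious
# coding positional mapping (exonic/splicing, CADD >= 12.37), eQTL mapping
# at source FDR <= 0.05 in five digestive/immune tissue types, chromatin
# interaction mapping at FDR < 1e-6 in liver and small bowel Hi-C.  The
# original analysis also excluded the MHC region and indels and forced the
# study's 71 reported lead SNPs (`predefined_leads`) because the input
# covered only the discovery phase.
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
eqtl_tissues:
  - Small_Intestine
  - Colon_Sigmoid
  - Colon_Transverse
  - Stomach
  - Whole_Blood
ci_tissues:
  - Liver
  - Small_Bowel
gene_types: [protein_coding]
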