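# Parameter preset for a schizophrenia GWAS application: deleterious
# coding positional mapping (exonic/splicing, CADD >= 12.37), eQTL mapping
# at source FDR <= 0.05 in ten brain tissue types, chromatin interaction
# mapping at FDR < 1e-6 in hippocampus and prefrontal cortex Hi-C.  The
# original analysis excluded the extended MHC region (chr6:25-34 Mb),
# chromosome X and indels, and forced the study's reported non-indel lead
# SNPs (`predefined_leads`).
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
  - Brain_Anterior_cingulate_cortex
  - Brain_Caudate_basal_ganglia
  - Brain_Cerebellar_Hemisphere
  - Brain_Cerebellum
  - Brain_Cortex
  - Brain_Frontal_Cortex
  - Brain_Hippocampus
  - Brain_Hypothalamus
  - Brain_Nucleus_accumbens_basal_ganglia
  - Brain_Putamen_basal_ganglia
ci_tissues:
  - Hippocampus
  - Prefrontal_Cortex
gene_types: [protein_coding]
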