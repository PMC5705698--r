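#' Default analysis parameters
#'
#' Returns the full set of tunable thresholds used across locus
#' characterization, SNP annotation, gene mapping and gene-to-function
#' analysis.  Any subset can be overridden via `...` or through the YAML
#' config (see [read_config()]).
#'
#' @param ... named overrides of individual parameters.
#'
#' @return A named list with class `"pg_params"`:
#' \describe{
#'   \item{p_sig}{genome-wide significance threshold for independent
#'     significant SNPs (default `5e-8`).}
#'   \item{r2_ind}{LD threshold: SNPs are independent significant when
#'     pairwise r2 is below this (default `0.6`); also the proxy threshold
#'     for candidate SNPs (r2 >= r2_ind tags a candidate).}
#'   \item{r2_lead}{LD threshold for lead SNPs (default `0.1`).}
#'   \item{merge_kb}{LD blocks closer than this many kb are merged into one
#'     genomic risk locus (strict `<`, default `250`).}
#'   \item{maf_min}{minor-allele-frequency filter for candidate SNPs
#'     (default `0.01`).}
#'   \item{pos_window_kb}{gene window for positional mapping (default `10`).}
#'   \item{cadd_min}{optional CADD threshold for functional SNP filtering
#'     (`12.37` is the conventional deleteriousness cut-off; default `NULL`,
#'     meaning no filter).}
#'   \item{eqtl_fdr_max}{eQTL significance filter on the source-provided FDR
#'     (default `0.05`).}
#'   \item{eqtl_p_max}{optional nominal-p alternative to the FDR filter.}
#'   \item{ci_fdr_max}{significance filter for chromatin interactions
#'     (default `1e-6`).}
#'   \item{promoter_up, promoter_down}{promoter window around the TSS in bp
#'     (defaults 250 upstream, 500 downstream, strand-aware).}
#'   \item{expr_min_rpkm}{a gene is "expressed" when its mean RPKM reaches
#'     this in at least one tissue (default `1`).}
#'   \item{winsor_cap}{RPKM winsorization cap for expression summaries
#'     (default `50`).}
#'   \item{deg_alpha}{Bonferroni-corrected alpha for DEG membership
#'     (default `0.05`).}
#'   \item{deg_lfc}{minimum absolute log2 fold change for DEG membership
#'     (default `0.58`, i.e. ~1.5-fold).}
#'   \item{enrich_adjp}{adjusted-p cut-off for reported enrichments
#'     (default `0.05`).}
#'   \item{enrich_min_overlap}{minimum overlap k for reported enrichments
#'     (default `2`).}
#'   \item{splice_bp}{intronic bases adjacent to an exon boundary classified
#'     as splicing (default `2`).}
#'   \item{flank_bp}{up/downstream flank for the consequence classifier
#'     (default `1000`).}
#' }
#' @export
default_params <- function(...) {
  p <- list(
    p_sig = 5e-8,
    r2_ind = 0.6,
    r2_lead = 0.1,
    merge_kb = 250,
    maf_min = 0.01,
    pos_window_kb = 10,
    cadd_min = NULL,
    eqtl_fdr_max = 0.05,
    eqtl_p_max = NULL,
    ci_fdr_max = 1e-6,
    promoter_up = 250,
    promoter_down = 500,
    expr_min_rpkm = 1,
    winsor_cap = 50,
    deg_alpha = 0.05,
    deg_lfc = 0.58,
    enrich_adjp = 0.05,
    enrich_min_overlap = 2,
    splice_bp = 2,
    flank_bp = 1000
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  class(p) <- "pg_params"
  validate_params(p)
  p
}

#' Validate a parameter list
#'
#' Checks positivity of all thresholds and the ordering constraint
#' `r2_lead <= r2_ind`.  Called by [default_params()]; exported so configs
#' can be validated independently.
#'
#' @param p a parameter list as returned by [default_params()].
#' @return `p`, invisibly, or an error.
#' @export
validate_params <- function(p) {
  num <- c("p_sig", "r2_ind", "r2_lead", "merge_kb", "maf_min",
           "pos_window_kb", "eqtl_fdr_max", "ci_fdr_max", "promoter_up",
           "promoter_down", "expr_min_rpkm", "winsor_cap", "deg_alpha",
           "deg_lfc", "enrich_adjp", "enrich_min_overlap", "splice_bp",
           "flank_bp")
  for (k in num) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("parameter '", k, "' must be a single positive number")
    }
  }
  for (k in c("cadd_min", "eqtl_p_max")) {
    v <- p[[k]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0)) {
      stop("parameter '", k, "' must be NULL or a single positive number")
    }
  }
  if (p$r2_lead > p$r2_ind) stop("r2_lead must be <= r2_ind")
  invisible(p)
}
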