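## Orchestration of the two end-to-end flows: snp2gene
## (loci -> SNP annotation -> gene mapping) and gene2func (expression
## summaries -> DEG sets -> enrichment), driven by a validated YAML
## configuration.  Every run writes tab-separated tables plus a run log
## recording parameters, input checksums and filtered-row counts; runs are
## deterministic given inputs and config.

config_known_keys <- c("inputs", "params", "eqtl_tissues", "ci_tissues",
                       "epigenomes", "strategies", "gene_types",
                       "predefined_leads", "regions", "magma", "out_dir")
input_known_keys <- c("sumstats", "panel", "ld", "genes", "cadd", "rdb",
                      "chromhmm", "eqtl", "interactions", "enhancers",
                      "promoters", "expression", "tissue_map", "genesets",
                      "catalog", "intolerance")

#' Read and validate a run configuration
#'
#' YAML file mirroring the parameter names of [default_params()] under
#' `params`, with an `inputs` section of file paths (relative paths are
#' resolved against the config file's directory), tissue/epigenome
#' selections, and per-strategy toggles.  Unknown keys are rejected and
#' every referenced path must exist.
#'
#' @param path YAML config path.
#' @return validated config list of class `pg_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  bad_in <- setdiff(names(cfg$inputs), input_known_keys)
  if (length(bad_in)) {
    stop("unknown input key(s): ", paste(bad_in, collapse = ", "))
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (nm in names(cfg$inputs)) {
    v <- cfg$inputs[[nm]]
    if (is.list(v)) {
      cfg$inputs[[nm]] <- lapply(v, resolve)
    } else {
      cfg$inputs[[nm]] <- resolve(v)
    }
  }
  paths <- unlist(cfg$inputs, use.names = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("referenced input path(s) do not exist: ",
         paste(missing, collapse = ", "))
  }
  cfg$params <- do.call(default_params, as.list(cfg$params))
  if (is.null(cfg$strategies)) {
    cfg$strategies <- list(positional = list(enabled = TRUE),
                           eqtl = list(enabled = TRUE),
                           chromatin = list(enabled = TRUE))
  }
  bad_st <- setdiff(names(cfg$strategies),
                    c("positional", "eqtl", "chromatin"))
  if (length(bad_st)) {
    stop("unknown strategy key(s): ", paste(bad_st, collapse = ", "))
  }
  if (is.null(cfg$gene_types)) cfg$gene_types <- "protein_coding"
  cfg$eqtl_tissues <- unlist(cfg$eqtl_tissues)
  cfg$ci_tissues <- unlist(cfg$ci_tissues)
  cfg$epigenomes <- unlist(cfg$epigenomes)
  cfg$gene_types <- unlist(cfg$gene_types)
  structure(cfg, class = "pg_config")
}

strategy_enabled <- function(cfg, name) {
  st <- cfg$strategies[[name]]
  !is.null(st) && isTRUE(st$enabled)
}

write_table <- function(x, dir, name) {
  # flatten list-columns for the on-disk tables
  x <- data.table::copy(data.table::as.data.table(x))
  for (cc in names(x)) {
    if (is.list(x[[cc]])) {
      data.table::set(x, j = cc,
                      value = vapply(x[[cc]], paste, character(1),
                                     collapse = ";"))
    }
  }
  data.table::fwrite(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     na = "NA")
}

run_log <- function(dir, cfg, extra) {
  paths <- unlist(cfg$inputs)
  sums <- tools::md5sum(paths)
  log <- list(config = unclass_config(cfg),
              input_md5 = as.list(sums),
              counts = extra)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

unclass_config <- function(cfg) {
  x <- unclass(cfg)
  x$params <- unclass(x$params)
  x$params <- Filter(Negate(is.null), x$params)
  x
}

#' Run the snp2gene flow
#'
#' Executes locus characterization, candidate-SNP annotation and the three
#' gene-mapping strategies in order, writing `GenomicRiskLoci.txt`,
#' `IndSigSNPs.txt`, `leadSNPs.txt`, `snps.txt`, `annot.txt`, `genes.txt`,
#' `eqtl.txt`, `ci.txt` and `run_log.json` to the output directory.
#'
#' @param config a `pg_config` ([read_config()]) or path to one.
#' @param out_dir output directory (overrides `out_dir` in the config).
#' @return list with all in-memory results (`loci`, `ind_sig`, `leads`,
#'   `candidates`, `annot`, `catalog_hits`, `mapped`, evidence tables,
#'   `locus_counts`), invisibly plus written files.
#' @export
run_snp2gene <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "pg_config")) config else read_config(config)
  out_dir <- if (!is.null(out_dir)) out_dir else cfg$out_dir
  if (is.null(out_dir)) stop("no output directory configured")
  if (!any(vapply(c("positional", "eqtl", "chromatin"), strategy_enabled,
                  logical(1), cfg = cfg))) {
    stop("all mapping strategies are disabled; enable at least one")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- cfg$params

  sumstats <- read_sumstats(cfg$inputs$sumstats)
  ref <- read_tables(cfg$inputs)

  regions <- NULL
  if (!is.null(cfg$regions)) {
    regions <- data.table::as.data.table(cfg$regions)
  }
  ch <- characterize_loci(sumstats, ref$panel, ref$ld, params,
                          predefined_leads = unlist(cfg$predefined_leads),
                          regions = regions)
  ann <- annotate_snps(ch$candidates, ref$genes, panel = ref$panel,
                       cadd = ref$cadd, rdb = ref$rdb,
                       chromhmm = ref$chromhmm, epigenomes = cfg$epigenomes,
                       catalog = ref$catalog,
                       splice_bp = params$splice_bp,
                       flank_bp = params$flank_bp)
  annot <- ann$annot

  run_filter <- function(st) {
    filter_snps_functional(
      annot,
      cadd_min = st$cadd_min,
      rdb_max = st$rdb_max,
      allowed_states = unlist(st$allowed_states),
      state_epigenomes = cfg$epigenomes,
      allowed_consequences = NULL)
  }
  pos_ev <- eqtl_ev <- ci_ev <- NULL
  if (strategy_enabled(cfg, "positional")) {
    st <- cfg$strategies$positional
    mode <- if (!is.null(st$mode)) st$mode else "window"
    pos_ev <- positional_map(
      run_filter(st), ref$genes, mode = mode,
      window_kb = if (!is.null(st$window_kb)) st$window_kb else
        params$pos_window_kb,
      allowed_consequences = if (!is.null(st$allowed_consequences))
        unlist(st$allowed_consequences) else c("exonic", "splicing"))
  }
  if (strategy_enabled(cfg, "eqtl")) {
    st <- cfg$strategies$eqtl
    if (identical(cfg$eqtl_tissues, "all")) {
      cfg$eqtl_tissues <- sort(unique(ref$eqtl$tissue))
    }
    eqtl_ev <- eqtl_map(run_filter(st), ref$eqtl, cfg$eqtl_tissues,
                        fdr_max = params$eqtl_fdr_max,
                        p_max = params$eqtl_p_max,
                        gene_models = ref$genes)
  }
  if (strategy_enabled(cfg, "chromatin")) {
    st <- cfg$strategies$chromatin
    ci_ev <- chromatin_map(
      run_filter(st), ref$interactions, ref$genes, cfg$ci_tissues,
      ci_fdr_max = params$ci_fdr_max,
      promoter_up = params$promoter_up,
      promoter_down = params$promoter_down,
      enhancer_sets = if (isTRUE(st$use_enhancer_filter)) ref$enhancers,
      promoter_sets = if (isTRUE(st$use_promoter_filter)) ref$promoters)
  }
  mapped <- combine_maps(pos_ev, eqtl_ev, ci_ev, ch$candidates, ch$loci,
                         ref$genes, intolerance = ref$intolerance,
                         gene_types = cfg$gene_types)
  counts <- locus_gene_counts(mapped, ch$loci)

  write_table(ch$loci, out_dir, "GenomicRiskLoci.txt")
  write_table(ch$ind_sig, out_dir, "IndSigSNPs.txt")
  write_table(ch$leads, out_dir, "leadSNPs.txt")
  write_table(ch$candidates, out_dir, "snps.txt")
  write_table(annot, out_dir, "annot.txt")
  write_table(ann$catalog_hits, out_dir, "gwascatalog.txt")
  write_table(mapped, out_dir, "genes.txt")
  if (!is.null(eqtl_ev)) write_table(eqtl_ev, out_dir, "eqtl.txt")
  if (!is.null(ci_ev)) write_table(ci_ev, out_dir, "ci.txt")
  write_table(counts, out_dir, "locus_gene_counts.txt")
  run_log(out_dir, cfg, list(
    n_sumstat_rows = nrow(sumstats),
    n_sumstat_skipped = attr(sumstats, "n_skipped"),
    n_ind_sig = nrow(ch$ind_sig), n_lead = nrow(ch$leads),
    n_candidates = nrow(ch$candidates), n_loci = nrow(ch$loci),
    n_mapped_genes = nrow(mapped)))
  run_magma_adapter(cfg, out_dir)

  invisible(list(loci = ch$loci, ind_sig = ch$ind_sig, leads = ch$leads,
                 candidates = ch$candidates, annot = annot,
                 catalog_hits = ann$catalog_hits, mapped = mapped,
                 pos_ev = pos_ev, eqtl_ev = eqtl_ev, ci_ev = ci_ev,
                 locus_counts = counts, out_dir = out_dir))
}

# optional external gene-analysis adapter: invoked only when a binary path
# is configured; an absent binary skips the stage with a notice
run_magma_adapter <- function(cfg, out_dir) {
  bin <- cfg$magma$binary
  if (is.null(bin)) return(invisible(NULL))
  if (!file.exists(bin)) {
    message("MAGMA binary not found at ", bin, "; gene-analysis stage skipped")
    return(invisible(NULL))
  }
  args <- unlist(cfg$magma$args)
  status <- system2(bin, args, stdout = file.path(out_dir, "magma.log"),
                    stderr = file.path(out_dir, "magma.log"))
  if (status != 0L) warning("MAGMA exited with status ", status)
  invisible(status)
}

#' Resolve a gene list against gene models
#'
#' Accepts stable gene ids or symbols (auto-detected per entry);
#' unresolvable entries are reported, not fatal.
#'
#' @param genes character vector of ids or symbols.
#' @param gene_models gene-model table.
#' @return list with `gene_id` (resolved stable ids) and `unresolved`.
#' @export
resolve_genes <- function(genes, gene_models) {
  genes <- unique(genes[nzchar(genes)])
  by_id <- genes %in% gene_models$gene_id
  by_sym <- !by_id & genes %in% gene_models$symbol
  resolved <- c(genes[by_id],
                gene_models$gene_id[match(genes[by_sym], gene_models$symbol)])
  list(gene_id = unique(resolved), unresolved = genes[!by_id & !by_sym])
}

#' Run the gene2func flow
#'
#' Filters to expressed genes, writes the per-gene-per-tissue expression
#' summaries (`gtex_summary.txt`), the full DEG statistics (`deg.txt`) and
#' the DEG / gene-set enrichment tables (`DEG_enrichment.txt`,
#' `GS_enrichment.txt`).
#'
#' @param config a `pg_config` or path.
#' @param genes character vector of gene ids/symbols, or a path to a
#'   one-id-per-line file.
#' @param out_dir output directory.
#' @param background optional custom background (ids/symbols); defaults to
#'   the protein-coding gene universe of the gene models.
#' @return list with `summary`, `deg`, `deg_enrichment`,
#'   `gs_enrichment`, `unresolved`, invisibly.
#' @export
run_gene2func <- function(config, genes, out_dir = NULL, background = NULL) {
  cfg <- if (inherits(config, "pg_config")) config else read_config(config)
  out_dir <- if (!is.null(out_dir)) out_dir else cfg$out_dir
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- cfg$params
  gm <- read_gene_models(cfg$inputs$genes)
  if (length(genes) == 1L && file.exists(genes)) {
    genes <- readLines(genes)
  }
  res <- resolve_genes(genes, gm)
  if (length(res$unresolved)) {
    message(length(res$unresolved), " gene(s) could not be resolved: ",
            paste(res$unresolved, collapse = ", "))
  }
  if (!length(res$gene_id)) stop("no input gene could be resolved")
  expr <- read_expression(cfg$inputs$expression, cfg$inputs$tissue_map)
  if (is.null(background)) {
    background <- gm$gene_id[gm$gene_type %in% cfg$gene_types]
  } else {
    background <- resolve_genes(background, gm)$gene_id
  }
  expressed <- filter_expressed(expr, params$expr_min_rpkm)
  summary_dt <- summarize_expression(expr, params$winsor_cap,
                                     genes = intersect(res$gene_id, expressed))
  deg <- build_deg_sets(expr, params$deg_alpha, params$deg_lfc,
                        genes = expressed)
  deg_enr <- enrich_deg(res$gene_id, deg, background,
                        adjp_max = params$enrich_adjp,
                        min_overlap = params$enrich_min_overlap)
  gs_enr <- NULL
  if (!is.null(cfg$inputs$genesets)) {
    collections <- lapply(stats::setNames(names(cfg$inputs$genesets),
                                          names(cfg$inputs$genesets)),
                          function(s) read_gmt(cfg$inputs$genesets[[s]], s))
    gs_enr <- enrich_gene_sets(res$gene_id, collections, background,
                               adjp_max = params$enrich_adjp,
                               min_overlap = params$enrich_min_overlap)
  }
  write_table(summary_dt, out_dir, "gtex_summary.txt")
  write_table(deg$stats, out_dir, "deg.txt")
  write_table(deg_enr$full, out_dir, "DEG_enrichment.txt")
  if (!is.null(gs_enr)) write_table(gs_enr$full, out_dir, "GS_enrichment.txt")
  run_log(out_dir, cfg, list(
    n_input_genes = length(res$gene_id),
    n_unresolved = length(res$unresolved),
    n_background = length(background),
    n_expressed = length(expressed)))
  invisible(list(summary = summary_dt, deg = deg, deg_enrichment = deg_enr,
                 gs_enrichment = gs_enr, unresolved = res$unresolved,
                 background = background, out_dir = out_dir))
}
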