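## Readers/writers for gene models, variant-score tables, eQTLs, chromatin
## interactions, epigenome region sets, expression matrices, gene-set
## collections (GMT), GWAS-catalog entries and gene intolerance scores.

#' Read gene models
#'
#' Accepts a delimited gene-model table (the native format, written by
#' [write_gene_models()]), a GFF3 file, or a BED12 file (the latter two via
#' \pkg{rtracklayer}).  The native table has columns `gene_id`, `symbol`,
#' `gene_type`, `chrom`, `start`, `end`, `strand`, `exon_starts`,
#' `exon_ends` (comma-separated, 1-based closed).  The TSS is derived from
#' strand: gene start on `+`, gene end on `-`.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"auto"`, `"table"`, `"gff3"` or `"bed12"`.
#' @param default_gene_type used for formats that carry no biotype (BED12).
#' @return `data.table` with columns `gene_id`, `symbol`, `gene_type`,
#'   `chrom`, `start`, `end`, `strand`, `tss` and list-columns
#'   `exon_start`, `exon_end`.
#' @export
read_gene_models <- function(path, format = c("auto", "table", "gff3", "bed12"),
                             default_gene_type = "protein_coding") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed12", "table")
  }
  gm <- switch(format,
    table = read_gene_models_table(path),
    gff3  = read_gene_models_gff3(path),
    bed12 = read_gene_models_bed12(path, default_gene_type)
  )
  validate_gene_models(gm)
  gm
}

read_gene_models_table <- function(path) {
  raw <- pg_fread(path, colClasses = list(character = c("exon_starts", "exon_ends")))
  need <- c("gene_id", "symbol", "gene_type", "chrom", "start", "end",
            "strand", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("gene-model table missing column(s): ",
                         paste(miss, collapse = ", "))
  split_int <- function(s) lapply(strsplit(as.character(s), ","), as.integer)
  data.table::data.table(
    gene_id    = as.character(raw$gene_id),
    symbol     = as.character(raw$symbol),
    gene_type  = as.character(raw$gene_type),
    chrom      = norm_chrom(raw$chrom),
    start      = as.integer(raw$start),
    end        = as.integer(raw$end),
    strand     = as.character(raw$strand),
    exon_start = split_int(raw$exon_starts),
    exon_end   = split_int(raw$exon_ends)
  )
}

read_gene_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GFF3 import requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  get_attr <- function(i, nm) {
    v <- md[[nm]]
    if (is.null(v)) return(rep(NA_character_, length(i)))
    out <- as.character(v)[i]
    out
  }
  gi <- which(type == "gene")
  if (!length(gi)) stop("no 'gene' features in GFF3 file")
  gene_id <- get_attr(gi, "gene_id")
  if (all(is.na(gene_id))) gene_id <- get_attr(gi, "ID")
  symbol <- get_attr(gi, "Name")
  gtype <- get_attr(gi, "gene_biotype")
  if (all(is.na(gtype))) gtype <- get_attr(gi, "biotype")
  gtype[is.na(gtype)] <- "other"
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]

  # transcripts: Parent = gene ID; exons: Parent = transcript ID
  gids_by_feature_id <- stats::setNames(gene_id, get_attr(gi, "ID"))
  ti <- which(type %in% c("mRNA", "transcript"))
  parent_of <- function(i) {
    v <- md$Parent
    vapply(seq_along(i), function(k) {
      pp <- v[[i[k]]]
      if (length(pp)) as.character(pp)[1L] else NA_character_
    }, character(1))
  }
  tx_gene <- gids_by_feature_id[parent_of(ti)]
  names(tx_gene) <- get_attr(ti, "ID")
  ei <- which(type == "exon")
  exon_gene <- get_attr(ei, "gene_id")
  if (all(is.na(exon_gene))) exon_gene <- unname(tx_gene[parent_of(ei)])

  gm <- data.table::data.table(
    gene_id   = gene_id,
    symbol    = symbol,
    gene_type = gtype,
    chrom     = norm_chrom(GenomicRanges::seqnames(gr)[gi]),
    start     = GenomicRanges::start(gr)[gi],
    end       = GenomicRanges::end(gr)[gi],
    strand    = as.character(GenomicRanges::strand(gr)[gi])
  )
  ex <- data.table::data.table(
    gene_id = exon_gene,
    start   = GenomicRanges::start(gr)[ei],
    end     = GenomicRanges::end(gr)[ei]
  )
  attach_exons(gm, ex)
}

read_gene_models_bed12 <- function(path, default_gene_type) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("BED12 import requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  gm <- data.table::data.table(
    gene_id   = as.character(md$name),
    symbol    = as.character(md$name),
    gene_type = default_gene_type,
    chrom     = norm_chrom(GenomicRanges::seqnames(gr)),
    start     = GenomicRanges::start(gr),
    end       = GenomicRanges::end(gr),
    strand    = as.character(GenomicRanges::strand(gr))
  )
  if (!is.null(md$blocks)) {
    bl <- md$blocks
    gm[, exon_start := lapply(seq_len(.N), function(i)
      as.integer(GenomicRanges::start(bl[[i]]) + start[i] - 1L))]
    gm[, exon_end := lapply(seq_len(.N), function(i)
      as.integer(GenomicRanges::end(bl[[i]]) + start[i] - 1L))]
  } else {
    gm[, exon_start := lapply(start, identity)]
    gm[, exon_end := lapply(end, identity)]
  }
  gm
}

# merge an exon table (gene_id, start, end) into list-columns, reducing
# overlapping exons across transcripts
attach_exons <- function(gm, ex) {
  merged <- lapply(gm$gene_id, function(g) {
    e <- ex[gene_id == g]
    if (!nrow(e)) return(list(integer(0), integer(0)))
    ir <- IRanges::reduce(IRanges::IRanges(e$start, e$end))
    list(as.integer(IRanges::start(ir)), as.integer(IRanges::end(ir)))
  })
  gm[, exon_start := lapply(merged, `[[`, 1L)]
  gm[, exon_end := lapply(merged, `[[`, 2L)]
  gm
}

#' Validate a gene-model table and fill the TSS
#' @param gm gene-model `data.table`.
#' @return `gm` with the `tss` column, invisibly modified in place.
#' @export
validate_gene_models <- function(gm) {
  if (any(gm$start > gm$end)) {
    bad <- which(gm$start > gm$end)[1L]
    stop("gene model coordinate inversion (start > end) for gene ",
         gm$gene_id[bad])
  }
  if (!all(gm$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  for (i in seq_len(nrow(gm))) {
    es <- gm$exon_start[[i]]; ee <- gm$exon_end[[i]]
    if (length(es) != length(ee)) stop("exon start/end length mismatch for ",
                                       gm$gene_id[i])
    if (!length(es)) next
    if (any(es > ee)) stop("exon inversion in gene ", gm$gene_id[i])
    if (any(es < gm$start[i]) || any(ee > gm$end[i])) {
      stop("exon outside gene span in gene ", gm$gene_id[i])
    }
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1] <= ee[-length(ee)])) {
      stop("exons must be sorted and non-overlapping in gene ", gm$gene_id[i])
    }
  }
  gm[, tss := data.table::fifelse(strand == "+", start, end)]
  if (anyDuplicated(gm$gene_id)) stop("duplicate gene_id in gene models")
  invisible(gm)
}

#' @rdname read_gene_models
#' @param gm gene-model `data.table`.
#' @export
write_gene_models <- function(gm, path) {
  out <- data.table::data.table(
    gene_id = gm$gene_id, symbol = gm$symbol, gene_type = gm$gene_type,
    chrom = gm$chrom, start = gm$start, end = gm$end, strand = gm$strand,
    exon_starts = vapply(gm$exon_start, paste, character(1), collapse = ","),
    exon_ends   = vapply(gm$exon_end, paste, character(1), collapse = ",")
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# interval queries; queries and subjects routinely carry disjoint
# chromosome sets, which is not an anomaly worth a seqlevels warning
pg_find_overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
}

pg_count_overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::countOverlaps(query, subject, ...))
}

# GRanges view of gene spans (used by the interval-query steps)
genes_granges <- function(gm, pad = 0L) {
  GenomicRanges::GRanges(
    seqnames = gm$chrom,
    ranges = IRanges::IRanges(pmax(1L, gm$start - pad), gm$end + pad),
    strand = gm$strand,
    gene_id = gm$gene_id
  )
}

# ---------------------------------------------------------------------------
# Variant score tables

#' Ordered RegulomeDB category vocabulary
#'
#' Categories from strongest (`1a`) to weakest (`7`) regulatory evidence;
#' filtering uses "category at or before the threshold in this order".
#' @return character vector of the 15 ordered categories.
#' @export
rdb_categories <- function() {
  c("1a", "1b", "1c", "1d", "1e", "1f", "2a", "2b", "2c",
    "3a", "3b", "4", "5", "6", "7")
}

#' Read variant-score lookup tables
#'
#' `read_cadd`: columns `chrom`, `pos`, `ref`, `alt`, `cadd` (PHRED-like).
#' `read_regulomedb`: columns `chrom`, `pos`, `rdb` (one of
#' [rdb_categories()]).
#' `read_chromhmm`: columns `chrom`, `bin_start` (0-based, multiple of the
#' 200-bp bin size), `epigenome`, `state` (1..15).
#'
#' @param path file path.
#' @return a `data.table` of the respective shape.
#' @export
read_cadd <- function(path) {
  x <- pg_fread(path)
  need <- c("chrom", "pos", "ref", "alt", "cadd")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("CADD table missing column(s): ",
                         paste(miss, collapse = ", "))
  x[, chrom := norm_chrom(chrom)]
  x[, `:=`(pos = as.integer(pos), ref = toupper(ref), alt = toupper(alt),
           cadd = as.numeric(cadd))]
  x[]
}

#' @rdname read_cadd
#' @export
read_regulomedb <- function(path) {
  x <- pg_fread(path)
  miss <- setdiff(c("chrom", "pos", "rdb"), names(x))
  if (length(miss)) stop("RegulomeDB table missing column(s): ",
                         paste(miss, collapse = ", "))
  x[, chrom := norm_chrom(chrom)]
  x[, `:=`(pos = as.integer(pos), rdb = as.character(rdb))]
  bad <- setdiff(unique(x$rdb), rdb_categories())
  if (length(bad)) stop("unknown RegulomeDB categories: ",
                        paste(bad, collapse = ", "))
  x[]
}

#' @rdname read_cadd
#' @param bin_bp chromatin-state bin size in bp (ChromHMM convention, 200).
#' @export
read_chromhmm <- function(path, bin_bp = 200L) {
  x <- pg_fread(path)
  miss <- setdiff(c("chrom", "bin_start", "epigenome", "state"), names(x))
  if (length(miss)) stop("chromatin-state table missing column(s): ",
                         paste(miss, collapse = ", "))
  x[, chrom := norm_chrom(chrom)]
  x[, `:=`(bin_start = as.integer(bin_start), epigenome = as.character(epigenome),
           state = as.integer(state))]
  if (any(x$state < 1L | x$state > 15L)) stop("chromatin states must be 1..15")
  if (any(x$bin_start %% bin_bp != 0L)) {
    stop("bin_start values must be multiples of ", bin_bp)
  }
  x[]
}

# ---------------------------------------------------------------------------
# eQTL, chromatin-interaction, epigenome-region tables

#' Read a cis-eQTL table
#'
#' Columns `chrom`, `pos`, `effect_allele`, `other_allele`, `gene_id`,
#' `tissue`, `p`, `fdr` (FDR as provided by the original source; it is
#' never recomputed here).
#'
#' @param path file path.
#' @return `data.table`.
#' @export
read_eqtl <- function(path) {
  x <- pg_fread(path)
  need <- c("chrom", "pos", "effect_allele", "other_allele",
            "gene_id", "tissue", "p", "fdr")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("eQTL table missing column(s): ",
                         paste(miss, collapse = ", "))
  x[, chrom := norm_chrom(chrom)]
  x[, `:=`(pos = as.integer(pos),
           effect_allele = toupper(effect_allele),
           other_allele = toupper(other_allele),
           gene_id = as.character(gene_id), tissue = as.character(tissue),
           p = as.numeric(p), fdr = as.numeric(fdr))]
  if (any(is.na(x$p) | x$p <= 0 | x$p > 1)) stop("eQTL p-values must lie in (0, 1]")
  x[]
}

#' Read significant chromatin interactions (BEDPE-like)
#'
#' Tab-separated file whose first six columns are the two half-open 0-based
#' intervals (`chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b`)
#' followed by `tissue` and `fdr` columns.  Coordinates are converted to the
#' internal 1-based closed convention.  Trans-chromosomal records are
#' accepted.
#'
#' @param path file path.
#' @return `data.table` with internal coordinates.
#' @export
read_interactions <- function(path) {
  x <- pg_fread(path)
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "tissue", "fdr")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("interaction table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (cc in c("start_a", "end_a", "start_b", "end_b")) {
    data.table::set(x, j = cc, value = as.integer(x[[cc]]))
  }
  bad <- which(x$start_a >= x$end_a | x$start_b >= x$end_b)
  if (length(bad)) {
    stop("interaction interval inversion (start >= end) in ", path,
         " at line ", bad[1L] + 1L)
  }
  a <- bed_to_internal(x$start_a, x$end_a)
  b <- bed_to_internal(x$start_b, x$end_b)
  data.table::data.table(
    chrom_a = norm_chrom(x$chrom_a), start_a = a$start, end_a = a$end,
    chrom_b = norm_chrom(x$chrom_b), start_b = b$start, end_b = b$end,
    tissue = as.character(x$tissue), fdr = as.numeric(x$fdr)
  )
}

#' @rdname read_interactions
#' @param x interaction `data.table` (internal coordinates).
#' @export
write_interactions <- function(x, path) {
  a <- internal_to_bed(x$start_a, x$end_a)
  b <- internal_to_bed(x$start_b, x$end_b)
  out <- data.table::data.table(
    chrom_a = x$chrom_a, start_a = a$start, end_a = a$end,
    chrom_b = x$chrom_b, start_b = b$start, end_b = b$end,
    tissue = x$tissue, fdr = x$fdr
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an epigenome region BED file (enhancers or promoters)
#'
#' Three-column BED (0-based half-open), converted to internal coordinates.
#'
#' @param path file path.
#' @param kind `"enhancer"` or `"promoter"`.
#' @param epigenome_id epigenome label the file belongs to.
#' @return `data.table` with `chrom`, `start`, `end`, `kind`, `epigenome`.
#' @export
read_region_bed <- function(path, kind = c("enhancer", "promoter"),
                            epigenome_id) {
  kind <- match.arg(kind)
  x <- data.table::fread(path, header = FALSE, data.table = TRUE)
  if (ncol(x) < 3L) stop("BED file must have at least 3 columns: ", path)
  data.table::setnames(x, 1:3, c("chrom", "start0", "end0"))
  x[, `:=`(start0 = as.integer(start0), end0 = as.integer(end0))]
  bad <- which(x$start0 >= x$end0)
  if (length(bad)) {
    stop("BED interval inversion in ", path, " at line ", bad[1L])
  }
  cc <- bed_to_internal(x$start0, x$end0)
  data.table::data.table(
    chrom = norm_chrom(x$chrom), start = cc$start, end = cc$end,
    kind = kind, epigenome = as.character(epigenome_id)
  )
}

#' @rdname read_region_bed
#' @param x region `data.table` (internal coordinates).
#' @export
write_region_bed <- function(x, path) {
  cc <- internal_to_bed(x$start, x$end)
  out <- data.table::data.table(chrom = x$chrom, start = cc$start, end = cc$end)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Expression matrix, gene sets, catalog, intolerance

#' Read a samples-by-genes expression matrix with a tissue map
#'
#' The matrix file is genes x samples (first column `gene_id`, remaining
#' columns one per sample, RPKM values >= 0); the tissue map is a
#' two-column table `sample_id`, `tissue`.  Every sample must be assigned to
#' exactly one tissue.
#'
#' @param matrix_path path to the expression matrix.
#' @param tissue_path path to the sample-to-tissue map.
#' @return a list of class `pg_expr` with elements `mat` (numeric matrix,
#'   rownames gene ids) and `tissue_of` (named character vector by sample).
#' @export
read_expression <- function(matrix_path, tissue_path) {
  m <- pg_fread(matrix_path)
  if (names(m)[1L] != "gene_id") stop("expression matrix must start with a gene_id column")
  genes <- as.character(m$gene_id)
  mat <- as.matrix(m[, -1, with = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  if (any(mat < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  tm <- pg_fread(tissue_path)
  miss <- setdiff(c("sample_id", "tissue"), names(tm))
  if (length(miss)) stop("tissue map missing column(s): ",
                         paste(miss, collapse = ", "))
  tissue_of <- stats::setNames(as.character(tm$tissue), as.character(tm$sample_id))
  unmapped <- setdiff(colnames(mat), names(tissue_of))
  if (length(unmapped)) {
    stop("sample(s) without a tissue assignment: ",
         paste(unmapped, collapse = ", "))
  }
  if (anyDuplicated(names(tissue_of))) stop("sample assigned to more than one tissue")
  structure(list(mat = mat, tissue_of = tissue_of[colnames(mat)]),
            class = "pg_expr")
}

#' @rdname read_expression
#' @param expr `pg_expr` object.
#' @param matrix_path,tissue_path output paths.
#' @export
write_expression <- function(expr, matrix_path, tissue_path) {
  out <- data.table::data.table(gene_id = rownames(expr$mat))
  out <- cbind(out, data.table::as.data.table(expr$mat))
  data.table::fwrite(out, matrix_path, sep = "\t", quote = FALSE)
  tm <- data.table::data.table(sample_id = names(expr$tissue_of),
                               tissue = unname(expr$tissue_of))
  data.table::fwrite(tm, tissue_path, sep = "\t", quote = FALSE)
  invisible(matrix_path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member gene ids.
#'
#' @param path file path.
#' @param source_label label for the collection (multiple-testing correction
#'   is performed per source).
#' @return list of class `pg_genesets` with elements `source_label`, `sets`
#'   (named list of character vectors) and `descriptions`.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("GMT line ", bad[1L], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  structure(list(source_label = source_label, sets = sets,
                 descriptions = stats::setNames(desc, nm)),
            class = "pg_genesets")
}

#' @rdname read_gmt
#' @param gs `pg_genesets` object.
#' @export
write_gmt <- function(gs, path) {
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$descriptions[[nm]], gs$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read GWAS-catalog entries
#'
#' Columns `chrom`, `pos`, `trait` and optional `reported_p`.
#' @param path file path.
#' @return `data.table`.
#' @export
read_catalog <- function(path) {
  x <- pg_fread(path)
  miss <- setdiff(c("chrom", "pos", "trait"), names(x))
  if (length(miss)) stop("catalog missing column(s): ",
                         paste(miss, collapse = ", "))
  x[, chrom := norm_chrom(chrom)]
  x[, `:=`(pos = as.integer(pos), trait = as.character(trait))]
  if (!"reported_p" %in% names(x)) x[, reported_p := NA_real_]
  x[, reported_p := as.numeric(reported_p)]
  x[]
}

#' Read gene intolerance scores (pLI, ncRVIS)
#' @param path delimited file with columns `gene_id`, `pli`, `ncrvis`.
#' @return `data.table`.
#' @export
read_intolerance <- function(path) {
  x <- pg_fread(path)
  miss <- setdiff(c("gene_id", "pli", "ncrvis"), names(x))
  if (length(miss)) stop("intolerance table missing column(s): ",
                         paste(miss, collapse = ", "))
  x[, `:=`(gene_id = as.character(gene_id), pli = as.numeric(pli),
           ncrvis = as.numeric(ncrvis))]
  x[]
}

#' Read a complete reference bundle
#'
#' Convenience loader mapping a named list of paths to the individual
#' readers.  Recognized names: `panel`, `ld`, `genes`, `cadd`, `rdb`,
#' `chromhmm`, `eqtl`, `interactions`, `enhancers` (named list of BED paths
#' by epigenome), `promoters` (idem), `expression` + `tissue_map`,
#' `genesets` (named list of GMT paths by source label), `catalog`,
#' `intolerance`.  Missing entries yield `NULL` stores; downstream stages
#' that need them raise their own errors.
#'
#' @param paths named list of file paths.
#' @return list of class `pg_ref` with one element per store.
#' @export
read_tables <- function(paths) {
  get <- function(nm) if (!is.null(paths[[nm]])) paths[[nm]] else NULL
  ref <- list(
    panel = if (!is.null(get("panel"))) read_panel(get("panel")),
    ld = if (!is.null(get("ld"))) read_ld(get("ld")),
    genes = if (!is.null(get("genes"))) read_gene_models(get("genes")),
    cadd = if (!is.null(get("cadd"))) read_cadd(get("cadd")),
    rdb = if (!is.null(get("rdb"))) read_regulomedb(get("rdb")),
    chromhmm = if (!is.null(get("chromhmm"))) read_chromhmm(get("chromhmm")),
    eqtl = if (!is.null(get("eqtl"))) read_eqtl(get("eqtl")),
    interactions = if (!is.null(get("interactions")))
      read_interactions(get("interactions")),
    enhancers = if (!is.null(get("enhancers")))
      data.table::rbindlist(lapply(names(get("enhancers")), function(e)
        read_region_bed(get("enhancers")[[e]], "enhancer", e))),
    promoters = if (!is.null(get("promoters")))
      data.table::rbindlist(lapply(names(get("promoters")), function(e)
        read_region_bed(get("promoters")[[e]], "promoter", e))),
    expression = if (!is.null(get("expression")))
      read_expression(get("expression"), get("tissue_map")),
    genesets = if (!is.null(get("genesets")))
      lapply(stats::setNames(names(get("genesets")), names(get("genesets"))),
             function(s) read_gmt(get("genesets")[[s]], s)),
    catalog = if (!is.null(get("catalog"))) read_catalog(get("catalog")),
    intolerance = if (!is.null(get("intolerance")))
      read_intolerance(get("intolerance"))
  )
  structure(ref, class = "pg_ref")
}
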