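## Gene mapping: three independent strategies over the candidate SNPs of the
## risk loci.  Positional mapping places SNPs in (windows around) gene
## bodies or restricts to selected consequences; eQTL mapping joins SNPs to
## significant cis SNP-gene pairs per tissue; chromatin-interaction mapping
## links SNP-bearing interaction ends to genes whose strand-aware promoter
## overlaps the other end.  Each strategy applies its own functional SNP
## filter to the ORIGINAL candidate set, so filters never leak across
## strategies.

#' Filter candidate SNPs on functional annotations
#'
#' Conjunction of the provided filters; a SNP lacking a score required by an
#' active filter fails that filter.  Each mapping strategy calls this
#' independently on the original candidate set.
#'
#' @param annotated annotated SNP table ([annotate_snps()]`$annot`).
#' @param cadd_min keep SNPs with CADD at or above this (e.g. 12.37).
#' @param rdb_max keep SNPs whose RegulomeDB category is at or before this
#'   in the ordered vocabulary ([rdb_categories()]; `1a` strongest).
#' @param allowed_states keep SNPs whose chromatin state (in at least one of
#'   `state_epigenomes`) is in this set of states (1..15).
#' @param state_epigenomes epigenomes consulted for `allowed_states`
#'   (default: all annotated).
#' @param allowed_consequences keep SNPs with one of these consequences.
#' @return the filtered subset of `annotated` (possibly empty, with a
#'   warning when a filter combination removes everything).
#' @export
filter_snps_functional <- function(annotated, cadd_min = NULL, rdb_max = NULL,
                                   allowed_states = NULL,
                                   state_epigenomes = NULL,
                                   allowed_consequences = NULL) {
  x <- data.table::as.data.table(annotated)
  keep <- rep(TRUE, nrow(x))
  if (!is.null(cadd_min)) {
    keep <- keep & !is.na(x$cadd) & x$cadd >= cadd_min
  }
  if (!is.null(rdb_max)) {
    ord <- rdb_categories()
    lim <- match(rdb_max, ord)
    if (is.na(lim)) stop("unknown RegulomeDB category: ", rdb_max)
    r <- match(x$rdb, ord)
    keep <- keep & !is.na(r) & r <= lim
  }
  if (!is.null(allowed_states)) {
    cols <- grep("^chromhmm_", names(x), value = TRUE)
    if (!is.null(state_epigenomes)) {
      cols <- intersect(cols, paste0("chromhmm_", state_epigenomes))
    }
    if (!length(cols)) {
      keep <- keep & FALSE
    } else {
      st <- as.matrix(x[, cols, with = FALSE])
      ok <- apply(st, 1L, function(v) any(!is.na(v) & v %in% allowed_states))
      keep <- keep & ok
    }
  }
  if (!is.null(allowed_consequences)) {
    keep <- keep & !is.na(x$consequence) &
      x$consequence %in% allowed_consequences
  }
  out <- x[keep]
  if (!nrow(out) && nrow(x)) {
    warning("functional SNP filter removed every candidate SNP")
  }
  out
}

#' Positional gene mapping
#'
#' Window mode maps a SNP to every gene whose span extended by
#' `window_kb` kb contains it.  Consequence mode maps a SNP to its
#' classifier-annotated gene(s) iff its consequence is in
#' `allowed_consequences` (e.g. exonic + splicing for deleterious-coding
#' mapping; intergenic annotations never map).
#'
#' @param filtered filtered annotated SNPs (from
#'   [filter_snps_functional()], or the full annotated set).
#' @param gene_models gene models.
#' @param mode `"window"` or `"consequence"`.
#' @param window_kb gene window in kb (window mode, default 10).
#' @param allowed_consequences consequence set (consequence mode).
#' @return evidence `data.table`: `gene_id`, `snp_id`, `strategy`,
#'   `detail` (consequence or distance).
#' @export
positional_map <- function(filtered, gene_models,
                           mode = c("window", "consequence"),
                           window_kb = 10,
                           allowed_consequences = c("exonic", "splicing")) {
  mode <- match.arg(mode)
  empty <- data.table::data.table(gene_id = character(0),
                                  snp_id = character(0),
                                  strategy = character(0),
                                  detail = character(0))
  x <- data.table::as.data.table(filtered)
  if (!nrow(x)) return(empty)
  if (mode == "window") {
    pad <- as.integer(round(window_kb * 1000))
    sg <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
    gg <- genes_granges(gene_models, pad = pad)
    hits <- pg_find_overlaps(sg, gg, ignore.strand = TRUE)
    if (!length(hits)) return(empty)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    d <- pmax(0L, pmax(gene_models$start[si] - x$pos[qi],
                       x$pos[qi] - gene_models$end[si]))
    out <- data.table::data.table(gene_id = gene_models$gene_id[si],
                                  snp_id = x$snp_id[qi],
                                  strategy = "positional",
                                  detail = paste0("dist=", d))
    return(out[order(gene_id, snp_id)])
  }
  sel <- x[!is.na(consequence) & consequence %in% allowed_consequences &
             nzchar(genes)]
  if (!nrow(sel)) return(empty)
  out <- sel[, .(gene_id = strsplit(genes, ",")[[1L]],
                 detail = paste0("consequence=", consequence)),
             by = snp_id]
  out[, strategy := "positional"]
  out[, .(gene_id, snp_id, strategy, detail)][order(gene_id, snp_id)]
}

# exact or allele-swapped match of SNPs against an allele-keyed table
allele_join <- function(x, tab) {
  exact <- tab[x, on = c(chrom = "chrom", pos = "pos",
                         effect_allele = "effect_allele",
                         other_allele = "other_allele"),
               which = TRUE]
  swapped <- tab[x, on = c(chrom = "chrom", pos = "pos",
                           effect_allele = "other_allele",
                           other_allele = "effect_allele"),
                 which = TRUE]
  list(exact = exact, swapped = swapped)
}

#' eQTL gene mapping
#'
#' Joins the (filtered) candidate SNPs to the eQTL store on chromosome,
#' position and alleles (exact or swapped orientation; strand flips are not
#' attempted), restricted to the selected tissues, keeping records with
#' source FDR at or below `fdr_max` (or nominal `p <= p_max` when nominal
#' filtering is chosen).  The cis bound (SNP to gene body distance at most
#' `cis_bp`) is enforced against the gene models.
#'
#' @param filtered filtered annotated SNPs; must carry `snp_id`, `chrom`,
#'   `pos` and allele columns (`ref_allele`/`alt_allele` or
#'   `effect_allele`/`other_allele`).
#' @param eqtl eQTL table ([read_eqtl()]).
#' @param tissues tissues to use; every requested tissue must exist in the
#'   store.
#' @param fdr_max FDR threshold (default 0.05); ignored when `p_max` given.
#' @param p_max optional nominal p-value threshold.
#' @param gene_models gene models (for the cis bound).
#' @param cis_bp cis distance bound in bp (default 1e6).
#' @return evidence `data.table`: `gene_id`, `snp_id`, `strategy`,
#'   `tissue`, `p`, `fdr`.
#' @export
eqtl_map <- function(filtered, eqtl, tissues, fdr_max = 0.05, p_max = NULL,
                     gene_models = NULL, cis_bp = 1e6) {
  empty <- data.table::data.table(gene_id = character(0), snp_id = character(0),
                                  strategy = character(0), tissue = character(0),
                                  p = numeric(0), fdr = numeric(0))
  x <- data.table::as.data.table(filtered)
  if (!nrow(x) || is.null(eqtl) || !nrow(eqtl)) return(empty)
  absent <- setdiff(tissues, unique(eqtl$tissue))
  if (length(absent)) {
    stop("requested tissue(s) absent from the eQTL store: ",
         paste(absent, collapse = ", "))
  }
  if (!"effect_allele" %in% names(x)) {
    x[, `:=`(effect_allele = alt_allele, other_allele = ref_allele)]
  }
  e <- eqtl[tissue %in% tissues]
  e <- if (!is.null(p_max)) e[p <= p_max] else e[fdr <= fdr_max]
  if (!nrow(e)) return(empty)
  xx <- x[, .(snp_id, chrom, pos, effect_allele, other_allele)]
  j1 <- e[xx, on = c("chrom", "pos", "effect_allele", "other_allele"),
          nomatch = NULL,
          .(snp_id = i.snp_id, gene_id, tissue, p, fdr, pos)]
  j2 <- e[xx, on = c(chrom = "chrom", pos = "pos",
                     effect_allele = "other_allele",
                     other_allele = "effect_allele"),
          nomatch = NULL,
          .(snp_id = i.snp_id, gene_id, tissue, p, fdr, pos)]
  out <- unique(rbind(j1, j2))
  if (!nrow(out)) return(empty)
  if (!is.null(gene_models)) {
    gs <- gene_models$start[match(out$gene_id, gene_models$gene_id)]
    ge <- gene_models$end[match(out$gene_id, gene_models$gene_id)]
    d <- pmax(0L, pmax(gs - out$pos, out$pos - ge))
    out <- out[!is.na(d) & d <= cis_bp]
  }
  out[, strategy := "eqtl"]
  out[, .(gene_id, snp_id, strategy, tissue, p, fdr)][order(gene_id, snp_id, tissue)]
}

#' Strand-aware promoter intervals
#'
#' The promoter is `promoter_up` bp upstream to `promoter_down` bp
#' downstream of the TSS: `[tss - up, tss + down]` on the plus strand,
#' mirrored to `[tss - down, tss + up]` on the minus strand.
#'
#' @param gene_models gene models.
#' @param promoter_up,promoter_down window in bp (defaults 250 / 500).
#' @return `data.table` with `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_intervals <- function(gene_models, promoter_up = 250L,
                               promoter_down = 500L) {
  gm <- gene_models
  plus <- gm$strand == "+"
  data.table::data.table(
    gene_id = gm$gene_id,
    chrom = gm$chrom,
    start = pmax(1L, as.integer(ifelse(plus, gm$tss - promoter_up,
                                       gm$tss - promoter_down))),
    end = as.integer(ifelse(plus, gm$tss + promoter_down,
                            gm$tss + promoter_up))
  )
}

#' Chromatin-interaction gene mapping
#'
#' Interactions in the selected tissues with FDR at or below `ci_fdr_max`
#' are considered in both orientations: a SNP overlapping one end maps to
#' every gene whose strand-aware promoter overlaps the other end.  When
#' `enhancer_sets` is given, the SNP must additionally fall inside an
#' enhancer interval of a selected epigenome; when `promoter_sets` is
#' given, the gene promoter must overlap a predicted promoter region.
#' There is no distance bound, and trans-chromosomal interactions are
#' honored.  Cases where the SNP end itself overlaps the mapped gene's
#' promoter are flagged (`promoter_promoter`).
#'
#' @param filtered filtered annotated SNPs (`snp_id`, `chrom`, `pos`).
#' @param interactions interaction table ([read_interactions()]).
#' @param gene_models gene models.
#' @param tissues tissues to use.
#' @param ci_fdr_max interaction significance threshold (default 1e-6).
#' @param promoter_up,promoter_down promoter window (defaults 250 / 500).
#' @param enhancer_sets optional region table (`chrom`, `start`, `end`,
#'   `epigenome`) of predicted enhancers.
#' @param promoter_sets optional region table of predicted promoters.
#' @return evidence `data.table`: `gene_id`, `snp_id`, `strategy`,
#'   `tissue`, `fdr`, `snp_end`, `gene_end` (interval labels
#'   `chrom:start-end`), `promoter_promoter`.
#' @export
chromatin_map <- function(filtered, interactions, gene_models, tissues,
                          ci_fdr_max = 1e-6, promoter_up = 250L,
                          promoter_down = 500L, enhancer_sets = NULL,
                          promoter_sets = NULL) {
  empty <- data.table::data.table(
    gene_id = character(0), snp_id = character(0), strategy = character(0),
    tissue = character(0), fdr = numeric(0), snp_end = character(0),
    gene_end = character(0), promoter_promoter = logical(0))
  x <- data.table::as.data.table(filtered)
  if (!nrow(x) || is.null(interactions) || !nrow(interactions)) return(empty)
  ci <- interactions[tissue %in% tissues & fdr <= ci_fdr_max]
  if (!nrow(ci)) return(empty)
  prom <- promoter_intervals(gene_models, promoter_up, promoter_down)
  if (!is.null(promoter_sets) && nrow(promoter_sets)) {
    pr <- GenomicRanges::GRanges(prom$chrom,
                                 IRanges::IRanges(prom$start, prom$end))
    ps <- GenomicRanges::GRanges(promoter_sets$chrom,
                                 IRanges::IRanges(promoter_sets$start,
                                                  promoter_sets$end))
    prom <- prom[pg_count_overlaps(pr, ps) > 0L]
    if (!nrow(prom)) return(empty)
  }
  snps <- x[, .(snp_id, chrom, pos)]
  if (!is.null(enhancer_sets) && nrow(enhancer_sets)) {
    sgr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
    en <- GenomicRanges::GRanges(enhancer_sets$chrom,
                                 IRanges::IRanges(enhancer_sets$start,
                                                  enhancer_sets$end))
    snps <- snps[pg_count_overlaps(sgr, en) > 0L]
    if (!nrow(snps)) return(empty)
  }
  sgr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  pgr <- GenomicRanges::GRanges(prom$chrom, IRanges::IRanges(prom$start, prom$end))

  one_orientation <- function(sc, ss, se, gc, gs, ge) {
    endA <- GenomicRanges::GRanges(sc, IRanges::IRanges(ss, se))
    endB <- GenomicRanges::GRanges(gc, IRanges::IRanges(gs, ge))
    sh <- pg_find_overlaps(sgr, endA, ignore.strand = TRUE)
    gh <- pg_find_overlaps(pgr, endB, ignore.strand = TRUE)
    if (!length(sh) || !length(gh)) return(NULL)
    sdt <- data.table::data.table(snp_i = S4Vectors::queryHits(sh),
                                  int_i = S4Vectors::subjectHits(sh))
    gdt <- data.table::data.table(gene_i = S4Vectors::queryHits(gh),
                                  int_i = S4Vectors::subjectHits(gh))
    merge(sdt, gdt, by = "int_i", allow.cartesian = TRUE)
  }
  o1 <- one_orientation(ci$chrom_a, ci$start_a, ci$end_a,
                        ci$chrom_b, ci$start_b, ci$end_b)
  o2 <- one_orientation(ci$chrom_b, ci$start_b, ci$end_b,
                        ci$chrom_a, ci$start_a, ci$end_a)
  fmt <- function(c, s, e) paste0(c, ":", s, "-", e)
  rows <- list()
  if (!is.null(o1) && nrow(o1)) {
    rows[[1]] <- o1[, .(gene_id = prom$gene_id[gene_i],
                        snp_id = snps$snp_id[snp_i],
                        tissue = ci$tissue[int_i], fdr = ci$fdr[int_i],
                        snp_end = fmt(ci$chrom_a[int_i], ci$start_a[int_i],
                                      ci$end_a[int_i]),
                        gene_end = fmt(ci$chrom_b[int_i], ci$start_b[int_i],
                                       ci$end_b[int_i]))]
  }
  if (!is.null(o2) && nrow(o2)) {
    rows[[2]] <- o2[, .(gene_id = prom$gene_id[gene_i],
                        snp_id = snps$snp_id[snp_i],
                        tissue = ci$tissue[int_i], fdr = ci$fdr[int_i],
                        snp_end = fmt(ci$chrom_b[int_i], ci$start_b[int_i],
                                      ci$end_b[int_i]),
                        gene_end = fmt(ci$chrom_a[int_i], ci$start_a[int_i],
                                       ci$end_a[int_i]))]
  }
  out <- data.table::rbindlist(rows)
  if (is.null(out) || !nrow(out)) return(empty)
  out <- unique(out)
  # flag promoter-promoter interactions: the SNP end overlaps the mapped
  # gene's own promoter window
  pp <- prom[match(out$gene_id, prom$gene_id)]
  se <- data.table::tstrsplit(sub("^.*:", "", out$snp_end), "-")
  sc <- sub(":.*$", "", out$snp_end)
  out[, promoter_promoter := pp$chrom == sc &
        as.integer(se[[1]]) <= pp$end & as.integer(se[[2]]) >= pp$start]
  out[, strategy := "chromatin"]
  out[, .(gene_id, snp_id, strategy, tissue, fdr, snp_end, gene_end,
          promoter_promoter)][order(gene_id, snp_id, tissue)]
}

#' Combine mapping strategies into the prioritized gene table
#'
#' Set union over genes with per-strategy flags, supporting SNPs, loci of
#' the supporting SNPs, an `inside_locus` indicator (gene span overlaps any
#' supporting locus span) and joined intolerance scores.  Restricted by
#' default to protein-coding genes.  The union is idempotent and
#' order-independent across strategies.
#'
#' @param pos_ev,eqtl_ev,ci_ev evidence tables from [positional_map()],
#'   [eqtl_map()], [chromatin_map()] (any may be `NULL` / empty).
#' @param candidates candidate SNPs with `locus_id` (from
#'   [characterize_loci()]).
#' @param loci locus table.
#' @param gene_models gene models.
#' @param intolerance optional intolerance table ([read_intolerance()]).
#' @param gene_types gene types retained (default `"protein_coding"`;
#'   `NULL` keeps all).
#' @return `data.table` with one row per mapped gene: `gene_id`, `symbol`,
#'   `gene_type`, `chrom`, `start`, `end`, logical `posMap`/`eqtlMap`/
#'   `ciMap`, per-strategy SNP counts, `loci` (comma-separated locus ids),
#'   `inside_locus`, `pli`, `ncrvis`.
#' @export
combine_maps <- function(pos_ev = NULL, eqtl_ev = NULL, ci_ev = NULL,
                         candidates, loci, gene_models, intolerance = NULL,
                         gene_types = "protein_coding") {
  evs <- list(positional = pos_ev, eqtl = eqtl_ev, chromatin = ci_ev)
  evs <- Filter(function(e) !is.null(e) && nrow(e), evs)
  empty <- data.table::data.table(
    gene_id = character(0), symbol = character(0), gene_type = character(0),
    chrom = character(0), start = integer(0), end = integer(0),
    posMap = logical(0), eqtlMap = logical(0), ciMap = logical(0),
    n_snps_pos = integer(0), n_snps_eqtl = integer(0), n_snps_ci = integer(0),
    loci = character(0), inside_locus = logical(0),
    pli = numeric(0), ncrvis = numeric(0))
  if (!length(evs)) return(empty)
  long <- data.table::rbindlist(
    lapply(evs, function(e) e[, .(gene_id, snp_id, strategy)]))
  long <- unique(long)
  gm <- gene_models
  keep_genes <- if (is.null(gene_types)) gm$gene_id else
    gm$gene_id[gm$gene_type %in% gene_types]
  long <- long[gene_id %in% keep_genes]
  if (!nrow(long)) return(empty)
  locus_of <- stats::setNames(candidates$locus_id, candidates$snp_id)
  long[, locus_id := unname(locus_of[snp_id])]
  per_gene <- long[, .(
    posMap = any(strategy == "positional"),
    eqtlMap = any(strategy == "eqtl"),
    ciMap = any(strategy == "chromatin"),
    n_snps_pos = data.table::uniqueN(snp_id[strategy == "positional"]),
    n_snps_eqtl = data.table::uniqueN(snp_id[strategy == "eqtl"]),
    n_snps_ci = data.table::uniqueN(snp_id[strategy == "chromatin"]),
    locus_ids = list(sort(unique(locus_id[!is.na(locus_id)])))
  ), by = gene_id]
  gi <- match(per_gene$gene_id, gm$gene_id)
  per_gene[, `:=`(symbol = gm$symbol[gi], gene_type = gm$gene_type[gi],
                  chrom = gm$chrom[gi], start = gm$start[gi],
                  end = gm$end[gi])]
  inside <- vapply(seq_len(nrow(per_gene)), function(i) {
    lids <- per_gene$locus_ids[[i]]
    if (!length(lids)) return(FALSE)
    ll <- loci[locus_id %in% lids]
    any(ll$chrom == per_gene$chrom[i] &
          ll$start <= per_gene$end[i] & ll$end >= per_gene$start[i])
  }, logical(1))
  per_gene[, inside_locus := inside]
  per_gene[, loci := vapply(locus_ids, paste, character(1), collapse = ",")]
  if (!is.null(intolerance)) {
    im <- match(per_gene$gene_id, intolerance$gene_id)
    per_gene[, `:=`(pli = intolerance$pli[im], ncrvis = intolerance$ncrvis[im])]
  } else {
    per_gene[, `:=`(pli = NA_real_, ncrvis = NA_real_)]
  }
  out <- per_gene[, .(gene_id, symbol, gene_type, chrom, start, end,
                      posMap, eqtlMap, ciMap,
                      n_snps_pos, n_snps_eqtl, n_snps_ci,
                      loci, inside_locus, pli, ncrvis)]
  out[order(chrom_rank(chrom), start, gene_id)]
}

#' Per-locus mapped-gene counts
#'
#' Counts mapped genes per risk locus; loci with exactly one mapped gene
#' support the "single prioritized gene" summary.
#'
#' @param mapped output of [combine_maps()].
#' @param loci locus table.
#' @return `data.table` with `locus_id`, `n_genes`, `single_gene`.
#' @export
locus_gene_counts <- function(mapped, loci) {
  if (!nrow(mapped)) {
    return(data.table::data.table(locus_id = loci$locus_id, n_genes = 0L,
                                  single_gene = FALSE))
  }
  pairs <- mapped[, .(locus_id = as.integer(strsplit(loci, ",")[[1L]])),
                  by = gene_id]
  cnt <- pairs[, .(n_genes = data.table::uniqueN(gene_id)), by = locus_id]
  out <- data.table::data.table(locus_id = loci$locus_id)
  out[, n_genes := cnt$n_genes[match(locus_id, cnt$locus_id)]]
  out[is.na(n_genes), n_genes := 0L]
  out[, single_gene := n_genes == 1L]
  out[]
}
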