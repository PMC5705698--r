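## Functional annotation of candidate SNPs: a positional consequence
## classifier over gene models (exonic/splicing/intronic/up-/downstream/
## intergenic, with ncRNA_* variants for non-protein-coding genes), left-join
## annotation of CADD, RegulomeDB and per-epigenome chromatin states, and
## exact positional matching against reported GWAS-catalog associations.

consequence_levels <- function() {
  c("splicing", "exonic", "UTR5", "UTR3", "intronic",
    "ncRNA_exonic", "ncRNA_intronic", "upstream", "downstream", "intergenic")
}

# rank in the precedence order (1 = highest precedence)
consequence_rank <- function(cons) {
  match(cons, consequence_levels())
}

# classify one SNP against one overlapping gene
classify_within_gene <- function(pos, gene, splice_bp) {
  es <- gene$exon_start[[1L]]; ee <- gene$exon_end[[1L]]
  coding <- identical(gene$gene_type, "protein_coding")
  in_exon <- length(es) && any(pos >= es & pos <= ee)
  if (in_exon) {
    return(if (coding) "exonic" else "ncRNA_exonic")
  }
  if (!length(es)) {
    # no exon structure recorded: treat the whole span as exonic
    return(if (coding) "exonic" else "ncRNA_exonic")
  }
  if (coding) {
    near_boundary <-
      any(pos >= ee + 1L & pos <= ee + splice_bp) ||
      any(pos >= es - splice_bp & pos <= es - 1L)
    if (near_boundary) return("splicing")
  }
  if (coding) "intronic" else "ncRNA_intronic"
}

#' Classify the positional consequence of SNPs
#'
#' A simplified gene-based consequence classifier.  Precedence (high to
#' low): splicing (within `splice_bp` of an exon-intron boundary, inside
#' the intron, protein-coding genes), exonic, intronic, upstream /
#' downstream (within `flank_bp` of the gene, strand-aware), intergenic.
#' For non-protein-coding genes the exonic/intronic classes become
#' `ncRNA_exonic` / `ncRNA_intronic`.  A SNP overlapping several genes is
#' annotated to all of them and receives the highest-precedence
#' consequence.  Intergenic SNPs are annotated to the two closest flanking
#' genes with their distances (one gene at chromosome ends).  UTR classes
#' are only emitted when CDS bounds are available in the models; without
#' them exonic is reported.
#'
#' @param snps `data.table` with `snp_id`, `chrom`, `pos`.
#' @param gene_models gene models ([read_gene_models()]).
#' @param splice_bp splicing window in bp (default 2).
#' @param flank_bp up-/downstream flank in bp (default 1000).
#' @return `data.table` with `snp_id`, `consequence`, `genes`
#'   (comma-separated gene ids, <= 2 for intergenic SNPs), `dist`
#'   (comma-separated distances in bp; 0 for genic SNPs).
#' @export
classify_consequence <- function(snps, gene_models, splice_bp = 2L,
                                 flank_bp = 1000L) {
  gm <- gene_models
  out <- data.table::data.table(snp_id = snps$snp_id,
                                consequence = NA_character_,
                                genes = NA_character_,
                                dist = NA_character_)
  if (!nrow(snps)) return(out)
  sg <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  gg <- genes_granges(gm)
  hits <- pg_find_overlaps(sg, gg, ignore.strand = TRUE)
  hit_by_snp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  for (i in seq_len(nrow(snps))) {
    pos <- snps$pos[i]; chrom <- snps$chrom[i]
    gi <- hit_by_snp[[as.character(i)]]
    if (!is.null(gi) && length(gi)) {
      cons <- vapply(gi, function(j)
        classify_within_gene(pos, gm[j], splice_bp), character(1))
      best <- min(consequence_rank(cons))
      out$consequence[i] <- consequence_levels()[best]
      out$genes[i] <- paste(gm$gene_id[gi], collapse = ",")
      out$dist[i] <- paste(rep(0L, length(gi)), collapse = ",")
      next
    }
    same_idx <- which(gm[["chrom"]] == chrom)
    same <- gm[same_idx]
    if (!nrow(same)) {
      out$consequence[i] <- "intergenic"
      out$genes[i] <- ""
      out$dist[i] <- ""
      warning("SNP ", snps$snp_id[i], " lies on a chromosome without genes")
      next
    }
    # flank check, strand-aware: upstream = before the TSS side
    dl <- pos - same$end    # >0 when the SNP is right of the gene
    dr <- same$start - pos  # >0 when the SNP is left of the gene
    updown <- rep(NA_character_, nrow(same))
    fdist <- rep(NA_integer_, nrow(same))
    right_of <- dl > 0L & dl <= flank_bp
    left_of <- dr > 0L & dr <= flank_bp
    updown[right_of & same$strand == "+"] <- "downstream"
    updown[right_of & same$strand == "-"] <- "upstream"
    updown[left_of & same$strand == "+"] <- "upstream"
    updown[left_of & same$strand == "-"] <- "downstream"
    fdist[right_of] <- dl[right_of]
    fdist[left_of] <- dr[left_of]
    if (any(!is.na(updown))) {
      cand <- which(!is.na(updown))
      ranks <- consequence_rank(updown[cand])
      keep <- cand[order(ranks, fdist[cand])][1L]
      out$consequence[i] <- updown[keep]
      out$genes[i] <- same$gene_id[keep]
      out$dist[i] <- as.character(fdist[keep])
      next
    }
    # intergenic: two closest flanking genes with distances
    lefts <- same[end < pos]
    rights <- same[start > pos]
    gl <- if (nrow(lefts)) lefts[which.min(pos - lefts$end)] else NULL
    gr <- if (nrow(rights)) rights[which.min(rights$start - pos)] else NULL
    ids <- c(if (!is.null(gl)) gl$gene_id, if (!is.null(gr)) gr$gene_id)
    ds <- c(if (!is.null(gl)) pos - gl$end, if (!is.null(gr)) gr$start - pos)
    out$consequence[i] <- "intergenic"
    out$genes[i] <- paste(ids, collapse = ",")
    out$dist[i] <- paste(ds, collapse = ",")
  }
  out
}

#' Annotate candidate SNPs with scores and chromatin states
#'
#' Left-join semantics throughout: a SNP missing from a score table keeps an
#' `NA` for that score and is never an error.  CADD is joined on
#' (chrom, pos) with an exact or allele-swapped (ref, alt) match;
#' RegulomeDB on (chrom, pos); chromatin states per selected epigenome by
#' 200-bp bin containment.  The candidate set is never changed (same rows
#' in, same rows out).
#'
#' @param candidates candidate SNPs ([collect_candidates()]); needs
#'   `snp_id`, `chrom`, `pos` and, for the CADD allele match, optional
#'   `ref_allele` / `alt_allele` columns (joined from the panel when
#'   absent).
#' @param panel reference panel (for alleles; optional if candidates carry
#'   allele columns).
#' @param cadd,rdb,chromhmm score tables ([read_cadd()] etc.); any may be
#'   `NULL`.
#' @param epigenomes character vector of epigenome ids to annotate
#'   chromatin states for (default: all in the table).
#' @param bin_bp chromatin-state bin size (200).
#' @return `data.table`: the candidates plus `cadd`, `rdb` and one
#'   `chromhmm_<epigenome>` column per selected epigenome.
#' @export
annotate_scores <- function(candidates, panel = NULL, cadd = NULL, rdb = NULL,
                            chromhmm = NULL, epigenomes = NULL,
                            bin_bp = 200L) {
  x <- data.table::copy(data.table::as.data.table(candidates))
  if (!all(c("ref_allele", "alt_allele") %in% names(x))) {
    if (!is.null(panel)) {
      pm <- match(x$snp_id, panel$snp_id)
      x[, `:=`(ref_allele = panel$ref_allele[pm],
               alt_allele = panel$alt_allele[pm])]
    } else {
      x[, `:=`(ref_allele = NA_character_, alt_allele = NA_character_)]
    }
  }
  if (!is.null(cadd)) {
    exact <- cadd[x, on = c(chrom = "chrom", pos = "pos",
                            ref = "ref_allele", alt = "alt_allele"),
                  x.cadd]
    swapped <- cadd[x, on = c(chrom = "chrom", pos = "pos",
                              ref = "alt_allele", alt = "ref_allele"),
                    x.cadd]
    x[, cadd := data.table::fifelse(is.na(exact), swapped, exact)]
  } else {
    x[, cadd := NA_real_]
  }
  if (!is.null(rdb)) {
    x[, rdb := rdb[x, on = c("chrom", "pos"), x.rdb]]
  } else {
    x[, rdb := NA_character_]
  }
  if (!is.null(chromhmm)) {
    epis <- if (is.null(epigenomes)) sort(unique(chromhmm$epigenome)) else epigenomes
    x[, bin_start := (pos - 1L) %/% bin_bp * bin_bp]
    for (e in epis) {
      sub <- chromhmm[epigenome == e]
      col <- paste0("chromhmm_", e)
      x[, (col) := sub[x, on = c("chrom", "bin_start"), x.state]]
    }
    x[, bin_start := NULL]
  }
  x[]
}

#' Match candidate SNPs against GWAS-catalog entries
#'
#' Exact (chrom, pos) matching; a SNP can collect several reported traits.
#'
#' @param candidates candidate SNP `data.table` (`snp_id`, `chrom`, `pos`).
#' @param catalog catalog table ([read_catalog()]).
#' @return `data.table` with one row per (SNP, catalog entry) hit:
#'   `snp_id`, `chrom`, `pos`, `trait`, `reported_p`.
#' @export
match_catalog <- function(candidates, catalog) {
  if (is.null(catalog) || !nrow(catalog)) {
    return(data.table::data.table(snp_id = character(0), chrom = character(0),
                                  pos = integer(0), trait = character(0),
                                  reported_p = numeric(0)))
  }
  x <- data.table::as.data.table(candidates)[, .(snp_id, chrom, pos)]
  hits <- merge(x, catalog, by = c("chrom", "pos"), allow.cartesian = TRUE)
  hits[, .(snp_id, chrom, pos, trait, reported_p)]
}

#' Annotate candidate SNPs (full step)
#'
#' Runs the consequence classifier, the score joins and the catalog match,
#' returning a single per-SNP annotation table plus the long catalog-hit
#' table.
#'
#' @inheritParams annotate_scores
#' @param gene_models gene models.
#' @param catalog optional catalog table.
#' @param consequence_override optional `data.table`
#'   (`snp_id`, `consequence`, `gene_id`) taking precedence over the
#'   internal classifier (e.g. codon-level calls from an external
#'   annotator).
#' @param splice_bp,flank_bp classifier windows.
#' @return list with `annot` (per-SNP table) and `catalog_hits`.
#' @export
annotate_snps <- function(candidates, gene_models, panel = NULL, cadd = NULL,
                          rdb = NULL, chromhmm = NULL, epigenomes = NULL,
                          catalog = NULL, consequence_override = NULL,
                          splice_bp = 2L, flank_bp = 1000L) {
  cons <- classify_consequence(candidates, gene_models, splice_bp, flank_bp)
  annot <- annotate_scores(candidates, panel, cadd, rdb, chromhmm, epigenomes)
  annot[, consequence := cons$consequence[match(snp_id, cons$snp_id)]]
  annot[, genes := cons$genes[match(snp_id, cons$snp_id)]]
  annot[, dist := cons$dist[match(snp_id, cons$snp_id)]]
  if (!is.null(consequence_override) && nrow(consequence_override)) {
    ov <- data.table::as.data.table(consequence_override)
    m <- match(annot$snp_id, ov$snp_id)
    hit <- !is.na(m)
    annot[hit, consequence := ov$consequence[m[hit]]]
    annot[hit, genes := ov$gene_id[m[hit]]]
    annot[hit, dist := "0"]
  }
  list(annot = annot[],
       catalog_hits = match_catalog(candidates, catalog))
}
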