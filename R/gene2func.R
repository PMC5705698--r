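## Gene-to-function analysis: expression summaries across tissues,
## construction of tissue differentially-expressed gene (DEG) sets with
## pooled-variance t-tests and Bonferroni correction, and hypergeometric
## enrichment of a gene list against gene-set collections and DEG sets with
## per-source Benjamini-Hochberg adjustment.

# per-tissue sample index list
tissue_groups <- function(expr) {
  split(seq_along(expr$tissue_of), expr$tissue_of)
}

#' Filter genes to those expressed in at least one tissue
#'
#' Keeps genes whose mean raw RPKM reaches `min_rpkm` in at least one
#' tissue (boundary inclusive).
#'
#' @param expr `pg_expr` object ([read_expression()]).
#' @param min_rpkm expression floor (default 1).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(expr, min_rpkm = 1) {
  groups <- tissue_groups(expr)
  if (any(lengths(groups) == 0L)) stop("tissue with zero samples")
  tm <- vapply(groups, function(ix) rowMeans(expr$mat[, ix, drop = FALSE]),
               numeric(nrow(expr$mat)))
  if (is.null(dim(tm))) tm <- matrix(tm, nrow = 1)
  rownames(expr$mat)[apply(tm, 1L, max) >= min_rpkm]
}

#' Summarize expression per gene and tissue
#'
#' Two summaries per (gene, tissue): `mean_log`, the per-tissue sample mean
#' of `log2(min(RPKM, winsor_cap) + 1)` (comparable across genes), and
#' `norm_log`, the same value re-centered to zero mean across tissues
#' within each gene (comparable across tissues).
#'
#' @param expr `pg_expr` object (typically restricted to expressed genes).
#' @param winsor_cap RPKM winsorization cap (default 50).
#' @param genes optional subset of gene ids.
#' @return `data.table` with `gene_id`, `tissue`, `mean_log`, `norm_log`.
#' @export
summarize_expression <- function(expr, winsor_cap = 50, genes = NULL) {
  mat <- expr$mat
  if (!is.null(genes)) mat <- mat[rownames(mat) %in% genes, , drop = FALSE]
  w <- log2(pmin(mat, winsor_cap) + 1)
  groups <- tissue_groups(expr)
  means <- vapply(groups, function(ix) rowMeans(w[, ix, drop = FALSE]),
                  numeric(nrow(w)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = nrow(w),
                    dimnames = list(rownames(w), names(groups)))
  }
  centered <- means - rowMeans(means)
  data.table::data.table(
    gene_id = rep(rownames(w), times = ncol(means)),
    tissue = rep(colnames(means), each = nrow(w)),
    mean_log = as.vector(means),
    norm_log = as.vector(centered)
  )
}

# vectorized pooled-variance two-sample t over the rows of a matrix:
# group 1 = columns ix, group 2 = the rest
pooled_t_rows <- function(X, ix) {
  n1 <- length(ix); n2 <- ncol(X) - n1
  x1 <- X[, ix, drop = FALSE]; x2 <- X[, -ix, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate cases: zero pooled variance
  zero <- sp2 <= 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    p[eq] <- 1; t[eq] <- 0
    ne <- zero & (m1 != m2)
    p[ne] <- .Machine$double.xmin
    t[ne] <- sign(m1[ne] - m2[ne]) * Inf
  }
  list(t = t, df = df, p = p, lfc = m1 - m2)
}

#' Build tissue DEG sets
#'
#' For every (gene, tissue) pair a two-sided pooled-variance Student
#' t-test compares the per-sample `log2(RPKM + 1)` values of the tissue's
#' samples against all other samples pooled (`df = n1 + n2 - 2`).
#' Winsorization is not applied here.  P-values are Bonferroni-corrected
#' across all tests performed; a gene joins a tissue's DEG set when the
#' corrected p is below `deg_alpha` and the absolute log fold change (the
#' difference of group means on the log2 scale) is at least `deg_lfc`.
#' Up/down sets split the two-sided set by the sign of the t statistic.
#'
#' @param expr `pg_expr` object.
#' @param deg_alpha corrected-p threshold (default 0.05).
#' @param deg_lfc absolute log2-fold-change threshold (default 0.58).
#' @param genes optional gene subset (e.g. [filter_expressed()]).
#' @param welch use Welch's unequal-variance t instead of the pooled test.
#' @return list of class `pg_degsets`: `stats` (`data.table` with
#'   `gene_id`, `tissue`, `t`, `df`, `p`, `adj_p`, `lfc`), and named lists
#'   `up`, `down`, `twoside` of gene-id sets per tissue.
#' @export
build_deg_sets <- function(expr, deg_alpha = 0.05, deg_lfc = 0.58,
                           genes = NULL, welch = FALSE) {
  mat <- expr$mat
  if (!is.null(genes)) mat <- mat[rownames(mat) %in% genes, , drop = FALSE]
  X <- log2(mat + 1)
  groups <- tissue_groups(expr)
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small)) {
    stop("tissue(s) with fewer than 2 samples: ", paste(small, collapse = ", "))
  }
  res <- lapply(names(groups), function(tt) {
    ix <- groups[[tt]]
    if (ncol(X) - length(ix) < 2L) {
      stop("fewer than 2 samples outside tissue ", tt)
    }
    r <- if (welch) welch_t_rows(X, ix) else pooled_t_rows(X, ix)
    data.table::data.table(gene_id = rownames(X), tissue = tt,
                           t = r$t, df = r$df, p = r$p, lfc = r$lfc)
  })
  stats_dt <- data.table::rbindlist(res)
  stats_dt[, adj_p := pmin(1, p * .N)]
  member <- stats_dt[adj_p < deg_alpha & abs(lfc) >= deg_lfc]
  tissues <- names(groups)
  pick <- function(cond_dt) {
    out <- lapply(tissues, function(tt) cond_dt[tissue == tt, gene_id])
    names(out) <- tissues
    out
  }
  structure(list(
    stats = stats_dt[],
    up = pick(member[t > 0]),
    down = pick(member[t < 0]),
    twoside = pick(member)
  ), class = "pg_degsets")
}

welch_t_rows <- function(X, ix) {
  n1 <- length(ix); n2 <- ncol(X) - n1
  x1 <- X[, ix, drop = FALSE]; x2 <- X[, -ix, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 <= 0
  if (any(zero)) {
    eq <- zero & (m1 == m2); p[eq] <- 1; t[eq] <- 0
    ne <- zero & (m1 != m2); p[ne] <- .Machine$double.xmin
    t[ne] <- sign(m1[ne] - m2[ne]) * Inf
  }
  list(t = t, df = df, p = p, lfc = m1 - m2)
}

#' Hypergeometric upper-tail p-value
#'
#' Probability of drawing at least `k` members of a `K`-gene set when `n`
#' genes are drawn without replacement from a background of `N`:
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Computed through the distribution's stable tail; `k = 0` gives 1.
#'
#' @param k overlap size (vectorized).
#' @param K set size within the background.
#' @param n input-list size within the background.
#' @param N background size.
#' @return numeric vector of upper-tail p-values.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, len); K <- rep_len(K, len)
  n <- rep_len(n, len); N <- rep_len(N, len)
  if (any(K > N | n > N)) stop("K and n must not exceed N")
  if (any(k < 0 | k > pmin(n, K))) stop("k must lie in [0, min(n, K)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

enrich_one_source <- function(genes, sets, source_label, background) {
  genes <- intersect(genes, background)
  N <- length(background)
  n <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    set_bg <- intersect(sets[[nm]], background)
    K <- length(set_bg)
    ov <- intersect(genes, set_bg)
    k <- length(ov)
    data.table::data.table(
      set_name = nm, source_label = source_label,
      N = N, K = K, n = n, k = k,
      p = if (K == 0L || n == 0L) 1 else hypergeom_pvalue(k, K, n, N),
      overlap_genes = paste(sort(ov), collapse = ","))
  })
  data.table::rbindlist(rows)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests a gene list against one or more gene-set collections.  Input genes
#' and sets are intersected with the background before `N`, `K`, `n`, `k`
#' are computed; genes outside the background are dropped with a logged
#' count.  Multiple-testing adjustment (Benjamini-Hochberg by default) is
#' applied within each `source_label` independently, never pooled.  The
#' reported subset keeps rows with adjusted p at or below `adjp_max` and
#' overlap `k >= min_overlap`; the full table is always returned.
#'
#' @param genes character vector of gene ids.
#' @param collections a `pg_genesets` object or list of them.
#' @param background character vector: the gene universe (e.g. all
#'   protein-coding gene ids from the gene models).
#' @param adjust method passed to [stats::p.adjust()] (default `"BH"`).
#' @param adjp_max,min_overlap report filters (defaults 0.05 and 2).
#' @return list with `full` and `report` `data.table`s (`set_name`,
#'   `source_label`, `N`, `K`, `n`, `k`, `p`, `adj_p`, `overlap_genes`).
#' @export
enrich_gene_sets <- function(genes, collections, background, adjust = "BH",
                             adjp_max = 0.05, min_overlap = 2L) {
  if (!length(background)) stop("empty enrichment background")
  if (inherits(collections, "pg_genesets")) collections <- list(collections)
  dropped <- setdiff(genes, background)
  if (length(dropped)) {
    message(length(dropped), " input gene(s) outside the background dropped")
  }
  full <- data.table::rbindlist(lapply(collections, function(gs)
    enrich_one_source(genes, gs$sets, gs$source_label, background)))
  if (!nrow(full)) {
    return(list(full = full, report = full))
  }
  full[, adj_p := stats::p.adjust(p, method = adjust), by = source_label]
  report <- full[adj_p <= adjp_max & k >= min_overlap]
  list(full = full[], report = report[])
}

#' Enrichment against tissue DEG sets
#'
#' Runs the hypergeometric machinery against each tissue's up, down and
#' two-sided DEG set; the direction is the multiple-testing source, so BH
#' runs within direction across tissues.  Empty DEG sets are skipped.
#'
#' @param genes character vector of gene ids.
#' @param deg_sets `pg_degsets` object ([build_deg_sets()]).
#' @param background gene universe.
#' @param adjust,adjp_max,min_overlap see [enrich_gene_sets()].
#' @return list with `full` and `report` tables; `source_label` is one of
#'   `DEG_up`, `DEG_down`, `DEG_twoside` and `set_name` the tissue.
#' @export
enrich_deg <- function(genes, deg_sets, background, adjust = "BH",
                       adjp_max = 0.05, min_overlap = 2L) {
  dirs <- c(up = "DEG_up", down = "DEG_down", twoside = "DEG_twoside")
  collections <- lapply(names(dirs), function(d) {
    sets <- Filter(length, deg_sets[[d]])
    structure(list(source_label = dirs[[d]], sets = sets,
                   descriptions = NULL), class = "pg_genesets")
  })
  collections <- Filter(function(gs) length(gs$sets), collections)
  if (!length(collections)) {
    e <- data.table::data.table(set_name = character(0),
                                source_label = character(0),
                                N = integer(0), K = integer(0), n = integer(0),
                                k = integer(0), p = numeric(0),
                                adj_p = numeric(0),
                                overlap_genes = character(0))
    return(list(full = e, report = e))
  }
  enrich_gene_sets(genes, collections, background, adjust, adjp_max,
                   min_overlap)
}
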