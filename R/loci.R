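## Characterization of genomic risk loci from GWAS summary statistics and a
## pre-computed pairwise-LD reference: greedy selection of independent
## significant SNPs (r2 < 0.6), lead SNPs (r2 < 0.1), collection of candidate
## SNPs (r2 >= 0.6 proxies, including reference-panel SNPs absent from the
## GWAS input), and merging of LD blocks closer than 250 kb into risk loci.

# deterministic ordering of chromosome labels: numeric first, then others
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  r <- ifelse(is.na(num), 1e6, num)
  extra <- match(chrom, sort(unique(chrom[is.na(num)])))
  ifelse(is.na(num), r + ifelse(is.na(extra), 0, extra), r)
}

# canonical greedy consideration order: ascending p, ties by chrom, pos, id
order_snps <- function(x) {
  order(x$p, chrom_rank(x$chrom), x$pos, x$snp_id)
}

# neighbor lookup restricted to a SNP universe and an r2 floor:
# named list snp -> character vector of correlated SNPs
neighbor_map <- function(ld, ids, min_r2) {
  sub <- ld$index[snp_a %in% ids & snp_b %in% ids & r2 >= min_r2]
  split(sub$snp_b, factor(sub$snp_a, levels = ids))
}

#' Select independent significant SNPs
#'
#' Greedy clumping: genome-wide significant SNPs (`p < p_sig`) present in
#' the reference panel are visited in ascending p-value order (ties broken
#' by chromosome, position, then SNP id) and a SNP is selected iff its r2
#' with every previously selected SNP is below `r2_ind`.  SNPs listed in
#' `forced` are selected unconditionally, before the greedy pass.
#'
#' @param sumstats summary statistics ([read_sumstats()]).
#' @param panel reference panel ([read_panel()]).
#' @param ld LD store ([read_ld()]).
#' @param params parameter list ([default_params()]).
#' @param forced optional character vector of SNP ids to force into the set.
#' @return `data.table` with `snp_id`, `chrom`, `pos`, `p`, `rank`,
#'   `forced`; zero rows when nothing is significant.
#' @export
select_independent_significant <- function(sumstats, panel, ld,
                                           params = default_params(),
                                           forced = NULL) {
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("reference panel is empty; LD-dependent selection is impossible")
  }
  sig <- sumstats[p < params$p_sig]
  in_panel <- sig$snp_id %in% panel$snp_id
  if (any(!in_panel)) {
    message(sum(!in_panel),
            " significant SNP(s) absent from the reference panel excluded",
            " from clumping")
    sig <- sig[in_panel]
  }
  sig <- sig[order_snps(sig)]
  consider <- sig$snp_id
  if (!is.null(forced) && length(forced)) {
    forced <- as.character(forced)
    consider <- c(forced, setdiff(consider, forced))
  }
  if (!length(consider)) {
    return(empty_ind_sig())
  }
  nb <- neighbor_map(ld, consider, params$r2_ind)
  selected <- character(0)
  in_sel <- new.env(parent = emptyenv())
  for (s in consider) {
    force_this <- s %in% forced
    if (!force_this) {
      blockers <- nb[[s]]
      if (!is.null(blockers) && length(blockers) &&
          any(vapply(blockers, exists, logical(1), envir = in_sel))) {
        next
      }
    }
    selected <- c(selected, s)
    assign(s, TRUE, envir = in_sel)
  }
  meta <- sumstats[match(selected, snp_id),
                   .(snp_id, chrom, pos, p)]
  # forced SNPs may be absent from the GWAS input entirely
  if (anyNA(meta$snp_id)) {
    miss <- which(is.na(meta$snp_id))
    pm <- match(selected[miss], panel$snp_id)
    meta$snp_id[miss] <- selected[miss]
    meta$chrom[miss] <- panel$chrom[pm]
    meta$pos[miss] <- panel$pos[pm]
  }
  meta[, rank := seq_len(.N)]
  meta[, forced := snp_id %in% forced]
  meta[]
}

empty_ind_sig <- function() {
  data.table::data.table(snp_id = character(0), chrom = character(0),
                         pos = integer(0), p = numeric(0),
                         rank = integer(0), forced = logical(0))
}

#' Collect candidate SNPs around independent significant SNPs
#'
#' A candidate SNP is any reference-panel variant with r2 >= `r2_ind` to at
#' least one independent significant SNP (each of which tags itself through
#' the implicit self-LD of 1).  Candidates absent from the GWAS input keep
#' `p = NA` and are flagged `non_gwas_tagged`.  The MAF filter
#' (`maf >= maf_min`) is applied to candidates only and never removes an
#' independent significant SNP.
#'
#' @inheritParams select_independent_significant
#' @param ind_sig output of [select_independent_significant()].
#' @return `data.table` with `snp_id`, `chrom`, `pos`, `maf`, `p`,
#'   `best_r2`, `nearest_ind_sig`, `non_gwas_tagged`, plus an attribute
#'   `"pairs"` holding the full (candidate, independent-significant, r2)
#'   relation used for LD-block construction.
#' @export
collect_candidates <- function(ind_sig, panel, ld, sumstats,
                               params = default_params()) {
  if (nrow(ind_sig) == 0L) {
    out <- data.table::data.table(
      snp_id = character(0), chrom = character(0), pos = integer(0),
      maf = numeric(0), p = numeric(0), best_r2 = numeric(0),
      nearest_ind_sig = character(0), non_gwas_tagged = logical(0))
    data.table::setattr(out, "pairs", data.table::data.table())
    return(out)
  }
  is_ids <- ind_sig$snp_id
  pairs <- ld$index[snp_a %in% is_ids & r2 >= params$r2_ind,
                    .(ind_snp = snp_a, snp_id = snp_b, r2)]
  pairs <- rbind(pairs,
                 data.table::data.table(ind_snp = is_ids, snp_id = is_ids,
                                        r2 = 1))
  pairs <- pairs[snp_id %in% panel$snp_id]
  # MAF filter (candidates only; independent significant SNPs are exempt)
  maf_of <- stats::setNames(panel$maf, panel$snp_id)
  keep <- maf_of[pairs$snp_id] >= params$maf_min | pairs$snp_id %in% is_ids
  pairs <- pairs[keep]
  # nearest independent significant SNP: max r2, ties to the smaller p
  p_of <- stats::setNames(ind_sig$p, ind_sig$snp_id)
  pairs[, ind_p := p_of[ind_snp]]
  data.table::setorder(pairs, snp_id, -r2, ind_p, ind_snp)
  cand <- pairs[, .(best_r2 = r2[1L], nearest_ind_sig = ind_snp[1L]),
                by = snp_id]
  pm <- match(cand$snp_id, panel$snp_id)
  cand[, `:=`(chrom = panel$chrom[pm], pos = panel$pos[pm],
              maf = panel$maf[pm])]
  cand[, p := sumstats$p[match(snp_id, sumstats$snp_id)]]
  cand[, non_gwas_tagged := is.na(p)]
  data.table::setorder(cand, chrom, pos, snp_id)
  out <- cand[, .(snp_id, chrom, pos, maf, p, best_r2, nearest_ind_sig,
                  non_gwas_tagged)]
  data.table::setattr(out, "pairs",
                      pairs[, .(ind_snp, snp_id, r2,
                                pos = panel$pos[match(snp_id, panel$snp_id)],
                                chrom = panel$chrom[match(snp_id, panel$snp_id)])])
  out
}

#' Select lead SNPs among independent significant SNPs
#'
#' Greedy pass over the independent significant SNPs in ascending p order:
#' a SNP becomes a lead iff its r2 with every previously selected lead is
#' below `r2_lead`.  Every non-lead is assigned to the first selected lead
#' it is correlated with at r2 >= `r2_lead`.
#'
#' @inheritParams collect_candidates
#' @param forced optional SNP ids forced to be leads (selected first,
#'   unconditionally).
#' @return `data.table` with `snp_id`, `chrom`, `pos`, `p` and the
#'   list-column `members` (ids of represented independent significant
#'   SNPs, the lead itself included).
#' @export
select_lead <- function(ind_sig, ld, params = default_params(),
                        forced = NULL) {
  if (nrow(ind_sig) == 0L) {
    return(data.table::data.table(snp_id = character(0), chrom = character(0),
                                  pos = integer(0), p = numeric(0),
                                  members = list()))
  }
  x <- ind_sig[order_snps(ind_sig)]
  consider <- x$snp_id
  if (!is.null(forced) && length(forced)) {
    consider <- c(intersect(forced, consider), setdiff(consider, forced))
  }
  r2m <- function(a, b) ld_r2(ld, a, b)
  leads <- character(0)
  assigned <- stats::setNames(rep(NA_character_, length(consider)), consider)
  for (s in consider) {
    if (s %in% forced) {
      leads <- c(leads, s); assigned[s] <- s; next
    }
    r2v <- if (length(leads)) r2m(rep(s, length(leads)), leads) else numeric(0)
    if (!length(leads) || all(r2v < params$r2_lead)) {
      leads <- c(leads, s)
      assigned[s] <- s
    } else {
      assigned[s] <- leads[which(r2v >= params$r2_lead)[1L]]
    }
  }
  # a non-lead may be orphaned only if forced leads replaced its blocker;
  # assign it to the first lead with r2 >= r2_lead, else to itself as lead
  orphan <- names(assigned)[is.na(assigned)]
  for (s in orphan) {
    r2v <- r2m(rep(s, length(leads)), leads)
    assigned[s] <- if (any(r2v >= params$r2_lead))
      leads[which(r2v >= params$r2_lead)[1L]] else s
  }
  out <- ind_sig[snp_id %in% leads][order_snps(ind_sig[snp_id %in% leads])]
  out <- out[, .(snp_id, chrom, pos, p)]
  out[, members := lapply(snp_id, function(l) names(assigned)[assigned == l])]
  out[]
}

#' Define genomic risk loci by merging LD blocks
#'
#' Each independent significant SNP spans an LD block: the minimum and
#' maximum position over its candidate SNPs (r2 >= `r2_ind`, itself
#' included).  Blocks on one chromosome are merged left-to-right while the
#' gap between consecutive blocks is strictly less than `merge_kb` kb.
#' Loci are numbered in genome order; every candidate SNP is assigned to
#' the locus of its `nearest_ind_sig`.
#'
#' @inheritParams collect_candidates
#' @param candidates output of [collect_candidates()].
#' @param leads output of [select_lead()].
#' @return list with `loci` (one row per locus: `locus_id`, `chrom`,
#'   `start`, `end`, `top_snp`, `top_p`, `n_ind_sig`, `n_lead`,
#'   `n_candidates`, list-columns `ind_sig_snps`, `lead_snps`) and
#'   `candidates` (input with a `locus_id` column).
#' @export
define_loci <- function(ind_sig, candidates, leads,
                        params = default_params()) {
  empty <- list(
    loci = data.table::data.table(
      locus_id = integer(0), chrom = character(0), start = integer(0),
      end = integer(0), top_snp = character(0), top_p = numeric(0),
      n_ind_sig = integer(0), n_lead = integer(0), n_candidates = integer(0),
      ind_sig_snps = list(), lead_snps = list()),
    candidates = data.table::copy(candidates)[, locus_id := integer(0)[seq_len(.N)]]
  )
  if (nrow(ind_sig) == 0L) return(empty)
  pairs <- attr(candidates, "pairs")
  pairs <- pairs[snp_id %in% candidates$snp_id]
  blocks <- pairs[, .(start = min(pos), end = max(pos),
                      chrom = chrom[1L]), by = ind_snp]
  blocks <- blocks[order(chrom_rank(chrom), start, end)]
  # transitive left-to-right merge within chromosome: strict < on the gap
  gap_max <- params$merge_kb * 1000
  blocks[, grp := {
    g <- integer(.N); cur <- 1L; g[1L] <- 1L
    if (.N > 1L) {
      right <- end[1L]
      for (i in 2:.N) {
        if (start[i] - right < gap_max) {
          g[i] <- cur
        } else {
          cur <- cur + 1L; g[i] <- cur
        }
        right <- max(right, end[i])
      }
    }
    g
  }, by = chrom]
  loci <- blocks[, .(start = min(start), end = max(end),
                     ind_sig_snps = list(ind_snp)), by = .(chrom, grp)]
  loci <- loci[order(chrom_rank(chrom), start)]
  loci[, locus_id := seq_len(.N)]
  # candidate -> locus through its nearest independent significant SNP
  locus_of_ind <- stats::setNames(
    rep(loci$locus_id, lengths(loci$ind_sig_snps)),
    unlist(loci$ind_sig_snps))
  cand <- data.table::copy(candidates)
  cand[, locus_id := unname(locus_of_ind[nearest_ind_sig])]
  lead_ids <- leads$snp_id
  loci[, lead_snps := lapply(ind_sig_snps, function(m) intersect(lead_ids, m))]
  top <- cand[!is.na(p)][order(p, snp_id), .SD[1L], by = locus_id]
  loci[, top_snp := top$snp_id[match(locus_id, top$locus_id)]]
  loci[, top_p := top$p[match(locus_id, top$locus_id)]]
  loci[, n_ind_sig := lengths(ind_sig_snps)]
  loci[, n_lead := lengths(lead_snps)]
  nc <- cand[, .N, by = locus_id]
  loci[, n_candidates := nc$N[match(locus_id, nc$locus_id)]]
  loci[is.na(n_candidates), n_candidates := 0L]
  list(loci = loci[, .(locus_id, chrom, start, end, top_snp, top_p,
                       n_ind_sig, n_lead, n_candidates,
                       ind_sig_snps, lead_snps)],
       candidates = cand)
}

#' Characterize genomic risk loci (full step)
#'
#' Orchestrates [select_independent_significant()],
#' [collect_candidates()], [select_lead()] and [define_loci()].
#' Pre-defined lead SNPs are forced into the independent-significant and
#' lead sets before greedy selection; a warning is issued for forced SNPs
#' that are not genome-wide significant in the input.  Pre-defined regions
#' restrict the summary statistics and candidates, and locus spans are
#' clipped to the regions.
#'
#' @inheritParams select_independent_significant
#' @param predefined_leads optional character vector of SNP ids (must exist
#'   in the panel).
#' @param regions optional `data.table` with `chrom`, `start`, `end`
#'   (1-based closed) restricting all annotation.
#' @return list with `ind_sig`, `leads`, `candidates`, `loci`, `params`.
#' @export
characterize_loci <- function(sumstats, panel, ld, params = default_params(),
                              predefined_leads = NULL, regions = NULL) {
  if (!is.null(regions)) {
    regions <- data.table::as.data.table(regions)
    regions[, chrom := norm_chrom(chrom)]
    sumstats <- sumstats[in_regions(sumstats$chrom, sumstats$pos, regions)]
  }
  forced <- NULL
  if (!is.null(predefined_leads) && length(predefined_leads)) {
    forced <- as.character(predefined_leads)
    absent <- setdiff(forced, panel$snp_id)
    if (length(absent)) {
      stop("pre-defined lead SNP(s) absent from the reference panel: ",
           paste(absent, collapse = ", "))
    }
    pvals <- sumstats$p[match(forced, sumstats$snp_id)]
    weak <- forced[is.na(pvals) | pvals >= params$p_sig]
    if (length(weak)) {
      warning("forced lead SNP(s) without genome-wide significance: ",
              paste(weak, collapse = ", "))
    }
  }
  ind_sig <- select_independent_significant(sumstats, panel, ld, params,
                                            forced = forced)
  cand <- collect_candidates(ind_sig, panel, ld, sumstats, params)
  if (!is.null(regions) && nrow(cand)) {
    keep <- in_regions(cand$chrom, cand$pos, regions)
    pairs <- attr(cand, "pairs")
    cand <- cand[keep]
    data.table::setattr(cand, "pairs", pairs[snp_id %in% cand$snp_id])
    ind_sig <- ind_sig[snp_id %in% cand$snp_id]
  }
  leads <- select_lead(ind_sig, ld, params, forced = forced)
  dl <- define_loci(ind_sig, cand, leads, params)
  if (!is.null(regions) && nrow(dl$loci)) {
    dl$loci <- clip_to_regions(dl$loci, regions)
  }
  list(ind_sig = ind_sig, leads = leads, candidates = dl$candidates,
       loci = dl$loci, params = params)
}

in_regions <- function(chrom, pos, regions) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start, regions$end))
  pg_count_overlaps(q, s) > 0L
}

clip_to_regions <- function(loci, regions) {
  for (i in seq_len(nrow(loci))) {
    r <- regions[chrom == loci$chrom[i] &
                   start <= loci$end[i] & end >= loci$start[i]]
    if (nrow(r)) {
      loci$start[i] <- max(loci$start[i], min(r$start))
      loci$end[i] <- min(loci$end[i], max(r$end))
    }
  }
  loci
}
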