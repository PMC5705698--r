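## Deterministic, seeded generator of every input table with planted
## structure: k association blocks with a known causal SNP each, per-locus
## planted genes (one with a deleterious exonic SNP, one cis-eQTL target,
## one chromatin-interaction target), planted tissue DEG genes and planted
## gene sets, plus null SNPs, distractor genes and distractor sets carrying
## no qualifying evidence.  Everything is reproducible bit-for-bit from one
## integer seed.

#' Define a synthetic scenario
#'
#' The scenario fixes the geometry and effect structure of the synthetic
#' data.  Within a block, pairwise LD decays linearly with distance:
#' `r2(d) = max(0, 0.95 - d * r2_decay_rate)`; blocks are separated by more
#' than 1 Mb so no cross-block pair is stored (off-block r2 is 0).  Planted
#' causal p-values are below 5e-8; a fraction of non-causal block SNPs is
#' omitted from the summary statistics to exercise non-GWAS-tagged proxies.
#'
#' @param seed integer seed governing all randomness.
#' @param n_loci number of planted association blocks (0 gives a null-only
#'   scenario).
#' @param snps_per_block SNPs per block (default 15).
#' @param snp_spacing_bp within-block SNP spacing (default 5000).
#' @param block_gap_bp distance between consecutive block starts beyond the
#'   block span (default 1.2e6; keeps blocks > 1 Mb apart).
#' @param r2_decay_rate per-bp linear r2 decay (default 1e-6: the whole
#'   block stays above r2 = 0.6 with the causal SNP).
#' @param n_null_snps unassociated SNPs placed far from every block.
#' @param omit_frac fraction of non-causal block SNPs omitted from the
#'   summary statistics (default 0.1).
#' @param n_extra_genes background genes without any evidence, placed in a
#'   distal region (default 30).
#' @param n_tissues,samples_per_tissue expression design (default 4 x 20).
#' @param planted_lfc log2 fold change of planted tissue-specific genes
#'   (default 2.0; 0 plants no effect).
#' @param deg_tissue tissue receiving the planted expression shifts.
#' @param chrom chromosome label (single synthetic chromosome by default).
#' @param chrom_len chromosome length; the layout must fit inside it.
#' @return list of class `pg_scenario`.
#' @export
synth_scenario <- function(seed = 1L, n_loci = 3L, snps_per_block = 15L,
                           snp_spacing_bp = 5000L, block_gap_bp = 1.2e6,
                           r2_decay_rate = 1e-6, n_null_snps = 50L,
                           omit_frac = 0.1, n_extra_genes = 30L,
                           n_tissues = 4L, samples_per_tissue = 20L,
                           planted_lfc = 2.0, deg_tissue = "T1",
                           chrom = "1", chrom_len = 2.5e8) {
  span <- (snps_per_block - 1L) * snp_spacing_bp
  need <- 1e6 + n_loci * (span + block_gap_bp) + 2e6 +
    n_null_snps * 10000 + (n_extra_genes + 1) * 20000
  if (need > chrom_len) {
    stop("scenario geometry overflows the chromosome length (need ",
         format(need, big.mark = ","), " bp)")
  }
  structure(list(
    seed = as.integer(seed), n_loci = as.integer(n_loci),
    snps_per_block = as.integer(snps_per_block),
    snp_spacing_bp = as.integer(snp_spacing_bp),
    block_gap_bp = block_gap_bp, r2_decay_rate = r2_decay_rate,
    n_null_snps = as.integer(n_null_snps), omit_frac = omit_frac,
    n_extra_genes = as.integer(n_extra_genes),
    n_tissues = as.integer(n_tissues),
    samples_per_tissue = as.integer(samples_per_tissue),
    planted_lfc = planted_lfc, deg_tissue = deg_tissue,
    chrom = chrom, chrom_len = chrom_len,
    block_span = span
  ), class = "pg_scenario")
}

rand_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = unname(ref), alt = unname(alt))
}

#' Generate the reference side of a scenario
#'
#' Builds the panel, LD table, gene models, score tables, eQTLs,
#' interactions, epigenome region sets, catalog and intolerance scores,
#' together with the planted truth.  Per locus: one gene with an exonic
#' causal SNP assigned a CADD score above the deleteriousness threshold
#' (all other SNPs stay below it), one distal gene with a sub-FDR eQTL, and
#' one distal gene whose promoter overlaps one end of a significant
#' interaction whose other end covers the block SNPs.  Distractor records
#' (failing eQTL FDR, failing interaction FDR, low-MAF SNPs, ncRNA genes)
#' exercise every filter.
#'
#' @param scenario a `pg_scenario`.
#' @return list with all reference stores (`panel`, `ld`, `genes`, `cadd`,
#'   `rdb`, `chromhmm`, `eqtl`, `interactions`, `enhancers`, `promoters`,
#'   `catalog`, `intolerance`) and `truth` (planted structure).
#' @export
generate_reference <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  chrom <- sc$chrom
  m <- sc$snps_per_block
  causal_idx <- (m + 1L) %/% 2L

  snp <- list(); ldp <- list(); genes <- list(); eqtl <- list()
  ci <- list(); truth_loci <- list()
  block_starts <- if (sc$n_loci > 0)
    1e6 + (seq_len(sc$n_loci) - 1L) * (sc$block_span + sc$block_gap_bp) else
    numeric(0)

  for (b in seq_len(sc$n_loci)) {
    bs <- block_starts[b]
    pos <- as.integer(bs + (seq_len(m) - 1L) * sc$snp_spacing_bp)
    ids <- sprintf("rs%d%03d", b, seq_len(m))
    al <- rand_alleles(m)
    maf <- round(stats::runif(m, 0.05, 0.5), 4)
    # one low-frequency non-causal SNP per block to exercise the MAF filter
    low_i <- if (causal_idx > 1L) 1L else 2L
    maf[low_i] <- 0.005
    snp[[b]] <- data.table::data.table(
      snp_id = ids, chrom = chrom, pos = pos,
      ref_allele = al$ref, alt_allele = al$alt, maf = maf,
      block = b, causal = seq_len(m) == causal_idx)
    pr <- expand.grid(i = seq_len(m), j = seq_len(m))
    pr <- pr[pr$i < pr$j, ]
    d <- abs(pos[pr$i] - pos[pr$j])
    r2 <- pmax(0, 0.95 - d * sc$r2_decay_rate)
    keep <- r2 >= 0.05
    ldp[[b]] <- data.table::data.table(
      snp_a = ids[pr$i[keep]], snp_b = ids[pr$j[keep]],
      r2 = round(r2[keep], 6))

    cp <- pos[causal_idx]
    g_cod <- sprintf("GENE_L%d_CODING", b)
    g_eq <- sprintf("GENE_L%d_EQTL", b)
    g_ci <- sprintf("GENE_L%d_CI", b)
    ci_strand <- if (b %% 2L == 1L) "+" else "-"
    genes[[b]] <- data.table::data.table(
      gene_id = c(g_cod, g_eq, g_ci,
                  sprintf("GENE_L%d_DIST1", b), sprintf("GENE_L%d_NC", b)),
      symbol = c(sprintf("CODG%d", b), sprintf("EQTG%d", b),
                 sprintf("CITG%d", b), sprintf("DSTG%d", b),
                 sprintf("NCG%d", b)),
      gene_type = c("protein_coding", "protein_coding", "protein_coding",
                    "protein_coding", "ncRNA"),
      chrom = chrom,
      start = as.integer(c(cp - 20000, cp + 400000, cp + 700000,
                           cp + 800000, cp + 900000)),
      end = as.integer(c(cp + 20000, cp + 410000, cp + 710000,
                         cp + 805000, cp + 903000)),
      strand = c("+", "+", ci_strand, "+", "+"),
      exon_start = list(c(cp - 150L, cp + 2000L), cp + 400000L,
                        cp + 700000L, cp + 800000L, cp + 900000L),
      exon_end = list(c(cp + 150L, cp + 2400L), cp + 400800L,
                      cp + 700800L, cp + 800800L, cp + 900800L))

    # eQTLs: three block SNPs -> the eQTL target at FDR 0.01; one
    # distractor record failing the FDR filter
    eq_snps <- unique(pmin(m, c(causal_idx, causal_idx + 1L, causal_idx + 2L)))
    eqtl[[b]] <- data.table::data.table(
      chrom = chrom, pos = pos[eq_snps],
      effect_allele = al$alt[eq_snps], other_allele = al$ref[eq_snps],
      gene_id = g_eq, tissue = sc$deg_tissue,
      p = signif(stats::runif(length(eq_snps), 1e-8, 1e-6), 3), fdr = 0.01)
    eqtl[[b]] <- rbind(eqtl[[b]], data.table::data.table(
      chrom = chrom, pos = pos[causal_idx],
      effect_allele = al$alt[causal_idx], other_allele = al$ref[causal_idx],
      gene_id = sprintf("GENE_L%d_DIST1", b), tissue = sc$deg_tissue,
      p = 0.01, fdr = 0.5))

    # interactions (written 0-based half-open): end A covers the block,
    # end B covers the CI target promoter; one under-threshold distractor
    tssB <- if (ci_strand == "+") cp + 700000L else cp + 710000L
    ci[[b]] <- data.table::data.table(
      chrom_a = chrom, start_a = as.integer(bs - 1L),
      end_a = as.integer(bs + 40000L),
      chrom_b = chrom, start_b = as.integer(tssB - 2000L),
      end_b = as.integer(tssB + 2000L),
      tissue = sc$deg_tissue, fdr = 1e-8)
    ci[[b]] <- rbind(ci[[b]], data.table::data.table(
      chrom_a = chrom, start_a = as.integer(bs - 1L),
      end_a = as.integer(bs + 40000L),
      chrom_b = chrom,
      start_b = as.integer(cp + 800000L), end_b = as.integer(cp + 804000L),
      tissue = sc$deg_tissue, fdr = 1e-3))

    truth_loci[[b]] <- list(
      locus = b, causal_snp = ids[causal_idx], causal_pos = cp,
      block_start = pos[1L], block_end = pos[m],
      coding_target = g_cod, eqtl_target = g_eq, ci_target = g_ci)
  }

  # null SNPs far from every block
  tail_start <- if (sc$n_loci > 0)
    max(block_starts) + sc$block_span + 2e6 else 3e6
  if (sc$n_null_snps > 0) {
    pos0 <- as.integer(tail_start + (seq_len(sc$n_null_snps) - 1L) * 10000L)
    al0 <- rand_alleles(sc$n_null_snps)
    snp[[length(snp) + 1L]] <- data.table::data.table(
      snp_id = sprintf("rsN%04d", seq_len(sc$n_null_snps)), chrom = chrom,
      pos = pos0, ref_allele = al0$ref, alt_allele = al0$alt,
      maf = round(stats::runif(sc$n_null_snps, 0.05, 0.5), 4),
      block = 0L, causal = FALSE)
  }
  snps <- data.table::rbindlist(snp)
  panel <- snps[, .(snp_id, chrom, pos, ref_allele, alt_allele, maf)]

  # background genes without evidence, distal to everything
  extra_start <- tail_start + sc$n_null_snps * 10000 + 1e6
  extra <- data.table::data.table(
    gene_id = sprintf("GENE_BG%03d", seq_len(sc$n_extra_genes)),
    symbol = sprintf("BGG%03d", seq_len(sc$n_extra_genes)),
    gene_type = "protein_coding", chrom = chrom,
    start = as.integer(extra_start + (seq_len(sc$n_extra_genes) - 1L) * 20000L),
    end = as.integer(extra_start + (seq_len(sc$n_extra_genes) - 1L) * 20000L + 5000L),
    strand = rep(c("+", "-"), length.out = sc$n_extra_genes))
  extra[, exon_start := lapply(start, function(s) s)]
  extra[, exon_end := lapply(start, function(s) s + 800L)]
  gm <- if (length(genes)) rbind(data.table::rbindlist(genes), extra) else extra
  validate_gene_models(gm)

  # scores: the causal SNP is highly deleterious, everything else is not
  cadd <- data.table::data.table(
    chrom = chrom, pos = snps$pos, ref = snps$ref_allele,
    alt = snps$alt_allele,
    cadd = round(ifelse(snps$causal, stats::runif(nrow(snps), 15, 30),
                        stats::runif(nrow(snps), 0, 10)), 3))
  rdb_pool <- rdb_categories()
  rdb <- data.table::data.table(
    chrom = chrom, pos = snps$pos,
    rdb = ifelse(snps$causal, "1b",
                 sample(rdb_pool[7:15], nrow(snps), replace = TRUE)))
  chromhmm <- data.table::data.table()
  if (sc$n_loci > 0) {
    ch <- lapply(seq_len(sc$n_loci), function(b) {
      bs <- block_starts[b]
      bins <- seq(((bs - 1) %/% 200) * 200,
                  ((bs + sc$block_span) %/% 200) * 200, by = 200)
      causal_bin <- ((truth_loci[[b]]$causal_pos - 1) %/% 200) * 200
      data.table::rbindlist(lapply(c("E1", "E2"), function(e)
        data.table::data.table(
          chrom = chrom, bin_start = as.integer(bins), epigenome = e,
          state = ifelse(bins == causal_bin, 1L,
                         sample(2:15, length(bins), replace = TRUE)))))
    })
    chromhmm <- data.table::rbindlist(ch)
  }

  enhancers <- if (sc$n_loci > 0) data.table::data.table(
    chrom = chrom, start = as.integer(block_starts),
    end = as.integer(block_starts + 40000L),
    kind = "enhancer", epigenome = "E1") else
    data.table::data.table(chrom = character(0), start = integer(0),
                           end = integer(0), kind = character(0),
                           epigenome = character(0))
  prom_iv <- promoter_intervals(gm)
  promoters <- data.table::data.table(
    chrom = prom_iv$chrom, start = prom_iv$start, end = prom_iv$end,
    kind = "promoter", epigenome = "E1")

  catalog <- if (sc$n_loci > 0) data.table::data.table(
    chrom = chrom,
    pos = vapply(truth_loci, function(t) t$causal_pos, numeric(1)),
    trait = sprintf("synthetic trait %d", seq_len(sc$n_loci)),
    reported_p = 1e-9) else
    data.table::data.table(chrom = character(0), pos = integer(0),
                           trait = character(0), reported_p = numeric(0))

  intolerance <- data.table::data.table(
    gene_id = gm$gene_id,
    pli = round(stats::runif(nrow(gm)), 3),
    ncrvis = round(stats::rnorm(nrow(gm)), 3))

  ld_tab <- if (length(ldp)) data.table::rbindlist(ldp) else
    data.table::data.table(snp_a = character(0), snp_b = character(0),
                           r2 = numeric(0))
  list(panel = panel, ld = ld_store(ld_tab), genes = gm, cadd = cadd,
       rdb = rdb, chromhmm = chromhmm,
       eqtl = if (length(eqtl)) data.table::rbindlist(eqtl) else
         data.table::data.table(chrom = character(0), pos = integer(0),
                                effect_allele = character(0),
                                other_allele = character(0),
                                gene_id = character(0), tissue = character(0),
                                p = numeric(0), fdr = numeric(0)),
       interactions = if (length(ci)) {
         x <- data.table::rbindlist(ci)
         a <- bed_to_internal(x$start_a, x$end_a)
         b2 <- bed_to_internal(x$start_b, x$end_b)
         data.table::data.table(chrom_a = x$chrom_a, start_a = a$start,
                                end_a = a$end, chrom_b = x$chrom_b,
                                start_b = b2$start, end_b = b2$end,
                                tissue = x$tissue, fdr = x$fdr)
       } else data.table::data.table(chrom_a = character(0), start_a = integer(0),
                                     end_a = integer(0), chrom_b = character(0),
                                     start_b = integer(0), end_b = integer(0),
                                     tissue = character(0), fdr = numeric(0)),
       enhancers = enhancers, promoters = promoters, catalog = catalog,
       intolerance = intolerance,
       truth = list(seed = sc$seed, n_loci = sc$n_loci, loci = truth_loci,
                    snps = snps))
}

#' Generate GWAS summary statistics for a scenario
#'
#' Planted causal SNPs receive a genome-wide significant p (drawn between
#' 1e-12 and about 3e-10); block neighbors are interpolated toward the null
#' in proportion to their r2 with the causal SNP (always strictly weaker
#' than the causal SNP); null SNPs draw p from Uniform(0,1).  A fraction
#' `omit_frac` of non-causal block SNPs is omitted from the output so the
#' locus stage sees non-GWAS-tagged proxies.
#'
#' @param scenario a `pg_scenario`.
#' @param ref output of [generate_reference()].
#' @return summary-statistics `data.table` (same shape as
#'   [read_sumstats()]).
#' @export
generate_sumstats <- function(scenario, ref) {
  sc <- scenario
  set.seed(sc$seed + 1L)
  snps <- ref$truth$snps
  x <- data.table::copy(snps)
  x[, lp := NA_real_]
  for (b in seq_len(sc$n_loci)) {
    bi <- which(x$block == b)
    ci_ <- bi[x$causal[bi]]
    lp_causal <- stats::runif(1, 9.5, 12)
    d <- abs(x$pos[bi] - x$pos[ci_])
    r2 <- pmax(0, 0.95 - d * sc$r2_decay_rate)
    x$lp[bi] <- lp_causal * r2 * 0.85
    x$lp[ci_] <- lp_causal
  }
  x[block == 0L, lp := -log10(stats::runif(.N))]
  x[, p := 10^(-lp)]
  # omit a fraction of non-causal block SNPs from the GWAS input
  omit <- x$block > 0L & !x$causal &
    stats::runif(nrow(x)) < sc$omit_frac
  x <- x[!omit]
  out <- data.table::data.table(
    snp_id = x$snp_id, chrom = x$chrom, pos = x$pos,
    effect_allele = x$alt_allele, other_allele = x$ref_allele,
    p = signif(x$p, 6),
    beta = round(stats::rnorm(nrow(x), 0, 0.05), 4),
    se = round(stats::runif(nrow(x), 0.01, 0.05), 4),
    n = 100000L)
  out[]
}

#' Generate the expression side of a scenario
#'
#' Per-sample baseline log2 expression is i.i.d. Normal(mean 2, sd 0.5);
#' each planted tissue-specific gene (the per-locus eQTL target by
#' default) is shifted by `planted_lfc` in `deg_tissue`.  RPKM is
#' recovered as `2^x - 1` clipped at 0.  Gene-set collections contain the
#' planted gene groups plus random distractor sets.
#'
#' @param scenario a `pg_scenario`.
#' @param ref output of [generate_reference()].
#' @return list with `expr` (`pg_expr`), `genesets` (named list of
#'   `pg_genesets`) and `deg_truth` (planted gene/tissue/lfc table).
#' @export
generate_expression <- function(scenario, ref) {
  sc <- scenario
  set.seed(sc$seed + 2L)
  genes <- ref$genes$gene_id
  tissues <- sprintf("T%d", seq_len(sc$n_tissues))
  samples <- as.vector(vapply(tissues, function(tt)
    sprintf("%s_S%02d", tt, seq_len(sc$samples_per_tissue)),
    character(sc$samples_per_tissue)))
  tissue_of <- stats::setNames(rep(tissues, each = sc$samples_per_tissue),
                               samples)
  X <- matrix(stats::rnorm(length(genes) * length(samples), 2, 0.5),
              nrow = length(genes),
              dimnames = list(genes, samples))
  deg_genes <- vapply(ref$truth$loci, function(t) t$eqtl_target, character(1))
  deg_truth <- data.table::data.table(gene_id = deg_genes,
                                      tissue = sc$deg_tissue,
                                      lfc = sc$planted_lfc)
  target_cols <- which(tissue_of == sc$deg_tissue)
  for (g in deg_genes) {
    X[g, target_cols] <- X[g, target_cols] + sc$planted_lfc
  }
  rpkm <- pmax(2^X - 1, 0)
  expr <- structure(list(mat = rpkm, tissue_of = tissue_of),
                    class = "pg_expr")

  sets <- list()
  if (length(deg_genes)) {
    sets[["PLANTED_EQTL_TARGETS"]] <- deg_genes
    sets[["PLANTED_CODING_TARGETS"]] <-
      vapply(ref$truth$loci, function(t) t$coding_target, character(1))
    sets[["PLANTED_ALL"]] <- unique(unlist(lapply(ref$truth$loci, function(t)
      c(t$coding_target, t$eqtl_target, t$ci_target))))
  }
  for (i in 1:5) {
    sets[[sprintf("DISTRACTOR_%d", i)]] <-
      sample(genes, min(5L, length(genes)))
  }
  gs <- structure(list(source_label = "synthetic_sets", sets = sets,
                       descriptions = stats::setNames(
                         rep("synthetic gene set", length(sets)),
                         names(sets))),
                  class = "pg_genesets")
  list(expr = expr, genesets = list(synthetic_sets = gs),
       deg_truth = deg_truth)
}

#' Write a complete synthetic input directory
#'
#' Generates the reference, summary statistics and expression for the
#' scenario and writes every table in its on-disk format, together with a
#' machine-readable manifest of the planted truth (`manifest.json`) and a
#' ready-to-run pipeline configuration (`config.yaml`).  Re-running with
#' the same scenario produces byte-identical files.
#'
#' @param scenario a `pg_scenario`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(scenario)
  ss <- generate_sumstats(scenario, ref)
  ex <- generate_expression(scenario, ref)
  fp <- function(f) file.path(dir, f)
  write_sumstats(ss, fp("sumstats.txt"))
  write_panel(ref$panel, fp("panel.txt"))
  write_ld(ref$ld, fp("ld.txt"))
  write_gene_models(ref$genes, fp("gene_models.txt"))
  data.table::fwrite(ref$cadd, fp("cadd.txt"), sep = "\t", quote = FALSE)
  data.table::fwrite(ref$rdb, fp("rdb.txt"), sep = "\t", quote = FALSE)
  data.table::fwrite(ref$chromhmm, fp("chromhmm.txt"), sep = "\t", quote = FALSE)
  data.table::fwrite(ref$eqtl, fp("eqtl.txt"), sep = "\t", quote = FALSE)
  write_interactions(ref$interactions, fp("interactions.txt"))
  write_region_bed(ref$enhancers, fp("enhancer.E1.bed"))
  write_region_bed(ref$promoters, fp("promoter.E1.bed"))
  write_expression(ex$expr, fp("expression.txt"), fp("sample_tissues.txt"))
  write_gmt(ex$genesets$synthetic_sets, fp("genesets.gmt"))
  data.table::fwrite(ref$catalog, fp("catalog.txt"), sep = "\t", quote = FALSE)
  data.table::fwrite(ref$intolerance, fp("intolerance.txt"), sep = "\t",
                     quote = FALSE)

  manifest <- list(
    seed = scenario$seed, n_loci = scenario$n_loci,
    deg_tissue = scenario$deg_tissue, planted_lfc = scenario$planted_lfc,
    loci = lapply(ref$truth$loci, function(t) t[
      c("locus", "causal_snp", "causal_pos", "block_start", "block_end",
        "coding_target", "eqtl_target", "ci_target")]),
    deg_genes = ex$deg_truth$gene_id,
    planted_sets = grep("^PLANTED", names(ex$genesets$synthetic_sets$sets),
                        value = TRUE))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  config <- list(
    inputs = list(
      sumstats = "sumstats.txt", panel = "panel.txt", ld = "ld.txt",
      genes = "gene_models.txt", cadd = "cadd.txt", rdb = "rdb.txt",
      chromhmm = "chromhmm.txt", eqtl = "eqtl.txt",
      interactions = "interactions.txt",
      enhancers = list(E1 = "enhancer.E1.bed"),
      promoters = list(E1 = "promoter.E1.bed"),
      expression = "expression.txt", tissue_map = "sample_tissues.txt",
      genesets = list(synthetic_sets = "genesets.gmt"),
      catalog = "catalog.txt", intolerance = "intolerance.txt"),
    params = list(cadd_min = 12.37),
    eqtl_tissues = list(scenario$deg_tissue),
    ci_tissues = list(scenario$deg_tissue),
    epigenomes = list("E1"),
    strategies = list(
      positional = list(enabled = TRUE, mode = "consequence",
                        allowed_consequences = list("exonic", "splicing"),
                        cadd_min = 12.37),
      eqtl = list(enabled = TRUE),
      chromatin = list(enabled = TRUE, use_enhancer_filter = FALSE,
                       use_promoter_filter = FALSE)),
    gene_types = list("protein_coding"))
  yaml::write_yaml(config, fp("config.yaml"))
  invisible(dir)
}
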