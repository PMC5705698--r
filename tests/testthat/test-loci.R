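# Locus characterization: greedy clumping, candidate collection, lead
# selection, block merging and predefined inputs.

params <- default_params()

test_that("greedy clumping follows the ascending-p shadowing rule", {
  ss <- mk_sumstats(c("A", "B", "C"), c(1e5, 2e5, 3e5),
                    c(1e-10, 1e-9, 1e-8))
  panel <- mk_panel(c("A", "B", "C"), c(1e5, 2e5, 3e5))
  # B shadowed by A; C nearly uncorrelated with both
  ld <- mk_ld(c("A", "A", "B"), c("B", "C", "C"), c(0.7, 0.04, 0.04))
  sel <- select_independent_significant(ss, panel, ld, params)
  expect_equal(sel$snp_id, c("A", "C"))
  expect_equal(sel$rank, c(1L, 2L))

  # chain: B blocked by A, C independent of A though correlated with B
  ld2 <- mk_ld(c("A", "B", "A"), c("B", "C", "C"), c(0.7, 0.7, 0.1))
  sel2 <- select_independent_significant(ss, panel, ld2, params)
  expect_equal(sel2$snp_id, c("A", "C"))

  # nothing genome-wide significant
  ss3 <- mk_sumstats(c("A", "B"), c(1e5, 2e5), c(1e-7, 0.5))
  expect_equal(nrow(select_independent_significant(ss3, panel, ld, params)), 0L)

  expect_error(select_independent_significant(ss, panel[0], ld, params),
               "empty")
})

test_that("SNPs absent from the panel are excluded from clumping with a note", {
  ss <- mk_sumstats(c("A", "Z"), c(1e5, 2e5), c(1e-10, 1e-9))
  panel <- mk_panel("A", 1e5)
  expect_message(
    sel <- select_independent_significant(ss, panel, empty_ld(), params),
    "absent from the reference panel")
  expect_equal(sel$snp_id, "A")
})

test_that("candidate collection includes proxies, applies the MAF filter and records nearest tags", {
  ss <- mk_sumstats("A", 1e5, 1e-10)
  panel <- mk_panel(c("A", "P1", "P2", "P3"), c(1e5, 1.1e5, 1.2e5, 1.3e5),
                    maf = c(0.3, 0.3, 0.005, 0.3))
  ld <- mk_ld(c("A", "A", "A"), c("P1", "P2", "P3"), c(0.65, 0.65, 0.5))
  sel <- select_independent_significant(ss, panel, ld, params)
  cand <- collect_candidates(sel, panel, ld, ss, params)
  # P1: proxy absent from the GWAS input, flagged; P2: fails MAF;
  # P3: below the r2 threshold; A: itself with self-LD 1
  expect_setequal(cand$snp_id, c("A", "P1"))
  expect_true(cand[snp_id == "P1", non_gwas_tagged])
  expect_true(is.na(cand[snp_id == "P1", p]))
  expect_equal(cand[snp_id == "A", best_r2], 1)
  expect_false(cand[snp_id == "A", non_gwas_tagged])
})

test_that("the MAF filter never removes an independent significant SNP", {
  ss <- mk_sumstats("A", 1e5, 1e-10)
  panel <- mk_panel("A", 1e5, maf = 0.002)
  sel <- select_independent_significant(ss, panel, empty_ld(), params)
  cand <- collect_candidates(sel, panel, empty_ld(), ss, params)
  expect_equal(cand$snp_id, "A")
})

test_that("nearest tag ties resolve to the smaller p", {
  ss <- mk_sumstats(c("A", "B"), c(1e5, 9e5), c(1e-9, 1e-10))
  panel <- mk_panel(c("A", "B", "P"), c(1e5, 9e5, 5e5))
  ld <- mk_ld(c("A", "B", "A"), c("P", "P", "B"), c(0.8, 0.8, 0.05))
  sel <- select_independent_significant(ss, panel, ld, params)
  cand <- collect_candidates(sel, panel, ld, ss, params)
  expect_equal(cand[snp_id == "P", nearest_ind_sig], "B")
})

test_that("lead selection and member assignment follow the r2 < 0.1 rule", {
  ss <- mk_sumstats(c("A", "C"), c(1e5, 3e5), c(1e-10, 1e-8))
  panel <- mk_panel(c("A", "C"), c(1e5, 3e5))
  ld_corr <- mk_ld("A", "C", 0.3)
  sel <- select_independent_significant(ss, panel, ld_corr, params)
  leads <- select_lead(sel, ld_corr, params)
  expect_equal(leads$snp_id, "A")
  expect_setequal(leads$members[[1]], c("A", "C"))

  ld_free <- mk_ld("A", "C", 0.05)
  leads2 <- select_lead(sel, ld_free, params)
  expect_setequal(leads2$snp_id, c("A", "C"))

  single <- select_lead(sel[1], ld_corr, params)
  expect_equal(single$snp_id, "A")
  expect_equal(single$members[[1]], "A")
})

test_that("LD blocks merge on gaps strictly below 250 kb", {
  mk_two_block <- function(gap_bp) {
    # block 1 candidates span [1.0, 1.2] Mb; block 2 starts after the gap
    b2 <- 1.2e6 + gap_bp
    ss <- mk_sumstats(c("A", "B"), c(1.1e6, b2 + 5e4), c(1e-10, 1e-9))
    panel <- mk_panel(c("A", "A1", "A2", "B", "B1", "B2"),
                      c(1.1e6, 1.0e6, 1.2e6, b2 + 5e4, b2, b2 + 1e5))
    ld <- mk_ld(c("A", "A", "B", "B"), c("A1", "A2", "B1", "B2"),
                rep(0.8, 4))
    characterize_loci(ss, panel, ld, params)
  }
  merged <- mk_two_block(150000)        # gap 150 kb < 250 kb
  expect_equal(nrow(merged$loci), 1L)
  expect_equal(merged$loci$start, 1.0e6)
  expect_equal(merged$loci$end, 1.2e6 + 150000 + 1e5)

  split <- mk_two_block(300000)         # gap 300 kb
  expect_equal(nrow(split$loci), 2L)

  # strict boundary: 249,999 merges, 250,000 does not
  expect_equal(nrow(mk_two_block(249999)$loci), 1L)
  expect_equal(nrow(mk_two_block(250000)$loci), 2L)
})

test_that("loci are numbered in genome order and candidates partition by locus", {
  sc <- synth_scenario(seed = 21, n_loci = 3)
  ref <- generate_reference(sc)
  ss <- generate_sumstats(sc, ref)
  ch <- characterize_loci(ss, ref$panel, ref$ld, params)
  expect_equal(ch$loci$locus_id, seq_len(nrow(ch$loci)))
  expect_true(all(diff(ch$loci$start) > 0))
  # pairwise disjoint spans with gaps >= merge distance
  gaps <- ch$loci$start[-1] - ch$loci$end[-nrow(ch$loci)]
  expect_true(all(gaps >= params$merge_kb * 1000))
  # every candidate belongs to exactly one locus
  expect_false(anyNA(ch$candidates$locus_id))
  expect_equal(nrow(ch$candidates),
               sum(ch$loci$n_candidates))
  # top SNP per locus attains the locus minimum p
  for (i in seq_len(nrow(ch$loci))) {
    members <- ch$candidates[locus_id == ch$loci$locus_id[i] & !is.na(p)]
    expect_equal(ch$loci$top_p[i], min(members$p))
  }
})

test_that("coverage: every excluded significant SNP is tagged by a selected one", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    ids <- sprintf("s%02d", seq_len(n))
    p <- stats::setNames(10^(-stats::runif(n, 8, 12)), ids)
    m <- random_r2_matrix(ids)
    fx <- fixture_from_matrix(p, m)
    sel <- select_independent_significant(fx$sumstats, fx$panel, fx$ld, params)
    excluded <- setdiff(ids, sel$snp_id)
    for (e in excluded) {
      expect_true(any(m[e, sel$snp_id] >= params$r2_ind))
    }
    leads <- select_lead(sel, fx$ld, params)
    for (e in setdiff(sel$snp_id, leads$snp_id)) {
      expect_true(any(m[e, leads$snp_id] >= params$r2_lead))
    }
  }
})

test_that("greedy selection matches the exhaustive oracle on random matrices", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    ids <- sprintf("s%02d", seq_len(n))
    p <- stats::setNames(10^(-stats::runif(n, 8, 12)), ids)
    m <- random_r2_matrix(ids)
    fx <- fixture_from_matrix(p, m)
    sel <- select_independent_significant(fx$sumstats, fx$panel, fx$ld, params)
    expect_identical(sel$snp_id, oracle_clump(p, m, params$r2_ind))
    leads <- select_lead(sel, fx$ld, params)
    psub <- p[sel$snp_id]
    expect_identical(sort(leads$snp_id),
                     sort(oracle_clump(psub, m[sel$snp_id, sel$snp_id,
                                               drop = FALSE],
                                       params$r2_lead)))
  }
})

test_that("stricter p_sig and looser r2_ind are monotone in the selection count", {
  set.seed(7)
  ids <- sprintf("s%02d", 1:10)
  p <- stats::setNames(10^(-stats::runif(10, 6, 12)), ids)
  m <- random_r2_matrix(ids)
  fx <- fixture_from_matrix(p, m)
  n_at <- function(p_sig, r2_ind) {
    nrow(select_independent_significant(
      fx$sumstats, fx$panel, fx$ld,
      default_params(p_sig = p_sig, r2_ind = r2_ind)))
  }
  expect_lte(n_at(5e-9, 0.6), n_at(5e-8, 0.6))
  expect_lte(n_at(5e-10, 0.6), n_at(5e-9, 0.6))
  expect_gte(n_at(5e-8, 0.8), n_at(5e-8, 0.6))
  expect_gte(n_at(5e-8, 0.6), n_at(5e-8, 0.3))
})

test_that("predefined leads are forced and predefined regions restrict loci", {
  sc <- synth_scenario(seed = 5, n_loci = 2)
  ref <- generate_reference(sc)
  ss <- generate_sumstats(sc, ref)
  base <- characterize_loci(ss, ref$panel, ref$ld, params)
  # forcing the greedy top SNP is a no-op
  top <- base$ind_sig$snp_id[1]
  forced <- characterize_loci(ss, ref$panel, ref$ld, params,
                              predefined_leads = top)
  expect_equal(forced$loci[, .(chrom, start, end, top_snp)],
               base$loci[, .(chrom, start, end, top_snp)])
  expect_setequal(forced$leads$snp_id, base$leads$snp_id)

  # a weak SNP is still forced, with a warning
  weak <- ss[p > 0.4][1, snp_id]
  expect_warning(
    fw <- characterize_loci(ss, ref$panel, ref$ld, params,
                            predefined_leads = weak),
    "without genome-wide significance")
  expect_true(weak %in% fw$ind_sig$snp_id)
  expect_true(weak %in% fw$leads$snp_id)

  # absent from the panel: error naming the SNP
  expect_error(characterize_loci(ss, ref$panel, ref$ld, params,
                                 predefined_leads = "rsNOPE"),
               "rsNOPE")

  # region covering no significant SNP -> zero loci
  empty_region <- data.table::data.table(chrom = "1", start = 1L, end = 2L)
  er <- characterize_loci(ss, ref$panel, ref$ld, params,
                          regions = empty_region)
  expect_equal(nrow(er$loci), 0L)

  # region covering only the first block -> one locus
  b1 <- base$loci[1]
  one_region <- data.table::data.table(chrom = b1$chrom,
                                       start = b1$start - 1e4,
                                       end = b1$end + 1e4)
  or <- characterize_loci(ss, ref$panel, ref$ld, params,
                          regions = one_region)
  expect_equal(nrow(or$loci), 1L)
  expect_equal(or$loci$top_snp, b1$top_snp)
})
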