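# Expression summaries, DEG construction, hypergeometric enrichment and
# multiple-testing behavior.

test_that("expression filtering keeps genes reaching the floor in one tissue", {
  m <- matrix(c(0.2, 0.2, 1.3, 1.3, 0.0, 0.0,   # kept: tissue B mean 1.3
                0, 0, 0, 0, 0, 0,                # dropped: all zero
                1.0, 1.0, 0.5, 0.5, 0.2, 0.2),   # kept: boundary mean 1.0
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:6)))
  expr <- mk_expr(m, rep(c("A", "B", "C"), each = 2))
  expect_setequal(filter_expressed(expr, 1), c("gA", "gC"))
})

test_that("expression summaries winsorize, log and center as documented", {
  m <- matrix(c(100, 100, 0, 0,
                3, 3, 3, 3),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("gHi", "gFlat"), paste0("s", 1:4)))
  expr <- mk_expr(m, rep(c("A", "B"), each = 2))
  s <- summarize_expression(expr, winsor_cap = 50)
  # RPKM 100 winsorized to 50: log2(51)
  expect_equal(s[gene_id == "gHi" & tissue == "A", mean_log], log2(51))
  expect_equal(s[gene_id == "gHi" & tissue == "B", mean_log], 0)
  # identical means across tissues center to zero everywhere
  expect_equal(s[gene_id == "gFlat", norm_log], c(0, 0))
  # per-gene centering sums to zero
  sums <- s[, .(z = sum(norm_log)), by = gene_id]
  expect_true(all(abs(sums$z) < 1e-9))
  # mean_log bounded by the winsor cap
  expect_true(all(s$mean_log <= log2(51)))
})

test_that("DEG statistics match the pooled t-test oracle to 1e-10", {
  set.seed(202)
  expr <- mk_tissue_mat(50, 5, c("T1", "T2", "T3", "T4"))
  deg <- build_deg_sets(expr)
  X <- log2(expr$mat + 1)
  n_checked <- 0L
  for (i in sample(nrow(deg$stats), 100)) {
    g <- deg$stats$gene_id[i]; tt <- deg$stats$tissue[i]
    in_t <- expr$tissue_of == tt
    ref <- stats::t.test(X[g, in_t], X[g, !in_t], var.equal = TRUE)
    expect_equal(deg$stats$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(deg$stats$df[i], unname(ref$parameter))
    expect_equal(deg$stats$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(deg$stats$lfc[i],
                 unname(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-10)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 100L)
  # Bonferroni over all tests performed
  expect_equal(deg$stats$adj_p, pmin(1, deg$stats$p * nrow(deg$stats)))
})

test_that("DEG membership enforces corrected p, lfc and sign rules", {
  set.seed(7)
  tissues <- rep(c("A", "B"), each = 10)
  m <- matrix(2^stats::rnorm(3 * 20, 2, 0.1) - 1, nrow = 3,
              dimnames = list(c("up_gene", "null_gene", "small_lfc"),
                              paste0("s", 1:20)))
  X <- log2(m + 1)
  # strong planted shift in tissue A for up_gene, 0.5-lfc for small_lfc
  X["up_gene", tissues == "A"] <- X["up_gene", tissues == "A"] + 2
  X["small_lfc", tissues == "A"] <- X["small_lfc", tissues == "A"] + 0.5
  expr <- mk_expr(pmax(2^X - 1, 0), tissues)
  deg <- build_deg_sets(expr)
  expect_true("up_gene" %in% deg$up$A)
  expect_true("up_gene" %in% deg$down$B)
  expect_false("null_gene" %in% unlist(deg$twoside))
  # tiny p but |lfc| < 0.58: excluded
  expect_lt(deg$stats[gene_id == "small_lfc" & tissue == "A", adj_p], 0.05)
  expect_false("small_lfc" %in% unlist(deg$twoside))
  # set algebra invariants
  for (tt in names(deg$up)) {
    expect_length(intersect(deg$up[[tt]], deg$down[[tt]]), 0)
    expect_setequal(deg$twoside[[tt]], union(deg$up[[tt]], deg$down[[tt]]))
  }
})

test_that("degenerate zero-variance groups are handled without NaN", {
  m <- matrix(c(rep(3, 4), rep(1, 4),
                rep(2, 8)), nrow = 2, byrow = TRUE,
              dimnames = list(c("g_sep", "g_const"), paste0("s", 1:8)))
  expr <- mk_expr(m, rep(c("A", "B"), each = 4))
  deg <- build_deg_sets(expr)
  expect_false(any(is.nan(deg$stats$p)))
  expect_equal(deg$stats[gene_id == "g_const", p], c(1, 1))
  expect_true(all(deg$stats[gene_id == "g_sep", p] <= 1e-300))
})

test_that("hypergeometric p-values match closed forms and enumeration", {
  expect_equal(hypergeom_pvalue(0, 5, 4, 10), 1)
  expect_equal(hypergeom_pvalue(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(5, 5, 5, 20), 1 / 15504, tolerance = 1e-12)
  # exhaustive enumeration for a compact grid
  for (N in c(5, 7, 9)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in max(0, n + K - N):min(n, K)) {
          en <- enum_hypergeom(k, K, n, N)
          expect_equal(hypergeom_pvalue(k, K, n, N),
                       en["count"] / en["total"],
                       tolerance = 1e-12, ignore_attr = TRUE)
        }
      }
    }
  }
  # monotone non-increasing in k
  p_seq <- hypergeom_pvalue(0:5, 8, 5, 20)
  expect_true(all(diff(p_seq) <= 0))
  expect_error(hypergeom_pvalue(6, 8, 5, 20), "k must")
  expect_error(hypergeom_pvalue(1, 25, 5, 20), "exceed")
})

test_that("enrichment adjusts per source and applies the report rules", {
  background <- sprintf("g%02d", 1:40)
  input <- background[1:8]
  gs1 <- structure(list(source_label = "src1", sets = list(
    hit = background[1:8],          # k = 8
    partial = background[7:16],     # k = 2
    single = background[c(1, 30:33)], # k = 1 but strong-ish
    miss = background[30:34]), descriptions = NULL),
    class = "pg_genesets")
  gs2 <- structure(list(source_label = "src2", sets = list(
    hit2 = background[1:8],
    m1 = background[21:25]), descriptions = NULL),
    class = "pg_genesets")
  res <- enrich_gene_sets(input, list(gs1, gs2), background)
  full <- res$full
  # per-source BH: identical raw p receives different adj_p across sources
  p_hit1 <- full[set_name == "hit", p]
  p_hit2 <- full[set_name == "hit2", p]
  expect_equal(p_hit1, p_hit2)
  expect_false(isTRUE(all.equal(full[set_name == "hit", adj_p],
                                full[set_name == "hit2", adj_p])))
  # BH oracle within each source
  for (src in c("src1", "src2")) {
    sub <- full[source_label == src]
    expect_equal(sub$adj_p, bh_oracle(sub$p))
  }
  # disjoint set: k = 0, p = 1, filtered from the report
  expect_equal(full[set_name == "miss", k], 0L)
  expect_equal(full[set_name == "miss", p], 1)
  expect_false("miss" %in% res$report$set_name)
  # k = 1 rows never reported regardless of adj_p
  expect_false("single" %in% res$report$set_name)
  expect_true(all(res$report$k >= 2))
  expect_true(all(res$report$adj_p >= res$report$p))
  expect_error(enrich_gene_sets(input, gs1, character(0)), "background")
})

test_that("genes outside the background are dropped before testing", {
  background <- sprintf("g%02d", 1:20)
  gs <- structure(list(source_label = "s", sets = list(A = background[1:5]),
                       descriptions = NULL), class = "pg_genesets")
  expect_message(
    res <- enrich_gene_sets(c(background[1:4], "alien1", "alien2"), gs,
                            background),
    "outside the background")
  expect_equal(res$full$n, 4L)
  expect_equal(res$full$N, 20L)
})

test_that("DEG enrichment attains its minimum p on the matching tissue", {
  set.seed(55)
  expr <- mk_tissue_mat(60, 8, c("T1", "T2", "T3"))
  X <- log2(expr$mat + 1)
  planted <- rownames(X)[1:6]
  X[planted, expr$tissue_of == "T2"] <- X[planted, expr$tissue_of == "T2"] + 2
  expr$mat <- pmax(2^X - 1, 0)
  deg <- build_deg_sets(expr)
  expect_setequal(deg$up$T2, planted)
  res <- enrich_deg(planted, deg, rownames(X))
  up <- res$full[source_label == "DEG_up"]
  expect_equal(up[which.min(p), set_name], "T2")
  # empty DEG sets are skipped, not tested
  expect_false(any(res$full$set_name %in%
                     names(Filter(function(s) !length(s), deg$up))))
})
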