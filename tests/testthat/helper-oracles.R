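# Independent first-principles oracles used to cross-check the package
# implementations.  These deliberately share no code with the package.

# Brute-force greedy clumping: visit SNPs in ascending p (ties by id),
# keep a SNP iff its r2 with every kept SNP is below thr.
oracle_clump <- function(p, r2mat, thr) {
  ids <- names(p)
  ord <- ids[order(p, ids)]
  kept <- character(0)
  for (s in ord) {
    if (!length(kept) || all(r2mat[s, kept] < thr)) kept <- c(kept, s)
  }
  kept
}

# Random symmetric r2 matrix with a point mass at zero
random_r2_matrix <- function(ids, zero_prob = 0.5) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- if (stats::runif(1) < zero_prob) 0 else stats::runif(1, 0.05, 1)
      m[i, j] <- m[j, i] <- v
    }
  }
  diag(m) <- 1
  m
}

# Build package-side stores from an r2 matrix and p-values
fixture_from_matrix <- function(p, r2mat, chrom = "1") {
  ids <- names(p)
  n <- length(ids)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (r2mat[i, j] >= 0.05) {
        pairs[[length(pairs) + 1L]] <- data.table::data.table(
          snp_a = ids[i], snp_b = ids[j], r2 = r2mat[i, j])
      }
    }
  }
  ld <- ld_store(if (length(pairs)) data.table::rbindlist(pairs) else
    data.table::data.table(snp_a = character(0), snp_b = character(0),
                           r2 = numeric(0)))
  panel <- data.table::data.table(
    snp_id = ids, chrom = chrom, pos = seq_len(n) * 1000L,
    ref_allele = "A", alt_allele = "G", maf = 0.3)
  sumstats <- data.table::data.table(
    snp_id = ids, chrom = chrom, pos = seq_len(n) * 1000L,
    effect_allele = "G", other_allele = "A", p = unname(p),
    beta = NA_real_, se = NA_real_, n = NA_integer_)
  list(panel = panel, ld = ld, sumstats = sumstats)
}

# Exhaustive hypergeometric upper tail by enumerating all n-subsets of a
# background of size N whose first K elements form the set; returns the
# integer count of subsets with overlap >= k and the total C(N, n).
enum_hypergeom <- function(k, K, n, N) {
  universe <- seq_len(N)
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  c(count = sum(overlap >= k), total = ncol(subsets))
}

# Brute-force Benjamini-Hochberg from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Union-find connected components over an edge list
components_of <- function(nodes, edges_a, edges_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(nodes, find, character(1))))
}
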