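## Reference-data layer: readers, writers and in-memory stores for every
## external table the pipeline consumes.  All coordinates are normalized here
## to a single internal convention: 1-based, fully-closed intervals, with
## chromosome labels stripped of any leading "chr".

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` (any case) so that mixed dialects
#' (`chr1` vs `1`) compare equal.
#'
#' @param x character or factor vector of chromosome labels.
#' @return character vector.
#' @export
norm_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

#' Convert 0-based half-open intervals to 1-based closed (and back)
#'
#' BED and BEDPE intervals are 0-based half-open; GWAS summary statistics and
#' GFF3 are 1-based closed.  These helpers are exact bijections on integer
#' intervals and are the only place the conversion happens.
#'
#' @param start,end integer vectors; for `bed_to_internal` the BED
#'   (0-based half-open) coordinates, for `internal_to_bed` the internal
#'   (1-based closed) ones.
#' @return a list with integer components `start` and `end` in the other
#'   convention.
#' @export
bed_to_internal <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @rdname bed_to_internal
#' @export
internal_to_bed <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

# fread wrapper with uniform error context
pg_fread <- function(path, ...) {
  if (!file.exists(path)) stop("input file not found: ", path)
  data.table::fread(path, header = TRUE, data.table = TRUE, ...)
}

# ---------------------------------------------------------------------------
# GWAS summary statistics

sumstat_synonyms <- list(
  snp_id        = c("snp_id", "snp", "rsid", "snpid", "markername", "marker", "id"),
  chrom         = c("chrom", "chr", "chromosome"),
  pos           = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "ea", "alt", "allele1"),
  other_allele  = c("other_allele", "a2", "oa", "nea", "ref", "allele2"),
  p             = c("p", "pval", "p_value", "pvalue", "p_bolt_lmm"),
  beta          = c("beta", "b", "effect"),
  se            = c("se", "stderr", "standard_error"),
  n             = c("n", "nobs", "samplesize", "sample_size")
)

resolve_column <- function(field, header, column_map) {
  if (!is.null(column_map) && field %in% names(column_map)) {
    cand <- column_map[[field]]
    if (!cand %in% header) {
      stop("configured column '", cand, "' for field '", field,
           "' not present in file header")
    }
    return(cand)
  }
  hit <- header[tolower(header) %in% sumstat_synonyms[[field]]]
  if (length(hit)) hit[1L] else NA_character_
}

#' Read GWAS summary statistics
#'
#' Reads a delimited summary-statistics file with a header line.  Columns are
#' resolved through `column_map` (canonical field -> file column name) or by
#' case-insensitive synonym matching (e.g. `rsID`, `CHR`, `BP`, `A1`, `A2`,
#' `P`).  Required fields are SNP id, chromosome, position, both alleles and
#' the p-value; `beta`, `se` and `n` are optional.
#'
#' Malformed rows (p outside (0,1], position below 1, empty or identical
#' alleles) are skipped with a message; their count is available as
#' `attr(x, "n_skipped")`.  Duplicate (chrom, pos, alleles) rows beyond the
#' first are likewise rejected and counted in `attr(x, "n_duplicates")`.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping canonical field
#'   names to file column names.
#' @param ... passed to [data.table::fread()] (e.g. `sep`).
#' @return a `data.table` with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `p`, `beta`, `se`, `n`.
#' @export
read_sumstats <- function(path, column_map = NULL, ...) {
  raw <- pg_fread(path, ...)
  header <- names(raw)
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "p")
  cols <- vapply(c(required, "beta", "se", "n"), resolve_column,
                 character(1), header = header, column_map = column_map)
  missing <- required[is.na(cols[required])]
  if (length(missing)) {
    stop("summary statistics are missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  x <- data.table::data.table(
    snp_id        = as.character(raw[[cols["snp_id"]]]),
    chrom         = norm_chrom(raw[[cols["chrom"]]]),
    pos           = as.integer(raw[[cols["pos"]]]),
    effect_allele = toupper(as.character(raw[[cols["effect_allele"]]])),
    other_allele  = toupper(as.character(raw[[cols["other_allele"]]])),
    p             = as.numeric(raw[[cols["p"]]])
  )
  x[, beta := if (!is.na(cols["beta"])) as.numeric(raw[[cols["beta"]]]) else NA_real_]
  x[, se   := if (!is.na(cols["se"]))   as.numeric(raw[[cols["se"]]])   else NA_real_]
  x[, n    := if (!is.na(cols["n"]))    as.integer(raw[[cols["n"]]])    else NA_integer_]

  ok <- !is.na(x$p) & x$p > 0 & x$p <= 1 &
    !is.na(x$pos) & x$pos >= 1L &
    nzchar(x$effect_allele) & nzchar(x$other_allele) &
    x$effect_allele != x$other_allele
  n_skipped <- sum(!ok)
  if (n_skipped) {
    message(n_skipped, " malformed summary-statistic row(s) skipped")
    x <- x[ok]
  }
  dup <- duplicated(x, by = c("chrom", "pos", "effect_allele", "other_allele"))
  n_dup <- sum(dup)
  if (n_dup) {
    message(n_dup, " duplicate (chrom,pos,alleles) row(s) rejected")
    x <- x[!dup]
  }
  data.table::setattr(x, "n_skipped", n_skipped)
  data.table::setattr(x, "n_duplicates", n_dup)
  x[]
}

#' Write summary statistics
#' @param x a sumstats `data.table` as returned by [read_sumstats()].
#' @param path output path (tab-separated, one header line).
#' @export
write_sumstats <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Reference panel

#' Read a reference-panel variant table
#'
#' Delimited table with columns `snp_id`, `chrom`, `pos`, `ref_allele`
#' (synonym `ref`), `alt_allele` (`alt`) and `maf`.  MAF must lie in
#' \[0, 0.5\] and (chrom, pos, ref, alt) must be unique.
#'
#' @param path file path.
#' @return `data.table` with the columns above.
#' @export
read_panel <- function(path) {
  raw <- pg_fread(path)
  nm <- tolower(names(raw))
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% nm) return(which(nm == cand)[1L])
    stop("panel file missing column: ", ..1)
  }
  x <- data.table::data.table(
    snp_id     = as.character(raw[[pick("snp_id", "snp", "rsid")]]),
    chrom      = norm_chrom(raw[[pick("chrom", "chr")]]),
    pos        = as.integer(raw[[pick("pos", "bp")]]),
    ref_allele = toupper(as.character(raw[[pick("ref_allele", "ref")]])),
    alt_allele = toupper(as.character(raw[[pick("alt_allele", "alt")]])),
    maf        = as.numeric(raw[[pick("maf")]])
  )
  if (any(is.na(x$maf) | x$maf < 0 | x$maf > 0.5)) {
    stop("panel MAF values must lie in [0, 0.5]")
  }
  if (anyDuplicated(x, by = c("chrom", "pos", "ref_allele", "alt_allele"))) {
    stop("panel contains duplicate (chrom,pos,ref,alt) variants")
  }
  x[]
}

#' @rdname read_panel
#' @param x panel `data.table`.
#' @export
write_panel <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# LD store

#' Read a pairwise-LD table into an LD store
#'
#' The file holds one row per SNP pair with columns `snp_a`, `snp_b`, `r2`.
#' Stored pairs are expected to be pre-filtered the way PLINK emits them
#' (r2 at or above a floor, pairs within a maximum distance); pairs absent
#' from the table are treated as r2 = 0 on lookup, and self-LD is implicit
#' r2 = 1.  The store is symmetric: both orientations are indexed.
#'
#' @param path file path.
#' @return an object of class `pg_ld`.
#' @export
read_ld <- function(path) {
  raw <- pg_fread(path)
  nm <- tolower(names(raw))
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% nm)) {
    stop("LD table must have columns snp_a, snp_b, r2")
  }
  x <- data.table::data.table(
    snp_a = as.character(raw[[which(nm == "snp_a")[1L]]]),
    snp_b = as.character(raw[[which(nm == "snp_b")[1L]]]),
    r2    = as.numeric(raw[[which(nm == "r2")[1L]]])
  )
  if (any(is.na(x$r2) | x$r2 < 0 | x$r2 > 1)) stop("r2 values must lie in [0, 1]")
  if (any(x$snp_a == x$snp_b)) stop("self pairs must not be stored (self-LD is implicit)")
  ld_store(x)
}

#' Build an LD store from a pair table
#' @param pairs `data.table` with `snp_a`, `snp_b`, `r2` (one orientation).
#' @return `pg_ld` object.
#' @export
ld_store <- function(pairs) {
  pairs <- data.table::as.data.table(pairs)[, .(snp_a, snp_b, r2)]
  both <- data.table::rbindlist(list(
    pairs,
    pairs[, .(snp_a = snp_b, snp_b = snp_a, r2 = r2)]
  ))
  both <- unique(both, by = c("snp_a", "snp_b"))
  data.table::setkeyv(both, c("snp_a", "snp_b"))
  structure(list(pairs = pairs, index = both), class = "pg_ld")
}

#' Query pairwise r2
#'
#' Vectorized lookup; `query(a, a)` is 1 and absent pairs are 0 (they were
#' below the storage floor or beyond the distance cap when the table was
#' pre-computed).
#'
#' @param ld a `pg_ld` store.
#' @param a,b character vectors of SNP ids (recycled to equal length).
#' @return numeric vector of r2 values.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  q <- data.table::data.table(snp_a = a, snp_b = b)
  hit <- ld$index[q, on = c("snp_a", "snp_b"), x.r2]
  out <- ifelse(a == b, 1, ifelse(is.na(hit), 0, hit))
  as.numeric(out)
}

#' Neighbors of a SNP in the LD store
#' @param ld `pg_ld` store.
#' @param snp single SNP id.
#' @param min_r2 keep neighbors with r2 at or above this.
#' @return `data.table` with `snp_b`, `r2` (the SNP itself is not included).
#' @export
ld_neighbors <- function(ld, snp, min_r2 = 0) {
  nb <- ld$index[.(as.character(snp)), on = "snp_a", nomatch = NULL]
  nb <- nb[r2 >= min_r2, .(snp_b, r2)]
  nb
}

#' Write an LD store back to its pair-table format
#' @param ld `pg_ld` store.
#' @param path output path.
#' @export
write_ld <- function(ld, path) {
  data.table::fwrite(ld$pairs, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Validate stored LD pairs against a panel
#'
#' Checks the storage contract: r2 at or above `min_r2` and pair distance at
#' most `max_dist_bp`, with both members present in the panel.
#'
#' @param ld `pg_ld` store.
#' @param panel panel `data.table`.
#' @param min_r2,max_dist_bp storage contract bounds.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_ld <- function(ld, panel, min_r2 = 0.05, max_dist_bp = 1e6) {
  p <- ld$pairs
  if (any(p$r2 < min_r2)) stop("stored LD pairs below the r2 floor")
  pos <- stats::setNames(panel$pos, panel$snp_id)
  chr <- stats::setNames(panel$chrom, panel$snp_id)
  if (any(!p$snp_a %in% panel$snp_id) || any(!p$snp_b %in% panel$snp_id)) {
    stop("LD pair references a SNP absent from the panel")
  }
  if (any(chr[p$snp_a] != chr[p$snp_b])) stop("cross-chromosome LD pair stored")
  if (any(abs(pos[p$snp_a] - pos[p$snp_b]) > max_dist_bp)) {
    stop("stored LD pair exceeds the distance cap")
  }
  invisible(TRUE)
}
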