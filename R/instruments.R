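#' Proportion of exposure variance explained by a variant
#'
#' Computes per-variant R^2 from summary statistics as
#' `beta^2 / (beta^2 + n * se^2)`. This is the algebraic simplification of
#' the conventional `2*EAF*(1-EAF)` form, in which the allele-frequency
#' factor multiplies numerator and denominator alike and cancels; the value
#' therefore does not depend on `eaf`.
#'
#' @param beta Per-allele effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @param n Sample size(s), strictly positive.
#' @return Numeric vector of variance proportions in \[0, 1).
#' @export
compute_pve <- function(beta, se, n) {
  if (any(se <= 0, na.rm = TRUE)) abort_domain("compute_pve requires se > 0")
  if (any(n <= 0, na.rm = TRUE)) abort_domain("compute_pve requires n > 0")
  beta^2 / (beta^2 + n * se^2)
}

#' Instrument-strength F-statistic
#'
#' `F = pve * (n - 2) / (1 - pve)`, the single-instrument strength statistic;
#' F > 10 is the conventional weak-instrument cutoff.
#'
#' @param pve Proportion of variance explained, in \[0, 1).
#' @param n Sample size(s), greater than 2.
#' @return Numeric vector of F-statistics (>= 0).
#' @export
compute_f <- function(pve, n) {
  if (any(pve < 0 | pve >= 1, na.rm = TRUE)) {
    abort_domain("compute_f requires 0 <= pve < 1")
  }
  pve * (n - 2) / (1 - pve)
}

#' LD matrices
#'
#' An LD matrix is a square symmetric matrix of squared correlations (r^2)
#' with unit diagonal and variant identifiers as dimnames. `read_ld_matrix()`
#' and `write_ld_matrix()` round-trip the TSV serialization (header row of
#' variant ids, one row per variant).
#'
#' @param path TSV path.
#' @return `read_ld_matrix()` returns the validated matrix.
#' @export
read_ld_matrix <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(tbl)
  rownames(m) <- colnames(m)
  validate_ld_matrix(m)
  m
}

#' @rdname read_ld_matrix
#' @param ld LD matrix with variant-id dimnames.
#' @export
write_ld_matrix <- function(ld, path) {
  validate_ld_matrix(ld)
  out <- as.data.frame(signif(ld, 10), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_ld_matrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
    abort_config("LD matrix must be square")
  }
  if (is.null(colnames(ld))) abort_config("LD matrix needs variant-id dimnames")
  if (any(abs(ld - t(ld)) > 1e-8)) abort_config("LD matrix must be symmetric")
  if (any(abs(diag(ld) - 1) > 1e-8)) abort_config("LD matrix diagonal must be 1")
  if (any(ld < -1e-12 | ld > 1 + 1e-12)) {
    abort_config("LD r^2 entries must lie in [0, 1]")
  }
  invisible(ld)
}

#' Greedy LD clumping
#'
#' Iteratively retains the remaining variant with the smallest p-value and
#' discards every other variant within `window_kb` of it whose squared
#' correlation with it is at least `r2_max`. Ties on p-value break by
#' smaller position, then lexicographic variant id, so output is
#' deterministic. Rows are returned in retention order.
#'
#' @param x Tibble with columns `variant_id`, `pos`, `pval` (extra columns
#'   pass through).
#' @param ld LD matrix covering every variant in `x`.
#' @param r2_max Squared-correlation threshold at or above which a nearby
#'   variant is removed (default 0.001).
#' @param window_kb Distance in kilobases within which LD pruning applies
#'   (default 10,000 kb).
#' @return The retained subset of `x`, in retention order.
#' @export
greedy_clump <- function(x, ld, r2_max = 0.001, window_kb = 10000) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(x)
  missing_ids <- setdiff(x$variant_id, colnames(ld))
  if (length(missing_ids) > 0) {
    abort_config(paste0("variant(s) absent from LD matrix: ",
                        paste(missing_ids, collapse = ", ")))
  }
  ord <- order(x$pval, x$pos, x$variant_id)
  x <- x[ord, , drop = FALSE]
  remaining <- rep(TRUE, nrow(x))
  keep_idx <- integer(0)
  window_bp <- window_kb * 1000
  while (any(remaining)) {
    i <- which(remaining)[1]
    keep_idx <- c(keep_idx, i)
    remaining[i] <- FALSE
    if (!any(remaining)) break
    j <- which(remaining)
    near <- abs(x$pos[j] - x$pos[i]) <= window_bp
    r2 <- ld[x$variant_id[j], x$variant_id[i]]
    remaining[j[near & r2 >= r2_max]] <- FALSE
  }
  x[keep_idx, , drop = FALSE]
}

#' Select genetic instruments for one gene
#'
#' Applies the instrument-selection cascade to a gene's cis-eQTL
#' associations: (1) genome-wide significance `pval < p_max`; (2)
#' minor-allele frequency `min(eaf, 1 - eaf) > maf_min`; (3) greedy LD
#' clumping at `r2_max` within `window_kb`; (4) instrument strength
#' `F > f_min`, with per-variant PVE and F computed from the variant's own
#' `beta`, `se` and `n`. Variants farther than `cis_window_bp` from the
#' gene's TSS (or on another chromosome) are flagged `is_trans`, which
#' downstream suppresses colocalization for the gene.
#'
#' @param exposure Sumstats tibble of the gene's eQTL associations (if a
#'   `gene_id` column is present it is filtered to `gene$gene_id`).
#' @param gene One-row gene-region tibble (`gene_id`, `symbol`, `chrom`,
#'   `tss`, `cis_window_bp`).
#' @param ld LD matrix covering the gene's candidate variants.
#' @param p_max Significance threshold (default 5e-8).
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @param r2_max,window_kb Clumping parameters (defaults 0.001 and 10,000).
#' @param f_min Minimum F-statistic (default 10).
#' @return Tibble of retained instruments with `pve`, `f_stat` and
#'   `is_trans` columns; the per-stage removal counts are attached as the
#'   `"selection_log"` attribute.
#' @export
select_instruments <- function(exposure, gene, ld,
                               p_max = 5e-8, maf_min = 0.01,
                               r2_max = 0.001, window_kb = 10000,
                               f_min = 10) {
  x <- tibble::as_tibble(exposure)
  if ("gene_id" %in% names(x)) {
    x <- x[x$gene_id == gene$gene_id, , drop = FALSE]
  }
  log <- c(candidates = nrow(x), not_significant = 0L, low_maf = 0L,
           clumped = 0L, weak = 0L, retained = 0L)

  sig <- !is.na(x$pval) & x$pval < p_max
  log["not_significant"] <- sum(!sig)
  x <- x[sig, , drop = FALSE]

  maf <- pmin(x$eaf, 1 - x$eaf)
  common <- !is.na(maf) & maf > maf_min
  log["low_maf"] <- sum(!common)
  x <- x[common, , drop = FALSE]

  n_pre <- nrow(x)
  if (n_pre > 0) x <- greedy_clump(x, ld, r2_max = r2_max, window_kb = window_kb)
  log["clumped"] <- n_pre - nrow(x)

  if (nrow(x) > 0) {
    x$pve <- compute_pve(x$beta, x$se, x$n)
    x$f_stat <- compute_f(x$pve, x$n)
    strong <- x$f_stat > f_min
    log["weak"] <- sum(!strong)
    x <- x[strong, , drop = FALSE]
  } else {
    x$pve <- double(0)
    x$f_stat <- double(0)
  }
  x$is_trans <- !(x$chrom == gene$chrom &
                    abs(x$pos - gene$tss) <= gene$cis_window_bp)
  log["retained"] <- nrow(x)
  attr(x, "selection_log") <- log
  x
}

#' @rdname select_instruments
#' @param x An instrument tibble returned by `select_instruments()`.
#' @export
selection_log <- function(x) attr(x, "selection_log")
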