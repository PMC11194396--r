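#' Summary-statistics tables
#'
#' A summary-statistics table ("sumstats") is a tibble with one row per
#' variant association and columns `variant_id`, `chrom`, `pos` (1-based,
#' GRCh37), `effect_allele`, `other_allele`, `eaf` (effect-allele frequency,
#' may be `NA`), `beta`, `se`, `pval`, `n`. eQTL tables additionally carry a
#' `gene_id` column (one row per gene x variant). Trait metadata travels in
#' attributes: `trait_id`, `trait_type` (`"quantitative"` or `"binary"`),
#' and for binary traits `n_cases` / `n_controls`.
#'
#' @name sumstats
NULL

SUMSTATS_FIELDS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

#' Build a validated summary-statistics tibble
#'
#' Coerces column types, enforces the per-row invariants (alleles in
#' \{A,C,G,T\} and distinct, `se > 0`, `eaf` in \[0,1\] or `NA`, `pval` in
#' (0,1\], `n > 0`, `pos >= 1`, unique `variant_id` per gene), and drops
#' violating rows. Drop counts per reason are recorded in the
#' `"validation_log"` attribute.
#'
#' @param x A data frame containing at least the sumstats columns.
#' @param trait_id Character scalar identifying the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_cases,n_controls Case/control counts, required when
#'   `trait_type = "binary"`.
#' @return A tibble of validated associations with trait metadata attached
#'   as attributes.
#' @export
as_sumstats <- function(x, trait_id = "trait", trait_type = c("quantitative", "binary"),
                        n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "binary" && (is.null(n_cases) || is.null(n_controls))) {
    abort_config("binary traits require `n_cases` and `n_controls`")
  }
  missing_cols <- setdiff(SUMSTATS_FIELDS, names(x))
  if (length(missing_cols) > 0) {
    abort_config(paste0(
      "missing mandatory sumstats column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }

  tbl <- tibble::as_tibble(x)
  tbl$variant_id <- as.character(tbl$variant_id)
  tbl$chrom <- as.character(tbl$chrom)
  tbl$pos <- as.integer(tbl$pos)
  tbl$effect_allele <- toupper(as.character(tbl$effect_allele))
  tbl$other_allele <- toupper(as.character(tbl$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) tbl[[col]] <- as.double(tbl[[col]])
  tbl$n <- as.double(tbl$n)

  ok_core <- !is.na(tbl$variant_id) & !is.na(tbl$pos) & tbl$pos >= 1L &
    !is.na(tbl$beta) & !is.na(tbl$se) & !is.na(tbl$pval) & !is.na(tbl$n)
  checks <- list(
    incomplete    = !ok_core,
    bad_alleles   = !(tbl$effect_allele %in% VALID_ALLELES &
                        tbl$other_allele %in% VALID_ALLELES &
                        tbl$effect_allele != tbl$other_allele),
    nonpositive_se = !is.na(tbl$se) & tbl$se <= 0,
    bad_eaf       = !is.na(tbl$eaf) & (tbl$eaf < 0 | tbl$eaf > 1),
    bad_pval      = !is.na(tbl$pval) & (tbl$pval <= 0 | tbl$pval > 1),
    nonpositive_n = !is.na(tbl$n) & tbl$n <= 0
  )
  bad <- Reduce(`|`, lapply(checks, function(v) v %in% TRUE))
  log <- vapply(checks, function(v) sum(v %in% TRUE), integer(1))

  key <- if ("gene_id" %in% names(tbl)) paste(tbl$gene_id, tbl$variant_id) else tbl$variant_id
  dup <- duplicated(key)
  log <- c(log, duplicate_variant_id = sum(dup & !bad))
  bad <- bad | dup

  dropped <- sum(bad)
  if (dropped > 0) {
    rlang::inform(sprintf(
      "as_sumstats: dropped %d invalid row(s) for trait '%s'", dropped, trait_id
    ), class = "targetmr_validation")
  }
  tbl <- tbl[!bad, , drop = FALSE]

  attr(tbl, "trait_id") <- trait_id
  attr(tbl, "trait_type") <- trait_type
  attr(tbl, "n_cases") <- n_cases
  attr(tbl, "n_controls") <- n_controls
  attr(tbl, "validation_log") <- c(log, n_dropped = dropped)
  tbl
}

#' @rdname as_sumstats
#' @export
validation_log <- function(x) attr(x, "validation_log")

#' @rdname as_sumstats
#' @export
trait_id <- function(x) attr(x, "trait_id") %||% "trait"

#' @rdname as_sumstats
#' @export
trait_type <- function(x) attr(x, "trait_type") %||% "quantitative"

#' Read a tab-separated summary-statistics file
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Optional named character vector mapping sumstats field
#'   names to the column names used in the file, e.g.
#'   `c(variant_id = "SNP", beta = "b")`. Unmapped fields are assumed to use
#'   their canonical names.
#' @inheritParams as_sumstats
#' @return A validated sumstats tibble (see [as_sumstats()]).
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = "trait",
                          trait_type = c("quantitative", "binary"),
                          n_cases = NULL, n_controls = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0) {
      abort_config(paste0(
        "column_map refers to column(s) absent from ", path, ": ",
        paste(missing_src, collapse = ", ")
      ))
    }
    for (field in names(column_map)) {
      names(raw)[names(raw) == column_map[[field]]] <- field
    }
  }
  tbl <- as_sumstats(raw, trait_id = trait_id, trait_type = match.arg(trait_type),
                     n_cases = n_cases, n_controls = n_controls)
  if (nrow(tbl) == 0) {
    abort_config(paste0("no valid rows remain after validating ", path))
  }
  tbl
}

#' Write a summary-statistics tibble as TSV
#'
#' Numeric columns are written with 10 significant digits so that a
#' write/read round trip preserves values to that precision.
#'
#' @param x A sumstats tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA_character_, formatC(v, digits = 10, format = "g"))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read gene/region metadata
#'
#' The gene-region table defines, per gene, the transcription start site and
#' the cis window within which eQTL variants count as cis instruments.
#'
#' @param path TSV with columns `gene_id`, `symbol`, `chrom`, `tss`, and
#'   optionally `cis_window_bp` (default 1 Mb).
#' @return A tibble with one row per gene.
#' @export
read_gene_regions <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("gene_id", "symbol", "chrom", "tss")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort_config(paste0("gene-region file lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!"cis_window_bp" %in% names(tbl)) tbl$cis_window_bp <- 1e6
  if (any(tbl$cis_window_bp <= 0)) abort_config("cis_window_bp must be positive")
  tbl$chrom <- as.character(tbl$chrom)
  tbl$tss <- as.integer(tbl$tss)
  tbl$cis_window_bp <- as.double(tbl$cis_window_bp)
  tbl
}

#' Read a druggable-gene list (one identifier per line)
#'
#' @param path Plain-text file with one gene identifier per line.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

# ---------------------------------------------------------------------------
# Allele harmonization

# Vectorized harmonization core. All inputs exposure-orientation; returns a
# tibble of per-variant actions plus the adjusted outcome beta/eaf.
harmonize_core <- function(ea_exp, oa_exp, eaf_exp,
                           ea_out, oa_out, eaf_out, beta_out,
                           palindrome_eaf_band = c(0.42, 0.58)) {
  lo <- palindrome_eaf_band[1]
  hi <- palindrome_eaf_band[2]
  k <- length(ea_exp)
  action <- character(k)
  beta <- beta_out
  eaf <- eaf_out

  pal <- is_palindromic(ea_exp, oa_exp)
  for (i in seq_len(k)) {
    if (pal[i]) {
      same_set <- setequal(c(ea_out[i], oa_out[i]), c(ea_exp[i], oa_exp[i]))
      if (!same_set) {
        action[i] <- "rejected:allele-mismatch"
      } else if (is.na(eaf_exp[i]) || (eaf_exp[i] > lo && eaf_exp[i] < hi)) {
        action[i] <- "rejected:palindromic-ambiguous"
      } else if (is.na(eaf_out[i])) {
        action[i] <- "rejected:palindromic-missing-eaf"
      } else if ((eaf_exp[i] - 0.5) * (eaf_out[i] - 0.5) >= 0) {
        # effect alleles on the same frequency side: already aligned
        action[i] <- "kept"
      } else {
        action[i] <- "flipped"
        beta[i] <- -beta[i]
        eaf[i] <- 1 - eaf[i]
      }
    } else if (ea_out[i] == ea_exp[i] && oa_out[i] == oa_exp[i]) {
      action[i] <- "kept"
    } else if (ea_out[i] == oa_exp[i] && oa_out[i] == ea_exp[i]) {
      action[i] <- "flipped"
      beta[i] <- -beta[i]
      eaf[i] <- if (is.na(eaf[i])) NA_real_ else 1 - eaf[i]
    } else {
      cea <- complement_allele(ea_out[i])
      coa <- complement_allele(oa_out[i])
      if (cea == ea_exp[i] && coa == oa_exp[i]) {
        action[i] <- "complemented"
      } else if (cea == oa_exp[i] && coa == ea_exp[i]) {
        action[i] <- "flipped"
        beta[i] <- -beta[i]
        eaf[i] <- if (is.na(eaf[i])) NA_real_ else 1 - eaf[i]
      } else {
        action[i] <- "rejected:allele-mismatch"
      }
    }
  }
  tibble::tibble(action = action, beta_out = beta, eaf_out = eaf)
}

#' Harmonize one exposure/outcome variant pair
#'
#' Aligns the outcome association to the exposure's effect allele. Swapped
#' alleles negate the outcome beta and reflect its allele frequency;
#' strand-flipped alleles (reported on the opposite strand) are complemented
#' first. Palindromic variants (A/T, G/C) whose exposure allele frequency
#' falls inside `palindrome_eaf_band` are rejected as strand-ambiguous;
#' outside the band they are aligned by frequency.
#'
#' @param exposure,outcome One-row data frames (or lists) with the sumstats
#'   fields; must share `variant_id`.
#' @param palindrome_eaf_band Length-2 numeric, the open frequency interval
#'   within which palindromic variants are considered ambiguous.
#' @return A list with elements `exposure`, `outcome` (outcome adjusted to
#'   the exposure orientation; unchanged on rejection), `action`, and
#'   `rejected` (logical).
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_band = c(0.42, 0.58)) {
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  stopifnot(nrow(exposure) == 1, nrow(outcome) == 1)
  if (exposure$variant_id != outcome$variant_id) {
    abort_config("harmonize_pair requires matching variant_id")
  }
  res <- harmonize_core(
    exposure$effect_allele, exposure$other_allele, exposure$eaf,
    outcome$effect_allele, outcome$other_allele, outcome$eaf, outcome$beta,
    palindrome_eaf_band
  )
  rejected <- startsWith(res$action, "rejected")
  if (!rejected) {
    outcome$beta <- res$beta_out
    outcome$eaf <- res$eaf_out
    outcome$effect_allele <- exposure$effect_allele
    outcome$other_allele <- exposure$other_allele
  }
  list(exposure = exposure, outcome = outcome, action = res$action,
       rejected = rejected)
}

#' Harmonize two summary-statistics tables variant-wise
#'
#' Joins exposure and outcome tables on `variant_id` and applies
#' [harmonize_pair()]'s allele-alignment rules to every shared variant.
#' Rejected variants are excluded from the result; the full per-variant
#' action report is available via [harmonization_report()].
#'
#' @param exposure,outcome Sumstats tibbles (see [as_sumstats()]).
#' @inheritParams harmonize_pair
#' @return A tibble of harmonized instruments with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `pval_exp`, `n_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `pval_out`, `n_out` (plus `pve` and `f_stat` if present on the
#'   exposure), carrying the harmonization report as an attribute.
#' @export
harmonize_sumstats <- function(exposure, outcome,
                               palindrome_eaf_band = c(0.42, 0.58)) {
  exp_cols <- intersect(
    c(SUMSTATS_FIELDS, "pve", "f_stat"), names(exposure)
  )
  x <- dplyr::select(tibble::as_tibble(exposure), dplyr::all_of(exp_cols))
  y <- dplyr::select(tibble::as_tibble(outcome), dplyr::all_of(SUMSTATS_FIELDS))
  joined <- dplyr::inner_join(x, y, by = "variant_id", suffix = c("_exp", "_out"))
  if (nrow(joined) == 0) {
    out <- empty_harmonized()
    attr(out, "harmonization_report") <-
      tibble::tibble(variant_id = character(), action = character())
    return(out)
  }
  res <- harmonize_core(
    joined$effect_allele_exp, joined$other_allele_exp, joined$eaf_exp,
    joined$effect_allele_out, joined$other_allele_out, joined$eaf_out,
    joined$beta_out, palindrome_eaf_band
  )
  report <- tibble::tibble(variant_id = joined$variant_id, action = res$action)

  keep <- !startsWith(res$action, "rejected")
  out <- tibble::tibble(
    variant_id = joined$variant_id,
    chrom = joined$chrom_exp,
    pos = joined$pos_exp,
    effect_allele = joined$effect_allele_exp,
    other_allele = joined$other_allele_exp,
    beta_exp = joined$beta_exp,
    se_exp = joined$se_exp,
    eaf_exp = joined$eaf_exp,
    pval_exp = joined$pval_exp,
    n_exp = joined$n_exp,
    beta_out = res$beta_out,
    se_out = joined$se_out,
    eaf_out = res$eaf_out,
    pval_out = joined$pval_out,
    n_out = joined$n_out
  )
  if ("pve" %in% names(joined)) out$pve <- joined$pve
  if ("f_stat" %in% names(joined)) out$f_stat <- joined$f_stat
  out <- out[keep, , drop = FALSE]
  attr(out, "harmonization_report") <- report
  out
}

empty_harmonized <- function() {
  tibble::tibble(
    variant_id = character(), chrom = character(), pos = integer(),
    effect_allele = character(), other_allele = character(),
    beta_exp = double(), se_exp = double(), eaf_exp = double(),
    pval_exp = double(), n_exp = double(),
    beta_out = double(), se_out = double(), eaf_out = double(),
    pval_out = double(), n_out = double()
  )
}

#' @rdname harmonize_sumstats
#' @param x A harmonized tibble returned by [harmonize_sumstats()].
#' @export
harmonization_report <- function(x) attr(x, "harmonization_report")

#' @rdname harmonize_sumstats
#' @param path Output TSV path for the per-variant action report.
#' @export
write_harmonization_report <- function(x, path) {
  rep <- harmonization_report(x)
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
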