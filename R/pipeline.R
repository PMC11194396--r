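# Study orchestration: discovery MR across the druggable genome, the
# sensitivity battery, colocalization, reverse MR, tiered external
# replication and the biomarker scan.

#' Study-level analysis configuration
#'
#' @param p_max,maf_min,r2_max,window_kb,f_min Instrument-selection
#'   thresholds (see [select_instruments()]).
#' @param ivw_mode `"multiplicative_random"` (default) or `"fixed"`.
#' @param discovery_alpha Family-wise level for discovery Bonferroni
#'   correction (denominator = number of genes with at least one
#'   instrument, recomputed per run).
#' @param coloc_threshold Decision threshold on PPH3 + PPH4.
#' @param p1,p2,p12 Colocalization priors.
#' @param w_exp,w_out Colocalization prior effect variances.
#' @param reverse_alpha Significance level for the bidirectional call.
#' @param validation_alpha Family-wise level for replication; the
#'   denominator is the number of genes tested in the disease family.
#' @param biomarker_alpha Per-test level of the (unadjusted) biomarker
#'   scan; set `biomarker_bonferroni = TRUE` to divide it by the number of
#'   biomarker outcomes.
#' @param biomarker_bonferroni Adjust the biomarker scan (default `FALSE`).
#' @param require_directional_consistency If `TRUE` (default), a validation
#'   estimate whose sign disagrees with discovery is reported as
#'   non-replicated regardless of its p-value.
#' @param palindrome_eaf_band Ambiguity band for palindromic variants.
#' @return A `study_config` list.
#' @export
study_config <- function(p_max = 5e-8, maf_min = 0.01, r2_max = 0.001,
                         window_kb = 10000, f_min = 10,
                         ivw_mode = c("multiplicative_random", "fixed"),
                         discovery_alpha = 0.05,
                         coloc_threshold = 0.8,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w_exp = 0.15^2, w_out = 0.2^2,
                         reverse_alpha = 0.05,
                         validation_alpha = 0.05,
                         biomarker_alpha = 0.05,
                         biomarker_bonferroni = FALSE,
                         require_directional_consistency = TRUE,
                         palindrome_eaf_band = c(0.42, 0.58)) {
  cfg <- list(
    p_max = p_max, maf_min = maf_min, r2_max = r2_max,
    window_kb = window_kb, f_min = f_min, ivw_mode = match.arg(ivw_mode),
    discovery_alpha = discovery_alpha, coloc_threshold = coloc_threshold,
    p1 = p1, p2 = p2, p12 = p12, w_exp = w_exp, w_out = w_out,
    reverse_alpha = reverse_alpha, validation_alpha = validation_alpha,
    biomarker_alpha = biomarker_alpha,
    biomarker_bonferroni = biomarker_bonferroni,
    require_directional_consistency = require_directional_consistency,
    palindrome_eaf_band = palindrome_eaf_band
  )
  stopifnot(all(vapply(
    cfg[c("p_max", "maf_min", "r2_max", "window_kb", "f_min",
          "discovery_alpha", "coloc_threshold", "reverse_alpha",
          "validation_alpha", "biomarker_alpha")],
    function(x) is.numeric(x) && x > 0, logical(1)
  )))
  class(cfg) <- "study_config"
  cfg
}

select_for_gene <- function(study, gene, config) {
  select_instruments(
    study$exposure, gene, study$ld[[gene$gene_id]],
    p_max = config$p_max, maf_min = config$maf_min,
    r2_max = config$r2_max, window_kb = config$window_kb,
    f_min = config$f_min
  )
}

estimate_from <- function(harm, config, gene_id, outcome_id) {
  if (nrow(harm) == 1) {
    wald_ratio(harm, gene_id = gene_id, outcome_id = outcome_id)
  } else {
    ivw(harm, mode = config$ivw_mode, gene_id = gene_id,
        outcome_id = outcome_id)
  }
}

na_estimate_cols <- function() {
  tibble::tibble(
    method = NA_character_, beta = NA_real_, se = NA_real_, pval = NA_real_,
    or_ = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n_snps = 0L
  )
}

#' Discovery-phase MR across all genes
#'
#' For every gene with at least one selectable instrument: harmonizes the
#' instruments against the discovery outcome, estimates the causal effect
#' (Wald ratio for one instrument, IVW otherwise), applies the MR-Steiger
#' directionality filter and re-estimates on the retained instruments, runs
#' the sensitivity battery (Cochran's Q, MR-Egger intercept), performs
#' Bayesian colocalization over the full cis region for cis genes, and runs
#' reverse MR for prioritized genes. The discovery Bonferroni threshold is
#' `discovery_alpha / m` with `m` the number of genes with instruments. A
#' gene is prioritized when its discovery p-value beats that threshold, it
#' survives Steiger filtering, and (where colocalization was performed)
#' PPH3 + PPH4 reaches the decision threshold; trans-instrumented genes
#' skip colocalization and are carried on the remaining evidence.
#'
#' @param study A `study_bundle` (see [simulate_study()] / [load_study()]).
#' @param config A [study_config()].
#' @return A tibble with one row per analyzed gene; the discovery threshold
#'   and gene count are attached as attributes, and the per-gene instrument
#'   ids as the list-column `instruments`.
#' @export
run_discovery <- function(study, config = study_config()) {
  if (nrow(study$genes) == 0) abort_config("study contains no genes")
  outcome_id <- trait_id(study$outcome)
  rows <- vector("list", nrow(study$genes))

  for (g in seq_len(nrow(study$genes))) {
    gene <- study$genes[g, ]
    insts <- select_for_gene(study, gene, config)
    if (nrow(insts) == 0) next
    harm <- harmonize_sumstats(insts, study$outcome,
                               palindrome_eaf_band = config$palindrome_eaf_band)
    if (nrow(harm) == 0) next

    est <- estimate_from(harm, config, gene$gene_id, outcome_id)
    het <- if (nrow(harm) >= 2) cochran_q(harm) else
      tibble::tibble(q = NA_real_, q_df = NA_integer_, q_pval = NA_real_)
    egg <- egger_intercept(harm)

    stg <- steiger_filter(harm)
    steiger_pass <- nrow(stg$instruments) > 0
    est_stg <- if (steiger_pass) {
      estimate_from(stg$instruments, config, gene$gene_id, outcome_id)
    } else {
      dplyr::bind_cols(tibble::tibble(gene_id = gene$gene_id,
                                      outcome_id = outcome_id),
                       na_estimate_cols())
    }

    # colocalization over the full harmonized cis region (cis genes only)
    is_trans_gene <- any(insts$is_trans)
    coloc <- NULL
    if (!is_trans_gene) {
      region_exp <- study$exposure[study$exposure$gene_id == gene$gene_id, ]
      cis <- region_exp$chrom == gene$chrom &
        abs(region_exp$pos - gene$tss) <= gene$cis_window_bp
      region <- harmonize_sumstats(region_exp[cis, ], study$outcome,
                                   palindrome_eaf_band = config$palindrome_eaf_band)
      if (nrow(region) > 0) {
        coloc <- coloc_posteriors(region, p1 = config$p1, p2 = config$p2,
                                  p12 = config$p12, w_exp = config$w_exp,
                                  w_out = config$w_out)
      }
    }
    coloc_cols <- if (is.null(coloc)) {
      tibble::tibble(pph0 = NA_real_, pph1 = NA_real_, pph2 = NA_real_,
                     pph3 = NA_real_, pph4 = NA_real_, pph34 = NA_real_,
                     coloc_pass = NA)
    } else {
      dplyr::bind_cols(
        coloc[, c("pph0", "pph1", "pph2", "pph3", "pph4", "pph34")],
        tibble::tibble(coloc_pass = coloc_decision(coloc, config$coloc_threshold))
      )
    }

    rows[[g]] <- dplyr::bind_cols(
      tibble::tibble(
        gene_id = gene$gene_id, symbol = gene$symbol,
        outcome_id = outcome_id,
        n_candidates = unname(selection_log(insts)["candidates"]),
        n_instruments = nrow(harm),
        is_trans = is_trans_gene
      ),
      est[, c("method", "beta", "se", "pval", "or_", "ci_low", "ci_high",
              "n_snps")],
      tibble::tibble(
        pve = sum(harm$pve), f_stat_min = min(harm$f_stat),
        steiger_pass = steiger_pass,
        n_steiger_removed = nrow(harm) - nrow(stg$instruments),
        beta_steiger = est_stg$beta, pval_steiger = est_stg$pval
      ),
      het, egg[, c("egger_intercept", "egger_intercept_pval")],
      coloc_cols,
      tibble::tibble(instruments = list(harm$variant_id))
    )
  }

  reports <- dplyr::bind_rows(rows)
  if (nrow(reports) == 0) {
    abort_config("no gene has a selectable instrument; nothing to analyze")
  }
  m <- nrow(reports)
  thr <- bonferroni_threshold(config$discovery_alpha, m)
  reports$discovery_threshold <- thr
  reports$significant <- reports$pval < thr
  reports$prioritized <- reports$significant & reports$steiger_pass &
    (is.na(reports$coloc_pass) | reports$coloc_pass)

  # reverse MR only for prioritized genes
  rev_cols <- tibble::tibble(
    reverse_method = NA_character_, reverse_beta = NA_real_,
    reverse_pval = NA_real_, reverse_testable = NA, bidirectional = NA
  )
  reports <- dplyr::bind_cols(reports, rev_cols[rep(1, m), ])
  for (i in which(reports$prioritized)) {
    gene <- study$genes[study$genes$gene_id == reports$gene_id[i], ]
    rev <- reverse_mr(
      study$outcome, study$exposure, gene, study$ld[[gene$gene_id]],
      p_max = config$p_max, maf_min = config$maf_min,
      r2_max = config$r2_max, window_kb = config$window_kb,
      f_min = config$f_min, mode = config$ivw_mode,
      alpha = config$reverse_alpha
    )
    reports$reverse_method[i] <- rev$method
    reports$reverse_beta[i] <- rev$beta
    reports$reverse_pval[i] <- rev$pval
    reports$reverse_testable[i] <- rev$testable
    reports$bidirectional[i] <- rev$bidirectional
  }

  attr(reports, "m_genes") <- m
  attr(reports, "discovery_threshold") <- thr
  reports
}

#' Tiered external replication
#'
#' Re-estimates each prioritized gene in every validation outcome. Under
#' the `"same_variant"` strategy the discovery instruments themselves are
#' looked up in the validation outcome (missing variants are logged);
#' `"significant_variant"` re-runs instrument selection from scratch before
#' estimating. Replication verdicts use the family-wise Bonferroni
#' threshold `validation_alpha / m` where `m` is the number of genes tested
#' in the family, and (by default) require the validation effect to agree
#' in direction with discovery.
#'
#' @param reports Discovery tibble from [run_discovery()].
#' @inheritParams run_discovery
#' @param strategy `"same_variant"` (default) or `"significant_variant"`.
#' @return A tibble with one row per prioritized gene x validation outcome.
#' @export
run_validation <- function(reports, study, config = study_config(),
                           strategy = c("same_variant", "significant_variant")) {
  strategy <- match.arg(strategy)
  prio <- reports[reports$prioritized, , drop = FALSE]
  if (nrow(prio) == 0 || length(study$validation) == 0) {
    return(tibble::tibble(
      gene_id = character(), outcome_id = character(), strategy = character(),
      method = character(), beta = double(), se = double(), pval = double(),
      or_ = double(), ci_low = double(), ci_high = double(),
      n_snps = integer(), n_missing_variants = integer(),
      family_threshold = double(), direction_consistent = logical(),
      testable = logical(), replicated = logical()
    ))
  }
  m_family <- nrow(prio)
  thr <- bonferroni_threshold(config$validation_alpha, m_family)
  out <- list()
  for (v in names(study$validation)) {
    vtab <- study$validation[[v]]
    for (i in seq_len(nrow(prio))) {
      gene <- study$genes[study$genes$gene_id == prio$gene_id[i], ]
      if (strategy == "same_variant") {
        ids <- prio$instruments[[i]]
        exp_g <- study$exposure[study$exposure$gene_id == gene$gene_id &
                                  study$exposure$variant_id %in% ids, ]
        n_missing <- sum(!ids %in% vtab$variant_id)
      } else {
        exp_g <- select_for_gene(study, gene, config)
        n_missing <- sum(!exp_g$variant_id %in% vtab$variant_id)
      }
      harm <- harmonize_sumstats(exp_g, vtab,
                                 palindrome_eaf_band = config$palindrome_eaf_band)
      if (nrow(harm) == 0) {
        row <- dplyr::bind_cols(
          tibble::tibble(gene_id = gene$gene_id, outcome_id = v,
                         strategy = strategy),
          na_estimate_cols(),
          tibble::tibble(n_missing_variants = n_missing,
                         family_threshold = thr,
                         direction_consistent = NA,
                         testable = FALSE, replicated = FALSE)
        )
      } else {
        est <- estimate_from(harm, config, gene$gene_id, v)
        consistent <- sign(est$beta) == sign(prio$beta[i])
        rep_ok <- est$pval < thr &&
          (!config$require_directional_consistency || consistent)
        row <- dplyr::bind_cols(
          tibble::tibble(gene_id = gene$gene_id, outcome_id = v,
                         strategy = strategy),
          est[, c("method", "beta", "se", "pval", "or_", "ci_low",
                  "ci_high", "n_snps")],
          tibble::tibble(n_missing_variants = n_missing,
                         family_threshold = thr,
                         direction_consistent = consistent,
                         testable = TRUE, replicated = rep_ok)
        )
      }
      out[[length(out) + 1]] <- row
    }
  }
  dplyr::bind_rows(out)
}

#' Biomarker association scan
#'
#' Estimates each prioritized gene against every biomarker outcome using
#' the discovery instruments, recording an association when the p-value
#' falls below `biomarker_alpha` (unadjusted by default).
#'
#' @inheritParams run_validation
#' @return A tibble with one row per prioritized gene x biomarker.
#' @export
run_biomarker_scan <- function(reports, study, config = study_config()) {
  prio <- reports[reports$prioritized, , drop = FALSE]
  empty <- tibble::tibble(
    gene_id = character(), outcome_id = character(), method = character(),
    beta = double(), se = double(), pval = double(), or_ = double(),
    ci_low = double(), ci_high = double(), n_snps = integer(),
    threshold = double(), associated = logical()
  )
  if (nrow(prio) == 0 || length(study$biomarkers) == 0) return(empty)
  thr <- config$biomarker_alpha /
    (if (config$biomarker_bonferroni) length(study$biomarkers) else 1)
  out <- list()
  for (b in names(study$biomarkers)) {
    btab <- study$biomarkers[[b]]
    for (i in seq_len(nrow(prio))) {
      gene_id <- prio$gene_id[i]
      ids <- prio$instruments[[i]]
      exp_g <- study$exposure[study$exposure$gene_id == gene_id &
                                study$exposure$variant_id %in% ids, ]
      harm <- harmonize_sumstats(exp_g, btab,
                                 palindrome_eaf_band = config$palindrome_eaf_band)
      if (nrow(harm) == 0) next
      est <- estimate_from(harm, config, gene_id, b)
      out[[length(out) + 1]] <- dplyr::bind_cols(
        est[, c("gene_id", "outcome_id", "method", "beta", "se", "pval",
                "or_", "ci_low", "ci_high", "n_snps")],
        tibble::tibble(threshold = thr, associated = est$pval < thr)
      )
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Run the full study pipeline
#'
#' Discovery MR, sensitivity battery and colocalization, reverse MR,
#' external replication across all validation outcomes, and the biomarker
#' scan, collected into an `mr_study` result.
#'
#' @inheritParams run_discovery
#' @param validation_strategy Replication strategy (see [run_validation()]).
#' @return An `mr_study` list with `discovery`, `validation`, `biomarkers`,
#'   and a `manifest` recording every threshold applied.
#' @export
run_study <- function(study, config = study_config(),
                      validation_strategy = "same_variant") {
  discovery <- run_discovery(study, config)
  validation <- run_validation(discovery, study, config,
                               strategy = validation_strategy)
  biomarkers <- run_biomarker_scan(discovery, study, config)
  replication <- if (nrow(validation) > 0) {
    dplyr::count(validation[validation$replicated %in% TRUE, ],
                 .data$gene_id, name = "n_replications")
  } else {
    tibble::tibble(gene_id = character(), n_replications = integer())
  }
  manifest <- list(
    thresholds = config[c("p_max", "maf_min", "r2_max", "window_kb", "f_min",
                          "discovery_alpha", "coloc_threshold",
                          "reverse_alpha", "validation_alpha",
                          "biomarker_alpha")],
    ivw_mode = config$ivw_mode,
    coloc_priors = config[c("p1", "p2", "p12", "w_exp", "w_out")],
    discovery_threshold = attr(discovery, "discovery_threshold"),
    m_genes_with_instruments = attr(discovery, "m_genes"),
    validation_strategy = validation_strategy,
    validation_strategy_definitions = list(
      same_variant = "re-estimate with the discovery instruments looked up in the validation outcome",
      significant_variant = "re-select instruments from the exposure under the discovery criteria, then estimate in the validation outcome"
    ),
    require_directional_consistency = config$require_directional_consistency,
    seed = if (!is.null(study$config)) study$config$seed else NA
  )
  structure(
    list(discovery = discovery, validation = validation,
         biomarkers = biomarkers, replication = replication,
         manifest = manifest),
    class = "mr_study"
  )
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf(
    "MR study: %d gene(s) analyzed, %d significant, %d prioritized\n",
    nrow(x$discovery), sum(x$discovery$significant),
    sum(x$discovery$prioritized)
  ))
  if (nrow(x$validation) > 0) {
    cat(sprintf("  validation rows: %d (%d replicated)\n",
                nrow(x$validation), sum(x$validation$replicated)))
  }
  if (nrow(x$biomarkers) > 0) {
    cat(sprintf("  biomarker associations: %d of %d tested\n",
                sum(x$biomarkers$associated), nrow(x$biomarkers)))
  }
  invisible(x)
}

#' Write the report bundle for a completed study
#'
#' Emits the discovery table, the sensitivity table (Steiger flag, reverse
#' MR, colocalization posteriors), the validation table, the gene x
#' biomarker association matrix, and a JSON manifest listing every
#' threshold and seed actually applied.
#'
#' @param result An `mr_study` from [run_study()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
make_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  disc <- result$discovery
  fmt <- function(x) ifelse(is.na(x), NA_character_,
                            formatC(x, digits = 10, format = "g"))
  discovery_tbl <- tibble::tibble(
    tissue = "blood", gene_id = disc$gene_id, symbol = disc$symbol,
    n_snps = disc$n_snps, method = disc$method,
    or_ = round(disc$or_, 3), ci_low = round(disc$ci_low, 3),
    ci_high = round(disc$ci_high, 3), pval = fmt(disc$pval),
    pve = fmt(disc$pve), f_stat_min = fmt(disc$f_stat_min),
    significant = disc$significant, prioritized = disc$prioritized
  )
  sensitivity_tbl <- tibble::tibble(
    tissue = "blood", gene_id = disc$gene_id, symbol = disc$symbol,
    steiger_pass = disc$steiger_pass,
    n_steiger_removed = disc$n_steiger_removed,
    egger_intercept = fmt(disc$egger_intercept),
    egger_intercept_pval = fmt(disc$egger_intercept_pval),
    q = fmt(disc$q), q_pval = fmt(disc$q_pval),
    reverse_or = round(exp(disc$reverse_beta), 3),
    reverse_pval = fmt(disc$reverse_pval),
    bidirectional = disc$bidirectional,
    pph3 = fmt(disc$pph3), pph4 = fmt(disc$pph4), pph34 = fmt(disc$pph34),
    coloc_pass = disc$coloc_pass
  )
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE
  )
  wt(discovery_tbl, "discovery.tsv")
  wt(sensitivity_tbl, "sensitivity.tsv")
  val <- result$validation
  val_out <- val
  for (col in c("beta", "se", "pval", "or_", "ci_low", "ci_high",
                "family_threshold")) {
    if (col %in% names(val_out)) val_out[[col]] <- fmt(val_out[[col]])
  }
  wt(val_out, "validation.tsv")
  if (nrow(result$biomarkers) > 0) {
    mat <- tidyr::pivot_wider(
      result$biomarkers[, c("gene_id", "outcome_id", "associated")],
      names_from = "outcome_id", values_from = "associated"
    )
    wt(mat, "biomarker_matrix.tsv")
  } else {
    wt(tibble::tibble(gene_id = character()), "biomarker_matrix.tsv")
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Forest plot of discovery estimates
#'
#' Odds ratios with 95% confidence intervals per gene, highlighting
#' prioritized genes.
#'
#' @param reports Discovery tibble from [run_discovery()] (or an
#'   `mr_study`).
#' @param max_genes Show at most this many genes, smallest p-values first.
#' @return A ggplot object.
#' @export
plot_forest <- function(reports, max_genes = 30) {
  if (inherits(reports, "mr_study")) reports <- reports$discovery
  df <- dplyr::arrange(tibble::as_tibble(reports), .data$pval)
  df <- utils::head(df, max_genes)
  df$symbol <- factor(df$symbol, levels = rev(df$symbol))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or_, y = .data$symbol,
                                   color = .data$prioritized)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI), log scale", y = NULL,
                  color = "Prioritized") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mr_fit <- function(object, ...) {
  df <- object$instruments
  flip <- sign(df$beta_exp)
  df$bx <- df$beta_exp * flip
  df$by <- df$beta_out * flip
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$by - Z975 * .data$se_out,
                   ymax = .data$by + Z975 * .data$se_out),
      width = 0, color = "grey60"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = object$estimate$beta,
                         color = "steelblue") +
    ggplot2::labs(x = "SNP effect on expression (SD)",
                  y = "SNP effect on outcome (log-odds)",
                  title = sprintf("%s: slope = causal estimate (%s)",
                                  object$estimate$gene_id,
                                  object$estimate$method)) +
    ggplot2::theme_minimal()
}
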