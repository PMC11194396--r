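# Causal estimation from harmonized instruments: Wald ratio, IVW,
# heterogeneity and pleiotropy diagnostics, Steiger directionality, and
# reverse MR. All estimators consume the harmonized tibble produced by
# harmonize_sumstats() (columns beta_exp, se_exp, beta_out, se_out, ...).

mr_estimate_row <- function(gene_id, outcome_id, method, beta, se, n_snps) {
  z <- beta / se
  tibble::tibble(
    gene_id = gene_id,
    outcome_id = outcome_id,
    method = method,
    beta = beta,
    se = se,
    pval = two_sided_p(z),
    or_ = exp(beta),
    ci_low = exp(beta - Z975 * se),
    ci_high = exp(beta + Z975 * se),
    n_snps = as.integer(n_snps)
  )
}

# per-instrument Wald ratios with first-order delta-method SEs
ratio_stats <- function(x) {
  if (any(x$beta_exp == 0)) {
    bad <- x$variant_id[x$beta_exp == 0]
    abort_domain(paste0("exposure effect is zero for variant(s): ",
                        paste(bad, collapse = ", ")))
  }
  list(ratio = x$beta_out / x$beta_exp, se = x$se_out / abs(x$beta_exp))
}

#' Wald-ratio causal estimate from a single instrument
#'
#' The single-SNP causal effect `beta_out / beta_exp`, with the first-order
#' delta-method standard error `se_out / |beta_exp|` (exposure uncertainty
#' is second-order for instruments passing the F > 10 strength filter; an
#' optional second-order correction adds the `se_exp` term).
#'
#' @param x One-row harmonized-instrument tibble.
#' @param gene_id,outcome_id Identifiers carried into the result.
#' @param second_order If `TRUE`, inflate the SE by the second-order
#'   delta-method term `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2/beta_exp^4)`.
#' @return A one-row estimate tibble with `beta` (log odds ratio per SD of
#'   expression), `se`, `pval`, `or_` and its 95% CI, and `n_snps = 1`.
#' @export
wald_ratio <- function(x, gene_id = NA_character_, outcome_id = NA_character_,
                       second_order = FALSE) {
  x <- tibble::as_tibble(x)
  stopifnot(nrow(x) == 1)
  rs <- ratio_stats(x)
  se <- rs$se
  if (second_order) {
    se <- sqrt(x$se_out^2 / x$beta_exp^2 +
                 x$beta_out^2 * x$se_exp^2 / x$beta_exp^4)
  }
  mr_estimate_row(gene_id, outcome_id, "wald_ratio", rs$ratio, se, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-instrument Wald ratios `r_i` with weights `1/se_i^2` where
#' `se_i` is the delta-method ratio SE. The fixed-effect SE is
#' `sqrt(1 / sum(w_i))`; the multiplicative-random-effects model (the
#' default) inflates it by `sqrt(max(1, Q/(k-1)))`, allowing for
#' heterogeneity between SNPs while never deflating below the fixed-effect
#' SE.
#'
#' @param x Harmonized-instrument tibble with at least 2 rows.
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @inheritParams wald_ratio
#' @return A one-row estimate tibble (`method` `"ivw_mre"` or `"ivw_fe"`).
#' @export
ivw <- function(x, mode = c("multiplicative_random", "fixed"),
                gene_id = NA_character_, outcome_id = NA_character_) {
  mode <- match.arg(mode)
  x <- tibble::as_tibble(x)
  if (nrow(x) < 2) {
    abort_domain("ivw requires >= 2 instruments; use wald_ratio for one")
  }
  rs <- ratio_stats(x)
  w <- 1 / rs$se^2
  est <- sum(w * rs$ratio) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  k <- nrow(x)
  q <- sum(w * (rs$ratio - est)^2)
  if (mode == "fixed") {
    mr_estimate_row(gene_id, outcome_id, "ivw_fe", est, se_fe, k)
  } else {
    se_mre <- se_fe * sqrt(max(1, q / (k - 1)))
    mr_estimate_row(gene_id, outcome_id, "ivw_mre", est, se_mre, k)
  }
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_i (r_i - r_hat)^2` over per-instrument ratios with
#' inverse-variance weights, compared to a chi-square distribution on
#' `k - 1` degrees of freedom.
#'
#' @inheritParams ivw
#' @return One-row tibble with `q`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(x) {
  x <- tibble::as_tibble(x)
  if (nrow(x) < 2) abort_domain("cochran_q requires >= 2 instruments")
  rs <- ratio_stats(x)
  w <- 1 / rs$se^2
  est <- sum(w * rs$ratio) / sum(w)
  q <- sum(w * (rs$ratio - est)^2)
  df <- nrow(x) - 1
  tibble::tibble(q = q, q_df = df, q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting every instrument so its
#' exposure effect is positive. A non-zero intercept indicates directional
#' horizontal pleiotropy. The p-value is two-sided normal.
#'
#' @inheritParams ivw
#' @return One-row tibble with `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`, `egger_slope`, and `computable` (`FALSE`, with
#'   `NA` statistics, when fewer than 3 instruments are available).
#' @export
egger_intercept <- function(x) {
  x <- tibble::as_tibble(x)
  if (nrow(x) < 3) {
    return(tibble::tibble(
      egger_intercept = NA_real_, egger_intercept_se = NA_real_,
      egger_intercept_pval = NA_real_, egger_slope = NA_real_,
      computable = FALSE
    ))
  }
  flip <- sign(x$beta_exp)
  bx <- x$beta_exp * flip
  by <- x$beta_out * flip
  fit <- stats::lm(by ~ bx, weights = 1 / x$se_out^2)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    egger_intercept = sm[1, 1],
    egger_intercept_se = sm[1, 2],
    egger_intercept_pval = two_sided_p(sm[1, 1] / sm[1, 2]),
    egger_slope = sm[2, 1],
    computable = TRUE
  )
}

#' MR-Steiger directionality filter
#'
#' For each instrument, compares the variance it explains in the exposure
#' (`r2_exp`, from [compute_pve()]) with the variance it explains in the
#' outcome (`r2_out = z^2 / (z^2 + n_out)` with `z = beta_out / se_out`, an
#' observed-scale approximation also used for binary outcomes). A valid
#' instrument must explain strictly more variance in the exposure than in
#' the outcome; instruments failing this are removed as directionally
#' ambiguous. The Steiger p-value tests the difference of the two
#' Fisher-transformed correlations across the two independent studies.
#'
#' @inheritParams ivw
#' @return A list with `instruments` (the retained subset of `x`) and
#'   `steiger`, a per-variant tibble with `r2_exp`, `r2_out`,
#'   `correct_direction` and `steiger_pval`.
#' @export
steiger_filter <- function(x) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    return(list(instruments = x, steiger = tibble::tibble(
      variant_id = character(), r2_exp = double(), r2_out = double(),
      correct_direction = logical(), steiger_pval = double()
    )))
  }
  r2_exp <- compute_pve(x$beta_exp, x$se_exp, x$n_exp)
  # z^2 / (z^2 + n) with z = beta/se, written as the identical pve form so
  # the exposure/outcome comparison uses one code path
  r2_out <- compute_pve(x$beta_out, x$se_out, x$n_out)
  zdiff <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (x$n_exp - 3) + 1 / (x$n_out - 3))
  res <- tibble::tibble(
    variant_id = x$variant_id,
    r2_exp = r2_exp,
    r2_out = r2_out,
    correct_direction = r2_exp > r2_out,
    steiger_pval = two_sided_p(zdiff)
  )
  list(instruments = x[res$correct_direction, , drop = FALSE], steiger = res)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error level (default 0.05).
#' @param m Number of tests, at least 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    abort_domain("bonferroni_threshold requires m >= 1")
  }
  alpha / m
}

#' Fit a gene-level MR model with diagnostics
#'
#' Routes one instrument to [wald_ratio()] and two or more to [ivw()], and
#' attaches Cochran's Q and the MR-Egger intercept where enough instruments
#' exist. Returns an `mr_fit` object with [generics::tidy()] /
#' [generics::glance()] methods and a [ggplot2::autoplot()] scatter.
#'
#' @inheritParams ivw
#' @param mode IVW mode when 2+ instruments are present.
#' @return An object of class `mr_fit`.
#' @export
fit_mr <- function(x, mode = c("multiplicative_random", "fixed"),
                   gene_id = NA_character_, outcome_id = NA_character_) {
  mode <- match.arg(mode)
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) abort_domain("fit_mr requires at least one instrument")
  est <- if (nrow(x) == 1) {
    wald_ratio(x, gene_id = gene_id, outcome_id = outcome_id)
  } else {
    ivw(x, mode = mode, gene_id = gene_id, outcome_id = outcome_id)
  }
  het <- if (nrow(x) >= 2) cochran_q(x) else
    tibble::tibble(q = NA_real_, q_df = NA_integer_, q_pval = NA_real_)
  structure(
    list(estimate = est, instruments = x, heterogeneity = het,
         egger = egger_intercept(x)),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(
    "MR fit (%s): %s -> %s\n  OR %.3f (95%% CI %.3f-%.3f), p = %.3g, %d SNP(s)\n",
    e$method, e$gene_id, e$outcome_id, e$or_, e$ci_low, e$ci_high, e$pval,
    e$n_snps
  ))
  invisible(x)
}

#' Tidy an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return The one-row estimate tibble.
#' @export
tidy.mr_fit <- function(x, ...) x$estimate

#' One-row model summary of an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return Tibble with instrument count, heterogeneity and pleiotropy
#'   diagnostics.
#' @export
glance.mr_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_snps = nrow(x$instruments)),
    x$heterogeneity,
    x$egger[, c("egger_intercept", "egger_intercept_pval", "computable")]
  )
}

#' Reverse Mendelian randomization
#'
#' Tests the disease -> expression direction: selects instruments from the
#' disease summary statistics under the same criteria as forward selection,
#' harmonizes them against the gene's eQTL associations as outcome, applies
#' the Steiger directionality filter in this direction (a disease
#' instrument must explain more disease variance than expression variance,
#' so signals that are merely the forward expression -> disease path seen
#' from the other side are excluded), and estimates via IVW (Wald ratio
#' with a single instrument). A reverse p-value below `alpha` flags the
#' gene as bidirectional.
#'
#' @param disease Sumstats tibble with the disease as trait.
#' @param eqtl Sumstats tibble of the gene's eQTL associations.
#' @param gene One-row gene-region tibble.
#' @param ld LD matrix for the region.
#' @param p_max,maf_min,r2_max,window_kb,f_min Selection thresholds, as in
#'   [select_instruments()].
#' @param mode IVW mode.
#' @param alpha Significance level for the bidirectional call (default 0.05).
#' @return One-row tibble: the reverse estimate plus `testable` and
#'   `bidirectional` flags. When the disease has no selectable instrument
#'   the estimate columns are `NA` and `testable` is `FALSE`.
#' @export
reverse_mr <- function(disease, eqtl, gene, ld,
                       p_max = 5e-8, maf_min = 0.01, r2_max = 0.001,
                       window_kb = 10000, f_min = 10,
                       mode = c("multiplicative_random", "fixed"),
                       alpha = 0.05) {
  mode <- match.arg(mode)
  out_id <- paste0("expression:", gene$gene_id)
  disease_id <- trait_id(disease)
  not_testable <- function() {
    est <- mr_estimate_row(disease_id, out_id, "none", NA_real_, NA_real_, 0L)
    est$pval <- NA_real_
    est$or_ <- NA_real_; est$ci_low <- NA_real_; est$ci_high <- NA_real_
    est$testable <- FALSE
    est$bidirectional <- FALSE
    est
  }
  disease <- tibble::as_tibble(disease)
  # restrict the disease scan to the gene's region (the LD matrix's span)
  region_ids <- colnames(ld)
  disease <- disease[disease$variant_id %in% region_ids, , drop = FALSE]
  insts <- select_instruments(disease, gene, ld, p_max = p_max,
                              maf_min = maf_min, r2_max = r2_max,
                              window_kb = window_kb, f_min = f_min)
  if (nrow(insts) == 0) return(not_testable())
  eq <- tibble::as_tibble(eqtl)
  if ("gene_id" %in% names(eq)) eq <- eq[eq$gene_id == gene$gene_id, , drop = FALSE]
  harm <- harmonize_sumstats(insts, eq)
  if (nrow(harm) == 0) return(not_testable())
  # directionality guard: a disease instrument must explain more disease
  # variance than expression variance, otherwise the "reverse" signal is
  # just the forward expression->disease path seen from the other side
  harm <- steiger_filter(harm)$instruments
  if (nrow(harm) == 0) return(not_testable())
  est <- if (nrow(harm) == 1) {
    wald_ratio(harm, gene_id = disease_id, outcome_id = out_id)
  } else {
    ivw(harm, mode = mode, gene_id = disease_id, outcome_id = out_id)
  }
  est$testable <- TRUE
  est$bidirectional <- est$pval < alpha
  est
}
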