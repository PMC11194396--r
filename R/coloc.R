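# Bayesian colocalization with approximate Bayes factors under the
# single-causal-variant assumption. Hypotheses over a shared region:
#   H0 no association with either trait; H1/H2 association with one trait
#   only; H3 both traits, distinct causal variants; H4 both traits, one
#   shared causal variant.

#' Log approximate Bayes factor for one association
#'
#' Wakefield-style asymptotic Bayes factor comparing a normal prior on the
#' effect (variance `w`) against the point null, from an estimate and its
#' standard error: with `v = se^2`, shrinkage `r = w/(v + w)` and
#' `z = beta/se`, the log ABF is `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @param w Prior effect variance (e.g. `0.15^2` for quantitative traits,
#'   `0.2^2` for binary traits on the log-odds scale).
#' @return Numeric vector of log Bayes factors.
#' @export
log_abf <- function(beta, se, w) {
  if (any(se <= 0)) abort_domain("log_abf requires se > 0")
  if (any(w <= 0)) abort_domain("log_abf requires w > 0")
  v <- se^2
  r <- w / (v + w)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalization posterior probabilities for a gene region
#'
#' Computes PPH0-PPH4 from harmonized per-variant summary statistics of two
#' traits over the same ordered variant set, assuming at most one causal
#' variant per trait. Per-variant log ABFs are combined into the five
#' hypothesis weights (H3 sums over ordered pairs of distinct variants; H4
#' over shared variants) entirely in log space via log-sum-exp, then
#' normalized.
#'
#' @param x Harmonized tibble (see [harmonize_sumstats()]) with columns
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`; one row per shared variant.
#' @param p1,p2 Prior probability that a given variant is causal for the
#'   exposure (resp. outcome) only (defaults 1e-4).
#' @param p12 Prior probability that a given variant is causal for both
#'   traits (default 1e-5).
#' @param w_exp,w_out Prior effect variances per trait; defaults `0.15^2`
#'   (quantitative exposure) and `0.2^2` (binary outcome log-odds).
#' @return A one-row `coloc_posterior` tibble with `pph0` ... `pph4`,
#'   `pph34 = pph3 + pph4`, and `n_variants`.
#' @export
coloc_posteriors <- function(x, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             w_exp = 0.15^2, w_out = 0.2^2) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) abort_domain("coloc_posteriors requires >= 1 shared variant")
  if (!(p1 > 0 && p2 > 0 && p12 > 0 && p1 + p2 + p12 < 1)) {
    abort_domain("priors must be positive with p1 + p2 + p12 < 1")
  }
  l1 <- log_abf(x$beta_exp, x$se_exp, w_exp)
  l2 <- log_abf(x$beta_out, x$se_out, w_out)

  s1 <- logsumexp(l1)            # log sum_i ABF1_i
  s2 <- logsumexp(l2)            # log sum_j ABF2_j
  s12 <- logsumexp(l1 + l2)      # log sum_i ABF1_i * ABF2_i

  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = if (nrow(x) > 1) log(p1) + log(p2) + logdiffexp(s1 + s2, s12) else -Inf,
    h4 = log(p12) + s12
  )
  post <- exp(lh - logsumexp(lh))
  post <- post / sum(post)
  out <- tibble::tibble(
    pph0 = post[["h0"]], pph1 = post[["h1"]], pph2 = post[["h2"]],
    pph3 = post[["h3"]], pph4 = post[["h4"]],
    pph34 = post[["h3"]] + post[["h4"]],
    n_variants = nrow(x)
  )
  class(out) <- c("coloc_posterior", class(out))
  out
}

#' Colocalization decision rule
#'
#' A gene region is considered to show evidence of a shared or overlapping
#' causal signal when `pph3 + pph4 >= threshold` (inclusive).
#'
#' @param post A `coloc_posterior` row from [coloc_posteriors()].
#' @param threshold Decision threshold on `pph3 + pph4` (default 0.8).
#' @return Logical scalar.
#' @export
coloc_decision <- function(post, threshold = 0.8) {
  (post$pph3 + post$pph4) >= threshold
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat(sprintf(
    "Colocalization posteriors over %d variant(s):\n  PPH0 %.3f  PPH1 %.3f  PPH2 %.3f  PPH3 %.3f  PPH4 %.3f\n",
    x$n_variants, x$pph0, x$pph1, x$pph2, x$pph3, x$pph4
  ))
  invisible(x)
}

#' Bar chart of colocalization posteriors
#'
#' @param object A `coloc_posterior` row.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coloc_posterior <- function(object, ...) {
  df <- tibble::tibble(
    hypothesis = factor(paste0("PPH", 0:4), levels = paste0("PPH", 0:4)),
    posterior = c(object$pph0, object$pph1, object$pph2, object$pph3,
                  object$pph4)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = "Posterior probability",
      title = "Colocalization hypothesis posteriors"
    ) +
    ggplot2::theme_minimal()
}
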