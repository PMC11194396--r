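# Small in-code fixtures and independent oracles used across the suite.

make_assoc <- function(variant_id = "rs1", chrom = "1", pos = 100L,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-9,
                       n = 30000) {
  tibble::tibble(
    variant_id = variant_id, chrom = chrom, pos = as.integer(pos),
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval, n = n
  )
}

make_harm <- function(beta_exp, se_exp, beta_out, se_out,
                      n_exp = 30000, n_out = 50000,
                      variant_id = paste0("rs", seq_along(beta_exp))) {
  tibble::tibble(
    variant_id = variant_id,
    chrom = "1", pos = seq_along(beta_exp) * 1000L,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp,
    eaf_exp = 0.3, pval_exp = 1e-10, n_exp = n_exp,
    beta_out = beta_out, se_out = se_out,
    eaf_out = 0.3, pval_out = 0.5, n_out = n_out
  )
}

# random symmetric r^2 matrix with unit diagonal, via a correlation matrix
random_ld <- function(ids) {
  m <- length(ids)
  a <- matrix(stats::rnorm(m * m), m)
  s <- stats::cov2cor(crossprod(a) + diag(m) * 0.5)
  r2 <- s^2
  dimnames(r2) <- list(ids, ids)
  r2
}

# Independent clumping oracle: scan variants in p-value priority order
# (ties: position, then id) and retain those not conflicting with an
# already-retained variant.
clump_oracle <- function(x, ld, r2_max, window_kb) {
  x <- x[order(x$pval, x$pos, x$variant_id), , drop = FALSE]
  retained <- integer(0)
  for (i in seq_len(nrow(x))) {
    conflict <- FALSE
    for (j in retained) {
      if (abs(x$pos[i] - x$pos[j]) <= window_kb * 1000 &&
          ld[x$variant_id[i], x$variant_id[j]] >= r2_max) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) retained <- c(retained, i)
  }
  x$variant_id[retained]
}

# Independent weighted-least-squares solve via normal equations
wls_oracle <- function(y, x, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  coef <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% coef
  sigma2 <- sum(w * resid^2) / (length(y) - 2)
  se <- unname(sqrt(diag(sigma2 * solve(XtWX))))
  list(intercept = unname(coef[1]), slope = unname(coef[2]),
       intercept_se = se[1])
}

# Exhaustive-enumeration colocalization oracle for tiny regions: weight
# every single-causal-variant configuration per trait explicitly.
coloc_oracle <- function(beta1, se1, beta2, se2,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w1 = 0.15^2, w2 = 0.2^2) {
  abf <- function(b, s, w) {
    r <- w / (s^2 + w)
    exp(0.5 * (log(1 - r) + r * (b / s)^2))
  }
  m <- length(beta1)
  a1 <- vapply(seq_len(m), function(i) abf(beta1[i], se1[i], w1), 1)
  a2 <- vapply(seq_len(m), function(i) abf(beta2[i], se2[i], w2), 1)
  w_h0 <- 1
  w_h1 <- sum(p1 * a1)
  w_h2 <- sum(p2 * a2)
  w_h3 <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) w_h3 <- w_h3 + p1 * p2 * a1[i] * a2[j]
    }
  }
  w_h4 <- sum(p12 * a1 * a2)
  w_all <- c(w_h0, w_h1, w_h2, w_h3, w_h4)
  stats::setNames(w_all / sum(w_all), paste0("pph", 0:4))
}
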