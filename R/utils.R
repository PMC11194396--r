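# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn inform
NULL

abort_config <- function(msg) rlang::abort(msg, class = "targetmr_config_error")
abort_domain <- function(msg) rlang::abort(msg, class = "targetmr_domain_error")

VALID_ALLELES <- c("A", "C", "G", "T")

complement_allele <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# log(exp(a) + exp(b) + ...) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; clamps tiny negative mass from rounding
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# 97.5% normal quantile used for all reported confidence intervals
Z975 <- 1.959964

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

# per-gene RNG stream: reproducible independently of gene iteration order,
# always below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483563)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
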