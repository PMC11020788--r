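# Hypothesis testing for H0: beta = 0 (no temporal shape).
#
# The test statistic is the proportional SSR reduction
# B = (SSR0 - SSR1) / SSR0. Under Gaussian null data, conditional on the cone
# projection landing on a face of dimension d, B is Beta(d/2, (n - q - d)/2);
# marginally B follows the mixture over the random face dimension, with a
# point mass at 0 when the active set is empty. Face-dimension weights come
# from estimate_mixture_weights().

#' Shape statistic B
#'
#' `B = (SSR0 - SSR1) / SSR0`: the fraction of null residual variation
#' explained by the shape-constrained term. 0 iff the cone adds nothing; 1 for
#' a perfect constrained fit. Returns `NA` for a degenerate fit (`SSR0 = 0`),
#' which callers map to p = 1.
#'
#' @param fit a [fit_lamm()] object (or any list with `ssr0` and `ssr1`).
#' @return B in \[0, 1\], or NA if `ssr0` is 0.
#' @export
shape_statistic <- function(fit) {
  if (is.null(fit$ssr0) || is.null(fit$ssr1)) stop("need 'ssr0' and 'ssr1'")
  if (fit$ssr0 <= 0) return(NA_real_)
  min(max((fit$ssr0 - fit$ssr1) / fit$ssr0, 0), 1)
}

#' Mixture-of-beta p-value for a shape statistic
#'
#' `p = sum_d w_d * Pr(Beta(d/2, (n - q - d)/2) > stat)` over active-face
#' dimensions d >= 1; the d = 0 component is a point mass at B = 0 and
#' contributes no survival mass for stat > 0. At stat = 0 the conservative
#' p = 1 is returned (the pipeline resolves this atom with a seeded
#' randomised draw instead; see the package vignette).
#'
#' @param stat shape statistic in \[0, 1\] (NA gives p = 1).
#' @param null a `"beta_mixture"` from [estimate_mixture_weights()].
#' @param n number of observations (cells).
#' @param q rank of the unconstrained columns.
#' @return p-value in \[0, 1\].
#' @export
pattern_pvalue <- function(stat, null, n, q) {
  if (is.na(stat)) return(1)
  if (stat < -1e-9 || stat > 1 + 1e-9) stop("'stat' must lie in [0, 1]")
  stat <- min(max(stat, 0), 1)
  w <- null$weights
  m <- length(w) - 1L
  if (n <= q + m) stop("need n > q + m for the beta null")
  if (stat <= 0) return(1)
  d <- seq_len(m)
  surv <- stats::pbeta(stat, d / 2, (n - q - d) / 2, lower.tail = FALSE)
  max(sum(w[-1L] * surv), 1e-300)
}

# Atom-resolved pattern p-value used by the pipeline: at B = 0 (empty active
# set, probability w0 under the null) draw p uniformly on (1 - w0, 1) so the
# pattern p-value is exactly Uniform(0,1) under the null. Consumes one draw
# from the current RNG stream.
.pattern_pvalue_random <- function(stat, null, n, q) {
  if (is.na(stat) || stat <= 1e-12)
    return(1 - null$weights[[1L]] * stats::runif(1))
  pattern_pvalue(stat, null, n, q)
}

#' Cauchy (ACAT) combination of dependent p-values
#'
#' `T = sum_i w_i tan((0.5 - p_i) pi)`; combined p = `0.5 - atan(T)/pi`.
#' P-values below 1e-15 enter through the asymptotically exact tail
#' `1/(p * pi)` (the tangent evaluated in extended precision); p-values at the
#' upper end are clipped to 1 - 1e-15. The result is floored at 1e-300.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param weights combination weights (default equal, summing to 1).
#' @return combined p-value.
#' @export
cauchy_combine <- function(p, weights = NULL) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  w <- weights %||% rep(1 / length(p), length(p))
  w <- w / sum(w)
  p_hi <- pmin(p, 1 - 1e-15)
  small <- p_hi < 1e-15
  tanv <- numeric(length(p))
  tanv[!small] <- tan((0.5 - p_hi[!small]) * pi)
  tanv[small] <- 1 / (pmax(p_hi[small], 1e-300) * pi)
  stat <- sum(w * tanv)
  max(0.5 - atan(stat) / pi, 1e-300)
}

#' Permutation-based false discovery rates
#'
#' Implements the empirical FDR from sample-level time permutations: with
#' observed p-values sorted increasingly and each permutation's null p-values
#' sorted increasingly,
#' `fdr_(g) = sum_{k<=g} sum_r I(P_(g)^obs > P_rk^null) / (R g)`,
#' clipped to \[0, 1\], monotonised with the reverse cumulative minimum along
#' the sorted order, and mapped back to the input gene order.
#'
#' @param p_obs observed p-values (length G).
#' @param p_null matrix of null p-values, one row per permutation (R x G), or
#'   a vector for R = 1.
#' @return FDR estimate per gene, in input order.
#' @export
permutation_fdr <- function(p_obs, p_null) {
  if (is.null(dim(p_null))) p_null <- matrix(p_null, nrow = 1L)
  G <- length(p_obs)
  if (ncol(p_null) != G)
    stop("shape mismatch: 'p_null' must have one column per observed p-value")
  if (any(!is.finite(p_obs)) || any(!is.finite(p_null)))
    stop("p-values must be finite")
  R <- nrow(p_null)
  ord <- order(p_obs)
  po <- p_obs[ord]
  num <- numeric(G)
  for (r in seq_len(R)) {
    ns <- sort(p_null[r, ])
    j <- 0L
    cnt <- integer(G)
    for (g in seq_len(G)) {
      while (j < G && ns[j + 1L] < po[g]) j <- j + 1L
      cnt[g] <- j
    }
    num <- num + pmin(cnt, seq_len(G))
  }
  fdr <- pmin(pmax(num / (R * seq_len(G)), 0), 1)
  fdr <- rev(cummin(rev(fdr)))
  out <- numeric(G)
  out[ord] <- fdr
  out
}
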