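#' Assign a temporal pattern from the four per-pattern fits
#'
#' For the linear model the call minimises AIC = 2k - 2 logL, where k counts
#' the estimated mean parameters (unconstrained columns plus active cone
#' coefficients) plus one for the residual variance; only active cone
#' coefficients count because the effective dimension of a shape-restricted
#' fit is the dimension of the face the projection lands on. For the mixed
#' model the marginal AIC is biased by the random effect, so the call
#' maximises the B-statistic instead. Ties are broken in the fixed order
#' growth, recession, peak, trough.
#'
#' @param fits list of four [fit_lamm()] objects, one per pattern (any order;
#'   matched by their `pattern` field).
#' @param method `"aic"` (linear fits) or `"bstat"` (mixed fits).
#' @return object of class `"pattern_call"`: list with `gene`, `pattern`
#'   (possibly `"none"`), `criterion` (named values per pattern), `method`.
#' @export
assign_pattern <- function(fits, method = c("aic", "bstat")) {
  method <- match.arg(method)
  pats <- vapply(fits, function(f) f$pattern, character(1))
  if (!setequal(pats, .patterns) || length(fits) != 4L)
    stop("'fits' must contain exactly one fit per pattern")
  fits <- fits[match(.patterns, pats)]

  if (method == "aic") {
    crit <- vapply(fits, function(f) {
      if (f$degenerate || !is.finite(f$loglik)) return(Inf)
      k <- f$q + length(f$active_set) + 1L
      2 * k - 2 * f$loglik
    }, numeric(1))
    pick <- if (all(!is.finite(crit))) "none"
            else .patterns[which.min(crit)]   # which.min takes first on ties
  } else {
    crit <- vapply(fits, function(f) {
      b <- shape_statistic(f)
      if (is.na(b)) 0 else b
    }, numeric(1))
    all_degen <- all(vapply(fits, function(f) f$ssr0 <= 0, logical(1)))
    pick <- if (all_degen || max(crit) <= 0) "none"
            else .patterns[which.max(crit)]
  }
  names(crit) <- .patterns
  structure(list(gene = fits[[1]]$gene, pattern = pick,
                 criterion = crit, method = method),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat("Pattern call (", x$method, "): ", x$pattern, "\n", sep = "")
  print(signif(x$criterion, 4))
  invisible(x)
}
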