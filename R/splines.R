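# M-, I- and C-spline bases on a time grid.
#
# M-splines of order k are nonnegative piecewise polynomials of degree k - 1
# that each integrate to one over the knot span. Their running integrals
# (I-splines) are monotone, rising from 0 at the first knot to 1 at the last;
# nonnegative combinations of I-splines are therefore nondecreasing curves.
# Integrating once more gives C-splines, which are convex and nondecreasing;
# nonnegative combinations (plus a free linear term) give convex curves, and
# negated columns give concave ones. These three families carry the four
# temporal patterns: growth/recession via I-splines, peak/trough via C-splines.

.check_knots <- function(knots) {
  if (length(knots) < 2L) stop("need at least 2 knots")
  if (anyDuplicated(knots)) stop("duplicate knots are not allowed")
  if (is.unsorted(knots)) stop("knots must be strictly increasing")
  as.numeric(knots)
}

# Boundary-augmented knot sequence: boundary knots repeated `order - 1` extra
# times so that n_basis = (#knots - 2) + order.
.augment_knots <- function(knots, order) {
  c(rep(knots[1], order - 1L), knots, rep(knots[length(knots)], order - 1L))
}

# Evaluate all order-`k` M-splines on augmented knots `tau` at points `x`
# via the order-1 definition and the printed order-k recursion.
.mspline_eval <- function(x, tau, k) {
  n_int <- length(tau) - 1L
  last <- tau[length(tau)]
  M <- matrix(0, length(x), n_int)
  for (l in seq_len(n_int)) {
    h <- tau[l + 1L] - tau[l]
    if (h > 0) {
      inside <- x >= tau[l] & (x < tau[l + 1L] | (x == last & tau[l + 1L] == last))
      M[inside, l] <- 1 / h
    }
  }
  ord <- 1L
  while (ord < k) {
    ord <- ord + 1L
    Mn <- matrix(0, length(x), length(tau) - ord)
    for (l in seq_len(ncol(Mn))) {
      den <- (ord - 1) * (tau[l + ord] - tau[l])
      if (den > 0)
        Mn[, l] <- ord * ((x - tau[l]) * M[, l] + (tau[l + ord] - x) * M[, l + 1L]) / den
    }
    M <- Mn
  }
  M
}

#' M-spline basis matrix
#'
#' @param x evaluation points, all within the knot range.
#' @param knots strictly increasing knot grid (first = min time, last = max).
#' @param order spline order k (order 1 = piecewise constant; each basis
#'   function integrates to 1 over the knot span).
#' @return length(x) x n_basis matrix, n_basis = length(knots) - 2 + order.
#' @export
mspline_basis <- function(x, knots, order = 2L) {
  knots <- .check_knots(knots)
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be >= 1")
  if (any(x < knots[1] | x > knots[length(knots)]))
    stop("evaluation points outside the knot range")
  tau <- .augment_knots(knots, order)
  B <- .mspline_eval(as.numeric(x), tau, order)
  colnames(B) <- paste0("M", seq_len(ncol(B)))
  B
}

# ---- exact integration of piecewise-polynomial bases ------------------------

# 7-point Gauss-Legendre nodes/weights on [-1, 1]; exact through degree 13,
# far beyond any order used here.
.gl7 <- local({
  x <- c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
         0.4058451513773972, 0.7415311855993945, 0.9491079123427585)
  w <- c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
         0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
         0.1294849661688697)
  list(x = x, w = w)
})

# Cumulative integral from knots[1] to each point in `x` of the columns of the
# basis produced by `f` (a function of evaluation points). Segments are the
# knot intervals, on which every column is a single polynomial.
.cum_integral <- function(f, x, knots) {
  ux <- sort(unique(c(knots, x)))
  nseg <- length(ux) - 1L
  a <- ux[-length(ux)]; b <- ux[-1L]
  half <- (b - a) / 2; mid <- (a + b) / 2
  pts <- as.vector(outer(.gl7$x, half) + rep(mid, each = 7L))
  vals <- f(pts)                               # (7 * nseg) x m
  m <- ncol(vals)
  seg <- matrix(0, nseg, m)
  for (s in seq_len(nseg)) {
    rows <- ((s - 1L) * 7L + 1L):(s * 7L)
    seg[s, ] <- half[s] * (.gl7$w %*% vals[rows, , drop = FALSE])
  }
  cum <- rbind(0, apply(seg, 2, cumsum))
  cum <- matrix(cum, nrow = nseg + 1L)
  cum[match(x, ux), , drop = FALSE]
}

#' I-spline basis matrix (integrated M-splines)
#'
#' Columns are nondecreasing, equal to 0 at the first knot and 1 at the last.
#'
#' @inheritParams mspline_basis
#' @param order order of the underlying M-splines (the I-spline columns are
#'   piecewise polynomials of degree `order`).
#' @export
ispline_basis <- function(x, knots, order = 2L) {
  knots <- .check_knots(knots)
  if (any(x < knots[1] | x > knots[length(knots)]))
    stop("evaluation points outside the knot range")
  B <- .cum_integral(function(p) mspline_basis(p, knots, order),
                     as.numeric(x), knots)
  colnames(B) <- paste0("I", seq_len(ncol(B)))
  B
}

#' C-spline basis matrix (integrated I-splines)
#'
#' Columns are nondecreasing and convex, equal to 0 at the first knot.
#'
#' @inheritParams ispline_basis
#' @export
cspline_basis <- function(x, knots, order = 2L) {
  knots <- .check_knots(knots)
  if (any(x < knots[1] | x > knots[length(knots)]))
    stop("evaluation points outside the knot range")
  B <- .cum_integral(function(p) ispline_basis(p, knots, order),
                     as.numeric(x), knots)
  colnames(B) <- paste0("C", seq_len(ncol(B)))
  B
}

.patterns <- c("growth", "recession", "peak", "trough")

#' Assemble the per-pattern design pair (W0, S)
#'
#' Growth and recession use I-spline cone columns with only an intercept in
#' the unconstrained part; peak and trough use C-spline cone columns with
#' intercept and a free linear term. Recession is the growth design with the
#' cone columns negated, and trough likewise mirrors peak, so a single
#' cone-projection code path (beta >= 0) serves all four shapes.
#'
#' Knots default to the distinct observed time values (the number of knots
#' equals the number of time points); when `n_knots` differs, knots are placed
#' equally spaced over the observed range. Bases are evaluated once per
#' distinct time and broadcast to cells.
#'
#' @param time per-cell numeric time values.
#' @param pattern one of `"growth"`, `"recession"`, `"peak"`, `"trough"`.
#' @param n_knots number of knots (>= 3); NULL = number of distinct times.
#' @param order order of the underlying M-splines (default 2: quadratic
#'   I-splines and cubic C-splines).
#' @return object of class `"shape_design"`: list with `pattern`, `W0`, `S`,
#'   `knots`, `order`, `time`.
#' @export
build_design <- function(time, pattern, n_knots = NULL, order = 2L) {
  pattern <- match.arg(pattern, .patterns)
  time <- as.numeric(time)
  ut <- sort(unique(time))
  if (length(ut) < 3L) stop("need at least 3 distinct time points")
  n_knots <- n_knots %||% length(ut)
  if (n_knots < 3L) stop("'n_knots' must be >= 3")
  knots <- if (n_knots == length(ut)) ut
           else seq(min(ut), max(ut), length.out = n_knots)

  grid_basis <- switch(pattern,
    growth = , recession = ispline_basis(ut, knots, order),
    peak = , trough = cspline_basis(ut, knots, order))
  sign <- if (pattern %in% c("recession", "peak")) -1 else 1
  S <- sign * grid_basis[match(time, ut), , drop = FALSE]

  n <- length(time)
  W0 <- if (pattern %in% c("growth", "recession")) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind("(Intercept)" = rep(1, n), t = time)
  }
  structure(list(pattern = pattern, W0 = W0, S = S, knots = knots,
                 order = as.integer(order), time = time),
            class = "shape_design")
}

#' @export
print.shape_design <- function(x, ...) {
  cat("Shape design:", x$pattern, "\n")
  cat("  cone columns:", ncol(x$S), " free columns:", ncol(x$W0), "\n")
  cat("  knots:", paste(signif(x$knots, 4), collapse = ", "),
      " (M-spline order ", x$order, ")\n", sep = "")
  invisible(x)
}
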