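# Least-squares projection onto the convex cone {F a + S b : b >= 0}.
#
# The solver works on crossproducts (X'X, X'y, y'y) so the same code serves
# raw vectors, whitened mixed-model systems (where the whitened crossproducts
# have a closed form over sample blocks) and the reduced m-dimensional
# quadratic programs used for the mixture-weight simulation. Free columns are
# always in the working set; cone columns enter by an active-set ("hinge")
# ascent: add the most violating edge, drop edges whose coefficient goes
# negative, stop when Karush-Kuhn-Tucker conditions hold. The cone designs can
# be rank deficient (bases evaluated at T distinct times, broadcast to cells);
# a column whose addition makes the working system singular cannot improve the
# fit and is barred until the active set next shrinks.

.cone_fit_cp <- function(XtX, Xty, yty, q, max_iter = NULL) {
  p <- ncol(XtX)
  free <- seq_len(q)
  cone <- if (q < p) seq.int(q + 1L, p) else integer(0)
  m <- length(cone)
  max_iter <- max_iter %||% (50L * (m + 1L))

  quad_ssr <- function(idx, cf) {
    max(0, yty - 2 * sum(cf * Xty[idx]) +
          sum(cf * (XtX[idx, idx, drop = FALSE] %*% cf)))
  }

  if (q > 0L) {
    cf0 <- .chol_solve(XtX[free, free, drop = FALSE], Xty[free])
    if (is.null(cf0)) stop("free (unconstrained) columns are rank deficient")
    cf0 <- drop(cf0)
    ssr0 <- quad_ssr(free, cf0)
  } else {
    cf0 <- numeric(0)
    ssr0 <- max(0, yty)
  }

  gtol <- 1e-9 * sqrt(pmax(diag(XtX)[cone], 0) * max(yty, .Machine$double.xmin)) + 1e-14

  active <- integer(0)
  barred <- integer(0)
  cur_cf <- cf0
  cur_ssr <- ssr0
  iter <- 0L

  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("cone projection did not converge (active-set iteration limit)")
    idx <- c(free, active)
    grad <- Xty[cone] -
      if (length(idx)) drop(XtX[cone, idx, drop = FALSE] %*% cur_cf) else 0
    cand <- setdiff(which(grad > gtol), c(match(active, cone), match(barred, cone)))
    cand <- cand[!is.na(cand)]
    if (!length(cand)) break
    j <- cone[cand[which.max(grad[cand])]]     # ties: which.max takes lowest index

    trial <- c(active, j)
    repeat {
      idx2 <- c(free, trial)
      cf <- .chol_solve(XtX[idx2, idx2, drop = FALSE], Xty[idx2])
      if (is.null(cf)) { cf <- NULL; break }
      cf <- drop(cf)
      bneg <- which(cf[q + seq_along(trial)] < -1e-10)
      if (!length(bneg)) break
      worst <- bneg[which.min(cf[q + bneg])]
      trial <- trial[-worst]
      if (!length(trial)) { cf <- if (q > 0L) cf0 else numeric(0); break }
    }
    if (is.null(cf)) { barred <- c(barred, j); next }
    new_ssr <- quad_ssr(c(free, trial), cf)
    if (new_ssr < cur_ssr - 1e-12 * max(cur_ssr, yty, 1e-300)) {
      active <- trial
      cur_cf <- cf
      cur_ssr <- new_ssr
      barred <- integer(0)
    } else {
      barred <- c(barred, j)                   # no strict improvement: bar it
    }
  }

  coef <- numeric(p)
  coef[c(free, active)] <- cur_cf
  list(coef = coef, active = sort(match(active, cone)),
       ssr1 = cur_ssr, ssr0 = ssr0, coef0 = cf0)
}

#' Project a response onto a shape-constrained cone
#'
#' Computes the least-squares projection of `y` onto
#' `{X_free a + X_cone b : b >= 0}` by active-set ascent over the cone edges.
#' The fitted values are the unique projection; the residual is orthogonal to
#' the free columns and to every active cone column, and inactive cone columns
#' have nonpositive residual correlation.
#'
#' @param y numeric response vector.
#' @param X_free matrix of unconstrained columns (must have full column rank).
#' @param X_cone matrix of cone columns (coefficients constrained nonnegative).
#' @return list with `alpha` (free coefficients), `beta` (nonnegative cone
#'   coefficients), `fitted`, `residuals`, `active` (indices of strictly
#'   positive cone coefficients), `ssr1` (residual sum of squares of the
#'   projection) and `ssr0` (free-columns-only fit).
#' @export
cone_projection <- function(y, X_free, X_cone) {
  y <- as.numeric(y)
  X_free <- as.matrix(X_free)
  X_cone <- as.matrix(X_cone)
  if (nrow(X_free) != length(y) || nrow(X_cone) != length(y))
    stop("design rows must match length(y)")
  if (ncol(X_cone) < 1L) stop("need at least one cone column")
  X <- cbind(X_free, X_cone)
  fit <- .cone_fit_cp(crossprod(X), drop(crossprod(X, y)), sum(y^2),
                      q = ncol(X_free))
  q <- ncol(X_free)
  fitted <- drop(X %*% fit$coef)
  list(alpha = fit$coef[seq_len(q)],
       beta = fit$coef[-seq_len(q)],
       fitted = fitted,
       residuals = y - fitted,
       active = fit$active,
       ssr1 = fit$ssr1,
       ssr0 = fit$ssr0)
}

# ---- null face-dimension weights -------------------------------------------
#
# Under H0 the gradient of the cone block after projecting out the free
# columns is c ~ N(0, sigma^2 G) with G the Schur complement; the distribution
# of the active-face dimension d depends only on G. Draws are classified by
# vectorised enumeration over faces (increasing cardinality); draws that no
# regular face claims (possible when G is singular) fall back to the
# active-set solver itself.

.face_weights <- function(G, n_sim = 10000L, seed = 101L) {
  m <- ncol(G)
  with_seed(seed, {
    eg <- eigen(G, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    r <- sum(ev > 1e-12 * max(ev, 1e-300))
    Z <- matrix(stats::rnorm(n_sim * r), n_sim, r)
    Cmat <- Z %*% (t(eg$vectors[, seq_len(r), drop = FALSE]) * sqrt(ev[seq_len(r)]))
    tolv <- 1e-8 * sqrt(pmax(diag(G), 1e-300))

    d <- rep(NA_integer_, n_sim)
    open <- which(apply(Cmat <= rep(tolv, each = n_sim), 1, all))
    d[open] <- 0L
    if (m <= 14L) {
      for (s in seq_len(m)) {
        if (!anyNA(d)) break
        for (A in utils::combn(m, s, simplify = FALSE)) {
          un <- which(is.na(d))
          if (!length(un)) break
          GA <- G[A, A, drop = FALSE]
          R <- tryCatch(chol(GA), error = function(e) NULL)
          if (is.null(R) || min(diag(R)) < 1e-7 * max(diag(R))) next
          Beta <- Cmat[un, A, drop = FALSE] %*% chol2inv(R)
          ok <- rowSums(Beta < -1e-10) == 0L
          if (s < m) {
            Ac <- setdiff(seq_len(m), A)
            Grad <- Cmat[un, Ac, drop = FALSE] - Beta %*% G[A, Ac, drop = FALSE]
            ok <- ok & rowSums(Grad > rep(tolv[Ac], each = length(un))) == 0L
          }
          d[un[ok]] <- s
        }
      }
    }
    for (i in which(is.na(d))) {
      fit <- .cone_fit_cp(G, Cmat[i, ], sum(Cmat[i, ]^2) + 1, q = 0L)
      d[i] <- length(fit$active)
    }
    w <- tabulate(d + 1L, nbins = m + 1L) / n_sim
    names(w) <- 0:m
    w
  })
}

#' Estimate mixture-of-beta null weights for a shape design
#'
#' Simulates the null distribution of the active-face dimension of the cone
#' projection: standard-normal responses are (implicitly) projected onto the
#' cone after removing the unconstrained columns, and the relative frequency
#' of each active-set size d becomes the weight of the Beta component with
#' first shape d/2. For the mixed model, pass `sample_id` and `lambda` so the
#' design geometry is the whitened one.
#'
#' @param design a [build_design()] object.
#' @param sample_id optional per-cell sample labels (mixed model).
#' @param lambda variance ratio sigma_u^2 / sigma_e^2 used for whitening.
#' @param covariates optional per-cell covariate matrix (free columns).
#' @param n_sim Monte-Carlo draws (>= 1000; default 10,000).
#' @param seed RNG seed for the weight simulation (documented default 101).
#' @return object of class `"beta_mixture"`: list with `weights` (named
#'   probabilities over d = 0..m), `m`, `n_sim`, `seed`.
#' @export
estimate_mixture_weights <- function(design, sample_id = NULL, lambda = 0,
                                     covariates = NULL, n_sim = 10000L,
                                     seed = 101L) {
  stopifnot(inherits(design, "shape_design"))
  if (n_sim < 1000L) stop("'n_sim' must be at least 1000")
  Xf <- cbind(design$W0, covariates)
  X <- cbind(Xf, design$S)
  q <- ncol(Xf)
  XtX <- crossprod(X)
  if (!is.null(sample_id) && lambda > 0) {
    sample_id <- factor(sample_id)
    ind <- stats::model.matrix(~ sample_id - 1)
    BX <- crossprod(ind, X)
    n_j <- as.numeric(colSums(ind))
    XtX <- .whiten_xtx(XtX, BX, n_j, lambda)
  }
  G <- .schur_cone(XtX, q)
  structure(list(weights = .face_weights(G, n_sim, seed),
                 m = ncol(design$S), n_sim = n_sim, seed = seed,
                 pattern = design$pattern, lambda = lambda),
            class = "beta_mixture")
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat("Beta-mixture null (", x$pattern %||% "design", ", lambda = ",
      signif(x$lambda %||% 0, 3), ")\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

# Schur complement of the cone block after eliminating the free columns.
.schur_cone <- function(XtX, q) {
  p <- ncol(XtX)
  cone <- seq.int(q + 1L, p)
  if (q == 0L) return(XtX)
  Aff <- XtX[seq_len(q), seq_len(q), drop = FALSE]
  Afc <- XtX[seq_len(q), cone, drop = FALSE]
  XtX[cone, cone, drop = FALSE] - crossprod(Afc, solve(Aff, Afc))
}

# Whitened crossproducts: K^{-1} = I - (lambda / (1 + lambda n_j)) J within
# each sample block, so X' K^{-1} X needs only per-block column sums.
.whiten_xtx <- function(XtX, BX, n_j, lambda) {
  if (lambda <= 0) return(XtX)
  cj <- lambda / (1 + lambda * n_j)
  XtX - crossprod(BX * sqrt(cj))
}

.whiten_xty <- function(Xty, BX, By, n_j, lambda) {
  if (lambda <= 0) return(Xty)
  cj <- lambda / (1 + lambda * n_j)
  Xty - drop(crossprod(BX, cj * By))
}

.whiten_yty <- function(yty, By, n_j, lambda) {
  if (lambda <= 0) return(yty)
  yty - sum(lambda / (1 + lambda * n_j) * By^2)
}
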