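# Linear additive mixed model with a shape-constrained spline term.
#
# Model per gene: y = W0 a0 + W a + S b + u + e, b >= 0, where u is a
# per-sample random effect (covariance sigma_u^2 * Sigma, Sigma block-diagonal
# all-ones over samples) and e is iid N(0, sigma_e^2). Writing
# lambda = sigma_u^2 / sigma_e^2, cov(y)/sigma_e^2 = K = lambda Sigma + I.
# Each block of K has eigenvalue (lambda n_j + 1) on the constant direction and
# 1 elsewhere, so K^{-1/2} acts in closed form per block and the whitened
# system is an ordinary cone-constrained regression.

# Profile Gaussian log-likelihood of the null mean model over lambda, using
# only crossproducts and per-block sums; O(M q^2) per evaluation.
.profile_lambda <- function(XtX0, BX0, n_j, Xty0, By, yty, n,
                            upper = 1e3, tol = 1e-6) {
  q <- ncol(XtX0)
  ll <- function(lambda) {
    A <- .whiten_xtx(XtX0, BX0, n_j, lambda)
    rhs <- .whiten_xty(Xty0, BX0, By, n_j, lambda)
    yl <- .whiten_yty(yty, By, n_j, lambda)
    cf <- .chol_solve(A, rhs)
    if (is.null(cf)) return(-Inf)
    rss <- max(yl - 2 * sum(cf * rhs) + sum(cf * (A %*% cf)),
               1e-12 * max(yl, 1e-300))
    -0.5 * n * log(rss / n) - 0.5 * sum(log1p(lambda * n_j))
  }
  at0 <- ll(0)
  opt <- stats::optimize(function(lg) ll(exp(lg)),
                         lower = log(1e-6), upper = log(upper),
                         maximum = TRUE, tol = tol)
  if (!is.finite(opt$objective) || opt$objective <= at0 + 1e-10) {
    lambda <- 0; obj <- at0
  } else {
    lambda <- exp(opt$maximum); obj <- opt$objective
  }
  # residual variance at the chosen lambda
  A <- .whiten_xtx(XtX0, BX0, n_j, lambda)
  rhs <- .whiten_xty(Xty0, BX0, By, n_j, lambda)
  yl <- .whiten_yty(yty, By, n_j, lambda)
  cf <- .chol_solve(A, rhs)
  rss <- max(yl - 2 * sum(cf * rhs) + sum(cf * (A %*% cf)), 0)
  sigma2 <- rss / n
  list(lambda = lambda, sigma2_e = sigma2, sigma2_u = lambda * sigma2,
       loglik = obj - 0.5 * n * (log(2 * pi) + 1))
}

#' Estimate variance components of the null mixed model
#'
#' Maximizes the profile Gaussian likelihood of the null mean model (the
#' unconstrained columns only) over the variance ratio
#' `lambda = sigma_u^2 / sigma_e^2 >= 0`. When every sample contains a single
#' cell the ratio is unidentifiable and `lambda = 0` is returned with a
#' warning.
#'
#' @param y numeric response (one gene's expression).
#' @param X0 matrix of null-model columns (intercept, optional time and
#'   covariates).
#' @param sample_id per-cell sample labels.
#' @return list with `sigma2_e`, `sigma2_u`, `lambda`, `loglik`.
#' @export
estimate_variance_components <- function(y, X0, sample_id) {
  y <- as.numeric(y)
  X0 <- as.matrix(X0)
  sample_id <- factor(sample_id)
  n_j <- as.numeric(table(sample_id))
  if (all(n_j == 1)) {
    warning("one cell per sample everywhere: lambda is unidentifiable, returning 0")
    cf <- stats::lm.fit(X0, y)
    s2 <- sum(cf$residuals^2) / length(y)
    return(list(sigma2_e = s2, sigma2_u = 0, lambda = 0,
                loglik = -0.5 * length(y) * (log(2 * pi * s2) + 1)))
  }
  ind <- stats::model.matrix(~ sample_id - 1)
  vc <- .profile_lambda(crossprod(X0), crossprod(ind, X0), n_j,
                        drop(crossprod(X0, y)), drop(crossprod(ind, y)),
                        sum(y^2), length(y))
  if (!is.finite(vc$loglik)) stop("non-finite profile likelihood")
  vc[c("sigma2_e", "sigma2_u", "lambda", "loglik")]
}

#' Whiten a mixed-model system by the closed-form block transform
#'
#' Applies `U^{-1} = K^{-1/2}` blockwise, where within sample block j the
#' matrix `K = lambda J + I` has eigenvalue `lambda n_j + 1` on the constant
#' direction (eigenvector `1/sqrt(n_j)`) and 1 on its orthogonal complement:
#' `v_tilde = v - (1 - (1 + lambda n_j)^{-1/2}) * mean(v_block)` per block,
#' in O(N) without forming any N x N matrix. After the transform the residual
#' covariance is `sigma_e^2 I`.
#'
#' @param y response vector.
#' @param X design matrix (any columns; transformed columnwise), or NULL.
#' @param sample_id per-cell sample labels.
#' @param lambda variance ratio (>= 0).
#' @return list with `y_tilde`, `X_tilde`, `log_det` (log-determinant of U).
#' @export
whiten <- function(y, X = NULL, sample_id, lambda) {
  if (lambda < 0) stop("'lambda' must be nonnegative")
  sample_id <- factor(sample_id)
  idx <- split(seq_along(y), sample_id)
  n_j <- lengths(idx)
  shrink <- 1 - 1 / sqrt(1 + lambda * n_j)
  y_t <- as.numeric(y)
  X_t <- if (!is.null(X)) as.matrix(X)
  for (j in seq_along(idx)) {
    ii <- idx[[j]]
    y_t[ii] <- y_t[ii] - shrink[j] * mean(y_t[ii])
    if (!is.null(X_t))
      X_t[ii, ] <- sweep(X_t[ii, , drop = FALSE], 2,
                         shrink[j] * colMeans(X_t[ii, , drop = FALSE]))
  }
  list(y_tilde = y_t, X_tilde = X_t,
       log_det = 0.5 * sum(log1p(lambda * n_j)))
}

#' Fit the shape-constrained model for one gene
#'
#' Builds (or accepts) the pattern design, optionally estimates the
#' sample-level variance ratio under the null mean model and whitens, then
#' projects the (whitened) expression onto the shape cone.
#'
#' @param bundle an [expression_bundle()].
#' @param gene gene name or row index.
#' @param pattern one of `"growth"`, `"recession"`, `"peak"`, `"trough"`.
#' @param model `"linear"` (independent errors) or `"mixed"` (per-sample
#'   random effect).
#' @param n_knots,order passed to [build_design()].
#' @param design optional prebuilt [build_design()] object.
#' @param lambda optional fixed variance ratio overriding estimation
#'   (mixed model only).
#' @return object of class `"lamm_fit"`.
#' @export
fit_lamm <- function(bundle, gene, pattern = "growth",
                     model = c("linear", "mixed"),
                     n_knots = NULL, order = 2L, design = NULL,
                     lambda = NULL) {
  stopifnot(inherits(bundle, "expr_bundle"))
  model <- match.arg(model)
  if (is.character(gene)) gene <- match(gene, bundle$gene_names)
  if (is.na(gene) || gene < 1 || gene > nrow(bundle$expr))
    stop("gene not found in bundle")
  y <- as.numeric(bundle$expr[gene, ])
  design <- design %||% build_design(bundle$time, pattern, n_knots, order)
  pattern <- design$pattern
  Xf <- cbind(design$W0, bundle$covariates)
  X <- cbind(Xf, design$S)
  q <- ncol(Xf)
  n <- length(y)

  degenerate <- stats::var(y) < 1e-14
  out <- list(gene = bundle$gene_names[gene], pattern = pattern, model = model,
              n = n, q = q, design = design, y = y,
              sample_id = bundle$sample_id, degenerate = degenerate)

  if (degenerate) {
    out <- c(out, list(
      alpha0 = c(mean(y), numeric(ncol(design$W0) - 1L)),
      alpha = numeric(q - ncol(design$W0)),
      beta = numeric(ncol(design$S)), mu_hat = rep(mean(y), n),
      ssr0 = 0, ssr1 = 0, active_set = integer(0), loglik = NA_real_,
      vc = NULL))
    class(out) <- "lamm_fit"
    return(out)
  }

  vc <- NULL
  log_det <- 0
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)

  if (model == "mixed") {
    n_j <- as.numeric(table(bundle$sample_id))
    if (all(n_j == 1) && is.null(lambda)) {
      warning("one cell per sample everywhere: lambda set to 0 (reduces to the linear model)")
      lambda <- 0
    }
    if (is.null(lambda)) {
      vc <- estimate_variance_components(y, Xf, bundle$sample_id)
      lambda <- vc$lambda
    } else {
      if (lambda < 0) stop("'lambda' must be nonnegative")
      vc <- list(lambda = lambda, sigma2_e = NA_real_, sigma2_u = NA_real_)
    }
    if (lambda > 0) {
      ind <- stats::model.matrix(~ sid - 1, data.frame(sid = bundle$sample_id))
      BX <- crossprod(ind, X)
      By <- drop(crossprod(ind, y))
      XtX <- .whiten_xtx(XtX, BX, n_j, lambda)
      Xty <- .whiten_xty(Xty, BX, By, n_j, lambda)
      yty <- .whiten_yty(yty, By, n_j, lambda)
      log_det <- 0.5 * sum(log1p(lambda * n_j))
    }
    vc$lambda <- lambda
  }

  fit <- .cone_fit_cp(XtX, Xty, yty, q)
  sigma2 <- max(fit$ssr1 / n, .Machine$double.xmin)
  loglik <- -0.5 * n * (log(2 * pi * sigma2) + 1) - log_det

  nw0 <- ncol(design$W0)
  out <- c(out, list(
    alpha0 = fit$coef[seq_len(nw0)],
    alpha = fit$coef[setdiff(seq_len(q), seq_len(nw0))],
    beta = fit$coef[-seq_len(q)],
    mu_hat = drop(X %*% fit$coef),
    ssr0 = fit$ssr0, ssr1 = fit$ssr1,
    active_set = fit$active, loglik = loglik, vc = vc))
  class(out) <- "lamm_fit"
  out
}

#' @export
print.lamm_fit <- function(x, ...) {
  cat("Shape-constrained LAMM fit (", x$model, ")\n", sep = "")
  cat("  gene:", x$gene, " pattern:", x$pattern, "\n")
  if (x$degenerate) {
    cat("  degenerate fit (constant expression)\n")
    return(invisible(x))
  }
  cat("  SSR null:", signif(x$ssr0, 6), " SSR fit:", signif(x$ssr1, 6),
      " B:", signif(shape_statistic(x), 4), "\n")
  cat("  active cone edges:", if (length(x$active_set))
    paste(x$active_set, collapse = ", ") else "none", "\n")
  if (!is.null(x$vc))
    cat("  variance ratio lambda:", signif(x$vc$lambda, 4), "\n")
  invisible(x)
}

#' @export
coef.lamm_fit <- function(object, ...) {
  cf <- c(object$alpha0, object$alpha, object$beta)
  names(cf) <- c(colnames(object$design$W0),
                 if (length(object$alpha)) paste0("w", seq_along(object$alpha)),
                 colnames(object$design$S))
  cf
}

#' @export
fitted.lamm_fit <- function(object, ...) object$mu_hat

#' @export
residuals.lamm_fit <- function(object, ...) object$y - object$mu_hat

#' @export
logLik.lamm_fit <- function(object, ...) {
  ll <- object$loglik
  attr(ll, "df") <- object$q + length(object$active_set) + 1L
  attr(ll, "nobs") <- object$n
  class(ll) <- "logLik"
  ll
}

#' Predict the fitted temporal trend
#'
#' Evaluates the fitted mean curve `W0(t) a0 + S(t) b` at new time values
#' (covariates, if any, contribute at zero).
#'
#' @param object a [fit_lamm()] object.
#' @param newtime numeric time values within the observed range.
#' @param ... unused.
#' @export
predict.lamm_fit <- function(object, newtime = NULL, ...) {
  d <- object$design
  newtime <- newtime %||% sort(unique(d$time))
  if (object$degenerate) return(rep(mean(object$y), length(newtime)))
  sgn <- if (d$pattern %in% c("recession", "peak")) -1 else 1
  S <- sgn * switch(d$pattern,
    growth = , recession = ispline_basis(newtime, d$knots, d$order),
    peak = , trough = cspline_basis(newtime, d$knots, d$order))
  W0 <- if (d$pattern %in% c("growth", "recession"))
    matrix(1, length(newtime), 1) else cbind(1, newtime)
  drop(W0 %*% object$alpha0 + S %*% object$beta)
}

#' @export
plot.lamm_fit <- function(x, ...) {
  d <- x$design
  graphics::plot(jitter(d$time, 0.3), x$y, pch = 16, cex = 0.4,
                 col = "grey60", xlab = "time point", ylab = "expression",
                 main = paste0(x$gene, " (", x$pattern, ")"), ...)
  tt <- seq(min(d$knots), max(d$knots), length.out = 100)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  mu_t <- tapply(x$y, d$time, mean)
  graphics::points(as.numeric(names(mu_t)), mu_t, pch = 4, col = "black")
  invisible(x)
}

#' Simulate responses from a fitted model
#'
#' Draws Gaussian responses around the fitted mean; for mixed fits a
#' per-sample random intercept with variance `sigma_u^2` is added.
#'
#' @param object a [fit_lamm()] object.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @export
simulate.lamm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$n
  s2 <- max(object$ssr1 / n, 0)
  su2 <- if (!is.null(object$vc)) object$vc$sigma2_u else 0
  if (!is.finite(su2)) su2 <- 0
  with_seed(seed, {
    out <- vapply(seq_len(nsim), function(i) {
      y <- object$mu_hat + stats::rnorm(n, 0, sqrt(s2))
      if (su2 > 0 && !is.null(object$sample_id)) {
        u <- stats::rnorm(nlevels(object$sample_id), 0, sqrt(su2))
        y <- y + u[as.integer(object$sample_id)]
      }
      y
    }, numeric(n))
    as.data.frame(out)
  })
}
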