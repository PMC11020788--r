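# Independent oracles and small fixture builders shared across the suite.

# Brute-force cone projection: enumerate every subset of cone columns, solve
# the unconstrained least squares on [F, S_A] by QR, keep sign-feasible
# solutions satisfying the KKT gradient condition, return the SSR-minimal one.
enum_cone_oracle <- function(y, Fm, S) {
  m <- ncol(S)
  qf <- ncol(Fm)
  best <- NULL
  for (mask in 0:(2^m - 1)) {
    A <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    X <- cbind(Fm, S[, A, drop = FALSE])
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) next
    cf <- qr.coef(qr_x, y)
    b <- cf[-seq_len(qf)]
    if (length(b) && any(b < -1e-10)) next
    r <- y - X %*% cf
    grad <- crossprod(S, r)
    if (any(grad > 1e-7 * sqrt(colSums(S^2) * sum(y^2)))) next
    ssr <- sum(r^2)
    if (is.null(best) || ssr < best$ssr - 1e-12) {
      beta_full <- numeric(m)
      beta_full[A] <- b[seq_along(A)]
      best <- list(ssr = ssr, active = A, beta = beta_full,
                   alpha = cf[seq_len(qf)])
    }
  }
  best
}

# Adaptive-quadrature integral of one basis column over [lo, hi].
quad_column <- function(basis_fun, col, lo, hi) {
  stats::integrate(function(t) basis_fun(t)[, col], lo, hi,
                   subdivisions = 500L, rel.tol = 1e-10)$value
}

# iid-Gaussian expression bundle on a balanced multi-sample time course, with
# optional planted mean shifts (genes x T matrix added per time point).
gaussian_bundle <- function(G = 20, T_n = 5, samples_per_t = 3, cells = 20,
                            seed = 1, shifts = NULL) {
  with_seed <- tdeshape:::with_seed
  with_seed(seed, {
    M <- T_n * samples_per_t
    N <- M * cells
    sid <- rep(seq_len(M), each = cells)
    time <- rep(rep(seq_len(T_n), each = samples_per_t), each = cells)
    expr <- matrix(stats::rnorm(G * N), G, N)
    if (!is.null(shifts)) {
      for (g in seq_len(nrow(shifts)))
        expr[g, ] <- expr[g, ] + shifts[g, time]
    }
    rownames(expr) <- paste0("g", seq_len(G))
    expression_bundle(expr = expr, time = time,
                      sample_id = paste0("s", sid))
  })
}

# tiny deterministic count fixture: genes x cells with controllable zeros
toy_counts <- function() {
  m <- rbind(
    c(5L, 0L, 2L, 1L),
    c(0L, 0L, 0L, 3L),
    c(1L, 1L, 1L, 1L)
  )
  dimnames(m) <- list(paste0("g", 1:3), paste0("c", 1:4))
  m
}
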