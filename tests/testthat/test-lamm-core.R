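test_that("cone projection reduces to ordinary least squares inside the cone", {
  set.seed(11)
  n <- 40
  Fm <- cbind(1, rnorm(n))
  S <- matrix(sort(rnorm(n)), n, 1)      # single cone column
  y <- drop(Fm %*% c(1, 2)) + 3 * S[, 1] + rnorm(n, 0, 0.1)
  cp <- cone_projection(y, Fm, S)
  ols <- lm.fit(cbind(Fm, S), y)
  expect_gt(cp$beta, 0)
  expect_equal(cp$fitted, unname(ols$fitted.values), tolerance = 1e-10)

  # unconstrained coefficient negative: beta pinned to 0, fit = F only
  y2 <- drop(Fm %*% c(1, 2)) - 3 * S[, 1] + rnorm(n, 0, 0.1)
  cp2 <- cone_projection(y2, Fm, S)
  expect_identical(cp2$beta, 0)
  expect_equal(cp2$ssr1, cp2$ssr0, tolerance = 1e-12)
  expect_equal(cp2$fitted, unname(lm.fit(Fm, y2)$fitted.values),
               tolerance = 1e-10)
})

test_that("cone projection satisfies KKT conditions on random problems", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:30, 1); m <- sample(2:6, 1)
    Fm <- cbind(1, matrix(rnorm(n * sample(0:2, 1)), n))
    S <- matrix(rnorm(n * m), n)
    y <- rnorm(n)
    cp <- cone_projection(y, Fm, S)
    r <- cp$residuals
    expect_lt(max(abs(crossprod(Fm, r))), 1e-7)                # orthogonal to F
    if (length(cp$active))
      expect_lt(max(abs(crossprod(S[, cp$active, drop = FALSE], r))), 1e-7)
    inactive <- setdiff(seq_len(m), cp$active)
    if (length(inactive))
      expect_lt(max(crossprod(S[, inactive, drop = FALSE], r)), 1e-6)
    expect_true(all(cp$beta >= 0))
    expect_gte(cp$ssr0, cp$ssr1 - 1e-12)
  }
})

test_that("cone projection agrees with Lawson-Hanson NNLS when all columns are conic", {
  skip_if_not_installed("pracma")
  set.seed(13)
  for (i in 1:10) {
    n <- 25; m <- 5
    S <- matrix(rnorm(n * m), n)
    y <- rnorm(n)
    fit <- tdeshape:::.cone_fit_cp(crossprod(S), drop(crossprod(S, y)),
                                   sum(y^2), q = 0L)
    nn <- pracma::lsqnonneg(S, y)
    expect_equal(fit$coef, nn$x, tolerance = 1e-7)
  }
})

test_that("rank-deficient free columns are rejected", {
  n <- 20
  Fm <- cbind(rep(1, n), rep(1, n))
  S <- matrix(rnorm(n), n, 1)
  expect_error(cone_projection(rnorm(n), Fm, S), "rank deficient")
})

test_that("linear fits recover planted spline signals and match the projection oracle", {
  b <- gaussian_bundle(G = 3, T_n = 5, cells = 10, seed = 21)
  d <- build_design(b$time, "growth")
  # plant an exact cone signal in gene 1: intercept + I-spline column
  b$expr[1, ] <- 2 + 1.5 * d$S[, 3]
  f <- fit_lamm(b, 1, "growth", model = "linear")
  expect_lt(f$ssr1, 1e-18)
  expect_equal(f$mu_hat, b$expr[1, ], tolerance = 1e-9)

  # constant gene: degenerate, flagged
  b$expr[2, ] <- 5
  f2 <- fit_lamm(b, 2, "growth", model = "linear")
  expect_true(f2$degenerate)
  expect_identical(f2$ssr0, 0)

  # random gene: ssr1 equals the exhaustive-face oracle
  y <- b$expr[3, ]
  f3 <- fit_lamm(b, 3, "growth", model = "linear")
  or <- enum_cone_oracle(y, d$W0, d$S)
  expect_equal(f3$ssr1, or$ssr, tolerance = 1e-9)
  expect_equal(f3$beta, or$beta, tolerance = 1e-7)
})

test_that("whitening uses the closed-form block eigenstructure", {
  set.seed(31)
  # lambda = 0: identity transform
  y <- rnorm(12)
  sid <- rep(1:3, each = 4)
  w0 <- whiten(y, sample_id = sid, lambda = 0)
  expect_identical(w0$y_tilde, y)
  expect_identical(w0$log_det, 0)

  # one block of n = 2, lambda = 1: K = I + J has eigenvalues (3, 1)
  K <- diag(2) + 1
  expect_equal(sort(eigen(K)$values), c(1, 3))
  # and the blockwise transform matches the dense K^{-1/2}
  y2 <- rnorm(2)
  w2 <- whiten(y2, sample_id = c(1, 1), lambda = 1)
  eg <- eigen(K, symmetric = TRUE)
  Kinv_sqrt <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  expect_equal(w2$y_tilde, drop(Kinv_sqrt %*% y2), tolerance = 1e-12)

  # M = 3 unequal blocks: transformed residual covariance is the identity
  sid3 <- rep(1:3, c(5, 8, 3))
  lam <- 0.7
  K3 <- diag(16) + lam * outer(sid3, sid3, "==")
  eg3 <- eigen(K3, symmetric = TRUE)
  Ki_sqrt <- eg3$vectors %*% diag(1 / sqrt(eg3$values)) %*% t(eg3$vectors)
  Y <- matrix(rnorm(16 * 500), 16)
  W <- apply(Y, 2, function(v) whiten(v, sample_id = sid3, lambda = lam)$y_tilde)
  Wd <- apply(Y, 2, function(v) drop(Ki_sqrt %*% v))
  expect_equal(W, Wd, tolerance = 1e-10)
  expect_equal(w2$log_det, 0.5 * log(3), tolerance = 1e-12)
  expect_error(whiten(y, sample_id = sid, lambda = -1), "nonnegative")
})

test_that("whiten followed by un-whiten is the identity", {
  set.seed(32)
  sid <- rep(1:4, c(3, 6, 2, 9))
  lam <- 1.3
  y <- rnorm(20)
  yt <- whiten(y, sample_id = sid, lambda = lam)$y_tilde
  # U = K^{1/2}: v -> v + (sqrt(1 + lam*n_j) - 1) * mean(v_block)
  back <- yt
  for (j in unique(sid)) {
    ii <- which(sid == j)
    back[ii] <- yt[ii] + (sqrt(1 + lam * length(ii)) - 1) * mean(yt[ii])
  }
  expect_equal(back, y, tolerance = 1e-10)
})

test_that("variance components: the fast profile equals a dense-matrix oracle", {
  set.seed(41)
  sid <- rep(1:5, each = 30)
  u <- rnorm(5, 0, 0.8)
  y <- 1 + u[sid] + rnorm(150)
  X0 <- matrix(1, 150, 1)
  est <- estimate_variance_components(y, X0, sid)
  ll_dense <- function(lam) {
    K <- diag(150) + lam * outer(sid, sid, "==")
    Ki <- solve(K)
    cf <- solve(t(X0) %*% Ki %*% X0, t(X0) %*% Ki %*% y)
    r <- y - X0 %*% cf
    rss <- drop(t(r) %*% Ki %*% r)
    -75 * log(rss / 150) - 0.5 * c(determinant(K)$modulus)
  }
  grid <- exp(seq(log(1e-4), log(50), length.out = 400))
  expect_equal(est$lambda, grid[which.max(sapply(grid, ll_dense))],
               tolerance = 0.05)
})

test_that("variance-ratio recovery over repeated simulations", {
  recover <- function(lam_true, seeds) vapply(seeds, function(s) {
    tdeshape:::with_seed(s, {
      sid <- rep(1:6, each = 100)
      u <- rnorm(6, 0, sqrt(lam_true))
      y <- 2 + u[sid] + rnorm(600)
      estimate_variance_components(y, matrix(1, 600, 1), sid)$lambda
    })
  }, numeric(1))
  l0 <- recover(0, 1:10)
  expect_gte(sum(l0 <= 0.05), 9)
  # with 6 sample blocks the realized random-effect variance is chi^2_5-noisy;
  # a wide band holds in nearly all draws
  l1 <- recover(1, 1:10)
  expect_gte(sum(l1 >= 0.2 & l1 <= 3), 8)
})

test_that("unidentifiable designs fall back to lambda = 0 with a warning", {
  y <- rnorm(10)
  expect_warning(
    vc <- estimate_variance_components(y, matrix(1, 10, 1), 1:10),
    "unidentifiable")
  expect_identical(vc$lambda, 0)
})

test_that("the mixed fit reduces to the linear fit when lambda is 0", {
  b <- gaussian_bundle(G = 2, T_n = 5, cells = 8, seed = 51)
  fl <- fit_lamm(b, 1, "peak", model = "linear")
  fm <- fit_lamm(b, 1, "peak", model = "mixed", lambda = 0)
  expect_identical(fm$ssr1, fl$ssr1)
  expect_identical(fm$beta, fl$beta)
  expect_identical(fm$mu_hat, fl$mu_hat)

  # one cell per sample: lambda unidentifiable, warned reduction
  expr <- matrix(rnorm(2 * 9), 2, 9)
  b1 <- expression_bundle(expr = expr, time = rep(1:3, each = 3),
                          sample_id = paste0("s", 1:9))
  expect_warning(fm1 <- fit_lamm(b1, 1, "growth", model = "mixed"),
                 "reduces to the linear model")
  fl1 <- fit_lamm(b1, 1, "growth", model = "linear")
  expect_identical(fm1$ssr1, fl1$ssr1)
  expect_identical(fm1$beta, fl1$beta)
})

test_that("the mixed fit matches a dense GLS-cone oracle", {
  set.seed(61)
  b <- gaussian_bundle(G = 1, T_n = 4, samples_per_t = 3, cells = 15, seed = 61)
  d <- build_design(b$time, "growth")
  u <- rnorm(nlevels(b$sample_id), 0, 0.5)
  b$expr[1, ] <- 0.5 + 0.8 * d$S[, 2] + u[as.integer(b$sample_id)] +
    rnorm(ncol(b$expr), 0, 0.7)
  fm <- fit_lamm(b, 1, "growth", model = "mixed")
  lam <- fm$vc$lambda
  # dense whitening at the same lambda, then the exhaustive-face oracle
  sid <- as.integer(b$sample_id)
  K <- diag(length(sid)) + lam * outer(sid, sid, "==")
  eg <- eigen(K, symmetric = TRUE)
  Ki_sqrt <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  yt <- drop(Ki_sqrt %*% b$expr[1, ])
  Ft <- Ki_sqrt %*% d$W0
  St <- Ki_sqrt %*% d$S
  or <- enum_cone_oracle(yt, Ft, St)
  expect_equal(fm$ssr1, or$ssr, tolerance = 1e-6)

  # noiseless shared growth signal: beta recovered, ssr ~ 0
  b$expr[1, ] <- 1 + 2 * d$S[, 3]
  fm2 <- fit_lamm(b, 1, "growth", model = "mixed")
  expect_lt(fm2$ssr1, 1e-12)
  # the cone basis is rank deficient on the grid, so beta itself is not
  # unique -- but the fitted mean is
  expect_equal(fm2$mu_hat, b$expr[1, ], tolerance = 1e-8)
})

test_that("ssr0 >= ssr1 with equality iff no cone coefficient is active", {
  set.seed(71)
  b <- gaussian_bundle(G = 30, T_n = 5, cells = 6, seed = 71)
  for (g in 1:30) {
    f <- fit_lamm(b, g, sample(c("growth", "peak"), 1), model = "linear")
    expect_gte(f$ssr0, f$ssr1 - 1e-10)
    if (length(f$active_set) == 0L)
      expect_equal(f$ssr0, f$ssr1, tolerance = 1e-12)
    else
      expect_gt(f$ssr0, f$ssr1)
  }
})

test_that("lamm_fit methods expose coefficients, fit and predictions", {
  b <- gaussian_bundle(G = 1, T_n = 5, cells = 10, seed = 81)
  d <- build_design(b$time, "growth")
  b$expr[1, ] <- 1 + 2 * d$S[, 4] + rnorm(ncol(b$expr), 0, 0.05)
  f <- fit_lamm(b, 1, "growth", model = "linear")
  expect_length(coef(f), 1 + ncol(d$S))
  expect_equal(fitted(f) + residuals(f), f$y)
  expect_equal(unname(attr(logLik(f), "df")), f$q + length(f$active_set) + 1L)
  pr <- predict(f, c(1, 3, 5))
  expect_length(pr, 3)
  expect_true(all(diff(pr) >= -1e-10))   # growth fit predicts nondecreasing
  sim <- simulate(f, nsim = 2, seed = 4)
  expect_identical(dim(sim), c(f$n, 2L))
})
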