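# Genewise screening driver: fit all genes under the four shape designs,
# test, combine, permute, call patterns.
#
# The engine never touches per-cell vectors inside the gene loop: every fit
# needs only X'X (shared per pattern), X'y, per-sample sums and y'y, all
# precomputed with a handful of matrix products. Whitening at a given
# variance ratio is a rank-M correction of those crossproducts, so the mixed
# model costs little more than the linear one.

# cache key grid for the mixture weights: lambda snapped to 0 or a geometric
# grid (weights vary smoothly in lambda; see the vignette)
.lambda_key <- function(lambda) {
  if (lambda < 1e-3) return(0)
  10^(round(log10(min(lambda, 1e3)) * 10) / 10)
}

# One full pass over all genes for a fixed time assignment.
# Returns per-gene p-values per pattern, combined p, B stats, calls, lambdas.
.tde_engine <- function(expr, time_idx, sample_id, covar, model,
                        n_knots, order, wcache, weights_n_sim,
                        block_sig, calls = TRUE) {
  G <- nrow(expr)
  N <- ncol(expr)
  sample_id <- droplevels(sample_id)
  M <- nlevels(sample_id)
  ind <- Matrix::sparseMatrix(i = seq_len(N), j = as.integer(sample_id),
                              x = 1, dims = c(N, M))
  n_j <- as.numeric(Matrix::colSums(ind))
  By <- as.matrix(expr %*% ind)                       # G x M
  yty <- Matrix::rowSums(expr * expr)
  ymean <- Matrix::rowSums(expr) / N
  degenerate <- (yty / N - ymean^2) < 1e-14

  designs <- lapply(.patterns, function(pt)
    build_design(time_idx, pt, n_knots, order))
  names(designs) <- .patterns

  pre <- lapply(designs, function(d) {
    Xf <- cbind(d$W0, covar)
    X <- cbind(Xf, d$S)
    XtX <- crossprod(X)
    list(X = X, q = ncol(Xf), p = ncol(X), XtX = XtX,
         BX = as.matrix(Matrix::crossprod(ind, X)),
         XtY = as.matrix(crossprod(X, Matrix::t(expr))))   # p x G
  })

  # two distinct null mean models: intercept(+covar) and intercept+t(+covar)
  null_sets <- list(iso = pre$growth, quad = pre$peak)
  null_q <- vapply(null_sets, `[[`, 0L, "q")
  pattern_null <- c(growth = "iso", recession = "iso",
                    peak = "quad", trough = "quad")

  get_weights <- function(pattern, lambda) {
    lk <- .lambda_key(lambda)
    key <- paste(pattern, lk, block_sig, sep = "|")
    w <- wcache[[key]]
    if (is.null(w)) {
      pp <- pre[[pattern]]
      XtXl <- .whiten_xtx(pp$XtX, pp$BX, n_j, lk)
      Gmat <- .schur_cone(XtXl, pp$q)
      w <- .face_weights(Gmat, n_sim = weights_n_sim, seed = 101L)
      wcache[[key]] <- w
    }
    w
  }

  p_mat <- matrix(1, G, 4L, dimnames = list(NULL, .patterns))
  b_mat <- matrix(0, G, 4L, dimnames = list(NULL, .patterns))
  aic_mat <- matrix(Inf, G, 4L, dimnames = list(NULL, .patterns))
  lambda_vec <- rep(NA_real_, G)
  call_vec <- rep("none", G)

  for (g in seq_len(G)) {
    if (degenerate[g]) next
    ytyg <- yty[g]
    Byg <- By[g, ]

    lam <- c(iso = 0, quad = 0)
    if (model == "mixed") {
      for (s in names(null_sets)) {
        ns <- null_sets[[s]]
        qf <- seq_len(ns$q)
        vc <- .profile_lambda(ns$XtX[qf, qf, drop = FALSE],
                              ns$BX[, qf, drop = FALSE], n_j,
                              ns$XtY[qf, g], Byg, ytyg, N)
        lam[s] <- vc$lambda
      }
      lambda_vec[g] <- lam[["iso"]]
    }

    for (k in seq_along(.patterns)) {
      pt <- .patterns[k]
      pp <- pre[[pt]]
      lg <- lam[[pattern_null[[pt]]]]
      XtXl <- .whiten_xtx(pp$XtX, pp$BX, n_j, lg)
      Xtyl <- .whiten_xty(pp$XtY[, g], pp$BX, Byg, n_j, lg)
      ytyl <- .whiten_yty(ytyg, Byg, n_j, lg)
      fit <- .cone_fit_cp(XtXl, Xtyl, ytyl, pp$q)

      if (fit$ssr0 <= 1e-12 * max(ytyl, 1e-300)) {
        b <- 0; pv <- 1
      } else {
        b <- min(max((fit$ssr0 - fit$ssr1) / fit$ssr0, 0), 1)
        wts <- get_weights(pt, lg)
        if (b <= 1e-12) {
          pv <- 1 - wts[[1L]] * stats::runif(1)
        } else {
          m <- length(wts) - 1L
          d <- seq_len(m)
          pv <- max(sum(wts[-1L] *
                          stats::pbeta(b, d / 2, (N - pp$q - d) / 2,
                                       lower.tail = FALSE)), 1e-300)
        }
      }
      b_mat[g, k] <- b
      p_mat[g, k] <- pv
      if (model == "linear") {
        s2 <- max(fit$ssr1 / N, .Machine$double.xmin)
        kpar <- pp$q + length(fit$active) + 1L
        aic_mat[g, k] <- 2 * kpar + N * (log(2 * pi * s2) + 1)
      }
    }
    if (calls) {
      call_vec[g] <- if (model == "linear") {
        .patterns[which.min(aic_mat[g, ])]
      } else if (max(b_mat[g, ]) <= 0) "none"
        else .patterns[which.max(b_mat[g, ])]
    }
  }

  p_comb <- vapply(seq_len(G), function(g) {
    if (degenerate[g]) 1 else cauchy_combine(p_mat[g, ])
  }, numeric(1))

  list(p_mat = p_mat, b_mat = b_mat, aic_mat = aic_mat,
       p_combined = p_comb, pattern = call_vec, lambda = lambda_vec,
       degenerate = degenerate)
}

#' Detect temporal expression patterns across all genes
#'
#' Runs the full screen: per gene, fit the growth, recession, peak and trough
#' designs (linear or mixed model), compute shape statistics and
#' mixture-of-beta p-values, combine the four p-values with the Cauchy rule,
#' estimate false discovery rates by sample-level time permutations, and
#' assign each gene a pattern (AIC for the linear model, B-statistic for the
#' mixed model).
#'
#' @param bundle an [expression_bundle()].
#' @param model `"auto"` picks `"mixed"` when some time point has at least two
#'   samples, `"linear"` otherwise.
#' @param knots number of spline knots (default: number of time points).
#' @param order M-spline order (default 2: quadratic I-/cubic C-splines).
#' @param permutations number of sample-level time permutations for the FDR
#'   (default 5); 0 skips the FDR column.
#' @param seed integer seed governing permutations and the randomised
#'   boundary-atom p-values.
#' @param weights_n_sim Monte-Carlo size for the mixture weights.
#' @param verbose log progress to stderr.
#' @return a data.frame of class `"tde_result"` with one row per (retained)
#'   gene: `gene`, `p_growth`, `p_recession`, `p_peak`, `p_trough`,
#'   `p_combined`, `fdr` (if permuted), `pattern`, `b_stat_max`, `lambda`
#'   (mixed), `model_version`.
#' @export
tde_test <- function(bundle, model = c("auto", "linear", "mixed"),
                     knots = NULL, order = 2L, permutations = 5L,
                     seed = 1L, weights_n_sim = 10000L, verbose = FALSE) {
  stopifnot(inherits(bundle, "expr_bundle"))
  model <- match.arg(model)
  if (model == "auto") {
    reps <- tapply(bundle$sample_id, bundle$time,
                   function(s) length(unique(s)))
    model <- if (any(reps >= 2)) "mixed" else "linear"
    .msg(verbose, "model = ", model, " (auto)")
  }
  if (nrow(bundle$expr) < 1L) stop("bundle contains no genes")
  if (permutations < 0) stop("'permutations' must be >= 0")

  wcache <- new.env(parent = emptyenv())
  block_sig <- paste(sort(paste(as.numeric(table(bundle$sample_id)),
                                tapply(bundle$time, bundle$sample_id, `[`, 1),
                                sep = ":")), collapse = ",")

  res <- with_seed(seed, {
    .msg(verbose, "fitting ", nrow(bundle$expr), " genes (", model, " model)")
    obs <- .tde_engine(bundle$expr, bundle$time, bundle$sample_id,
                       bundle$covariates, model, knots, order,
                       wcache, weights_n_sim, block_sig)
    p_null <- NULL
    if (permutations > 0L) {
      p_null <- matrix(NA_real_, permutations, nrow(bundle$expr))
      for (r in seq_len(permutations)) {
        .msg(verbose, "permutation ", r, "/", permutations)
        pb <- permute_times(bundle)
        pr <- .tde_engine(pb$expr, pb$time, pb$sample_id, pb$covariates,
                          model, knots, order, wcache, weights_n_sim,
                          block_sig, calls = FALSE)
        p_null[r, ] <- pr$p_combined
      }
    }
    list(obs = obs, p_null = p_null)
  })
  obs <- res$obs

  out <- data.frame(gene = bundle$gene_names,
                    p_growth = obs$p_mat[, "growth"],
                    p_recession = obs$p_mat[, "recession"],
                    p_peak = obs$p_mat[, "peak"],
                    p_trough = obs$p_mat[, "trough"],
                    p_combined = obs$p_combined,
                    stringsAsFactors = FALSE)
  if (!is.null(res$p_null))
    out$fdr <- permutation_fdr(obs$p_combined, res$p_null)
  out$pattern <- obs$pattern
  out$b_stat_max <- apply(obs$b_mat, 1, max)
  if (model == "mixed") out$lambda <- obs$lambda
  out$model_version <- model

  attr(out, "config") <- list(model = model, knots = knots, order = order,
                              permutations = permutations, seed = seed)
  attr(out, "time_map") <- bundle$time_map
  class(out) <- c("tde_result", "data.frame")
  out
}

#' @export
print.tde_result <- function(x, ...) {
  cfg <- attr(x, "config")
  model <- cfg$model %||% unique(x$model_version)[1]
  cat("Temporal pattern screen (", model, " model, ",
      nrow(x), " genes)\n", sep = "")
  if (!is.null(x$fdr)) {
    sig <- x$fdr <= 0.05
    cat("  genes at FDR <= 0.05:", sum(sig), "\n")
    if (any(sig)) print(table(pattern = x$pattern[sig]))
  } else {
    cat("  genes at p_combined < 0.05:", sum(x$p_combined < 0.05), "\n")
  }
  invisible(x)
}

#' @export
summary.tde_result <- function(object, fdr_cutoff = 0.05, ...) {
  hits <- if (!is.null(object$fdr)) object$fdr <= fdr_cutoff
          else object$p_combined < fdr_cutoff
  structure(list(n_genes = nrow(object), n_sig = sum(hits),
                 fdr_cutoff = fdr_cutoff,
                 by_pattern = table(object$pattern[hits]),
                 config = attr(object, "config")),
            class = "summary.tde_result")
}

#' @export
print.summary.tde_result <- function(x, ...) {
  cat("Temporal pattern screen summary\n")
  cat("  genes tested:", x$n_genes, "\n")
  cat("  significant at", if (is.null(x$config$permutations) ||
                              x$config$permutations > 0)
    paste0("FDR <= ", x$fdr_cutoff, ":") else
    paste0("p < ", x$fdr_cutoff, ":"), x$n_sig, "\n")
  if (x$n_sig > 0) print(x$by_pattern)
  invisible(x)
}

#' @export
plot.tde_result <- function(x, ...) {
  graphics::hist(x$p_combined, breaks = 40, main = "combined p-values",
                 xlab = "p", col = "grey80", border = "white", ...)
  invisible(x)
}

#' Write a results table to TSV
#'
#' @param x a [tde_test()] result.
#' @param path output file.
#' @export
write_results <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Benchmark power, type-I error and pattern accuracy on simulated data
#'
#' Generates replicate datasets from the gamma-Poisson simulator, runs the
#' screen, and scores against the generator's truth: power = detected
#' temporal genes / planted temporal genes at each estimated-FDR cutoff
#' (detection uses the method's own permutation FDR; truth only labels
#' TP/FP); type-I error = fraction of flat genes with combined p below each
#' alpha; accuracy = per true pattern, the fraction of FDR-significant genes
#' assigned that pattern.
#'
#' To keep per-gene sequencing depth at the level of the full `panel_genes`
#' panel when fewer genes are simulated, `lib_loc` is offset by
#' `log(n_genes / panel_genes)`.
#'
#' @param params a [sim_params()] object (its `seed` is replaced per
#'   replicate, derived from `seed`).
#' @param model `"linear"` or `"mixed"`.
#' @param n_replicates number of simulation replicates.
#' @param fdr_cutoffs estimated-FDR grid for power.
#' @param alpha type-I error grid.
#' @param permutations permutations per run.
#' @param seed base seed.
#' @param panel_genes nominal panel size for the depth offset.
#' @param verbose log progress.
#' @return object of class `"tde_benchmark"`.
#' @export
benchmark_power <- function(params, model = c("linear", "mixed"),
                            n_replicates = 2L, fdr_cutoffs = 0.05,
                            alpha = 0.05, permutations = 5L, seed = 1L,
                            panel_genes = 10000L, verbose = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  model <- match.arg(model)
  power <- matrix(NA_real_, n_replicates, length(fdr_cutoffs),
                  dimnames = list(NULL, paste0("fdr", fdr_cutoffs)))
  power_oracle <- power
  typeI <- matrix(NA_real_, n_replicates, length(alpha),
                  dimnames = list(NULL, paste0("alpha", alpha)))
  acc <- matrix(NA_real_, n_replicates, 4L,
                dimnames = list(NULL, .patterns))
  lib_eff <- params$lib_loc + log(params$n_genes / panel_genes)

  for (r in seq_len(n_replicates)) {
    rep_seed <- as.integer(seed) * 1000L + r
    p_r <- params
    p_r$lib_loc <- lib_eff
    p_r$seed <- rep_seed
    .msg(verbose, "replicate ", r, ": simulating")
    truth <- simulate_counts(p_r)
    bundle <- as_expression_bundle(truth)
    .msg(verbose, "replicate ", r, ": testing (", model, ")")
    res <- tde_test(bundle, model = model, permutations = permutations,
                    seed = rep_seed, verbose = verbose)

    is_tmp <- truth$is_temporal
    pat <- truth$true_pattern
    ix <- match(res$gene, names(is_tmp))
    detected <- if (!is.null(res$fdr)) res$fdr else res$p_combined
    ord <- order(res$p_combined)
    fdp <- cumsum(!is_tmp[ix][ord]) / seq_along(ord)
    fdp_env <- -rev(cummax(rev(-fdp)))   # smallest achievable FDP at depth >= k
    tp_cum <- cumsum(is_tmp[ix][ord])
    for (ci in seq_along(fdr_cutoffs)) {
      hit_genes <- res$gene[detected <= fdr_cutoffs[ci]]
      power[r, ci] <- sum(is_tmp[hit_genes]) / sum(is_tmp)
      k <- which(fdp_env <= fdr_cutoffs[ci])
      power_oracle[r, ci] <- if (length(k)) tp_cum[max(k)] / sum(is_tmp) else 0
    }
    flat <- res$gene[!is_tmp[ix]]
    for (ai in seq_along(alpha))
      typeI[r, ai] <- mean(res$p_combined[match(flat, res$gene)] < alpha[ai])
    hits <- res[detected <= fdr_cutoffs[1], ]
    for (k in seq_along(.patterns)) {
      pk <- .patterns[k]
      sub <- hits[pat[match(hits$gene, names(pat))] == pk, ]
      acc[r, k] <- if (nrow(sub)) mean(sub$pattern == pk) else NA_real_
    }
  }
  structure(list(params = params, model = model, power = power,
                 power_oracle = power_oracle, type_I = typeI, accuracy = acc,
                 mean_power = colMeans(power),
                 mean_power_oracle = colMeans(power_oracle),
                 mean_type_I = colMeans(typeI),
                 mean_accuracy = colMeans(acc, na.rm = TRUE)),
            class = "tde_benchmark")
}

#' @export
print.tde_benchmark <- function(x, ...) {
  cat("Simulation benchmark (", x$model, " model, ",
      nrow(x$power), " replicates)\n", sep = "")
  cat("  mean power (estimated FDR):",
      paste(sprintf("%s = %.3f", colnames(x$power), x$mean_power),
            collapse = ", "), "\n")
  cat("  mean power (realized FDP):",
      paste(sprintf("%s = %.3f", colnames(x$power_oracle),
                    x$mean_power_oracle), collapse = ", "), "\n")
  cat("  mean type-I error:",
      paste(sprintf("%s = %.3f", colnames(x$type_I), x$mean_type_I),
            collapse = ", "), "\n")
  cat("  mean pattern accuracy:",
      paste(sprintf("%s = %.3f", names(x$mean_accuracy), x$mean_accuracy),
            collapse = ", "), "\n")
  invisible(x)
}
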