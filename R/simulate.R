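# Gamma-Poisson simulator of multi-sample time-course scRNA-seq counts.
#
# Hierarchy (Splatter-style): gene base means are Gamma(shape, rate); each
# cell draws a log-normal library size; each sample applies a log-normal
# multiplicative batch factor to all genes; temporal genes multiply in a
# per-time-point effect profile realising their assigned pattern. Expected
# counts allocate each cell's library over genes proportionally to the
# composed means, and observed counts are Poisson. Parameters are named after
# the corresponding Splatter arguments so published configurations transcribe
# directly.

.sim_patterns <- c("growth", "recession", "peak", "trough",
                   "bi-plateau", "multi-modal")

#' Simulation parameters for the time-course count generator
#'
#' Defaults reproduce the baseline scenario of the simulation study this
#' package's power and calibration checks mirror: 5 time points, 3
#' samples/time point, 100 cells/sample, 10,000 genes, temporal-gene
#' probability `de_prob = 0.3`, time-point effect `de_facloc = 0.4`, expected
#' log-UMI `lib_loc = 9.4`, sample-level batch effect `batch_facloc = 0.04`.
#'
#' @param n_timepoints number of stages T (>= 3).
#' @param n_samples_per_timepoint biological replicates per stage.
#' @param n_cells_per_sample cells per sample.
#' @param n_genes number of genes.
#' @param de_prob probability a gene is temporal.
#' @param de_facloc median log-fold range of a temporal gene across stages.
#' @param de_facscale lognormal sd of the per-gene effect magnitude.
#' @param lib_loc,lib_scale meanlog/sdlog of the per-cell library size.
#' @param batch_facloc meanlog (= sdlog) of per-sample batch factors; 0 gives
#'   factors exactly 1.
#' @param mean_shape,mean_rate Gamma parameters of gene base means.
#' @param pattern_mix named probability vector over the six temporal patterns
#'   (growth, recession, peak, trough, bi-plateau, multi-modal).
#' @param profile_mode `"splatter"` (default) draws independent log-normal
#'   effect factors one time point at a time (each affected with probability
#'   `de_tp_prob`) and keeps draws whose realized profile classifies as the
#'   gene's assigned pattern, reproducing the ragged profiles of
#'   per-time-point differential expression; `"canonical"` uses the smooth
#'   unit-shape profiles of [pattern_effect_profile()] scaled by a per-gene
#'   log-normal magnitude.
#' @param de_tp_prob probability each time point of a temporal gene carries an
#'   effect factor (splatter mode).
#' @param seed integer seed.
#' @return object of class `"sim_params"`.
#' @export
sim_params <- function(n_timepoints = 5L, n_samples_per_timepoint = 3L,
                       n_cells_per_sample = 100L, n_genes = 10000L,
                       de_prob = 0.3, de_facloc = 0.4, de_facscale = 0.4,
                       lib_loc = 9.4, lib_scale = 0.2, batch_facloc = 0.04,
                       mean_shape = 0.6, mean_rate = 0.3,
                       pattern_mix = NULL,
                       profile_mode = c("splatter", "canonical"),
                       de_tp_prob = 0.3, seed = 1L) {
  profile_mode <- match.arg(profile_mode)
  if (n_timepoints < 3L) stop("'n_timepoints' must be >= 3")
  if (de_prob < 0 || de_prob > 1) stop("'de_prob' must lie in [0, 1]")
  if (min(n_samples_per_timepoint, n_cells_per_sample, n_genes) < 1)
    stop("sizes must be positive")
  if (batch_facloc < 0 || de_facloc < 0 || lib_scale < 0)
    stop("scale parameters must be nonnegative")
  pm <- pattern_mix %||%
    stats::setNames(rep(1 / 6, 6), .sim_patterns)
  if (is.null(names(pm)) || !all(names(pm) %in% .sim_patterns))
    stop("'pattern_mix' must be named with patterns among: ",
         paste(.sim_patterns, collapse = ", "))
  pm <- pm / sum(pm)
  structure(list(n_timepoints = as.integer(n_timepoints),
                 n_samples_per_timepoint = as.integer(n_samples_per_timepoint),
                 n_cells_per_sample = as.integer(n_cells_per_sample),
                 n_genes = as.integer(n_genes), de_prob = de_prob,
                 de_facloc = de_facloc, de_facscale = de_facscale,
                 lib_loc = lib_loc, lib_scale = lib_scale,
                 batch_facloc = batch_facloc, mean_shape = mean_shape,
                 mean_rate = mean_rate, pattern_mix = pm,
                 profile_mode = profile_mode, de_tp_prob = de_tp_prob,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Per-time-point multiplicative effect profile of a temporal pattern
#'
#' Returns the multiplicative factor applied to a temporal gene's base mean at
#' each time point; `effect` is the total log-range of the profile. Growth is
#' nondecreasing, recession nonincreasing, peak rises to an interior maximum,
#' trough dips to an interior minimum (a downward effect), bi-plateau is a
#' single step between two flat levels, and multi-modal oscillates over the
#' early stages then flattens.
#'
#' @param pattern one of the six simulated patterns.
#' @param n_timepoints number of stages T (>= 3).
#' @param effect total log-range (0 gives an all-ones vector).
#' @return numeric vector of length T of multiplicative factors.
#' @export
pattern_effect_profile <- function(pattern, n_timepoints, effect) {
  pattern <- match.arg(pattern, .sim_patterns)
  T_n <- as.integer(n_timepoints)
  if (T_n < 3L) stop("'n_timepoints' must be >= 3")
  mid <- ceiling((T_n + 1) / 2)
  shape <- switch(pattern,
    growth = seq(0, 1, length.out = T_n),
    recession = seq(1, 0, length.out = T_n),
    peak = {
      up <- seq(0, 1, length.out = mid)
      c(up, rev(up)[-1][seq_len(T_n - mid)])
    },
    trough = {
      up <- seq(0, 1, length.out = mid)
      -c(up, rev(up)[-1][seq_len(T_n - mid)])
    },
    `bi-plateau` = rep(c(0, 1), c(floor(T_n / 2), T_n - floor(T_n / 2))),
    `multi-modal` = {
      s <- numeric(T_n)
      s[seq(2L, min(T_n, 4L), by = 2L)] <- 1
      s
    })
  exp(effect * shape)
}

# Classify a realized log-effect profile into one of the six pattern labels
# ("none" when flat). Monotone multi-level profiles are growth/recession; a
# two-level single-step profile (either direction) is bi-plateau; one interior
# turning point gives peak (up-down) or trough (down-up); anything with more
# direction changes is multi-modal.
.classify_profile <- function(l, eps = 1e-12) {
  if (all(abs(l) <= eps)) return("none")
  dl <- diff(l)
  up <- any(dl > eps)
  dn <- any(dl < -eps)
  n_lev <- length(unique(round(l, 9)))
  n_steps <- sum(abs(dl) > eps)
  if (up != dn) {
    if (n_lev == 2L && n_steps == 1L) return("bi-plateau")
    return(if (up) "growth" else "recession")
  }
  s <- sign(dl)[abs(dl) > eps]
  if (sum(diff(s) != 0) == 1L)
    return(if (s[1] > 0) "peak" else "trough")
  "multi-modal"
}

# Draw a per-time-point log-effect profile the way per-time-point differential
# expression produces them: each time point is affected with probability
# tp_prob and receives a signed log-normal factor; draws are kept when the
# realized shape classifies as the target pattern. Falls back to the smooth
# canonical profile if no draw matches within max_tries.
.draw_profile <- function(target, T_n, facloc, facscale, tp_prob,
                          max_tries = 500L) {
  for (i in seq_len(max_tries)) {
    aff <- stats::runif(T_n) < tp_prob
    if (!any(aff)) next
    l <- numeric(T_n)
    l[aff] <- sample(c(1, -1), sum(aff), replace = TRUE) *
      stats::rnorm(sum(aff), facloc, facscale)
    if (.classify_profile(l) == target) return(exp(l))
  }
  pattern_effect_profile(target, T_n, facloc * exp(stats::rnorm(1, 0, facscale)))
}

#' Simulate time-course counts with known temporal truth
#'
#' @param params a [sim_params()] object.
#' @return object of class `"sim_truth"`: list with `counts` (genes x cells
#'   integer matrix), `time` (1..T per cell), `sample_id`, `is_temporal`,
#'   `true_pattern` (`"none"` for flat genes), `time_factors` (genes x T
#'   multiplicative effect profiles), `batch_factors` (genes x samples),
#'   `effect_size` (per-gene log-range), `params`.
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    T_n <- p$n_timepoints
    M <- T_n * p$n_samples_per_timepoint
    n_cells <- M * p$n_cells_per_sample
    G <- p$n_genes

    sample_time <- rep(seq_len(T_n), each = p$n_samples_per_timepoint)
    sample_of_cell <- rep(seq_len(M), each = p$n_cells_per_sample)
    time_of_cell <- sample_time[sample_of_cell]

    base_mean <- stats::rgamma(G, shape = p$mean_shape, rate = p$mean_rate)
    base_mean <- pmax(base_mean, 1e-8)

    is_temporal <- stats::runif(G) < p$de_prob
    true_pattern <- rep("none", G)
    n_de <- sum(is_temporal)
    if (n_de > 0) {
      true_pattern[is_temporal] <- sample(names(p$pattern_mix), n_de,
                                          replace = TRUE, prob = p$pattern_mix)
    }
    # time-point factors per gene (G x T)
    time_fac <- matrix(1, G, T_n)
    if (p$profile_mode == "canonical") {
      eff <- numeric(G)
      eff[is_temporal] <- p$de_facloc * stats::rlnorm(n_de, 0, p$de_facscale)
      for (g in which(is_temporal)) {
        time_fac[g, ] <- pattern_effect_profile(true_pattern[g], T_n, eff[g])
      }
    } else {
      for (g in which(is_temporal)) {
        time_fac[g, ] <- .draw_profile(true_pattern[g], T_n, p$de_facloc,
                                       p$de_facscale, p$de_tp_prob)
      }
    }
    lf <- log(time_fac)
    effect_size <- apply(lf, 1, max) - apply(lf, 1, min)

    # per-sample batch factors applied to all genes (G x M)
    if (p$batch_facloc > 0) {
      bf <- matrix(stats::rlnorm(G * M, meanlog = p$batch_facloc,
                                 sdlog = p$batch_facloc), G, M)
      flip <- matrix(stats::runif(G * M) < 0.5, G, M)
      bf[flip] <- 1 / bf[flip]
    } else {
      bf <- matrix(1, G, M)
    }

    lib <- stats::rlnorm(n_cells, meanlog = p$lib_loc, sdlog = p$lib_scale)

    counts <- matrix(0L, G, n_cells)
    for (j in seq_len(M)) {
      cells <- which(sample_of_cell == j)
      mu_g <- base_mean * time_fac[, sample_time[j]] * bf[, j]
      prop <- mu_g / sum(mu_g)
      lam <- outer(prop, lib[cells])
      counts[, cells] <- stats::rpois(length(lam), lam)
    }
    rownames(counts) <- sprintf("gene%05d", seq_len(G))
    colnames(counts) <- sprintf("cell%06d", seq_len(n_cells))

    structure(list(counts = counts,
                   time = time_of_cell,
                   sample_id = factor(sprintf("s%02d", sample_of_cell)),
                   is_temporal = stats::setNames(is_temporal, rownames(counts)),
                   true_pattern = stats::setNames(true_pattern, rownames(counts)),
                   effect_size = stats::setNames(effect_size, rownames(counts)),
                   time_factors = time_fac,
                   batch_factors = bf,
                   params = p),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated time-course counts\n")
  cat("  genes:", nrow(x$counts), " cells:", ncol(x$counts), "\n")
  cat("  time points:", x$params$n_timepoints,
      " samples:", nlevels(x$sample_id), "\n")
  cat("  temporal genes:", sum(x$is_temporal),
      sprintf("(%.1f%%)", 100 * mean(x$is_temporal)), "\n")
  print(table(x$true_pattern[x$is_temporal]))
  invisible(x)
}

#' Convert simulator output to an expression bundle
#'
#' @param truth a [simulate_counts()] object.
#' @param ... passed to [expression_bundle()] (e.g. `max_zero_prop`).
#' @export
as_expression_bundle <- function(truth, ...) {
  stopifnot(inherits(truth, "sim_truth"))
  expression_bundle(counts = truth$counts, time = truth$time,
                    sample_id = truth$sample_id, ...)
}

#' Mix cells across adjacent stages ("intertwined" cells)
#'
#' Re-composes each stage so a fraction `p1` of its cells come from the stage
#' itself, `p2` from the previous stage and `p3` from the next (boundary
#' stages borrow only from their single neighbour with proportions
#' renormalised to `p1/(p1 + p2)` and `p2/(p1 + p2)`). Expression stays that
#' of the source cell; the time label (and target sample) reflect the new
#' assignment — emulating asynchronous differentiation.
#'
#' @param truth a [simulate_counts()] object.
#' @param p1,p2,p3 mixing proportions, summing to 1.
#' @param seed optional seed.
#' @return a new `"sim_truth"` with the same dimensions.
#' @export
intertwine_cells <- function(truth, p1 = 0.9, p2 = 0.08, p3 = 0.02,
                             seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (abs(p1 + p2 + p3 - 1) > 1e-8) stop("p1 + p2 + p3 must sum to 1")
  T_n <- truth$params$n_timepoints
  with_seed(seed, {
    src <- integer(ncol(truth$counts))
    for (s in levels(truth$sample_id)) {
      cells <- which(truth$sample_id == s)
      stage <- truth$time[cells[1]]
      if (stage == 1L) {
        stages <- c(1L, 2L); probs <- c(p1, p2) / (p1 + p2)
      } else if (stage == T_n) {
        stages <- c(T_n, T_n - 1L); probs <- c(p1, p2) / (p1 + p2)
      } else {
        stages <- c(stage, stage - 1L, stage + 1L); probs <- c(p1, p2, p3)
      }
      pick_stage <- sample(stages, length(cells), replace = TRUE, prob = probs)
      src[cells[pick_stage == stage]] <- cells[pick_stage == stage]
      for (st in setdiff(unique(pick_stage), stage)) {
        tgt <- cells[pick_stage == st]
        pool <- which(truth$time == st)
        src[tgt] <- sample(pool, length(tgt),
                           replace = length(tgt) > length(pool))
      }
    }
    out <- truth
    out$counts <- truth$counts[, src, drop = FALSE]
    colnames(out$counts) <- colnames(truth$counts)
    out$source_cell <- src
    out
  })
}
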