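`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never clobbers user randomness.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)

# Solve A x = b by Cholesky with a relative condition guard; NULL signals a
# (near-)singular system so callers can treat the column set as redundant.
.chol_solve <- function(A, b, rcond_tol = 1e-10) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  d <- diag(R)
  if (min(d) < sqrt(rcond_tol) * max(d)) return(NULL)
  backsolve(R, backsolve(R, b, transpose = TRUE))
}
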