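# Internal helpers shared across modules.

nextPow2 <- function(n) as.integer(2^ceiling(log2(n)))

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed = NULL` leaves the stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stratified fold assignment: every fold contains both classes whenever
# the class counts allow it. Caller controls the RNG state.
stratifiedFolds <- function(labels, k) {
  labels <- as.factor(labels)
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Index range of `times` falling inside the closed window [w1, w2],
# with half-sample tolerance so printed millisecond bounds that sit a
# fraction of a sample off the grid still select the intended samples.
timesInWindow <- function(times, window, tol = NULL) {
  if (is.null(tol)) tol <- 0.5 * stats::median(diff(times))
  which(times >= window[1] - tol & times <= window[2] + tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
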