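# Internal helpers shared across modules.

# m/z matching tolerance: the larger of an absolute window (Da) and a
# relative window (ppm of the value itself).
mz_tolerance <- function(mz, abs_tol, ppm_tol) {
  pmax(abs_tol, ppm_tol * mz * 1e-6)
}

# Single-linkage grouping of 1-d values: sorted values are chained while the
# gap between neighbours is within the local tolerance. Returns an integer
# group index aligned with the input order.
group_values_1d <- function(values, abs_tol, ppm_tol) {
  n <- length(values)
  if (n == 0L) return(integer(0))
  ord <- order(values)
  v <- values[ord]
  grp <- integer(n)
  grp[1L] <- 1L
  if (n > 1L) {
    gaps <- diff(v)
    tol <- mz_tolerance((v[-n] + v[-1L]) / 2, abs_tol, ppm_tol)
    grp <- cumsum(c(1L, as.integer(gaps > tol)))
  }
  out <- integer(n)
  out[ord] <- grp
  out
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) * 7919L + 17L
}

# Rank-based (Mann-Whitney) AUC of scores for a binary label vector.
rank_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
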