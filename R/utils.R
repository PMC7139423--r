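# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Stable 31-bit hash of a character key.  Used to derive per-participant
# random-number substreams from one master seed so that adding a participant
# (or changing simulation order) never perturbs existing series.
hash_stream <- function(...) {
  s <- paste(unlist(list(...)), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  h
}

substream_seed <- function(seed, ...) {
  as.integer((as.numeric(seed) %% 2147483629 + 1000003 * hash_stream(...)) %%
               2147483629)
}

# Guarded central-difference Hessian.  The restricted log-likelihood is only
# defined where the marginal covariance is positive definite; near boundary
# estimates a fixed step can leave that region, so steps shrink until every
# required evaluation is finite.
fd_hessian <- function(f, x, rel_h = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x) * rel_h, 1e-7)
  for (i in seq_len(k)) {
    for (try in 1:30) {
      ei <- replace(numeric(k), i, h[i])
      if (is.finite(f(x + ei)) && is.finite(f(x - ei))) break
      h[i] <- h[i] / 2
    }
  }
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(k), j, h[j])
        v <- (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
                f(x - ei - ej)) / (4 * h[i] * h[j])
        if (!is.finite(v)) v <- 0
        H[i, j] <- H[j, i] <- v
      }
    }
  }
  H
}

# Moore-Penrose inverse via SVD, used only as a fallback when the observed
# information matrix is numerically singular at a boundary solution.
ginv_svd <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
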