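# internal numerical helpers

log2pi <- log(2 * pi)

## log(sum(exp(x))) along columns of a matrix, guarded against underflow
logsumexp <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 2L, max)
    bad <- !is.finite(m)
    out <- m + log(colSums(exp(sweep(x, 2L, ifelse(bad, 0, m)))))
    out[bad] <- -Inf
    out
  } else {
    m <- max(x)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(x - m)))
  }
}

## central-difference gradient
num_grad <- function(f, x, h = NULL, ...) {
  if (is.null(h)) h <- 1e-5 * pmax(1, abs(x))
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- h[j]
    g[j] <- (f(x + e, ...) - f(x - e, ...)) / (2 * h[j])
  }
  g
}

## central-difference Hessian (symmetrized)
num_hessian <- function(f, x, h = NULL, ...) {
  d <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(x))
  H <- matrix(0, d, d)
  f0 <- f(x, ...)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h[i]
    H[i, i] <- (f(x + ei, ...) - 2 * f0 + f(x - ei, ...)) / h[i]^2
    if (i < d) for (j in seq.int(i + 1L, d)) {
      ej <- numeric(d); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej, ...) - f(x + ei - ej, ...) -
           f(x - ei + ej, ...) + f(x - ei - ej, ...)) / (4 * h[i] * h[j])
    }
  }
  H
}

## numeric Jacobian of a vector-valued function
num_jacobian <- function(f, x, h = NULL, ...) {
  if (is.null(h)) h <- 1e-6 * pmax(1, abs(x))
  f0 <- f(x, ...)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- h[j]
    J[, j] <- (f(x + e, ...) - f(x - e, ...)) / (2 * h[j])
  }
  J
}

## correlation matrix from a vector of atanh-transformed lower-triangle entries
corr_from_atanh <- function(z, d) {
  R <- diag(d)
  if (d > 1L && length(z)) {
    R[lower.tri(R)] <- tanh(z)
    R[upper.tri(R)] <- t(R)[upper.tri(R)]
  }
  R
}

`%||%` <- function(a, b) if (is.null(a)) b else a
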