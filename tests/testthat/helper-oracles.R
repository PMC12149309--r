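# Independent definitional oracles, written from the mathematical definitions
# with plain loops. They share no code with the package internals they check.

# Hankel embedding by double loop
oracle_embed <- function(x, L) {
  n <- length(x)
  k <- n - L + 1
  X <- matrix(0, L, k)
  for (i in seq_len(L)) {
    for (j in seq_len(k)) X[i, j] <- x[i + j - 1]
  }
  X
}

# anti-diagonal averaging by explicit enumeration
oracle_inverse_embed <- function(X) {
  L <- nrow(X)
  K <- ncol(X)
  n <- L + K - 1
  out <- numeric(n)
  for (s in seq_len(n)) {
    vals <- c()
    for (i in seq_len(L)) {
      j <- s - i + 1
      if (j >= 1 && j <= K) vals <- c(vals, X[i, j])
    }
    out[s] <- mean(vals)
  }
  out
}

# one full thresholding iteration assembled from the definitions:
# SVD -> per-value soft threshold -> rank-wise outer-product sum ->
# anti-diagonal average -> re-embed
oracle_iterate_once <- function(X, tau) {
  s <- svd(X)
  recon <- matrix(0, nrow(X), ncol(X))
  for (r in seq_along(s$d)) {
    sig <- max(0, s$d[r] - tau)
    if (sig > 0) recon <- recon + sig * (s$u[, r] %o% s$v[, r])
  }
  oracle_embed(oracle_inverse_embed(recon), nrow(X))
}

# agreement statistics from definitional loops
oracle_agreement <- function(a, b) {
  n <- length(a)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- a[i] - b[i]
  bias <- sum(d) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - bias)^2
  sd_d <- sqrt(ss / (n - 1))
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- 0
  da <- 0
  db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  list(
    pearson_r = num / sqrt(da * db),
    rmse = sqrt(sum(d^2) / n),
    mae = sum(abs(d)) / n,
    bias = bias,
    loa_low = bias - 1.96 * sd_d,
    loa_high = bias + 1.96 * sd_d
  )
}

# trapezoid-rule RMS of the clean synthetic waveform over [0, duration]
oracle_rms_trapezoid <- function(spec, n_fine = 200000) {
  t <- seq(0, spec$duration, length.out = n_fine + 1)
  y <- spec$resp_amp * sin(2 * pi * spec$resp_freq * t)
  for (k in seq_along(spec$cardiac_freqs)) {
    y <- y + spec$cardiac_amps[k] * sin(2 * pi * spec$cardiac_freqs[k] * t)
  }
  y2 <- y^2
  dt <- spec$duration / n_fine
  integral <- sum((y2[-1] + y2[-length(y2)]) / 2) * dt
  sqrt(integral / spec$duration)
}
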