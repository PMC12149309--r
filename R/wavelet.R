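# Periodized orthonormal Daubechies wavelet transform. Written in-package
# because the surrounding R stack ships no discrete-wavelet package; only the
# pieces the denoising baseline needs (periodic DWT/IDWT, soft shrinkage).

# scaling (low-pass) filters, orthonormal Daubechies family
daubechies_filter <- function(name) {
  switch(name,
    "haar" = ,
    "db1" = c(1, 1) / sqrt(2),
    "db2" = c(
      0.48296291314469025, 0.83651630373746899,
      0.22414386804185735, -0.12940952255092145
    ),
    "db4" = c(
      0.23037781330885523, 0.71484657055254153,
      0.63088076792959036, -0.02798376941698385,
      -0.18703481171888114, 0.03084138183598697,
      0.03288301166698295, -0.01059740178499728
    ),
    stop("unknown wavelet '", name, "'; supported: haar/db1, db2, db4",
      call. = FALSE
    )
  )
}

# one periodized analysis step: x (even length) -> list(approx, detail)
dwt_step <- function(x, h) {
  n <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1) # quadrature mirror filter
  half <- n / 2
  a <- numeric(half)
  d <- numeric(half)
  base <- 2 * (seq_len(half) - 1) # 0-based start of each window
  for (m in seq_along(h)) {
    idx <- (base + m - 1) %% n + 1
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(approx = a, detail = d)
}

# one periodized synthesis step, exact inverse of dwt_step
idwt_step <- function(a, d, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n <- 2 * length(a)
  x <- numeric(n)
  base <- 2 * (seq_along(a) - 1)
  for (m in seq_along(h)) {
    idx <- (base + m - 1) %% n + 1
    x[idx] <- x[idx] + h[m] * a + g[m] * d
  }
  x
}

#' Wavelet soft-threshold denoising baseline
#'
#' Multi-level periodized discrete wavelet transform, soft shrinkage of all
#' detail coefficients, and reconstruction. This is the conventional baseline
#' the iterative SVD scheme is benchmarked against; the exact settings of the
#' historical pipeline are not published, so the defaults here are the widely
#' used ones — db4, 4 decomposition levels, and the universal threshold
#' `sigma_hat * sqrt(2 log N)` with `sigma_hat = MAD(finest detail) / 0.6745`
#' — and outputs should be read as a baseline approximation.
#'
#' @param x Signal (numeric vector or data frame with a `value` column).
#' @param wavelet `"db4"` (default), `"db2"`, or `"haar"`/`"db1"`.
#' @param level Decomposition depth; must satisfy `2^level <= length(x)`.
#' @param threshold `"universal"` (default), `"none"`, or a numeric threshold
#'   applied to every detail coefficient.
#' @return Denoised numeric vector, same length as the input.
#' @export
#' @examples
#' sim <- bcg_simulate(bcg_spec(duration = 5), snr_db = 5, seed = 3)
#' w <- wavelet_denoise(sim$noisy)
#' measure_snr(w, sim$cardiac)
wavelet_denoise <- function(x, wavelet = "db4", level = 4,
                            threshold = "universal") {
  v <- signal_values(x)
  h <- daubechies_filter(wavelet)
  n0 <- length(v)
  if (2^level > n0) {
    stop("level ", level, " too deep for a signal of ", n0, " samples",
      call. = FALSE
    )
  }
  # pad to a multiple of 2^level; transform+inverse is exact, so the pad
  # returns to ~0 and is dropped after reconstruction
  block <- 2^level
  n <- ceiling(n0 / block) * block
  v_pad <- c(v, rep(0, n - n0))

  approx <- v_pad
  details <- vector("list", level)
  for (j in seq_len(level)) {
    st <- dwt_step(approx, h)
    approx <- st$approx
    details[[j]] <- st$detail
  }

  if (identical(threshold, "universal")) {
    sigma_hat <- stats::mad(details[[1]]) # constant 1.4826 = 1/0.6745
    thr <- sigma_hat * sqrt(2 * log(n))
  } else if (identical(threshold, "none")) {
    thr <- 0
  } else if (is.numeric(threshold) && length(threshold) == 1 && threshold >= 0) {
    thr <- threshold
  } else {
    stop("threshold must be 'universal', 'none', or a single non-negative number",
      call. = FALSE
    )
  }
  if (thr > 0) {
    details <- lapply(details, function(d) sign(d) * pmax(abs(d) - thr, 0))
  }

  for (j in rev(seq_len(level))) {
    approx <- idwt_step(approx, details[[j]], h)
  }
  approx[seq_len(n0)]
}
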