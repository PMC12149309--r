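#' Hankel (trajectory) matrix embedding
#'
#' Slides a window of length `L` along the signal to build the `L x (N-L+1)`
#' trajectory matrix `X[i, j] = x[i + j - 1]`, whose anti-diagonals are
#' constant.
#'
#' @param x Signal (numeric vector or data frame with a `value` column).
#' @param L Window length in samples, `1 <= L <= length(x)`.
#' @return Numeric matrix of dimension `L x (N - L + 1)`.
#' @export
#' @examples
#' embed_hankel(c(1, 2, 3, 4), 2)
embed_hankel <- function(x, L) {
  v <- signal_values(x)
  n <- length(v)
  if (L < 1) stop("window L must be at least 1", call. = FALSE)
  if (L > n) stop("window L (", L, ") exceeds signal length (", n, ")", call. = FALSE)
  k <- n - L + 1
  matrix(v[outer(seq_len(L), seq_len(k) - 1L, `+`)], nrow = L, ncol = k)
}

#' Anti-diagonal averaging (inverse Hankel embedding)
#'
#' Maps an `L x K` matrix back to a length `N = L + K - 1` signal: sample `n`
#' is the mean of all entries on the anti-diagonal `i + j - 2 == n - 1`. This
#' is the orthogonal projection onto Hankel structure, so it inverts
#' [embed_hankel()] exactly and is non-expansive in Frobenius norm.
#'
#' @param X Numeric matrix (need not be Hankel).
#' @return Numeric vector of length `nrow(X) + ncol(X) - 1`.
#' @export
#' @examples
#' inverse_embed(embed_hankel(1:5, 3))
inverse_embed <- function(X) {
  if (!is.matrix(X) || length(X) == 0) stop("X must be a non-empty matrix", call. = FALSE)
  l <- nrow(X)
  k <- ncol(X)
  n <- l + k - 1
  # mean per anti-diagonal, computed as offset + mean(deviation from offset):
  # exactly the offset on constant anti-diagonals, so Hankel input round-trips
  # bit-for-bit
  offset <- numeric(n)
  offset[seq_len(k)] <- X[1, ]
  if (l > 1) offset[(k + 1):n] <- X[2:l, k]
  diag_id <- as.vector(row(X) + col(X)) - 1L
  sums <- rowsum(as.vector(X) - offset[diag_id], group = diag_id)
  counts <- pmin(seq_len(n), l, k, n - seq_len(n) + 1)
  offset + as.vector(sums) / counts
}

#' Soft-threshold singular values
#'
#' Shrinks each singular value toward zero: `sigma_new = max(0, sigma - tau)`.
#' Order is preserved for a non-increasing input.
#'
#' @param sigma Non-increasing, non-negative singular values.
#' @param tau Threshold (>= 0), in the same units as the singular values.
#' @return Shrunk singular values, same length.
#' @export
#' @examples
#' shrink_singular_values(c(5, 3, 1), 2)
shrink_singular_values <- function(sigma, tau) {
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  pmax(sigma - tau, 0)
}

#' One ESVT iteration on a trajectory matrix
#'
#' SVD, singular-value soft-thresholding at `tau`, low-rank reconstruction
#' `U diag(sigma_new) V^T`, anti-diagonal averaging, and re-embedding. The
#' output is Hankel and its Frobenius norm never exceeds the input's
#' (thresholding shrinks the norm; averaging is an orthogonal projection).
#'
#' @param X Trajectory matrix (from [embed_hankel()]).
#' @param tau Soft threshold (>= 0).
#' @return Hankel matrix of the same dimension.
#' @export
esvt_iterate_once <- function(X, tau) {
  if (!is.matrix(X) || length(X) == 0) stop("X must be a non-empty matrix", call. = FALSE)
  s <- tryCatch(svd(X), error = function(e) {
    stop("SVD failed on ", nrow(X), "x", ncol(X), " matrix: ", conditionMessage(e),
      call. = FALSE
    )
  })
  sig <- shrink_singular_values(s$d, tau)
  r <- sum(sig > 0)
  if (r == 0) {
    return(matrix(0, nrow(X), ncol(X)))
  }
  xs <- s$u[, seq_len(r), drop = FALSE] %*%
    (sig[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
  embed_hankel(inverse_embed(xs), nrow(X))
}

#' ESVT denoising of a time series
#'
#' The full denoising pipeline: embed the signal into an `L x (N-L+1)` Hankel
#' matrix and alternate singular-value soft-thresholding with Hankel
#' re-projection for `iterations` passes, then average the final matrix back
#' to a time series. The re-projection between iterations is what makes the
#' iteration count a real degree of freedom: thresholding singular values
#' `i` times in a row without it would collapse to a single threshold
#' `i * tau`.
#'
#' @param x Signal (numeric vector, or data frame with a `value` column).
#' @param tau Soft threshold (singular-value units).
#' @param iterations Number of ESVT passes (>= 1).
#' @param window Embedding window `L` in samples; the default 200 is 2 s at
#'   100 Hz.
#' @param rate Sampling rate (Hz), carried into the output for plotting.
#' @param rehankelize If `TRUE` (default) each iteration re-projects onto
#'   Hankel structure; if `FALSE` the threshold is applied `iterations` times
#'   to the singular values of one SVD (equivalent to a single threshold
#'   `iterations * tau`), kept for comparison.
#' @param keep_iterations If `TRUE`, the denoised signal after every iteration
#'   is stored in the result (`$iterates`, a list of numeric vectors).
#' @return An object of class `esvt_denoise`: list with `denoised` (tibble
#'   `time`, `value`), `input` (numeric), `params` (tau, iterations, window),
#'   `per_iteration_energy` (Frobenius norms after each iteration, never
#'   increasing), `rate`, and optionally `iterates`.
#' @export
#' @examples
#' sim <- bcg_simulate(bcg_spec(duration = 5), snr_db = 5, seed = 7)
#' fit <- esvt_denoise(sim$noisy, tau = 20, iterations = 2)
#' glance(fit)
esvt_denoise <- function(x, tau, iterations, window = 200, rate = 100,
                         rehankelize = TRUE, keep_iterations = FALSE) {
  v <- signal_values(x)
  if (iterations < 1) stop("iterations must be at least 1", call. = FALSE)
  if (window > length(v)) {
    stop("signal (", length(v), " samples) is shorter than the window (",
      window, ")",
      call. = FALSE
    )
  }
  energy <- numeric(iterations)
  iterates <- if (keep_iterations) vector("list", iterations) else NULL
  if (rehankelize) {
    X <- embed_hankel(v, window)
    for (i in seq_len(iterations)) {
      X <- esvt_iterate_once(X, tau)
      energy[i] <- sqrt(sum(X^2))
      if (keep_iterations) iterates[[i]] <- inverse_embed(X)
    }
    den <- inverse_embed(X)
  } else {
    X <- embed_hankel(v, window)
    s <- svd(X)
    for (i in seq_len(iterations)) {
      sig <- shrink_singular_values(s$d, i * tau)
      energy[i] <- sqrt(sum(sig^2))
      if (keep_iterations || i == iterations) {
        r <- sum(sig > 0)
        xs <- if (r == 0) {
          matrix(0, nrow(X), ncol(X))
        } else {
          s$u[, seq_len(r), drop = FALSE] %*%
            (sig[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
        }
        den <- inverse_embed(xs)
        if (keep_iterations) iterates[[i]] <- den
      }
    }
  }
  structure(
    list(
      denoised = tibble::tibble(time = (seq_along(den) - 1) / rate, value = den),
      input = v,
      params = list(tau = tau, iterations = iterations, window = window),
      per_iteration_energy = energy,
      rate = rate,
      iterates = iterates
    ),
    class = "esvt_denoise"
  )
}

#' @export
print.esvt_denoise <- function(x, ...) {
  cat(
    "<esvt_denoise> N =", length(x$input), "samples, tau =", x$params$tau,
    ", iterations =", x$params$iterations, ", window =", x$params$window, "\n"
  )
  invisible(x)
}

#' @rdname esvt_denoise
#' @param x An `esvt_denoise` object.
#' @param ... Unused.
#' @method tidy esvt_denoise
#' @export
tidy.esvt_denoise <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$per_iteration_energy),
    frobenius_energy = x$per_iteration_energy
  )
}

#' @rdname esvt_denoise
#' @method glance esvt_denoise
#' @export
glance.esvt_denoise <- function(x, ...) {
  tibble::tibble(
    n = length(x$input),
    tau = x$params$tau,
    iterations = x$params$iterations,
    window = x$params$window,
    final_energy = x$per_iteration_energy[length(x$per_iteration_energy)],
    residual_rms = rms(x$denoised$value - x$input)
  )
}

#' Denoise a long record in overlapping chunks
#'
#' Splits the signal into chunks, denoises each with [esvt_denoise()], and
#' cross-fades the overlaps with raised-cosine weights. Signals no longer than
#' one chunk are passed to [esvt_denoise()] unchanged. Chunking keeps the
#' trajectory matrix small (30 s chunks at 100 Hz give a 200 x 2801 matrix)
#' at the cost of a small boundary discrepancy against the monolithic result.
#'
#' @inheritParams esvt_denoise
#' @param chunk_s Chunk length in seconds; must exceed `2 * overlap_s` and
#'   cover at least `window` samples.
#' @param overlap_s Overlap between adjacent chunks in seconds.
#' @return An `esvt_denoise` object (per-iteration energies are summed over
#'   chunks).
#' @export
chunked_denoise <- function(x, tau, iterations, window = 200, rate = 100,
                            chunk_s = 30, overlap_s = 2, rehankelize = TRUE) {
  v <- signal_values(x)
  chunk_n <- round(chunk_s * rate)
  ov <- round(overlap_s * rate)
  if (chunk_n <= 2 * ov) stop("chunk_s must exceed 2 * overlap_s", call. = FALSE)
  if (chunk_n < window) stop("chunk shorter than the embedding window", call. = FALSE)
  n <- length(v)
  if (n <= chunk_n) {
    return(esvt_denoise(v, tau, iterations,
      window = window, rate = rate,
      rehankelize = rehankelize
    ))
  }
  step <- chunk_n - ov
  # full-length chunks only; the last one is anchored to the record end
  starts <- unique(c(seq(1, n - chunk_n + 1, by = step), n - chunk_n + 1))
  out <- numeric(n)
  wsum <- numeric(n)
  energy <- numeric(iterations)
  for (s0 in starts) {
    s1 <- min(s0 + chunk_n - 1, n)
    fit <- esvt_denoise(v[s0:s1], tau, iterations,
      window = window, rate = rate,
      rehankelize = rehankelize
    )
    m <- s1 - s0 + 1
    w <- rep(1, m)
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(ov) / (ov + 1)) # raised cosine 0..1
    if (s0 > 1) w[seq_len(ov)] <- ramp
    if (s1 < n) w[m - ov + seq_len(ov)] <- rev(ramp)
    out[s0:s1] <- out[s0:s1] + w * fit$denoised$value
    wsum[s0:s1] <- wsum[s0:s1] + w
    energy <- energy + fit$per_iteration_energy
  }
  den <- out / wsum
  structure(
    list(
      denoised = tibble::tibble(time = (seq_along(den) - 1) / rate, value = den),
      input = v,
      params = list(
        tau = tau, iterations = iterations, window = window,
        chunk_s = chunk_s, overlap_s = overlap_s
      ),
      per_iteration_energy = energy,
      rate = rate,
      iterates = NULL
    ),
    class = "esvt_denoise"
  )
}
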