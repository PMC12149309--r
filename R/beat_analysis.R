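#' Detect heartbeat peaks in an ECG or BCG signal
#'
#' Band-pass filters the signal for the requested modality (R waves sit in a
#' higher band than the broader BCG J wave), then picks local maxima above an
#' adaptive threshold — a rolling median plus `k` times the MAD of the
#' filtered signal — and enforces a refractory period by keeping the largest
#' peak within any conflicting pair.
#'
#' @param x Signal (numeric vector or data frame with a `value` column).
#' @param rate Sampling rate (Hz).
#' @param mode `"bcg-j"` (1-12 Hz pre-filter) or `"ecg-r"` (5-25 Hz).
#' @param refractory_s Minimum separation between reported peaks (s).
#' @param k Threshold multiplier on the MAD.
#' @param median_window_s Width of the rolling-median baseline (s).
#' @return A peak-annotation tibble with columns `index` (0-based sample
#'   index, matching the dataset's peak-file convention) and `time` (s);
#'   attribute `rate`. A flat signal yields zero rows, which is valid.
#' @export
#' @examples
#' bt <- beat_train(60, duration = 20, fs = 100, seed = 1)
#' detect_peaks(bt$signal, rate = 100, mode = "bcg-j")
detect_peaks <- function(x, rate, mode = c("bcg-j", "ecg-r"),
                         refractory_s = 0.3, k = 2.5, median_window_s = 1.5) {
  mode <- match.arg(mode)
  v <- signal_values(x)
  if (anyNA(v)) stop("signal contains NA/NaN values", call. = FALSE)
  if (length(v) <= 2 * refractory_s * rate) {
    stop("signal shorter than twice the refractory period", call. = FALSE)
  }
  band <- if (mode == "ecg-r") c(5, 25) else c(1, 12)
  band[2] <- min(band[2], 0.45 * rate)
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  f <- as.numeric(signal::filtfilt(bf, v))

  win <- floor(median_window_s * rate / 2) * 2 + 1 # odd
  baseline <- stats::runmed(f, min(win, length(f) - (1 - length(f) %% 2)))
  thr <- baseline + k * stats::mad(f)

  n <- length(f)
  is_max <- c(FALSE, f[2:(n - 1)] > f[1:(n - 2)] & f[2:(n - 1)] >= f[3:n], FALSE)
  cand <- which(is_max & f > thr)

  # refractory: greedy by amplitude
  keep <- logical(length(cand))
  min_gap <- refractory_s * rate
  for (i in order(f[cand], decreasing = TRUE)) {
    if (!any(abs(cand[keep] - cand[i]) < min_gap)) keep[i] <- TRUE
  }
  idx <- sort(cand[keep])
  out <- tibble::tibble(index = idx - 1L, time = (idx - 1) / rate)
  attr(out, "rate") <- rate
  out
}

#' Heart rate from peak annotations
#'
#' @param peaks Peak annotations: a tibble with a `time` column (s), as from
#'   [detect_peaks()] or [read_peak_csv()].
#' @param method `"mean-interval"` (one HR per recording: 60 over the mean
#'   inter-peak interval) or `"per-beat"` (60 over each interval).
#' @return A single bpm value (`"mean-interval"`) or a vector of per-beat bpm
#'   values (`"per-beat"`, length `nrow(peaks) - 1`).
#' @export
#' @examples
#' peaks <- tibble::tibble(time = 0:10)
#' peaks_to_hr(peaks) # 60 bpm
peaks_to_hr <- function(peaks, method = c("mean-interval", "per-beat")) {
  method <- match.arg(method)
  times <- if (is.data.frame(peaks)) peaks$time else peaks
  if (length(times) < 2) {
    stop("at least two peaks are required for a heart rate", call. = FALSE)
  }
  iv <- diff(times)
  if (any(iv <= 0)) stop("peak times must be strictly increasing", call. = FALSE)
  switch(method,
    "mean-interval" = 60 / mean(iv),
    "per-beat" = 60 / iv
  )
}

#' Agreement statistics between two heart-rate series
#'
#' Pairwise agreement between BCG-derived and ECG-derived heart rates:
#' Pearson correlation, RMSE, MAE, and the Bland-Altman bias and limits of
#' agreement. Differences are `hr_a - hr_b` (BCG minus ECG by convention, so
#' a positive bias means the BCG reads high); the limits of agreement are
#' `bias +/- 1.96 * SD(diff)` with the sample (n-1) standard deviation.
#'
#' @param hr_a,hr_b Equal-length paired heart-rate vectors (bpm), n >= 3.
#' @return An object of class `hr_agreement`: list with the six statistics
#'   (`pearson_r`, `rmse`, `mae`, `bias`, `loa_low`, `loa_high`), `n_pairs`,
#'   `r_defined` (FALSE when either input is constant, in which case
#'   `pearson_r` is `NA` and the remaining statistics are still computed),
#'   and `data` (tibble `hr_a`, `hr_b`, `mean_hr`, `diff`).
#' @export
#' @examples
#' a <- c(60, 72, 80, 66)
#' b <- c(59, 73, 79, 68)
#' glance(hr_agreement(a, b))
hr_agreement <- function(hr_a, hr_b) {
  a <- as.double(hr_a)
  b <- as.double(hr_b)
  if (length(a) != length(b)) stop("paired inputs must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("at least 3 pairs are required", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d) # n-1 denominator
  r_defined <- stats::sd(a) > 0 && stats::sd(b) > 0
  structure(
    list(
      pearson_r = if (r_defined) stats::cor(a, b) else NA_real_,
      rmse = sqrt(mean(d^2)),
      mae = mean(abs(d)),
      bias = bias,
      loa_low = bias - 1.96 * sd_d,
      loa_high = bias + 1.96 * sd_d,
      n_pairs = n,
      r_defined = r_defined,
      data = tibble::tibble(
        hr_a = a, hr_b = b,
        mean_hr = (a + b) / 2, diff = d
      )
    ),
    class = "hr_agreement"
  )
}

#' @export
print.hr_agreement <- function(x, ...) {
  cat("<hr_agreement> n =", x$n_pairs, "pairs\n")
  cat(
    "  r =", round(x$pearson_r, 3),
    " RMSE =", round(x$rmse, 3), "bpm",
    " MAE =", round(x$mae, 3), "bpm\n"
  )
  cat(
    "  bias =", round(x$bias, 3), "bpm, LOA [",
    round(x$loa_low, 3), ",", round(x$loa_high, 3), "]\n"
  )
  invisible(x)
}

#' @rdname hr_agreement
#' @param x An `hr_agreement` object.
#' @param ... Unused.
#' @method tidy hr_agreement
#' @export
tidy.hr_agreement <- function(x, ...) {
  tibble::tibble(
    statistic = c("pearson_r", "rmse", "mae", "bias", "loa_low", "loa_high"),
    estimate = c(x$pearson_r, x$rmse, x$mae, x$bias, x$loa_low, x$loa_high)
  )
}

#' @rdname hr_agreement
#' @method glance hr_agreement
#' @export
glance.hr_agreement <- function(x, ...) {
  tibble::tibble(
    pearson_r = x$pearson_r, rmse = x$rmse, mae = x$mae, bias = x$bias,
    loa_low = x$loa_low, loa_high = x$loa_high, n_pairs = x$n_pairs
  )
}

#' Match detected peaks to ground-truth times
#'
#' Greedy one-to-one matching of detected peak times to reference times within
#' a tolerance, used to score detectors on generated beat trains.
#'
#' @param detected,truth Peak times (s); tibbles with a `time` column are
#'   accepted.
#' @param tol_s Matching tolerance (s).
#' @return A list with `n_matched`, `recall` (fraction of truth matched),
#'   `precision`, and `abs_err_s` (absolute timing errors of the matches).
#' @export
match_peaks <- function(detected, truth, tol_s = 0.03) {
  dt <- if (is.data.frame(detected)) detected$time else as.double(detected)
  tr <- if (is.data.frame(truth)) truth$time else as.double(truth)
  used <- logical(length(dt))
  errs <- numeric(0)
  for (t0 in tr) {
    if (length(dt) == 0) break
    j <- which.min(ifelse(used, Inf, abs(dt - t0)))
    if (length(j) == 1 && !used[j] && abs(dt[j] - t0) <= tol_s) {
      used[j] <- TRUE
      errs <- c(errs, abs(dt[j] - t0))
    }
  }
  list(
    n_matched = length(errs),
    recall = if (length(tr)) length(errs) / length(tr) else NA_real_,
    precision = if (length(dt)) length(errs) / length(dt) else NA_real_,
    abs_err_s = errs
  )
}
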