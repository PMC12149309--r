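#' Derive a reproducible sub-stream seed
#'
#' Mixes a master seed with one or more stream indices so that every
#' realization of an experiment gets its own seed, reproducible without
#' generating the preceding realizations. The mix is a small multiplicative
#' congruential hash over the Mersenne prime 2^31 - 1, so results always fit
#' in a 32-bit integer.
#'
#' @param seed Master seed (non-negative integer).
#' @param ... Integer stream indices (e.g. realization number, grid cell).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 3)
#' derive_seed(1, 3, 7)
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.double(seed) %% m
  for (k in c(...)) {
    # 48271 is the MINSTD multiplier; products stay below 2^53 so doubles are exact
    h <- (h * 48271 + as.double(k) + 1) %% m
  }
  h <- (h * 48271 + 1) %% m
  as.integer(h %% (m - 2) + 1)
}

# Accept a bare numeric vector or a data frame with a signal column.
signal_values <- function(x, col = "value") {
  if (is.data.frame(x)) {
    if (!col %in% names(x)) {
      stop("data frame input must have a '", col, "' column", call. = FALSE)
    }
    x <- x[[col]]
  }
  if (!is.numeric(x)) stop("signal must be numeric", call. = FALSE)
  as.double(x)
}

rms <- function(x) sqrt(mean(x^2))

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
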