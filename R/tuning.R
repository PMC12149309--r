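#' Pilot scale for threshold grids
#'
#' Median leading singular value of the trajectory matrix over a few noisy
#' pilot realizations of the spec, used to express threshold grids in a
#' scale-free way (fractions of the typical largest singular value).
#'
#' @param spec A [bcg_spec()].
#' @param snr_db Nominal noise level of the pilots (dB).
#' @param window Embedding window (samples).
#' @param n_pilot Number of pilot realizations.
#' @param seed Master seed; pilot seeds are derived sub-streams.
#' @return Median leading singular value (a.u.).
#' @export
pilot_sigma <- function(spec, snr_db = 0, window = 200, n_pilot = 5, seed = 1L) {
  lead <- vapply(seq_len(n_pilot), function(p) {
    sim <- bcg_simulate(spec, snr_db, seed = derive_seed(seed, 9999L, p))
    svd(embed_hankel(sim$noisy, window), nu = 0, nv = 0)$d[1]
  }, numeric(1))
  stats::median(lead)
}

#' Grid search for the ESVT threshold and iteration count
#'
#' For every `(tau, i)` cell, generates `n_realizations` noisy synthetic BCG
#' signals (per-realization seeds derived from `seed`), denoises them, and
#' averages the output SNR against the chosen reference. The optimum is the
#' cell with the highest mean SNR; ties go to the smaller iteration count,
#' then the smaller threshold (the cheapest adequate filter).
#'
#' By default the score references the full clean signal
#' (cardiac + respiratory). Scoring against the cardiac component alone is
#' available via `reference = "cardiac"`, but under the study's synthetic
#' conditions the respiratory term dominates the signal and no soft-threshold
#' filter can remove it while keeping the much smaller cardiac harmonics, so
#' that objective is maximized by suppressing everything (the all-zero output
#' scores exactly 0 dB): it has no useful argmax. See the methods vignette.
#'
#' Because one ESVT run at `max(iter_grid)` iterations visits every smaller
#' iteration count on the way, each realization is denoised once per `tau`
#' and scored at all iteration counts.
#'
#' @param spec A [bcg_spec()] defining the synthetic signal.
#' @param tau_grid Absolute thresholds (a.u.). If `NULL` (default), built as
#'   `tau_rel * pilot_sigma(...)`.
#' @param tau_rel Relative threshold grid used when `tau_grid` is `NULL`;
#'   default 0.05 to 0.5 of the pilot leading singular value.
#' @param iter_grid Iteration counts (positive integers).
#' @param snr_db Nominal noise level of the tuning signals (dB).
#' @param n_realizations Noise realizations averaged per cell.
#' @param window Embedding window (samples).
#' @param seed Master seed; realization seeds are derived sub-streams.
#' @param reference SNR reference for scoring: `"clean"` (default,
#'   cardiac + respiratory) or `"cardiac"`.
#' @return An object of class `esvt_grid`: list with `snr` (long tibble:
#'   `tau`, `iterations`, `snr_db`), `snr_matrix` (tau rows x iteration
#'   columns), `tau_grid`, `iter_grid`, `optimum` (list `tau`, `iterations`,
#'   `snr_db`), `nominal_snr_db`, `n_realizations`, `seed`, `window`.
#' @export
#' @examples
#' spec <- bcg_spec(duration = 10)
#' gr <- esvt_grid_search(spec,
#'   tau_grid = c(20, 60), iter_grid = c(1, 2),
#'   n_realizations = 2, seed = 1
#' )
#' gr$optimum
esvt_grid_search <- function(spec, tau_grid = NULL,
                             tau_rel = seq(0.05, 0.5, by = 0.05),
                             iter_grid = 1:10, snr_db = 0,
                             n_realizations = 5, window = 200, seed = 1L,
                             reference = c("clean", "cardiac")) {
  reference <- match.arg(reference)
  if (!is.null(tau_grid) && length(tau_grid) == 0) {
    stop("tau_grid must be non-empty", call. = FALSE)
  }
  if (length(iter_grid) == 0) stop("iter_grid must be non-empty", call. = FALSE)
  if (n_realizations < 1) stop("n_realizations must be >= 1", call. = FALSE)
  if (is.null(tau_grid)) {
    tau_grid <- tau_rel * pilot_sigma(spec,
      snr_db = snr_db, window = window,
      n_pilot = 5, seed = seed
    )
  }
  iter_grid <- sort(unique(as.integer(iter_grid)))
  tau_grid <- sort(tau_grid)
  imax <- max(iter_grid)

  snr_mat <- matrix(0, length(tau_grid), length(iter_grid),
    dimnames = list(tau = tau_grid, iterations = iter_grid)
  )
  for (r in seq_len(n_realizations)) {
    sim <- bcg_simulate(spec, snr_db, seed = derive_seed(seed, r))
    ref <- if (reference == "clean") sim$clean else sim$cardiac
    for (ti in seq_along(tau_grid)) {
      fit <- esvt_denoise(sim$noisy, tau_grid[ti], imax,
        window = window,
        rate = spec$rate, keep_iterations = TRUE
      )
      for (ii in seq_along(iter_grid)) {
        snr_mat[ti, ii] <- snr_mat[ti, ii] +
          measure_snr(fit$iterates[[iter_grid[ii]]], ref)
      }
    }
  }
  snr_mat <- snr_mat / n_realizations
  if (any(!is.finite(snr_mat))) {
    bad <- which(!is.finite(snr_mat), arr.ind = TRUE)[1, ]
    stop("non-finite SNR at tau = ", tau_grid[bad[1]], ", iterations = ",
      iter_grid[bad[2]],
      call. = FALSE
    )
  }

  # argmax with ties broken by smaller iteration count, then smaller tau
  best <- max(snr_mat)
  cand <- which(snr_mat == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  opt <- cand[1, ]

  long <- tidyr::expand_grid(tau = tau_grid, iterations = iter_grid)
  long$snr_db <- as.vector(t(snr_mat))

  structure(
    list(
      snr = long,
      snr_matrix = snr_mat,
      tau_grid = tau_grid,
      iter_grid = iter_grid,
      optimum = list(
        tau = tau_grid[opt[1]], iterations = iter_grid[opt[2]],
        snr_db = best
      ),
      nominal_snr_db = snr_db,
      n_realizations = n_realizations,
      seed = as.integer(seed),
      window = window,
      reference = reference
    ),
    class = "esvt_grid"
  )
}

#' @export
print.esvt_grid <- function(x, ...) {
  cat(
    "<esvt_grid>", length(x$tau_grid), "x", length(x$iter_grid),
    "grid at nominal", x$nominal_snr_db, "dB,", x$n_realizations,
    "realizations/cell\n"
  )
  cat(
    "  optimum: tau =", signif(x$optimum$tau, 4), ", iterations =",
    x$optimum$iterations, "(mean cardiac SNR", round(x$optimum$snr_db, 2), "dB)\n"
  )
  invisible(x)
}

#' @rdname esvt_grid_search
#' @param x An `esvt_grid` object.
#' @param ... Unused.
#' @method tidy esvt_grid
#' @export
tidy.esvt_grid <- function(x, ...) x$snr

#' @rdname esvt_grid_search
#' @method glance esvt_grid
#' @export
glance.esvt_grid <- function(x, ...) {
  tibble::tibble(
    tau_opt = x$optimum$tau,
    i_opt = x$optimum$iterations,
    snr_opt_db = x$optimum$snr_db,
    nominal_snr_db = x$nominal_snr_db,
    n_cells = length(x$snr_matrix),
    n_realizations = x$n_realizations,
    seed = x$seed
  )
}

#' Benchmark ESVT against the wavelet baseline
#'
#' For each nominal noise level and each seed, draws one noisy realization of
#' the synthetic BCG, denoises it with both methods, and records the SNR gain
#' (output SNR minus input SNR, both scored against the chosen reference; the
#' default scores against the cardiac component alone, so removing either
#' noise or respiratory drift counts as gain). Gains are averaged over seeds
#' per level.
#'
#' @param spec A [bcg_spec()].
#' @param snr_levels Nominal noise levels (dB); the study conditions are 0-15.
#' @param n_seeds Realizations per level (>= 1; the headline comparisons use 10).
#' @param esvt_params List with `tau` and `iterations` (and optionally
#'   `window`), e.g. from the `optimum` of [esvt_grid_search()].
#' @param wavelet_params List of [wavelet_denoise()] arguments.
#' @param seed Master seed; per-level/per-realization seeds are derived.
#' @param reference SNR reference for the gains: `"cardiac"` (default) or
#'   `"clean"`.
#' @return An object of class `esvt_benchmark`: list with `runs` (tibble:
#'   `nominal_snr_db`, `realization`, `method`, `input_snr_db`,
#'   `output_snr_db`, `gain_db`) and `summary` (mean gain per level and
#'   method), plus the settings.
#' @export
esvt_benchmark <- function(spec, snr_levels = c(0, 5, 10, 15), n_seeds = 10,
                           esvt_params, wavelet_params = list(), seed = 1L,
                           reference = c("cardiac", "clean")) {
  reference <- match.arg(reference)
  if (n_seeds < 1) stop("n_seeds must be >= 1", call. = FALSE)
  stopifnot(is.list(esvt_params), !is.null(esvt_params$tau), !is.null(esvt_params$iterations))
  window <- esvt_params$window %||% 200
  rows <- list()
  for (li in seq_along(snr_levels)) {
    lev <- snr_levels[li]
    for (r in seq_len(n_seeds)) {
      sim <- bcg_simulate(spec, lev, seed = derive_seed(seed, li, r))
      ref <- if (reference == "cardiac") sim$cardiac else sim$clean
      input_snr <- measure_snr(sim$noisy, ref)
      esvt_out <- tryCatch(
        esvt_denoise(sim$noisy, esvt_params$tau, esvt_params$iterations,
          window = window, rate = spec$rate
        )$denoised$value,
        error = function(e) {
          stop("ESVT failed at level ", lev, " dB, realization ", r, ": ",
            conditionMessage(e),
            call. = FALSE
          )
        }
      )
      wave_out <- tryCatch(
        do.call(wavelet_denoise, c(list(x = sim$noisy), wavelet_params)),
        error = function(e) {
          stop("wavelet baseline failed at level ", lev, " dB, realization ",
            r, ": ", conditionMessage(e),
            call. = FALSE
          )
        }
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        nominal_snr_db = lev,
        realization = r,
        method = c("esvt", "wavelet"),
        input_snr_db = input_snr,
        output_snr_db = c(
          measure_snr(esvt_out, ref),
          measure_snr(wave_out, ref)
        )
      )
    }
  }
  runs <- dplyr::bind_rows(rows)
  runs$gain_db <- runs$output_snr_db - runs$input_snr_db
  summary <- runs |>
    dplyr::group_by(.data$nominal_snr_db, .data$method) |>
    dplyr::summarise(
      mean_gain_db = mean(.data$gain_db),
      median_gain_db = stats::median(.data$gain_db),
      n = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(
      runs = runs, summary = summary, snr_levels = snr_levels,
      n_seeds = n_seeds, esvt_params = esvt_params,
      wavelet_params = wavelet_params, seed = as.integer(seed),
      reference = reference
    ),
    class = "esvt_benchmark"
  )
}

#' @export
print.esvt_benchmark <- function(x, ...) {
  cat("<esvt_benchmark>", x$n_seeds, "realizations per level\n")
  print(tidyr::pivot_wider(x$summary[, c("nominal_snr_db", "method", "mean_gain_db")],
    names_from = "method", values_from = "mean_gain_db"
  ))
  invisible(x)
}

#' @rdname esvt_benchmark
#' @param x An `esvt_benchmark` object.
#' @param ... Unused.
#' @method tidy esvt_benchmark
#' @export
tidy.esvt_benchmark <- function(x, ...) x$runs

#' @rdname esvt_benchmark
#' @method glance esvt_benchmark
#' @export
glance.esvt_benchmark <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("nominal_snr_db", "method", "mean_gain_db")],
    names_from = "method", values_from = "mean_gain_db",
    names_glue = "{method}_mean_gain_db"
  )
}

#' Export / import a grid-search heatmap
#'
#' Writes the SNR matrix as CSV (threshold rows, iteration columns) plus a
#' JSON sidecar carrying the optimum, seeds, and settings; the reader
#' round-trips the matrix bit-exactly.
#'
#' @param grid An `esvt_grid` from [esvt_grid_search()].
#' @param path Output CSV path; the sidecar goes to `<path>.json`.
#' @return `write_heatmap_csv()` returns `path` invisibly;
#'   `read_heatmap_csv()` returns an `esvt_grid` (without the long tibble's
#'   provenance beyond what the sidecar stores).
#' @export
write_heatmap_csv <- function(grid, path) {
  stopifnot(inherits(grid, "esvt_grid"))
  df <- tibble::as_tibble(grid$snr_matrix, .name_repair = "minimal")
  names(df) <- paste0("i", grid$iter_grid)
  df <- dplyr::bind_cols(tibble::tibble(tau = grid$tau_grid), df)
  readr::write_csv(df, path)
  jsonlite::write_json(
    list(
      optimum = grid$optimum, nominal_snr_db = grid$nominal_snr_db,
      n_realizations = grid$n_realizations, seed = grid$seed,
      window = grid$window
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @export
read_heatmap_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tau_grid <- df$tau
  iter_grid <- as.integer(sub("^i", "", names(df)[-1]))
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(tau = tau_grid, iterations = iter_grid)
  long <- tidyr::expand_grid(tau = tau_grid, iterations = iter_grid)
  long$snr_db <- as.vector(t(m))
  structure(
    list(
      snr = long, snr_matrix = m, tau_grid = tau_grid, iter_grid = iter_grid,
      optimum = meta$optimum, nominal_snr_db = meta$nominal_snr_db,
      n_realizations = meta$n_realizations, seed = meta$seed,
      window = meta$window
    ),
    class = "esvt_grid"
  )
}
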