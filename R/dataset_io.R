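SITE_CODES <- c(EJ = "mitral_valve", XJ = "left_ventricle", ZJ = "aortic_valve")

#' Parse / format a recording folder name
#'
#' Recording folders are named `hdata<SubjectID><EJ|XJ|ZJ>`, where the suffix
#' encodes the echocardiographic site: EJ = mitral valve, XJ = left ventricle,
#' ZJ = aortic valve.
#'
#' @param folder_name Folder name, e.g. `"hdata36ZJ"`.
#' @return `parse_record_name()`: list with `subject_id` (integer) and `site`;
#'   `format_record_name()`: the folder name string.
#' @export
#' @examples
#' parse_record_name("hdata36ZJ")
#' format_record_name(3, "mitral_valve")
parse_record_name <- function(folder_name) {
  m <- regmatches(
    folder_name,
    regexec("^hdata([0-9]+)(EJ|XJ|ZJ)$", folder_name)
  )[[1]]
  if (length(m) != 3) {
    stop(
      "'", folder_name,
      "' does not match the expected pattern hdata<SubjectID><EJ|XJ|ZJ>",
      call. = FALSE
    )
  }
  list(subject_id = as.integer(m[2]), site = unname(SITE_CODES[m[3]]))
}

#' @rdname parse_record_name
#' @param subject_id Integer subject identifier.
#' @param site One of `"mitral_valve"`, `"left_ventricle"`, `"aortic_valve"`.
#' @export
format_record_name <- function(subject_id, site) {
  code <- names(SITE_CODES)[match(site, SITE_CODES)]
  if (is.na(code)) {
    stop("unknown site '", site, "'; expected one of ",
      paste(SITE_CODES, collapse = ", "),
      call. = FALSE
    )
  }
  paste0("hdata", as.integer(subject_id), code)
}

#' Read / write a recording's signal.csv
#'
#' The per-recording `signal.csv` holds three header-less columns sampled at
#' 100 Hz: raw BCG, ECG, and the denoised BCG. Values round-trip at full
#' double precision.
#'
#' @param path File path.
#' @param rate Sampling rate (Hz).
#' @return A tibble with columns `time`, `raw_bcg`, `ecg`, `denoised_bcg`;
#'   attribute `rate`.
#' @export
read_signal_csv <- function(path, rate = 100) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = FALSE, colClasses = "character")
  if (ncol(df) != 3) {
    stop("signal file must have exactly 3 columns (raw BCG, ECG, denoised BCG); got ",
      ncol(df),
      call. = FALSE
    )
  }
  start <- 1
  first <- suppressWarnings(as.numeric(unlist(df[1, ])))
  if (all(is.na(first))) start <- 2 # tolerate a header row
  vals <- lapply(df[start:nrow(df), , drop = FALSE], function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric value in row ", bad + start - 1, call. = FALSE)
    }
    v
  })
  n <- length(vals[[1]])
  out <- tibble::tibble(
    time = (seq_len(n) - 1) / rate,
    raw_bcg = vals[[1]], ecg = vals[[2]], denoised_bcg = vals[[3]]
  )
  attr(out, "rate") <- rate
  out
}

#' @rdname read_signal_csv
#' @param signals Tibble with columns `raw_bcg`, `ecg`, `denoised_bcg`.
#' @export
write_signal_csv <- function(signals, path) {
  stopifnot(all(c("raw_bcg", "ecg", "denoised_bcg") %in% names(signals)))
  readr::write_csv(
    signals[, c("raw_bcg", "ecg", "denoised_bcg")], path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read / write a peak-annotation CSV
#'
#' Peak files have two header-less columns: the raw sample index and the
#' corresponding time in seconds. Indices are assumed 0-based; each file is
#' checked against its time column, and if the 1-based reading fits the times
#' better the indices are shifted with a message. Residual index/time
#' inconsistencies beyond half a sample are counted and attached as attribute
#' `n_inconsistent` with a warning.
#'
#' @param path File path. An empty file yields a valid zero-row annotation.
#' @param rate Sampling rate (Hz).
#' @return A tibble with columns `index` (0-based) and `time` (s); attributes
#'   `rate` and `n_inconsistent`.
#' @export
read_peak_csv <- function(path, rate = 100) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    out <- tibble::tibble(index = integer(0), time = double(0))
    attr(out, "rate") <- rate
    attr(out, "n_inconsistent") <- 0L
    return(out)
  }
  df <- utils::read.csv(path, header = FALSE)
  if (ncol(df) != 2) {
    stop("peak file must have exactly 2 columns (index, time); got ", ncol(df),
      call. = FALSE
    )
  }
  idx <- as.numeric(df[[1]])
  tm <- as.numeric(df[[2]])
  if (anyNA(idx) || anyNA(tm)) stop("non-numeric peak entries", call. = FALSE)
  if (is.unsorted(idx, strictly = TRUE)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  half <- 0.5 / rate
  err0 <- abs(idx / rate - tm)
  err1 <- abs((idx - 1) / rate - tm)
  if (sum(err1 <= half) > sum(err0 <= half)) {
    message("peak file ", basename(path), ": indices read as 1-based; shifting by -1")
    idx <- idx - 1
    err0 <- err1
  }
  n_bad <- sum(err0 > half)
  if (n_bad > 0) {
    warning(n_bad, " peak(s) in ", basename(path),
      " have index/time mismatch beyond half a sample",
      call. = FALSE
    )
  }
  out <- tibble::tibble(index = as.integer(idx), time = tm)
  attr(out, "rate") <- rate
  attr(out, "n_inconsistent") <- as.integer(n_bad)
  out
}

#' @rdname read_peak_csv
#' @param peaks Tibble with columns `index` (0-based) and `time`.
#' @export
write_peak_csv <- function(peaks, path) {
  stopifnot(all(c("index", "time") %in% names(peaks)))
  readr::write_csv(peaks[, c("index", "time")], path, col_names = FALSE)
  invisible(path)
}

#' Scan a dataset root for recordings and report integrity
#'
#' Walks the `Data`-style directory, counts recording folders matching the
#' `hdata<ID><EJ|XJ|ZJ>` convention, checks each for the five expected files
#' (peak CSVs, UCG video, signal.csv, signal.pdf — videos and images are only
#' enumerated, never decoded), and notes the EF image folder. Missing items
#' are reported, never thrown.
#'
#' @param root Dataset root directory.
#' @return A list of class `dataset_report`: `n_recordings`, `site_counts`,
#'   `n_subjects`, `ef_folder_present`, `recordings` (tibble: `folder`,
#'   `subject_id`, `site`, `has_signal`, `has_bcg_peaks`, `has_ecg_peaks`,
#'   `has_video`, `missing`), and `unrecognized` (folder names that match no
#'   convention).
#' @export
scan_dataset <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  is_rec <- grepl("^hdata[0-9]+(EJ|XJ|ZJ)$", dirs)
  recs <- dirs[is_rec]
  rows <- purrr::map(recs, function(d) {
    p <- parse_record_name(d)
    base <- file.path(root, d)
    files <- list.files(base)
    has_signal <- "signal.csv" %in% files
    has_bcg <- any(grepl("_BCG\\.csv$", files))
    has_ecg <- any(grepl("_ECG\\.csv$", files))
    has_video <- any(grepl("_UCG\\.(AVI|avi)$", files))
    missing <- c(
      if (!has_signal) "signal.csv",
      if (!has_bcg) "*_BCG.csv",
      if (!has_ecg) "*_ECG.csv",
      if (!has_video) "*_UCG.AVI"
    )
    tibble::tibble(
      folder = d, subject_id = p$subject_id, site = p$site,
      has_signal = has_signal, has_bcg_peaks = has_bcg,
      has_ecg_peaks = has_ecg, has_video = has_video,
      missing = paste(missing, collapse = ";")
    )
  })
  recordings <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(
      folder = character(0), subject_id = integer(0), site = character(0),
      has_signal = logical(0), has_bcg_peaks = logical(0),
      has_ecg_peaks = logical(0), has_video = logical(0),
      missing = character(0)
    )
  }
  structure(
    list(
      n_recordings = nrow(recordings),
      site_counts = table(factor(recordings$site, levels = unname(SITE_CODES))),
      n_subjects = length(unique(recordings$subject_id)),
      ef_folder_present = "EF_ALLsubject" %in% dirs,
      recordings = recordings,
      unrecognized = setdiff(dirs[!is_rec], "EF_ALLsubject")
    ),
    class = "dataset_report"
  )
}

#' @export
print.dataset_report <- function(x, ...) {
  cat(
    "<dataset_report>", x$n_recordings, "recordings from", x$n_subjects,
    "subjects; EF folder:", if (x$ef_folder_present) "present" else "absent", "\n"
  )
  print(x$site_counts)
  invisible(x)
}

#' Read the subject metadata table
#'
#' Reads the `Subject_Info`-style table (xlsx via readxl when available, or
#' CSV/TSV) with a tolerant header map, and recomputes BMI as
#' `weight / (height/100)^2` when absent.
#'
#' @param path Path to `.xlsx`, `.csv`, or `.tsv`.
#' @return A tibble with columns `id`, `sex`, `age`, `height`, `weight`,
#'   `heart_rate`, `ef`, `bmi`, and `group` when derivable (any annotation
#'   column mentioning AF/PVC/PAC maps to `"arrhythmia"`, HF to `"hf"`, else
#'   `"sinus"`).
#' @export
read_subject_info <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "xlsx" = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading .xlsx requires the readxl package", call. = FALSE)
      }
      readxl::read_excel(path)
    },
    "csv" = readr::read_csv(path, show_col_types = FALSE),
    "tsv" = readr::read_tsv(path, show_col_types = FALSE),
    stop("unsupported metadata format '.", ext, "' (use xlsx/csv/tsv)", call. = FALSE)
  )
  nm <- tolower(gsub("[^a-z0-9]", "", tolower(names(raw))))
  pick <- function(...) {
    for (cand in c(...)) {
      j <- which(nm == cand)
      if (length(j)) return(raw[[j[1]]])
    }
    NULL
  }
  out <- tibble::tibble(
    id = as.integer(pick("id", "subjectid", "subject")),
    sex = as.character(pick("sex", "gender") %||% NA_character_),
    age = as.numeric(pick("age", "ageyears") %||% NA_real_),
    height = as.numeric(pick("height", "heightcm") %||% NA_real_),
    weight = as.numeric(pick("weight", "weightkg") %||% NA_real_),
    heart_rate = as.numeric(pick("heartrate", "hr", "hrbpm") %||% NA_real_),
    ef = as.numeric(pick("ef", "efpercent", "ejectionfraction") %||% NA_real_)
  )
  bmi <- pick("bmi")
  out$bmi <- if (!is.null(bmi)) as.numeric(bmi) else out$weight / (out$height / 100)^2
  ann <- pick("group", "imagingtypes", "type", "annotation", "diagnosis")
  out$group <- if (!is.null(ann)) {
    a <- toupper(as.character(ann))
    dplyr::case_when(
      grepl("HF|HEART FAILURE", a) ~ "hf",
      grepl("AF|PVC|PAC|ARRHY", a) ~ "arrhythmia",
      TRUE ~ "sinus"
    )
  } else {
    NA_character_
  }
  out
}

#' Summarize subject metadata per variable
#'
#' Mean, sample SD, and range of the anthropometric and cardiac variables for
#' a (sub)group of subjects, in the shape of a demographics table. With a
#' single subject the SD is reported as 0 and flagged.
#'
#' @param records Tibble as from [read_subject_info()].
#' @param group Optional group label to filter on (matched against the `group`
#'   column).
#' @param variables Which numeric columns to summarize.
#' @return A tibble with columns `variable`, `n`, `mean`, `sd`, `min`, `max`,
#'   `sd_flagged`.
#' @export
summarize_metadata <- function(records, group = NULL,
                               variables = c(
                                 "age", "height", "weight", "bmi",
                                 "heart_rate", "ef"
                               )) {
  df <- records
  if (!is.null(group)) df <- dplyr::filter(df, .data$group == !!group)
  if (nrow(df) == 0) stop("no subjects in the requested group", call. = FALSE)
  purrr::map_dfr(variables, function(v) {
    x <- df[[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble::tibble(
        variable = v, n = 0L, mean = NA_real_, sd = NA_real_,
        min = NA_real_, max = NA_real_, sd_flagged = NA
      ))
    }
    one <- length(x) == 1
    tibble::tibble(
      variable = v, n = length(x), mean = mean(x),
      sd = if (one) 0 else stats::sd(x),
      min = min(x), max = max(x), sd_flagged = one
    )
  })
}

#' Recording-level heart-rate validation over a dataset tree
#'
#' For every recording folder under `root`, derives one heart rate per
#' modality — from the shipped J-peak/R-peak annotation files by default, or
#' by re-detecting peaks on `signal.csv` with [detect_peaks()] — and computes
#' the BCG-vs-ECG agreement statistics over recordings.
#'
#' @param root Dataset root directory.
#' @param redetect If `TRUE`, ignore the annotation files and run the peak
#'   detector on the raw signals.
#' @param method Heart-rate estimator passed to [peaks_to_hr()]
#'   (recording-level `"mean-interval"` by default; `"per-beat"` pools all
#'   beat-to-beat rates across recordings).
#' @param rate Sampling rate (Hz).
#' @return A list with `per_recording` (tibble: `folder`, `subject_id`,
#'   `site`, `hr_bcg`, `hr_ecg`) and `agreement` (an [hr_agreement()] object,
#'   BCG minus ECG).
#' @export
validate_hr <- function(root, redetect = FALSE,
                        method = c("mean-interval", "per-beat"), rate = 100) {
  method <- match.arg(method)
  rep <- scan_dataset(root)
  recs <- rep$recordings
  if (nrow(recs) == 0) stop("no recordings found under ", root, call. = FALSE)
  hr_b_all <- list()
  hr_e_all <- list()
  rows <- list()
  for (i in seq_len(nrow(recs))) {
    d <- file.path(root, recs$folder[i])
    if (redetect) {
      sig <- read_signal_csv(file.path(d, "signal.csv"), rate = rate)
      pk_b <- detect_peaks(sig$raw_bcg, rate, mode = "bcg-j")
      pk_e <- detect_peaks(sig$ecg, rate, mode = "ecg-r")
    } else {
      bf <- list.files(d, pattern = "_BCG\\.csv$", full.names = TRUE)
      ef <- list.files(d, pattern = "_ECG\\.csv$", full.names = TRUE)
      if (!length(bf) || !length(ef)) next
      pk_b <- read_peak_csv(bf[1], rate = rate)
      pk_e <- read_peak_csv(ef[1], rate = rate)
    }
    if (nrow(pk_b) < 2 || nrow(pk_e) < 2) next
    hb <- peaks_to_hr(pk_b, method)
    he <- peaks_to_hr(pk_e, method)
    if (method == "per-beat") {
      m <- min(length(hb), length(he))
      hr_b_all[[length(hr_b_all) + 1]] <- hb[seq_len(m)]
      hr_e_all[[length(hr_e_all) + 1]] <- he[seq_len(m)]
      hb <- mean(hb)
      he <- mean(he)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      folder = recs$folder[i], subject_id = recs$subject_id[i],
      site = recs$site[i], hr_bcg = unname(hb), hr_ecg = unname(he)
    )
  }
  per_recording <- dplyr::bind_rows(rows)
  if (method == "per-beat") {
    agr <- hr_agreement(unlist(hr_b_all), unlist(hr_e_all))
  } else {
    agr <- hr_agreement(per_recording$hr_bcg, per_recording$hr_ecg)
  }
  list(per_recording = per_recording, agreement = agr)
}

#' Write a synthetic dataset tree (test fixture)
#'
#' Generates a small, fully synthetic copy of the dataset layout — recording
#' folders with `signal.csv`, `*_BCG.csv`/`*_ECG.csv` peak files, placeholder
#' video entries, an `EF_ALLsubject` folder, and a `Subject_Info.csv` table —
#' from beat trains with per-subject heart rates. It exists so every reader
#' and the heart-rate validation pipeline can be exercised without any
#' download; it carries no real physiology.
#'
#' @param root Directory to create.
#' @param n_subjects Number of synthetic subjects.
#' @param duration Per-recording duration (s).
#' @param seed Master seed.
#' @param hr_range Range of subject heart rates (bpm).
#' @return `root`, invisibly.
#' @export
write_synthetic_dataset <- function(root, n_subjects = 3, duration = 60,
                                    seed = 1L, hr_range = c(55, 95)) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "EF_ALLsubject"), showWarnings = FALSE)
  sites <- unname(SITE_CODES)
  meta <- list()
  for (s in seq_len(n_subjects)) {
    hr <- hr_range[1] + (hr_range[2] - hr_range[1]) *
      ((derive_seed(seed, s) %% 1000) / 999)
    site <- sites[(s - 1) %% 3 + 1]
    folder <- format_record_name(s, site)
    d <- file.path(root, folder)
    dir.create(d, showWarnings = FALSE)

    ecg <- beat_train(hr, duration,
      fs = 100, jitter_sd = 0.01,
      template = "biphasic", width = 0.02, seed = derive_seed(seed, s, 1)
    )
    # BCG beats lag the ECG R wave by a mechanical delay with beat-to-beat
    # variability, so the two modalities' heart rates agree closely but not
    # exactly
    lag_jitter <- withr::with_seed(
      derive_seed(seed, s, 3),
      stats::rnorm(length(ecg$peak_times), 0, 0.01)
    )
    bcg_times <- ecg$peak_times + 0.15 + lag_jitter
    n <- nrow(ecg$signal)
    t <- ecg$signal$time
    bcg_val <- rep(0, n)
    for (tc in bcg_times) bcg_val <- bcg_val + exp(-((t - tc) / 0.04)^2 / 2)
    noise <- withr::with_seed(derive_seed(seed, s, 2), stats::rnorm(n, 0, 0.05))
    raw_bcg <- bcg_val + noise

    fit <- esvt_denoise(raw_bcg, tau = 2, iterations = 1, window = 200, rate = 100)
    sig <- tibble::tibble(
      raw_bcg = raw_bcg, ecg = ecg$signal$value,
      denoised_bcg = fit$denoised$value
    )
    write_signal_csv(sig, file.path(d, "signal.csv"))

    jp <- round(bcg_times * 100)
    rp <- round(ecg$peak_times * 100)
    write_peak_csv(
      tibble::tibble(index = as.integer(jp), time = jp / 100),
      file.path(d, paste0(folder, "_BCG.csv"))
    )
    write_peak_csv(
      tibble::tibble(index = as.integer(rp), time = rp / 100),
      file.path(d, paste0(folder, "_ECG.csv"))
    )
    writeLines("synthetic placeholder (never decoded)",
      file.path(d, paste0(folder, "_UCG.AVI"))
    )
    writeLines("synthetic placeholder", file.path(d, "signal.pdf"))
    meta[[s]] <- tibble::tibble(
      ID = s, Sex = c("M", "F")[s %% 2 + 1], Age = 30 + s * 5,
      Height = 165 + s, Weight = 60 + 2 * s,
      `Heart Rate` = round(hr), EF = 55 + s,
      Group = "sinus"
    )
  }
  readr::write_csv(dplyr::bind_rows(meta), file.path(root, "Subject_Info.csv"))
  invisible(root)
}
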