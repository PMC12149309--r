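test_that("recording names parse and format per the naming convention", {
  expect_equal(
    parse_record_name("hdata36ZJ"),
    list(subject_id = 36L, site = "aortic_valve")
  )
  expect_equal(
    parse_record_name("hdata3EJ"),
    list(subject_id = 3L, site = "mitral_valve")
  )
  expect_equal(parse_record_name("hdata12XJ")$site, "left_ventricle")
  expect_error(parse_record_name("hdataEF"), "hdata<SubjectID>")

  # round trip over the full id/site domain sample
  for (id in c(1L, 36L, 850L)) {
    for (site in c("mitral_valve", "left_ventricle", "aortic_valve")) {
      expect_equal(
        parse_record_name(format_record_name(id, site)),
        list(subject_id = id, site = site)
      )
    }
  }
  expect_error(format_record_name(1, "tricuspid"), "unknown site")
})

test_that("signal CSVs read, validate, and round-trip at full precision", {
  dir <- withr::local_tempdir()
  sig <- tibble::tibble(
    raw_bcg = withr::with_seed(1, stats::rnorm(10)),
    ecg = withr::with_seed(2, stats::rnorm(10)),
    denoised_bcg = withr::with_seed(3, stats::rnorm(10))
  )
  path <- file.path(dir, "signal.csv")
  write_signal_csv(sig, path)
  back <- read_signal_csv(path)
  expect_equal(nrow(back), 10)
  expect_identical(back$raw_bcg, sig$raw_bcg)
  expect_identical(back$denoised_bcg, sig$denoised_bcg)
  expect_equal(back$time, (0:9) / 100)

  # wrong column count is a format error
  writeLines(c("1,2", "3,4"), file.path(dir, "two.csv"))
  expect_error(read_signal_csv(file.path(dir, "two.csv")), "3 columns")

  # non-numeric cells are reported with their row
  writeLines(c("1,2,3", "4,x,6"), file.path(dir, "bad.csv"))
  expect_error(read_signal_csv(file.path(dir, "bad.csv")), "row 2")
})

test_that("peak CSVs validate index/time consistency", {
  dir <- withr::local_tempdir()

  writeLines(c("100,1.00", "200,2.00"), file.path(dir, "ok.csv"))
  pk <- read_peak_csv(file.path(dir, "ok.csv"), rate = 100)
  expect_equal(pk$index, c(100L, 200L))
  expect_equal(attr(pk, "n_inconsistent"), 0L)

  # inconsistent time draws a warning, not an error
  writeLines(c("100,5.00", "200,2.00"), file.path(dir, "warn.csv"))
  expect_warning(pkw <- read_peak_csv(file.path(dir, "warn.csv"), rate = 100), "mismatch")
  expect_gte(attr(pkw, "n_inconsistent"), 1L)

  # 1-based files are detected via the time column and shifted
  writeLines(c("101,1.00", "201,2.00"), file.path(dir, "onebased.csv"))
  expect_message(pk1 <- read_peak_csv(file.path(dir, "onebased.csv"), rate = 100), "1-based")
  expect_equal(pk1$index, c(100L, 200L))

  # empty file: valid empty annotations
  file.create(file.path(dir, "empty.csv"))
  expect_equal(nrow(read_peak_csv(file.path(dir, "empty.csv"))), 0)

  # non-monotone indices rejected
  writeLines(c("200,2.00", "100,1.00"), file.path(dir, "rev.csv"))
  expect_error(read_peak_csv(file.path(dir, "rev.csv")), "increasing")

  # write -> read round trip
  out <- tibble::tibble(index = c(10L, 55L), time = c(0.10, 0.55))
  write_peak_csv(out, file.path(dir, "rt.csv"))
  expect_equal(read_peak_csv(file.path(dir, "rt.csv"), rate = 100)$index, out$index)
})

test_that("dataset scanning reports structure without decoding media", {
  root <- file.path(withr::local_tempdir(), "ds")
  write_synthetic_dataset(root, n_subjects = 3, duration = 30, seed = 5)

  rep <- scan_dataset(root)
  expect_equal(rep$n_recordings, 3)
  expect_equal(rep$n_subjects, 3)
  expect_true(rep$ef_folder_present)
  expect_equal(sum(rep$site_counts), 3)
  expect_true(all(rep$recordings$has_signal))
  expect_true(all(rep$recordings$missing == ""))

  # missing files are reported, never thrown
  unlink(file.path(root, rep$recordings$folder[1], "signal.csv"))
  rep2 <- scan_dataset(root)
  expect_match(rep2$recordings$missing[1], "signal.csv")

  # empty root: zero counts
  empty <- file.path(withr::local_tempdir(), "empty")
  dir.create(empty)
  rep0 <- scan_dataset(empty)
  expect_equal(rep0$n_recordings, 0)
  expect_false(rep0$ef_folder_present)
})

test_that("metadata summaries follow the mean/SD/range convention", {
  rec <- tibble::tibble(
    id = 1:3, sex = c("M", "F", "M"), age = c(40, 50, 60),
    height = c(170, 160, 180), weight = c(70, 60, 80),
    heart_rate = c(60, 70, 80), ef = c(30, 40, 50), group = "hf"
  )
  rec$bmi <- rec$weight / (rec$height / 100)^2
  s <- summarize_metadata(rec, group = "hf")
  ef <- s[s$variable == "ef", ]
  expect_equal(ef$mean, 40)
  expect_equal(ef$sd, 10)
  expect_equal(c(ef$min, ef$max), c(30, 50))

  # single subject: SD reported as 0 with a flag
  s1 <- summarize_metadata(rec[1, ])
  expect_equal(unique(s1$sd), 0)
  expect_true(all(s1$sd_flagged))

  expect_error(summarize_metadata(rec, group = "sinus"), "no subjects")
})

test_that("subject metadata reads with tolerant headers and recomputed BMI", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "Subject_Info.csv")
  readr::write_csv(tibble::tibble(
    SubjectID = 1:2, Sex = c("M", "F"), `Age (years)` = c(40, 62),
    `Height (cm)` = c(170, 158), `Weight (Kg)` = c(72, 55),
    `Heart Rate` = c(66, 74), `EF (%)` = c(63, 39),
    `Imaging Types` = c("EJ,XJ", "ZJ(AF)")
  ), path)
  info <- read_subject_info(path)
  expect_equal(info$id, 1:2)
  expect_equal(info$ef, c(63, 39))
  expect_equal(info$bmi, c(72, 55) / c(1.70, 1.58)^2)
  expect_equal(info$group, c("sinus", "arrhythmia"))
})

test_that("heart-rate validation runs end-to-end on a synthetic tree", {
  root <- file.path(withr::local_tempdir(), "ds")
  write_synthetic_dataset(root, n_subjects = 5, duration = 60, seed = 8)

  res <- validate_hr(root)
  expect_equal(nrow(res$per_recording), 5)
  # the BCG beat train lags the ECG train beat-for-beat, so recording-level
  # heart rates agree tightly
  expect_gt(res$agreement$pearson_r, 0.99)
  expect_lt(abs(res$agreement$bias), 1)

  # re-detection path exercises the peak detector on signal.csv
  res2 <- validate_hr(root, redetect = TRUE)
  expect_equal(nrow(res2$per_recording), 5)
  expect_gt(res2$agreement$pearson_r, 0.95)

  # per-beat pooling is available
  res3 <- validate_hr(root, method = "per-beat")
  expect_gt(res3$agreement$n_pairs, 100)
})
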