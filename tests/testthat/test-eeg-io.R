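test_that("matrix CSV round trip is bitwise-exact for integer-valued data", {
  rec <- toy_recording()
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(rec, path)
  back <- read_recording(path, format = "matrix_csv")
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$sampling_rate_hz, 500)
  expect_identical(unname(back$data), unname(rec$data))
})

test_that("segment extraction is sample-exact with half-open 0-based windows", {
  rec <- recording(matrix(0:9999, nrow = 1), "F3", 500, "s1")
  segs <- extract_segments(rec, list(c(10, 4)))
  # [10 s, 14 s) at 500 Hz -> samples 5000..6999 (0-based), values equal index
  expect_equal(segs$F3[[1]]$n, 2000)
  expect_equal(segs$F3[[1]]$samples[1], 5000)
  expect_equal(segs$F3[[1]]$samples[2000], 6999)
  # smallest window: one sample
  one <- extract_segments(rec, list(c(0, 0.002)))
  expect_equal(one$F3[[1]]$samples, 0)
  # adjacent windows concatenate to the contiguous slice
  two <- extract_segments(rec, list(c(1, 2), c(3, 2)))
  expect_equal(c(two$F3[[1]]$samples, two$F3[[2]]$samples),
               as.numeric(500:2499))
  expect_error(extract_segments(rec, list(c(19, 2))), "out of bounds")
  expect_error(extract_segments(rec, list(c(-1, 2))), "out of bounds")
  expect_warning(extract_segments(rec, list(c(0, 2), c(1, 2))), "overlap")
})

test_that("the canonical 30 s marker yields 15,000 samples from sample 5000", {
  rec <- recording(matrix(rnorm(25000), nrow = 1), "O1", 500, "s1")
  seg <- extract_segments(rec, list(c(10, 30)))$O1[[1]]
  expect_equal(seg$n, 15000)
  expect_equal(seg$samples, rec$data[1, 5001:20000])
})

test_that("EDF round trip preserves labels, rate, and values to quantization", {
  set.seed(2)
  rec <- recording(matrix(rnorm(8 * 2000, sd = 30), nrow = 8),
                   ectmse:::MONTAGE, 500, "edf1")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, format = "edf")
  expect_identical(back$channel_labels, ectmse:::MONTAGE)
  expect_equal(back$sampling_rate_hz, 500)
  expect_equal(dim(back$data), dim(rec$data))
  # 16-bit quantization: worst error is the physical span / 2^16
  span <- apply(rec$data, 1, function(v) diff(range(v)))
  expect_lt(max(abs(back$data - rec$data)), max(span) / 65536 * 1.01)
})

test_that("montage validation catches missing channels and EDF labels normalize", {
  rec7 <- recording(matrix(rnorm(7 * 1000), nrow = 7),
                    setdiff(ectmse:::MONTAGE, "O1"), 500, "bad")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec7, path)
  expect_error(read_recording(path), "missing required channels.*O1")
  # decorated labels ("EEG F3-A1" style) still map onto the montage
  rec8 <- recording(matrix(rnorm(8 * 1000), nrow = 8),
                    paste0("EEG ", tolower(ectmse:::MONTAGE), "-A1"), 500)
  path2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec8, path2)
  back <- read_recording(path2)
  expect_setequal(back$channel_labels, ectmse:::MONTAGE)
})

test_that("artifact flagging equals an exhaustive per-sample scan", {
  oracle_clean <- function(x, amp, grad) {
    for (v in x) if (abs(v) > amp) return(FALSE)
    if (length(x) > 1)
      for (i in 2:length(x)) if (abs(x[i] - x[i - 1]) > grad) return(FALSE)
    TRUE
  }
  expect_true(flag_artifacts(rep(0, 100)))
  spiky <- rnorm(100); spiky[50] <- 500
  expect_false(flag_artifacts(spiky, amp_limit_uv = 100))
  ramp <- cumsum(rep(1, 50))  # max step 1
  expect_false(flag_artifacts(ramp, amp_limit_uv = 1000, grad_limit_uv = 0.5))
  expect_true(flag_artifacts(ramp, amp_limit_uv = 1000, grad_limit_uv = 1.0))
  set.seed(13)
  for (i in 1:25) {
    x <- rnorm(200, sd = 40)
    amp <- runif(1, 50, 150); grad <- runif(1, 20, 120)
    expect_identical(flag_artifacts(x, amp, grad), oracle_clean(x, amp, grad))
  }
  expect_error(flag_artifacts(rnorm(10), amp_limit_uv = -1), "positive")
})

test_that("clinical table reader enforces the condition vocabulary and sparsity rules", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(session = sprintf("S%02d", 1:24),
                   condition = rep(c("pre_ect", "during_ect", "after_ect",
                                     "lorazepam"), c(3, 7, 8, 6)),
                   bfcrs = rep(10L, 24), bdnf_ng_ml = NA_real_)
  df$bdnf_ng_ml[c(2, 7, 14, 22)] <- c(8, 11, 14, 13)
  write.csv(df, path, row.names = FALSE)
  clin <- read_clinical_table(path)
  expect_equal(nrow(clin), 24)
  expect_equal(sum(is.na(clin$bdnf_ng_ml)), 20)
  df_bad <- df; df_bad$condition[1] <- "baseline"
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_clinical_table(path), "unknown condition")
  df_neg <- df; df_neg$bfcrs[3] <- -2L
  write.csv(df_neg, path, row.names = FALSE)
  expect_error(read_clinical_table(path), "negative")
  writeLines("session,condition,bfcrs,bdnf_ng_ml", path)
  expect_error(read_clinical_table(path), "empty")
})

test_that("course table reader validates schema, positivity, and contiguity", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(table1_fixture()), path, row.names = FALSE)
  tab <- read_course_table(path)
  expect_s3_class(tab, "ect_course_table")
  expect_equal(nrow(tab), 8)
  bad <- as.data.frame(table1_fixture()); bad$session[8] <- 9
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_course_table(path), "contiguous")
  bad2 <- as.data.frame(table1_fixture()); bad2$charge_mC[1] <- 0
  write.csv(bad2, path, row.names = FALSE)
  expect_error(read_course_table(path), "positive")
})

test_that("YAML manifest reader resolves paths and default markers", {
  dir <- withr::local_tempdir()
  yaml::write_yaml(list(sessions = list(
    list(id = "S01", condition = "pre_ect", file = "S01.csv",
         markers = list(c(0, 30), c(30, 30))),
    list(id = "S02", condition = "lorazepam", file = "S02.csv"))),
    file.path(dir, "manifest.yaml"))
  man <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_length(man, 2)
  expect_equal(man[[1]]$file, file.path(dir, "S01.csv"))
  expect_equal(man[[2]]$markers, list(c(0, 30), c(30, 30)))
  yaml::write_yaml(list(sessions = list(
    list(id = "S01", condition = "nope", file = "S01.csv"))),
    file.path(dir, "manifest.yaml"))
  expect_error(read_manifest(file.path(dir, "manifest.yaml")),
               "unknown condition")
})
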