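make_curve <- function(v, ch, p = entropy_params()) {
  structure(list(sampen = v, channel = ch, segment_index = NA_integer_,
                 params = p), class = "mse_curve")
}

test_that("session summaries collapse scale bands by region correctly", {
  p <- entropy_params()
  const <- lapply(ectmse:::MONTAGE, function(ch) make_curve(rep(2.5, 40), ch, p))
  names(const) <- ectmse:::MONTAGE
  s <- summarize_session(const, "S01", "pre_ect")
  expect_equal(s$frontocentral_low_sf, 2.5)
  expect_equal(s$occipital_high_sf, 2.5)
  # hand-built curves verified by direct arithmetic
  curves <- list(
    F3 = make_curve(1:40 / 10, "F3", p), F4 = make_curve(rep(1, 40), "F4", p),
    C3 = make_curve(rep(2, 40), "C3", p), C4 = make_curve(rep(0, 40), "C4", p),
    O1 = make_curve(1:40 / 20, "O1", p), O2 = make_curve(rep(3, 40), "O2", p))
  s2 <- summarize_session(curves, "S02", "during_ect")
  expect_equal(s2$frontocentral_low_sf,
               mean(c((1:5) / 10, rep(1, 5), rep(2, 5), rep(0, 5))))
  expect_equal(s2$occipital_high_sf, mean(c((31:40) / 20, rep(3, 10))))
  expect_error(summarize_session(curves[-6]), "missing for required channels.*O2")
})

test_that("session summaries are permutation-invariant and count skipped entries", {
  p <- entropy_params()
  set.seed(31)
  curves <- lapply(ectmse:::MONTAGE, function(ch) make_curve(runif(40), ch, p))
  names(curves) <- ectmse:::MONTAGE
  s <- summarize_session(curves, "a", "pre_ect")
  shuffled <- curves[sample(names(curves))]
  s2 <- summarize_session(shuffled, "a", "pre_ect")
  expect_equal(s$frontocentral_low_sf, s2$frontocentral_low_sf)
  expect_equal(s$occipital_high_sf, s2$occipital_high_sf)
  # an undefined entry is skipped, reported, and changes the mean accordingly
  curves$O1$sampen[35] <- NA
  expect_warning(s3 <- summarize_session(curves, "a", "pre_ect"), "skipped")
  expect_equal(s3$n_missing_high, 1L)
  vals <- c(curves$O1$sampen[31:40], curves$O2$sampen[31:40])
  expect_equal(s3$occipital_high_sf, mean(vals, na.rm = TRUE))
  curves$O1$sampen[31:40] <- NA
  curves$O2$sampen[31:40] <- NA
  expect_error(summarize_session(curves, "a", "pre_ect"), "all SampEn entries")
})

test_that("condition averages are idempotent and take midpoints", {
  df <- data.frame(session = c("a", "b", "c"),
                   condition = c("pre_ect", "pre_ect", "during_ect"),
                   frontocentral_low_sf = c(1, 3, 5),
                   occipital_high_sf = c(2, 4, 6))
  cm <- condition_average(df)
  expect_equal(cm$frontocentral_low_sf[cm$condition == "pre_ect"], 2)
  expect_equal(cm$occipital_high_sf[cm$condition == "pre_ect"], 3)
  expect_equal(cm$frontocentral_low_sf[cm$condition == "during_ect"], 5)
  # single-session condition is itself; averaging identical sessions idempotent
  same <- df[c(1, 1), ]
  expect_equal(condition_average(same)$frontocentral_low_sf, 1)
  expect_error(condition_average(df, "lorazepam"), "no sessions")
})

test_that("Pearson computations agree with a from-scratch covariance oracle", {
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(15); y <- 0.5 * x + rnorm(15)
    expect_equal(cor(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("reproducibility correlation hits the trivial limits", {
  mk <- function(vals1, vals2) {
    do.call(rbind, lapply(seq_along(vals1), function(i) {
      data.frame(session = sprintf("S%02d", i),
                 channel = rep(c("F3", "F4", "C3", "C4", "O1", "O2"), 2),
                 segment = rep(1:2, each = 6),
                 sampen_mean = c(rep(vals1[i], 6), rep(vals2[i], 6)))
    }))
  }
  v <- c(1, 2, 3, 5, 8)
  r_same <- reproducibility_correlation(mk(v, v))
  expect_equal(unname(r_same), rep(1, 3), tolerance = 1e-12)
  r_anti <- reproducibility_correlation(mk(v, mean(v) - (v - mean(v))))
  expect_equal(unname(r_anti), rep(-1, 3), tolerance = 1e-12)
  expect_error(reproducibility_correlation(mk(rep(1, 5), v)), "zero variance")
  expect_error(reproducibility_correlation(mk(v[1:2], v[1:2])), ">= 3 sessions")
})

test_that("reproducibility correlation matches the variance-ratio attenuation oracle", {
  # shared session effect + independent per-segment noise of known variance
  # ratio: expected r = sb^2 / (sb^2 + sw^2)
  set.seed(51)
  sb <- 1; sw <- 0.5
  expected <- sb^2 / (sb^2 + sw^2)
  n <- 200
  rs <- replicate(20, {
    tru <- rnorm(n, sd = sb)
    df <- do.call(rbind, lapply(1:n, function(i) {
      data.frame(session = sprintf("S%03d", i),
                 channel = rep(c("F3", "F4", "C3", "C4", "O1", "O2"), 2),
                 segment = rep(1:2, each = 6),
                 sampen_mean = 2 + rep(tru[i] + rnorm(2, sd = sw), each = 6))
    }))
    mean(reproducibility_correlation(df))
  })
  expect_equal(mean(rs), expected, tolerance = 0.05)
})

test_that("segment-scalar helper reduces curve nests to the long format", {
  p <- entropy_params(max_sf = 4)
  mkc <- function(v, ch, k) structure(
    list(sampen = v, channel = ch, segment_index = k, params = p),
    class = "mse_curve")
  nest <- list(S01 = list(F3 = list(mkc(c(1, 2, 3, NA), "F3", 1),
                                    mkc(c(2, 2, 2, 2), "F3", 2))))
  df <- curves_to_segment_scalars(nest)
  expect_equal(nrow(df), 2)
  expect_equal(df$sampen_mean, c(2, 2))  # NA skipped in the per-curve mean
})

test_that("clinical associations recover exact linear dependence and handle exclusion", {
  summaries <- data.frame(
    session = sprintf("S%02d", 1:8),
    condition = c(rep("pre_ect", 2), rep("during_ect", 3), rep("lorazepam", 3)),
    frontocentral_low_sf = c(8, 7.5, 5, 4, 3, 7.8, 7.6, 7.9),
    occipital_high_sf = c(1, 1.2, 2.5, 3, 3.2, 1.1, 1.2, 1.0))
  # BFCRS exactly linear in frontocentral complexity among non-lorazepam
  # sessions, but low (clinically improved) under lorazepam
  clinical <- data.frame(
    session = summaries$session,
    condition = summaries$condition,
    bfcrs = c(30, 28, 18, 14, 10, 9, 8, 7),
    bdnf_ng_ml = c(8, NA, 11, NA, 14, NA, 13, 12))
  clinical$bfcrs[1:5] <- 4 * summaries$frontocentral_low_sf[1:5] - 2
  res <- clinical_association(summaries, clinical)
  expect_s3_class(res, "data.frame")
  row <- res[res$summary == "frontocentral_low_sf" &
             res$clinical_var == "bfcrs" & res$excluded_conditions != "", ]
  expect_equal(row$pearson_r, 1, tolerance = 1e-12)
  expect_equal(row$n_points, 5)
  row_all <- res[res$summary == "frontocentral_low_sf" &
                 res$clinical_var == "bfcrs" & res$excluded_conditions == "", ]
  expect_lt(abs(row_all$pearson_r), 1)
  expect_equal(row_all$n_points, 8)
  # BDNF used only where measured
  row_bdnf <- res[res$summary == "occipital_high_sf" &
                  res$clinical_var == "bdnf_ng_ml" &
                  res$excluded_conditions == "", ]
  expect_equal(row_bdnf$n_points, 5)
  # constant clinical variable is a zero-variance error
  clinical$bfcrs <- 10
  expect_error(clinical_association(summaries, clinical), "zero variance")
  # scatter data travel with the result
  expect_true(length(attr(res, "scatter")) >= 4)
})

test_that("ECT course summary computes threshold, seizure-producing means, failures", {
  s <- ect_course_summary(table1_fixture())
  expect_equal(s$threshold_first_mC, 151.1)
  expect_equal(s$n_failed, 1)
  expect_equal(s$n_stimulations, 8)
  expect_equal(s$mean_seizure_s, mean(c(54, 69, 55, 57, 60, 70, 78)))
  one <- ectmse:::as_course_table(data.frame(
    session = 1, stimulation = 1, percent_energy = 30, charge_mC = 100,
    seizure_duration_s = 50))
  s1 <- ect_course_summary(one)
  expect_equal(s1$mean_charge_mC, 100)
  expect_equal(s1$mean_seizure_s, 50)
  expect_equal(s1$n_failed, 0)
})
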