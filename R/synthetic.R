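#' Configuration for the synthetic ECT-course study generator
#'
#' Defines the surrogate study the generator emulates: 24 resting-state EEG
#' sessions (3 pre-ECT, 7 during-ECT, 8 after-ECT, 6 under lorazepam), two
#' 30 s eyes-closed segments per session at 500 Hz over the eight-electrode
#' montage, with a 1/f-like broadband background, posterior-dominant alpha,
#' and condition-dependent complexity effects injected mechanistically:
#'
#' * `lambda_f` (fine-scale regularity, in \[0, 1\]) mixes in a smoothed,
#'   hence locally predictable, version of the background on the
#'   frontocentral channels, lowering small-scale-factor SampEn;
#' * `lambda_c` (coarse-scale variability, >= 0) adds a standardized
#'   band-limited slow stochastic component (0.3-6 Hz) on the occipital
#'   channels, raising large-scale-factor SampEn.
#'
#' Because the effects are injected through signal construction rather than
#' by targeting entropy values, the entropy estimator remains an honest
#' measurement of the generated dynamics.
#'
#' The clinical model produces a BFCRS trajectory that is high before
#' treatment, falls during ECT, partially relapses after, and falls again
#' under lorazepam (integer-rounded Gaussian noise, floored at 0), and a
#' serum BDNF level that rises with ECT, observed at four sessions only to
#' emulate sparse serum sampling.
#'
#' @param seed Integer seed; all randomness in [generate_study()] flows from it.
#' @param n_sessions Named counts per condition (defaults 3/7/8/6).
#' @param sampling_rate_hz,segment_s,target_sd_uv Signal geometry and scale.
#' @param background_exponent Spectral slope beta of the 1/f^beta background.
#' @param alpha_freq_hz Alpha oscillation frequency.
#' @param alpha_amp Named per-channel relative alpha amplitude.
#' @param effects Named per-condition list of `lambda_f` and `lambda_c`.
#' @param effect_jitter_sd SD of the per-session jitter applied to the
#'   lambdas (shared by both segments, so it sets the between-session
#'   variance that limits the between-segment reproducibility correlation).
#' @param clinical List of BFCRS/BDNF trajectory parameters.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_sessions = c(pre_ect = 3L, during_ect = 7L, after_ect = 8L,
                   lorazepam = 6L),
    sampling_rate_hz = 500, segment_s = 30, target_sd_uv = 20,
    background_exponent = 1, alpha_freq_hz = 10,
    alpha_amp = c(F3 = 0.1, F4 = 0.1, C3 = 0.25, C4 = 0.25,
                  P3 = 0.6, P4 = 0.6, O1 = 1.2, O2 = 1.2),
    effects = list(
      pre_ect    = list(lambda_f = 0.10, lambda_c = 0.10),
      during_ect = list(lambda_f = 0.55, lambda_c = 0.60),
      after_ect  = list(lambda_f = 0.45, lambda_c = 0.45),
      lorazepam  = list(lambda_f = 0.12, lambda_c = 0.12)),
    effect_jitter_sd = 0.04,
    clinical = list(bfcrs_pre = 28, bfcrs_during_end = 6,
                    bfcrs_after_end = 16, bfcrs_lorazepam_end = 7,
                    bfcrs_noise_sd = 1.5,
                    bdnf_baseline = 8, bdnf_ect_rise = 6,
                    bdnf_noise_sd = 0.8, n_bdnf_obs = 4L)) {
  if (!all(CONDITIONS %in% names(n_sessions)))
    stop("n_sessions must name all four conditions")
  if (any(n_sessions < 1)) stop("session counts must be >= 1")
  if (!(background_exponent >= 0)) stop("background_exponent must be >= 0")
  for (cond in CONDITIONS) {
    ef <- effects[[cond]]
    if (is.null(ef)) stop("effects missing condition: ", cond)
    if (ef$lambda_f < 0 || ef$lambda_f > 1)
      stop("lambda_f must lie in [0, 1]")
    if (ef$lambda_c < 0) stop("lambda_c must be >= 0")
  }
  if (!(sampling_rate_hz > 0) || !(segment_s > 0) || !(target_sd_uv > 0))
    stop("rates, durations and target SD must be positive")
  structure(list(seed = as.integer(seed), n_sessions = n_sessions,
                 sampling_rate_hz = sampling_rate_hz, segment_s = segment_s,
                 target_sd_uv = target_sd_uv,
                 background_exponent = background_exponent,
                 alpha_freq_hz = alpha_freq_hz, alpha_amp = alpha_amp,
                 effects = effects, effect_jitter_sd = effect_jitter_sd,
                 clinical = clinical),
            class = "generator_config")
}

zscore <- function(x) (x - mean(x)) / sd(x)

# 1/f^beta Gaussian background by spectral shaping of white noise with
# random phases (beta = 0 reduces to white noise).
spectral_noise <- function(n, beta, band = NULL, fs = NULL) {
  if (beta == 0 && is.null(band)) return(rnorm(n))
  white <- rnorm(n)
  X <- fft(white)
  k <- c(0, seq_len(n - 1))
  f <- pmin(k, n - k)                    # two-sided frequency index
  amp <- ifelse(f == 0, 0, f^(-beta / 2))
  if (!is.null(band)) {
    hz <- f * fs / n
    amp <- amp * as.numeric(hz >= band[1] & hz < band[2])
  }
  x <- Re(fft(X * amp, inverse = TRUE)) / n
  if (sd(x) == 0) stop("degenerate spectral band")
  zscore(x)
}

#' Generate one channel's synthetic resting EEG segment
#'
#' Builds one segment as: standardized 1/f^beta background; a fraction
#' `lambda_f` of a moving-average-smoothed (locally predictable) copy of the
#' background mixed in; an additive band-limited (0.3-6 Hz) slow stochastic
#' component scaled by `lambda_c`; and an amplitude-modulated alpha
#' oscillation scaled by the channel's `alpha_amp`. The sum is standardized
#' to `target_sd_uv`. Randomness comes from R's global RNG: seed it (or call
#' through [generate_study()]) for reproducibility.
#'
#' @param cfg A [generator_config()].
#' @param channel Electrode name (selects `alpha_amp`).
#' @param condition Condition label (selects the default lambdas).
#' @param lambda_f,lambda_c Optional overrides of the condition's effect
#'   sizes (used internally to apply session jitter and region targeting).
#' @param segment_index Stored on the returned segment.
#' @return An `eeg_segment` of `segment_s * sampling_rate_hz` samples.
#' @export
generate_channel_signal <- function(cfg, channel, condition,
                                    lambda_f = NULL, lambda_c = NULL,
                                    segment_index = NA_integer_) {
  stopifnot(inherits(cfg, "generator_config"))
  ef <- cfg$effects[[condition]]
  if (is.null(ef)) stop("unknown condition: ", condition)
  if (is.null(lambda_f)) lambda_f <- ef$lambda_f
  if (is.null(lambda_c)) lambda_c <- ef$lambda_c
  if (lambda_f < 0 || lambda_f > 1) stop("lambda_f must lie in [0, 1]")
  if (lambda_c < 0) stop("lambda_c must be >= 0")
  fs <- cfg$sampling_rate_hz
  n <- as.integer(round(cfg$segment_s * fs))
  bg <- spectral_noise(n, cfg$background_exponent)
  if (lambda_f > 0) {
    k <- 9L  # ~55 Hz first spectral null at 500 Hz: damps fine-scale jumps
    sm <- filter(bg, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- 0
    bg <- zscore((1 - lambda_f) * bg + lambda_f * zscore(as.numeric(sm)))
  }
  if (lambda_c > 0) {
    slow <- spectral_noise(n, 0, band = c(0.3, 6), fs = fs)
    bg <- bg + lambda_c * slow
  }
  aamp <- cfg$alpha_amp[[channel]]
  if (is.null(aamp)) aamp <- 0
  if (aamp > 0) {
    t <- seq_len(n) / fs
    env <- 1 + 0.5 * spectral_noise(n, 0, band = c(0.05, 0.5), fs = fs)
    env <- pmax(env, 0.2)
    osc <- env * sin(2 * pi * cfg$alpha_freq_hz * t + runif(1, 0, 2 * pi))
    bg <- bg + aamp * zscore(osc)
  }
  segment(zscore(bg) * cfg$target_sd_uv, fs, channel = channel,
          segment_index = segment_index)
}

#' Generate a complete surrogate treatment-course study
#'
#' Produces the full study the pipeline analyses: sessions in chronological
#' order (pre-ECT, during-ECT, after-ECT, lorazepam), each with two segments
#' per channel over the eight-electrode montage; per-session BFCRS and sparse
#' BDNF following the configured trajectories; and the packaged ECT course
#' table ([table1_fixture()]). Condition effects are applied regionally:
#' `lambda_f` on F3/F4/C3/C4, `lambda_c` on O1/O2, with per-session jitter
#' shared by both segments. Identical seed and configuration give an
#' identical study.
#'
#' @param cfg A [generator_config()].
#' @return List with `sessions` (list of session records: `session_id`,
#'   `condition`, `segments`, `bfcrs`, `bdnf_ng_ml`), `clinical` (data
#'   frame), and `course` (an `ect_course_table`).
#' @export
generate_study <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  conds <- rep(CONDITIONS, times = cfg$n_sessions[CONDITIONS])
  n_total <- length(conds)
  clinical <- synth_clinical(cfg, conds)
  low_ch <- c("F3", "F4", "C3", "C4")
  sessions <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cond <- conds[i]
    ef <- cfg$effects[[cond]]
    lf <- min(max(ef$lambda_f + rnorm(1, 0, cfg$effect_jitter_sd), 0), 1)
    lc <- max(ef$lambda_c + rnorm(1, 0, cfg$effect_jitter_sd), 0)
    segs <- lapply(MONTAGE, function(ch) {
      lapply(1:2, function(k) {
        generate_channel_signal(
          cfg, ch, cond,
          lambda_f = if (ch %in% low_ch) lf else 0,
          lambda_c = if (ch %in% c("O1", "O2")) lc else 0,
          segment_index = k)
      })
    })
    names(segs) <- MONTAGE
    sessions[[i]] <- list(session_id = sprintf("S%02d", i), condition = cond,
                          segments = segs, bfcrs = clinical$bfcrs[i],
                          bdnf_ng_ml = clinical$bdnf_ng_ml[i])
  }
  clinical$session <- vapply(sessions, `[[`, "", "session_id")
  list(sessions = sessions,
       clinical = clinical[c("session", "condition", "bfcrs", "bdnf_ng_ml")],
       course = table1_fixture())
}

# BFCRS/BDNF trajectories over the chronologically ordered sessions.
synth_clinical <- function(cfg, conds) {
  cl <- cfg$clinical
  n <- length(conds)
  traj <- numeric(n)
  idx <- split(seq_len(n), factor(conds, levels = CONDITIONS))
  ramp <- function(from, to, k) if (k == 1) to else seq(from, to, length.out = k)
  traj[idx$pre_ect] <- cl$bfcrs_pre
  traj[idx$during_ect] <- ramp(cl$bfcrs_pre - 2, cl$bfcrs_during_end,
                               length(idx$during_ect))
  traj[idx$after_ect] <- ramp(cl$bfcrs_during_end + 2, cl$bfcrs_after_end,
                              length(idx$after_ect))
  traj[idx$lorazepam] <- ramp(cl$bfcrs_after_end - 2, cl$bfcrs_lorazepam_end,
                              length(idx$lorazepam))
  bfcrs <- pmax(round(traj + rnorm(n, 0, cl$bfcrs_noise_sd)), 0)
  bdnf_traj <- numeric(n)
  bdnf_traj[idx$pre_ect] <- cl$bdnf_baseline
  bdnf_traj[idx$during_ect] <- cl$bdnf_baseline +
    cl$bdnf_ect_rise * seq_along(idx$during_ect) / length(idx$during_ect)
  bdnf_traj[idx$after_ect] <- cl$bdnf_baseline + cl$bdnf_ect_rise * 0.9
  bdnf_traj[idx$lorazepam] <- cl$bdnf_baseline + cl$bdnf_ect_rise * 0.7
  # sparse serum sampling: one observation per study phase
  obs <- vapply(idx[lengths(idx) > 0], function(v) v[ceiling(length(v) / 2)],
                integer(1))
  obs <- sort(obs)[seq_len(min(cl$n_bdnf_obs, length(obs)))]
  bdnf <- rep(NA_real_, n)
  bdnf[obs] <- pmax(bdnf_traj[obs] + rnorm(length(obs), 0, cl$bdnf_noise_sd),
                    0.1)
  data.frame(condition = conds, bfcrs = as.integer(bfcrs), bdnf_ng_ml = bdnf,
             stringsAsFactors = FALSE)
}

#' Packaged ECT course table
#'
#' The eight-stimulation course profile shipped with the package: percent
#' energy settings, delivered charge (mC) and seizure duration (s) for seven
#' twice-weekly bifrontal ECT sessions, session 7 holding two stimulations
#' (the first of which failed to elicit a seizure).
#'
#' @return An `ect_course_table` with 8 rows.
#' @examples
#' ect_course_summary(table1_fixture())
#' @export
table1_fixture <- function() {
  as_course_table(data.frame(
    session = c(1, 2, 3, 4, 5, 6, 7, 7),
    stimulation = c(1, 1, 1, 1, 1, 1, 1, 2),
    percent_energy = c(30, 25, 20, 15, 10, 10, 5, 10),
    charge_mC = c(151.1, 125.2, 100.1, 74.7, 49.8, 49.8, 49.8, 49.8),
    seizure_duration_s = c(54, 69, 55, 57, 60, 70, 0, 78)))
}

#' Write a generated study to disk in the formats the readers consume
#'
#' Writes, under `dir`: one matrix CSV per session (two concatenated 30 s
#' segments per channel), `manifest.yaml` with per-session segment markers,
#' `clinical.csv`, and `course.csv`. A study written this way can be read
#' back and analysed through [read_manifest()]/[run_pipeline()], so the
#' generator exercises the same I/O paths as real data.
#'
#' @param study Result of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- study$sessions[[1]]$segments[[1]][[1]]$sampling_rate_hz
  seg_s <- study$sessions[[1]]$segments[[1]][[1]]$n / fs
  entries <- lapply(study$sessions, function(s) {
    mat <- do.call(rbind, lapply(s$segments, function(pair) {
      c(pair[[1]]$samples, pair[[2]]$samples)
    }))
    rec <- recording(mat, names(s$segments), fs, s$session_id)
    fn <- paste0(s$session_id, ".csv")
    write_matrix_csv(rec, file.path(dir, fn))
    list(id = s$session_id, condition = s$condition, file = fn,
         markers = list(c(0, seg_s), c(seg_s, seg_s)))
  })
  yaml::write_yaml(list(sessions = entries), file.path(dir, "manifest.yaml"))
  write.csv(study$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(as.data.frame(study$course), file.path(dir, "course.csv"),
            row.names = FALSE)
  invisible(file.path(dir, "manifest.yaml"))
}
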