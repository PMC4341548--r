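#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Either `manifest` points
#' at an existing study on disk, or `generate` holds a [generator_config()]
#' and the pipeline synthesizes its input first (written under
#' `out_dir/input` so the run is reproducible from files).
#'
#' @param manifest Path to a session manifest (see [read_manifest()]), or
#'   `NULL` when `generate` is given.
#' @param out_dir Output directory.
#' @param generate Optional [generator_config()].
#' @param clinical,course Paths to the clinical and ECT-course CSVs; default
#'   to `clinical.csv` / `course.csv` next to the manifest.
#' @param entropy An [entropy_params()].
#' @param sfs Scale factors to evaluate (`NULL` = all `1:max_sf`; restricting
#'   to the summary bands speeds the run without changing the summaries).
#' @param epoch_s,log_base Spectral options (see [power_spectrum()]).
#' @param bands Band edges (see [default_bands()]).
#' @param amp_limit_uv,grad_limit_uv Artifact-flag limits
#'   (see [flag_artifacts()]).
#' @param sf_low,sf_high,low_channels,high_channels Summary-band definitions
#'   (see [summarize_session()]).
#' @param exclude_conditions Conditions excluded in the second association
#'   variant (default `"lorazepam"`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, out_dir = "ectmse-out",
                            generate = NULL, clinical = NULL, course = NULL,
                            entropy = entropy_params(), sfs = NULL,
                            epoch_s = 2, log_base = "log10",
                            bands = default_bands(),
                            amp_limit_uv = 100, grad_limit_uv = 50,
                            sf_low = 1:5, sf_high = 31:40,
                            low_channels = c("F3", "F4", "C3", "C4"),
                            high_channels = c("O1", "O2"),
                            exclude_conditions = "lorazepam") {
  if (is.null(manifest) && is.null(generate))
    stop("either a manifest path or a generator config is required")
  if (!is.null(generate)) stopifnot(inherits(generate, "generator_config"))
  stopifnot(inherits(entropy, "entropy_params"))
  if (any(c(sf_low, sf_high) > entropy$max_sf))
    stop("summary SF bands must lie within 1..max_sf")
  structure(list(manifest = manifest, out_dir = out_dir, generate = generate,
                 clinical = clinical, course = course, entropy = entropy,
                 sfs = sfs, epoch_s = epoch_s, log_base = log_base,
                 bands = bands, amp_limit_uv = amp_limit_uv,
                 grad_limit_uv = grad_limit_uv, sf_low = sf_low,
                 sf_high = sf_high, low_channels = low_channels,
                 high_channels = high_channels,
                 exclude_conditions = exclude_conditions),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Maps a flat YAML document onto [pipeline_config()]; nested `entropy` and
#' `generate` blocks map onto [entropy_params()] and [generator_config()]
#' fields.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$entropy)) y$entropy <- do.call(entropy_params, y$entropy)
  if (!is.null(y$generate)) y$generate <- do.call(generator_config, y$generate)
  if (!is.null(y$manifest))
    y$manifest <- file.path(dirname(path), y$manifest)
  do.call(pipeline_config, y)
}

#' Run the full treatment-course analysis
#'
#' Sequences the whole analysis: read (or synthesize and write) the study;
#' cut and artifact-check the two 30 s segments per channel; compute MSE
#' curves per segment and average them per channel; compute Hanning-windowed
#' power spectra (segment-averaged pre-log); collapse each session to the
#' frontocentral SF 1-5 and occipital SF 31-40 summaries; average per
#' condition; correlate the summaries with BFCRS and BDNF with and without
#' the excluded conditions; and summarize the ECT course table. Results are
#' written as tidy CSVs plus a single JSON report, with a log recording every
#' default that fired. Identical inputs give identical outputs.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @return (Invisibly) a list: `mse` (long data frame), `spectra`,
#'   `summaries`, `condition_means`, `associations`, `course_summary`,
#'   `alpha_dominance`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  if (!is.null(config$generate)) {
    logf("generating synthetic study (seed %d)", config$generate$seed)
    study <- generate_study(config$generate)
    input_dir <- file.path(config$out_dir, "input")
    config$manifest <- write_study(study, input_dir)
  }
  man <- read_manifest(config$manifest)
  base <- dirname(config$manifest)
  clin_path <- if (is.null(config$clinical)) file.path(base, "clinical.csv") else config$clinical
  course_path <- if (is.null(config$course)) file.path(base, "course.csv") else config$course
  clinical <- read_clinical_table(clin_path)
  course <- read_course_table(course_path)
  logf("manifest: %d sessions; entropy m=%d r=%.2g max_sf=%d (%s); artifact limits %g/%g uV",
       length(man), config$entropy$m, config$entropy$r_frac,
       config$entropy$max_sf, config$entropy$r_mode,
       config$amp_limit_uv, config$grad_limit_uv)
  sfs <- if (is.null(config$sfs)) seq_len(config$entropy$max_sf) else config$sfs
  mse_rows <- list(); spec_rows <- list(); summaries <- list()
  alpha_ok <- logical(0)
  for (s in man) {
    rec <- read_recording(s$file, session_id = s$id)
    segs <- extract_segments(rec, s$markers)
    avg_curves <- list(); spectra2 <- list()
    for (ch in rec$channel_labels) {
      pair <- segs[[ch]]
      for (k in seq_along(pair)) {
        if (!flag_artifacts(pair[[k]], config$amp_limit_uv,
                            config$grad_limit_uv))
          logf("session %s channel %s segment %d flagged as artifactual",
               s$id, ch, k)
      }
      curves <- lapply(pair, mse_curve, params = config$entropy, sfs = sfs)
      for (k in seq_along(curves)) {
        mse_rows[[length(mse_rows) + 1L]] <- data.frame(
          session = s$id, condition = s$condition, channel = ch,
          segment = k, sf = sfs, sampen = curves[[k]]$sampen[sfs],
          stringsAsFactors = FALSE)
      }
      avg_curves[[ch]] <- average_segments(curves[[1]], curves[[2]])
      ps <- lapply(pair, power_spectrum, epoch_s = config$epoch_s,
                   log_base = config$log_base)
      pow <- (ps[[1]]$power + ps[[2]]$power) / 2
      logp <- if (config$log_base == "log10") log10(pow) else log(pow)
      spectra2[[ch]] <- ps[[1]]
      spectra2[[ch]]$power <- pow
      spectra2[[ch]]$log_power <- logp
      spec_rows[[length(spec_rows) + 1L]] <- data.frame(
        session = s$id, condition = s$condition, channel = ch,
        freq_hz = ps[[1]]$freqs_hz, log_power = logp,
        stringsAsFactors = FALSE)
    }
    alpha_ok[s$id] <- alpha_dominance_check(spectra2[["O1"]],
                                            spectra2[["O2"]],
                                            bands = config$bands)
    if (!alpha_ok[s$id])
      logf("session %s failed the posterior alpha-dominance check", s$id)
    summaries[[s$id]] <- summarize_session(
      avg_curves, session_id = s$id, condition = s$condition,
      sf_low = config$sf_low, sf_high = config$sf_high,
      low_channels = config$low_channels,
      high_channels = config$high_channels)
  }
  mse <- do.call(rbind, mse_rows)
  spectra <- do.call(rbind, spec_rows)
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  cond_means <- condition_average(summaries)
  assoc <- clinical_association(summaries, clinical,
                                exclude = config$exclude_conditions)
  course_sum <- ect_course_summary(course)
  # schema version comments keep the inter-stage CSV contract explicit
  write_tidy <- function(df, fn, schema) {
    p <- file.path(config$out_dir, fn)
    con <- file(p, "w"); on.exit(close(con), add = TRUE)
    writeLines(paste0("# ectmse v1 schema: ", schema), con)
    write.csv(df, con, row.names = FALSE)
    p
  }
  write_tidy(mse, "mse.csv", "session,condition,channel,segment,sf,sampen")
  write_tidy(spectra, "spectra.csv",
             "session,condition,channel,freq_hz,log_power")
  write_tidy(summaries, "summaries.csv",
             paste(names(summaries), collapse = ","))
  report <- list(course_summary = course_sum,
                 condition_means = cond_means,
                 associations = assoc,
                 alpha_dominance = alpha_ok,
                 n_sessions = nrow(summaries))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  logf("wrote mse.csv, spectra.csv, summaries.csv, report.json")
  invisible(c(report, list(mse = mse, spectra = spectra,
                           summaries = summaries, out_dir = config$out_dir)))
}

#' Read a tidy MSE CSV back into a long data frame
#'
#' Counterpart of the `mse.csv` written by [run_pipeline()] and the CLI `mse`
#' stage (schema-comment line tolerated).
#'
#' @param path CSV path.
#' @return Data frame `session, condition, channel, segment, sf, sampen`.
#' @export
read_mse_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("session", "condition", "channel", "segment", "sf", "sampen")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("MSE CSV missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Session summaries from a long MSE table
#'
#' File-level counterpart of [summarize_session()]: averages each channel's
#' two segments, then collapses scale-band by region. Used by the CLI
#' `summarize` stage so stages compose via files.
#'
#' @param mse Long data frame as from [read_mse_csv()].
#' @inheritParams summarize_session
#' @return Data frame of per-session summary rows.
#' @export
summarize_mse_table <- function(mse, sf_low = 1:5, sf_high = 31:40,
                                low_channels = c("F3", "F4", "C3", "C4"),
                                high_channels = c("O1", "O2")) {
  out <- lapply(split(mse, mse$session), function(d) {
    seg_avg <- stats::aggregate(sampen ~ channel + sf, data = d, FUN = mean,
                                na.action = stats::na.pass)
    max_sf <- max(mse$sf)
    curves <- lapply(split(seg_avg, seg_avg$channel), function(g) {
      v <- rep(NA_real_, max_sf)
      v[g$sf] <- g$sampen
      structure(list(sampen = v, channel = g$channel[1],
                     segment_index = NA_integer_,
                     params = entropy_params(max_sf = max_sf)),
                class = "mse_curve")
    })
    summarize_session(curves, session_id = d$session[1],
                      condition = d$condition[1], sf_low = sf_low,
                      sf_high = sf_high, low_channels = low_channels,
                      high_channels = high_channels)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
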