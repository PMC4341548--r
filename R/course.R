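#' Scale-band by region complexity summary for one session
#'
#' Collapses a session's segment-averaged MSE curves into the two scalars
#' tracked over the treatment course: `frontocentral_low_sf`, the mean SampEn
#' over scale factors 1-5 across F3, F4, C3, C4 (20 values), and
#' `occipital_high_sf`, the mean over scale factors 31-40 across O1 and O2
#' (20 values). Undefined SampEn entries are skipped and their count reported
#' in the `n_missing_*` columns; a band with every entry missing is an error.
#'
#' @param curves Named list of `mse_curve` objects (one per channel,
#'   segment-averaged), containing at least the six required channels.
#' @param session_id,condition Carried into the result.
#' @param sf_low,sf_high Scale-factor bands (defaults 1:5 and 31:40).
#' @param low_channels,high_channels Region channel sets.
#' @return One-row data frame: `session`, `condition`,
#'   `frontocentral_low_sf`, `occipital_high_sf`, `n_missing_low`,
#'   `n_missing_high`.
#' @export
summarize_session <- function(curves, session_id = NA, condition = NA,
                              sf_low = 1:5, sf_high = 31:40,
                              low_channels = c("F3", "F4", "C3", "C4"),
                              high_channels = c("O1", "O2")) {
  need <- c(low_channels, high_channels)
  missing <- setdiff(need, names(curves))
  if (length(missing))
    stop("curves missing for required channels: ",
         paste(missing, collapse = ", "))
  band_mean <- function(channels, sfs) {
    vals <- unlist(lapply(channels, function(ch) {
      cv <- curves[[ch]]
      stopifnot(inherits(cv, "mse_curve"))
      if (max(sfs) > length(cv$sampen))
        stop("curve for ", ch, " shorter than requested band")
      cv$sampen[sfs]
    }))
    n_na <- sum(is.na(vals))
    if (n_na == length(vals))
      stop("all SampEn entries undefined in band")
    if (n_na > 0)
      warning(n_na, " undefined SampEn entries skipped in band summary")
    c(mean(vals, na.rm = TRUE), n_na)
  }
  lo <- band_mean(low_channels, sf_low)
  hi <- band_mean(high_channels, sf_high)
  data.frame(session = session_id, condition = condition,
             frontocentral_low_sf = lo[1], occipital_high_sf = hi[1],
             n_missing_low = as.integer(lo[2]),
             n_missing_high = as.integer(hi[2]),
             stringsAsFactors = FALSE)
}

#' Per-condition mean of session summaries
#'
#' @param summaries Data frame of [summarize_session()] rows.
#' @param condition One of the four condition labels, or `NULL` for all.
#' @return Data frame with one row per condition: mean
#'   `frontocentral_low_sf` and `occipital_high_sf` plus session count.
#' @export
condition_average <- function(summaries, condition = NULL) {
  stopifnot(all(c("condition", "frontocentral_low_sf",
                  "occipital_high_sf") %in% names(summaries)))
  if (!is.null(condition)) {
    summaries <- summaries[summaries$condition %in% condition, , drop = FALSE]
    if (!nrow(summaries)) stop("no sessions in condition: ", condition)
  }
  agg <- lapply(split(summaries, summaries$condition), function(d) {
    data.frame(condition = d$condition[1],
               frontocentral_low_sf = mean(d$frontocentral_low_sf, na.rm = TRUE),
               occipital_high_sf = mean(d$occipital_high_sf, na.rm = TRUE),
               n_sessions = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(match(out$condition, CONDITIONS)), , drop = FALSE]
}

#' Between-segment reproducibility correlation per region
#'
#' For each region (frontal F3/F4, central C3/C4, occipital O1/O2) the two
#' segments of each session are reduced to one scalar each — the mean SampEn
#' over the region's channels and all scale factors — and the Pearson
#' correlation between segment-1 and segment-2 scalars is computed across
#' sessions.
#'
#' @param seg_scalars Data frame with columns `session`, `channel`,
#'   `segment` (1 or 2), `sampen_mean` (that channel/segment's mean SampEn
#'   over all scale factors); see [curves_to_segment_scalars()].
#' @return Named numeric vector of Pearson r, one per region.
#' @export
reproducibility_correlation <- function(seg_scalars) {
  need <- c("session", "channel", "segment", "sampen_mean")
  stopifnot(all(need %in% names(seg_scalars)))
  vapply(REGIONS, function(chs) {
    d <- seg_scalars[seg_scalars$channel %in% chs, , drop = FALSE]
    per <- lapply(split(d, list(d$session, d$segment), drop = TRUE),
                  function(g) data.frame(session = g$session[1],
                                         segment = g$segment[1],
                                         value = mean(g$sampen_mean, na.rm = TRUE)))
    per <- do.call(rbind, per)
    s1 <- per[per$segment == 1, ]
    s2 <- per[per$segment == 2, ]
    common <- intersect(s1$session, s2$session)
    if (length(common) < 3)
      stop("need >= 3 sessions with both segments")
    v1 <- s1$value[match(common, s1$session)]
    v2 <- s2$value[match(common, s2$session)]
    if (sd(v1) == 0 || sd(v2) == 0)
      stop("zero variance across sessions in a segment's scalars")
    cor(v1, v2)
  }, numeric(1))
}

#' Reduce per-segment MSE curves to region-scalar input
#'
#' Helper that turns a nested list of per-session, per-channel, per-segment
#' `mse_curve` objects into the long data frame consumed by
#' [reproducibility_correlation()].
#'
#' @param curves_by_session Named list (by session id) of named lists (by
#'   channel) of length-2 lists of `mse_curve` (segments 1 and 2).
#' @return Data frame `session`, `channel`, `segment`, `sampen_mean`.
#' @export
curves_to_segment_scalars <- function(curves_by_session) {
  rows <- list()
  for (sid in names(curves_by_session)) {
    chans <- curves_by_session[[sid]]
    for (ch in names(chans)) {
      for (k in seq_along(chans[[ch]])) {
        cv <- chans[[ch]][[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          session = sid, channel = ch, segment = k,
          sampen_mean = mean(cv$sampen, na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Association of complexity summaries with clinical course
#'
#' Descriptive Pearson correlations between each complexity summary
#' (`frontocentral_low_sf`, `occipital_high_sf`) and each clinical variable
#' (`bfcrs`, `bdnf_ng_ml`), computed both over all sessions and with the
#' `exclude` conditions removed (by default the lorazepam sessions, since
#' lorazepam improved the clinical score without changing EEG complexity).
#' Sessions with a missing clinical value are dropped pairwise — BDNF is
#' sparse by design and is never interpolated. No p-values are computed: the
#' association is descriptive.
#'
#' @param summaries Data frame of [summarize_session()] rows.
#' @param clinical Data frame from [read_clinical_table()] (columns `session`,
#'   `bfcrs`, `bdnf_ng_ml`).
#' @param exclude Conditions to drop in the excluded variant (default
#'   `"lorazepam"`). Use `character(0)` for the all-sessions variant only.
#' @return Data frame with columns `summary`, `clinical_var`,
#'   `excluded_conditions`, `pearson_r`, `n_points`; the paired scatter data
#'   are attached as attribute `"scatter"` (a list of data frames).
#' @export
clinical_association <- function(summaries, clinical,
                                 exclude = "lorazepam") {
  clin_cols <- c("session", intersect(c("bfcrs", "bdnf_ng_ml"),
                                      names(clinical)))
  merged <- merge(summaries, clinical[clin_cols], by = "session")
  variants <- list(none = character(0))
  if (length(exclude)) variants[[paste(exclude, collapse = "+")]] <- exclude
  rows <- list(); scatter <- list()
  for (vn in names(variants)) {
    dat <- merged[!merged$condition %in% variants[[vn]], , drop = FALSE]
    for (sm in c("frontocentral_low_sf", "occipital_high_sf")) {
      for (cv in c("bfcrs", "bdnf_ng_ml")) {
        ok <- is.finite(dat[[sm]]) & is.finite(dat[[cv]])
        d <- dat[ok, , drop = FALSE]
        if (nrow(d) < 3)
          stop("fewer than 3 overlapping sessions for ", sm, " vs ", cv)
        if (sd(d[[sm]]) == 0 || sd(d[[cv]]) == 0)
          stop("zero variance in ", sm, " vs ", cv)
        key <- paste(sm, cv, vn, sep = "|")
        scatter[[key]] <- d[c("session", "condition", sm, cv)]
        rows[[key]] <- data.frame(
          summary = sm, clinical_var = cv,
          excluded_conditions = if (vn == "none") "" else vn,
          pearson_r = cor(d[[sm]], d[[cv]]), n_points = nrow(d),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scatter") <- scatter
  out
}

#' ECT course summary statistics
#'
#' Summarizes the stimulation-level course table: the first treatment's
#' threshold charge, mean charge and mean seizure duration over
#' seizure-producing stimulations (duration > 0), and the number of failed
#' (zero-duration) stimulations.
#'
#' @param table An `ect_course_table` (see [read_course_table()],
#'   [table1_fixture()]).
#' @return List with `threshold_first_mC`, `mean_charge_mC`,
#'   `mean_seizure_s`, `n_failed`, `n_stimulations`.
#' @export
ect_course_summary <- function(table) {
  stopifnot(inherits(table, "ect_course_table") || is.data.frame(table))
  if (!nrow(table)) stop("empty course table")
  first <- table[table$session == min(table$session), , drop = FALSE]
  first <- first[order(first$stimulation), , drop = FALSE]
  ok <- table$seizure_duration_s > 0
  list(threshold_first_mC = first$charge_mC[1],
       mean_charge_mC = mean(table$charge_mC[ok]),
       mean_seizure_s = mean(table$seizure_duration_s[ok]),
       n_failed = sum(!ok),
       n_stimulations = nrow(table))
}
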