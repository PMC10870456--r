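#' Segmentation configuration
#'
#' @param min_duration minimum time (s) a threshold crossing must be
#'   sustained to count as the APA onset; suppresses single-sample noise
#'   crossings.
#' @param settle_band half-width of the settling band around baseline used
#'   to terminate the returning phase, as a fraction of `lean_max`.
#' @param filter_hz optional low-pass cutoff (Hz) for a zero-phase
#'   second-order Butterworth filter applied to the projected signal before
#'   detection; `NULL` (default) disables filtering. Zero-phase filtering
#'   smears sharp post-onset excursions backwards in time and can bias the
#'   threshold-crossing onset early, so it is reserved for noisy
#'   recordings.
#' @param baseline_window time window (s, length-2 vector) used as the
#'   quiet-stance baseline; `NULL` means the whole preparation phase
#'   `[0, target_onset)`.
#' @return A list of class `segment_config`.
#' @export
segment_config <- function(min_duration = 0.05, settle_band = 0.10,
                           filter_hz = NULL, baseline_window = NULL) {
  check_number(min_duration, "min_duration", 0)
  check_number(settle_band, "settle_band", 0, 1, closed_lower = FALSE)
  if (!is.null(filter_hz)) check_number(filter_hz, "filter_hz", 0,
                                        closed_lower = FALSE)
  structure(list(min_duration = min_duration, settle_band = settle_band,
                 filter_hz = filter_hz, baseline_window = baseline_window),
            class = "segment_config")
}

#' Project a planar COP trial onto its task direction
#'
#' Reduces the planar (AP, ML) COP to the signed scalar displacement along
#' the straight line from the central point to the target: each channel is
#' centered on its quiet-stance baseline mean and the pair is projected
#' onto the unit target vector. Positive values point toward the target.
#'
#' @param trial a [cop_trial].
#' @param layout a [target_layout] containing the trial's `target_id`.
#' @param baseline_window optional time window (s) for the baseline means;
#'   defaults to the whole preparation phase.
#' @return Numeric vector (cm) of the same length as `trial$time`.
#' @export
project_onto_direction <- function(trial, layout, baseline_window = NULL) {
  dir <- target_direction(layout, trial$target_id)
  if (is.null(baseline_window)) {
    baseline_window <- c(0, trial$target_onset)
  }
  bl <- trial$time >= baseline_window[1] & trial$time < baseline_window[2]
  if (!any(bl)) {
    ls_abort("baseline window contains no samples", "leansim_error_validation")
  }
  ap <- trial$cop_ap - mean(trial$cop_ap[bl])
  ml <- trial$cop_ml - mean(trial$cop_ml[bl])
  ap * dir$unit[1] + ml * dir$unit[2]
}

#' Detect the APA onset by a sustained 2-SD threshold crossing
#'
#' The onset is the first post-onset time at which the signal deviates from
#' the baseline mean by more than twice the baseline standard deviation in
#' the direction opposite the target (i.e. goes below it, the signal being
#' oriented toward the target), sustained for at least `min_duration`.
#'
#' @param signal 1-D COP displacement toward the target, cm (e.g. from
#'   [project_onto_direction()]).
#' @param time sample times, s.
#' @param target_onset target-onset event time, s.
#' @param baseline_window time window (s) defining the "initial signal"
#'   whose mean and SD set the threshold; default `[0, target_onset)`.
#' @param min_duration sustain requirement, s (default 0.05).
#' @return The crossing time (s). Raises a condition of class
#'   `leansim_error_no_apa` when no sustained crossing exists.
#' @export
detect_apa_onset <- function(signal, time, target_onset,
                             baseline_window = NULL, min_duration = 0.05) {
  if (is.null(baseline_window)) baseline_window <- c(0, target_onset)
  if (baseline_window[2] > target_onset + 1e-9) {
    ls_abort("baseline window must lie before target onset",
             "leansim_error_validation")
  }
  bl <- time >= baseline_window[1] & time < baseline_window[2]
  bm <- mean(signal[bl])
  bsd <- sd(signal[bl])
  thr <- bm - 2 * bsd
  fs <- 1 / median(diff(time))
  n_min <- max(1L, as.integer(round(min_duration * fs)))

  post <- which(time > target_onset)
  below <- signal[post] < thr
  # first run of >= n_min consecutive below-threshold samples
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= n_min)
  if (length(hit) == 0L) {
    ls_abort("no APA detected: signal never crossed the 2-SD threshold opposite the target",
             "leansim_error_no_apa")
  }
  time[post[starts[hit[1]]]]
}

# first local extremum at or after index `from` (sign change of the
# forward difference, zero differences carried through)
.first_extremum_after <- function(s, from) {
  n <- length(s)
  if (from >= n) return(NA_integer_)
  ds <- sign(diff(s))
  last <- 0
  for (i in seq(max(from - 1L, 1L), n - 1L)) {
    if (ds[i] == 0) next
    if (last != 0 && ds[i] != last && i >= from) return(i)
    last <- ds[i]
  }
  NA_integer_
}

#' Segment a COP trial into its five phases
#'
#' Decomposes a voluntary-lean COP trial into preparation, planning, APA,
#' reaching and returning, and extracts the temporal parameters and the two
#' spatial features used for gain identification:
#' \itemize{
#'   \item `t_r` (reaction time): APA onset ([detect_apa_onset()]) minus
#'     target onset;
#'   \item APA end: first return of the signal to the baseline mean after
#'     the APA extremum; `t_APA` = end - onset; `apa_size` = peak-to-peak
#'     displacement within the APA window;
#'   \item `t_f` (reaching time): from APA onset to the global
#'     toward-target maximum; `lean_max` = that maximum minus baseline;
#'   \item `t_b` (return time): from the maximum to the first local
#'     extremum after the signal settles within `settle_band * lean_max`
#'     of baseline (falling back to the settling entry itself when the
#'     approach is monotone);
#'   \item `t_total = t_r + t_f + t_b`, an identity by construction.
#' }
#'
#' @param trial a [cop_trial].
#' @param layout a [target_layout] for the projection.
#' @param config a [segment_config].
#' @return An object of class `segmentation_result`.
#' @export
segment_trial <- function(trial, layout, config = segment_config()) {
  s <- project_onto_direction(trial, layout, config$baseline_window)
  res <- .segment_signal(s, trial$time, trial$target_onset, config)
  res$target_id <- trial$target_id
  res
}

# 1-D segmentation core shared by segment_trial() and the identification
# feature evaluator; `s` is the projected, baseline-centered toward-target
# signal on the uniform output grid.
.segment_signal <- function(s, time, onset, config = segment_config()) {
  fs <- 1 / median(diff(time))
  if (!is.null(config$filter_hz)) {
    bf <- signal::butter(2, config$filter_hz / (fs / 2), type = "low")
    s <- as.numeric(signal::filtfilt(bf, s))
  }
  bw <- if (is.null(config$baseline_window)) c(0, onset) else
    config$baseline_window
  bl <- time >= bw[1] & time < bw[2]
  bm <- mean(s[bl])
  bsd <- sd(s[bl])

  onset_time <- detect_apa_onset(s, time, onset, bw, config$min_duration)
  onset_idx <- which(time == onset_time)[1]

  # APA end: first return to the baseline mean after the APA extremum
  after <- seq(onset_idx, length(s))
  back <- after[s[after] >= bm]
  back <- back[back > onset_idx]
  if (length(back) == 0L) {
    ls_abort("segmentation failed: COP never returned to baseline after the APA",
             "leansim_error_segmentation")
  }
  apa_end_idx <- back[1]
  apa_win <- onset_idx:apa_end_idx
  apa_size <- max(s[apa_win]) - min(s[apa_win])

  # reaching peak: global toward-target maximum after the APA
  reach_win <- apa_end_idx:length(s)
  peak_idx <- reach_win[which.max(s[reach_win])]
  if (peak_idx >= length(s) || s[peak_idx] <= bm) {
    ls_abort("segmentation failed: no reaching peak found (monotone drift?)",
             "leansim_error_segmentation")
  }
  lean_max <- s[peak_idx] - bm

  # returning: entry into the settling band, then the first local extremum
  band <- config$settle_band * lean_max
  post_peak <- seq(peak_idx + 1L, length(s))
  entry <- post_peak[(s[post_peak] - bm) <= band]
  if (length(entry) == 0L) {
    ls_abort("segmentation failed: COP never settled near baseline after the peak",
             "leansim_error_segmentation")
  }
  ext_idx <- .first_extremum_after(s, entry[1])
  settle_rule <- "extremum"
  if (is.na(ext_idx)) {
    ext_idx <- entry[1]
    settle_rule <- "band_entry"
  }

  t_r <- onset_time - onset
  t_APA <- time[apa_end_idx] - onset_time
  t_f <- time[peak_idx] - onset_time
  t_b <- time[ext_idx] - time[peak_idx]

  structure(list(
    t_r = t_r, t_APA = t_APA, t_f = t_f, t_b = t_b,
    t_total = t_r + t_f + t_b,
    apa_size = apa_size, lean_max = lean_max,
    apa_onset_idx = onset_idx, apa_end_idx = apa_end_idx,
    peak_idx = peak_idx, return_end_idx = ext_idx,
    baseline_mean = bm, baseline_sd = bsd,
    settle_rule = settle_rule
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation> t_r %.3f s, t_APA %.3f s, t_f %.3f s, t_b %.3f s (total %.3f s)\n  APA size %.3f cm, Lean_max %.3f cm\n",
    x$t_r, x$t_APA, x$t_f, x$t_b, x$t_total, x$apa_size, x$lean_max))
  invisible(x)
}

#' Aggregate per-trial features into per-direction means
#'
#' Averages the repeated trials of one subject direction-wise (the protocol
#' repeats each direction four times). Flagged trials (e.g. no APA
#' detected) are excluded and the number of trials actually used is
#' reported.
#'
#' @param features a data.frame with a `target_id` column, numeric feature
#'   columns, and optionally a logical `flagged` column.
#' @return A data.frame with one row per direction: the feature means, `n`
#'   used, and `n_flagged`. Directions whose trials are all flagged are
#'   kept with `NA` features and `missing = TRUE`.
#' @export
aggregate_subject <- function(features) {
  if (!"target_id" %in% names(features)) {
    ls_abort("`features` must contain a target_id column",
             "leansim_error_validation")
  }
  if (!"flagged" %in% names(features)) features$flagged <- FALSE
  num_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                             logical(1))], "target_id")
  out <- lapply(split(features, features$target_id), function(d) {
    ok <- !d$flagged
    means <- if (any(ok)) {
      colMeans(d[ok, num_cols, drop = FALSE])
    } else {
      setNames(rep(NA_real_, length(num_cols)), num_cols)
    }
    cbind(data.frame(target_id = d$target_id[1]),
          as.data.frame(as.list(means)),
          data.frame(n = sum(ok), n_flagged = sum(!ok),
                     missing = !any(ok)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
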