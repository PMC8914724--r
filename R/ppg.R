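# Motion-adaptive PPG cleaning and beat-feature extraction.
#
# The gyroscope is the channel most sensitive to motion, so windows of the
# recording are labelled low/high motion from the mean increment of the
# cumulative gyroscope change, and the PPG stream is low-pass filtered with
# a cutoff matched to each window's motion state before smoothing and
# adaptive-threshold beat detection.

#' Classify windows into low/high motion from cumulative gyroscope change
#'
#' Splits the recording into consecutive windows of `window_s` seconds and
#' computes each window's mean increment of the cumulative gyroscope
#' change. Windows whose mean exceeds `threshold` are labelled `"high"`;
#' ties go to `"low"`. The default threshold is the median of the window
#' means, which adapts the split to each subject's activity mix.
#'
#' @param cum_gyro cumulative gyroscope change series (from
#'   [cumulative_change()]), one value per sample.
#' @param sample_rate_hz sampling rate of the series, Hz.
#' @param window_s window length in seconds (default 60, aligned with the
#'   one-minute aggregation grid).
#' @param threshold motion threshold on the window-mean increment
#'   (deg/s per sample); `NULL` uses the per-recording median.
#' @return Data frame: `window_index`, `mean_change`, `state`
#'   (`"low"`/`"high"`), plus attribute `"sample_state"` giving the state of
#'   every sample.
#' @export
classify_motion <- function(cum_gyro, sample_rate_hz, window_s = 60,
                            threshold = NULL) {
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  n <- length(cum_gyro)
  increments <- c(0, diff(cum_gyro))
  per_win <- max(1L, round(window_s * sample_rate_hz))
  # a series shorter than one window becomes a single window; a trailing
  # partial window is classified on its own
  win <- ((seq_len(n) - 1L) %/% per_win) + 1L
  means <- as.numeric(tapply(increments, win, mean))
  if (is.null(threshold)) threshold <- stats::median(means)
  state <- ifelse(means > threshold, "high", "low")
  out <- data.frame(window_index = seq_along(means),
                    mean_change = means,
                    state = state,
                    stringsAsFactors = FALSE)
  attr(out, "sample_state") <- state[win]
  attr(out, "threshold") <- threshold
  out
}

# Zero-phase 2nd-order Butterworth low-pass with reflection padding to
# suppress boundary transients.
lowpass_zerophase <- function(x, cutoff_hz, fs) {
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  n <- length(x)
  pad <- min(n - 1, round(3 * fs))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]),
          x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}

#' Motion-adaptive low-pass filtering of a PPG stream
#'
#' Filters the signal with a zero-phase 2nd-order Butterworth low-pass,
#' using a laxer cutoff in low-motion windows and a stricter one in
#' high-motion windows (motion artifact is broad-band, the cardiac
#' fundamental stays below 3 Hz even at 180 bpm). Both filtered versions
#' are computed over the full reflection-padded signal and the output
#' selects per sample according to its window's state, so window
#' boundaries introduce no transients and the output length equals the
#' input length. With all windows in the low state the result is exactly
#' the single-pass low-motion filter.
#'
#' @param ppg raw PPG samples.
#' @param motion result of [classify_motion()] (or any object with a
#'   `"sample_state"` attribute matching `ppg` in length).
#' @param cutoff_low_motion_hz,cutoff_high_motion_hz low-pass cutoffs, Hz;
#'   must satisfy `0 < high <= low < sample_rate_hz/2`.
#' @param sample_rate_hz sampling rate, Hz.
#' @return Filtered PPG, same length as the input.
#' @export
adaptive_lowpass <- function(ppg, motion, cutoff_low_motion_hz = 4,
                             cutoff_high_motion_hz = 2.5, sample_rate_hz) {
  if (!(cutoff_high_motion_hz > 0 &&
        cutoff_high_motion_hz <= cutoff_low_motion_hz &&
        cutoff_low_motion_hz < sample_rate_hz / 2))
    stop("cutoffs must satisfy 0 < high <= low < sample_rate/2",
         call. = FALSE)
  state <- attr(motion, "sample_state")
  if (is.null(state)) state <- rep("low", length(ppg))
  if (length(state) != length(ppg))
    stop("motion states do not match the PPG length", call. = FALSE)
  y_low <- lowpass_zerophase(ppg, cutoff_low_motion_hz, sample_rate_hz)
  if (!any(state == "high")) return(y_low)
  y_high <- lowpass_zerophase(ppg, cutoff_high_motion_hz, sample_rate_hz)
  ifelse(state == "high", y_high, y_low)
}

#' Centered moving-average smoothing
#'
#' Removes residual high-frequency detail after filtering. The window must
#' be odd so the average is centered; edge samples use shrunken
#' (truncated) windows, preserving the signal length.
#'
#' @param x numeric signal.
#' @param window_samples odd window width in samples; 1 is the identity.
#' @return Smoothed signal, same length as `x`.
#' @export
smooth_ppg <- function(x, window_samples) {
  if (window_samples < 1 || window_samples %% 2 == 0)
    stop("window_samples must be odd and >= 1", call. = FALSE)
  n <- length(x)
  if (window_samples == 1 || n == 1) return(x)
  half <- (window_samples - 1) / 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect heart beats in a cleaned PPG signal
#'
#' Adaptive-threshold peak detection: candidate regions are samples rising
#' above a centered moving-average baseline by a fraction of the local
#' signal spread; each contiguous region contributes its maximum as one
#' beat, and peaks closer than the refractory period `60/bpm_max` seconds
#' keep only the larger. Detection is flagged as failed (not an error) on
#' flat signals or when the implied beat rate falls outside the
#' physiological gate.
#'
#' @param ppg cleaned (filtered + smoothed) PPG samples; at least 10 s.
#' @param sample_rate_hz sampling rate, Hz.
#' @param bpm_min,bpm_max physiological gate on the implied beat rate
#'   (default 40-180 bpm).
#' @return List with `times` (beat instants in seconds from the first
#'   sample) and `success` flag.
#' @export
detect_beats <- function(ppg, sample_rate_hz, bpm_min = 40, bpm_max = 180) {
  n <- length(ppg)
  if (n < 10 * sample_rate_hz)
    stop("detect_beats needs at least 10 s of signal", call. = FALSE)
  win <- round(0.75 * sample_rate_hz)
  if (win %% 2 == 0) win <- win + 1
  baseline <- smooth_ppg(ppg, win)
  d <- ppg - baseline
  spread <- stats::sd(d)
  if (!is.finite(spread) || spread < 1e-9)
    return(list(times = numeric(0), success = FALSE))
  above <- d > 0.5 * spread
  if (!any(above)) return(list(times = numeric(0), success = FALSE))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  peak_idx <- mapply(function(s, e) s - 1L + which.max(ppg[s:e]),
                     starts[runs$values], ends[runs$values])
  peak_idx <- sort(peak_idx)
  refractory <- 60 / bpm_max
  keep <- logical(length(peak_idx))
  last <- -Inf
  last_i <- 0L
  for (i in seq_along(peak_idx)) {
    t_i <- (peak_idx[i] - 1) / sample_rate_hz
    if (t_i - last >= refractory) {
      keep[i] <- TRUE
      last <- t_i
      last_i <- i
    } else if (ppg[peak_idx[i]] > ppg[peak_idx[last_i]]) {
      keep[last_i] <- FALSE
      keep[i] <- TRUE
      last <- t_i
      last_i <- i
    }
  }
  times <- (peak_idx[keep] - 1) / sample_rate_hz
  dur_min <- n / sample_rate_hz / 60
  implied_bpm <- length(times) / dur_min
  success <- implied_bpm >= bpm_min && implied_bpm <= bpm_max
  list(times = times, success = success)
}

#' Beat-to-beat features from inter-beat intervals
#'
#' Computes the time-domain descriptors used per minute: mean inter-beat
#' interval `ibi` (ms), `bpm = 60000/ibi`, `RMSSD` (root mean square of
#' successive IBI differences, ms) and the breathing rate (Hz) as the
#' dominant frequency of the IBI modulation within 0.1-0.5 Hz (the IBI
#' series is interpolated to a uniform 4 Hz grid, linearly detrended, and
#' the periodogram peak inside the band taken). The breathing rate needs
#' at least 8 beats to resolve; otherwise it is `NA` and left to
#' imputation.
#'
#' @param ibi_ms vector of inter-beat intervals in ms (at least 2, i.e. at
#'   least 3 beats).
#' @param beat_times_s optional beat instants (seconds) of length
#'   `length(ibi_ms) + 1`, required for the breathing-rate spectrum.
#' @return List: `ibi`, `bpm`, `breathingrate`, `RMSSD`, `success`.
#' @export
beat_features <- function(ibi_ms, beat_times_s = NULL) {
  if (length(ibi_ms) < 2)
    return(list(ibi = NA_real_, bpm = NA_real_, breathingrate = NA_real_,
                RMSSD = NA_real_, success = FALSE))
  ibi <- mean(ibi_ms)
  bpm <- 60000 / ibi
  rmssd <- sqrt(mean(diff(ibi_ms)^2))
  br <- NA_real_
  if (!is.null(beat_times_s) && length(ibi_ms) >= 8) {
    mid <- (beat_times_s[-1] + beat_times_s[-length(beat_times_s)]) / 2
    grid <- seq(min(mid), max(mid), by = 0.25)
    if (length(grid) >= 16) {
      y <- stats::approx(mid, ibi_ms, xout = grid)$y
      y <- stats::resid(stats::lm(y ~ grid))
      sp <- stats::spec.pgram(stats::ts(y, frequency = 4), plot = FALSE,
                              taper = 0.1, detrend = TRUE)
      band <- sp$freq >= 0.1 & sp$freq <= 0.5
      if (any(band)) br <- sp$freq[band][which.max(sp$spec[band])]
    }
  }
  list(ibi = ibi, bpm = bpm, breathingrate = br, RMSSD = rmssd,
       success = TRUE)
}

#' Per-minute beat features from detected beat instants
#'
#' Slices detected beats into the recording's one-minute grid and computes
#' [beat_features()] per minute. Minutes with fewer than 3 beats, or where
#' the minute's rate falls outside the physiological gate, are flagged as
#' failures (to be filled by [impute_failures()]).
#'
#' @param beat_times_s beat instants in seconds from the recording start.
#' @param n_minutes number of complete minutes in the recording.
#' @param bpm_min,bpm_max physiological gate.
#' @return Data frame, one row per minute: `minute_index`, `ibi`, `bpm`,
#'   `breathingrate`, `RMSSD`, `success`.
#' @export
minute_beat_features <- function(beat_times_s, n_minutes,
                                 bpm_min = 40, bpm_max = 180) {
  rows <- lapply(seq_len(n_minutes), function(m) {
    sel <- beat_times_s >= (m - 1) * 60 & beat_times_s < m * 60
    beats <- beat_times_s[sel]
    if (length(beats) < 3)
      return(data.frame(minute_index = m, ibi = NA_real_, bpm = NA_real_,
                        breathingrate = NA_real_, RMSSD = NA_real_,
                        success = FALSE))
    bf <- beat_features(diff(beats) * 1000, beats)
    ok <- bf$success && is.finite(bf$bpm) &&
      bf$bpm >= bpm_min && bf$bpm <= bpm_max
    data.frame(minute_index = m, ibi = bf$ibi, bpm = bf$bpm,
               breathingrate = bf$breathingrate, RMSSD = bf$RMSSD,
               success = ok)
  })
  do.call(rbind, rows)
}

#' Impute failed minutes with the last successful value
#'
#' Every failed minute's `ibi`, `bpm`, `breathingrate` and `RMSSD` are
#' copied from the most recent successful minute. A failure before any
#' success falls back to documented cold-start defaults (cohort-scale
#' means: bpm 78, ibi 772 ms, breathing rate 0.22 Hz, RMSSD 75.2 ms) and a
#' message is logged. A breathing rate that is `NA` in an otherwise
#' successful minute is carried forward the same way.
#'
#' @param minute_features data frame from [minute_beat_features()].
#' @param cold_start named list of fallback values.
#' @return The data frame with no missing cells; the `success` column
#'   records which rows were measured rather than imputed.
#' @export
impute_failures <- function(minute_features,
                            cold_start = list(bpm = 78, ibi = 772,
                                              breathingrate = 0.22,
                                              RMSSD = 75.2)) {
  df <- minute_features
  cols <- c("ibi", "bpm", "breathingrate", "RMSSD")
  cold_used <- FALSE
  for (i in seq_len(nrow(df))) {
    if (!isTRUE(df$success[i])) {
      if (i == 1) {
        df[1, cols] <- cold_start[cols]
        cold_used <- TRUE
      } else {
        df[i, cols] <- df[i - 1, cols]
      }
    } else {
      for (cc in cols) {
        if (is.na(df[i, cc])) {
          df[i, cc] <- if (i == 1) {
            cold_used <- TRUE
            cold_start[[cc]]
          } else df[i - 1, cc]
        }
      }
    }
  }
  if (cold_used)
    message("impute_failures: cold-start defaults used for minute 1")
  df
}

#' Full PPG pipeline: motion-adaptive cleaning to per-minute beat features
#'
#' Runs the whole chain on one recording: motion classification from the
#' cumulative gyroscope change, adaptive low-pass filtering, moving-average
#' smoothing (default window 0.25 s, rounded odd), beat detection,
#' per-minute feature extraction and last-value imputation.
#'
#' @param recording a `raw_recording`.
#' @param kinematics optional [compute_kinematics()] result.
#' @param cutoff_low_motion_hz,cutoff_high_motion_hz adaptive filter
#'   cutoffs, Hz.
#' @param smooth_s smoothing window in seconds.
#' @param window_s motion-classification window, seconds.
#' @param threshold motion threshold; `NULL` = per-recording median.
#' @param bpm_min,bpm_max physiological gate.
#' @return Data frame of imputed per-minute beat features (one row per
#'   complete minute).
#' @export
ppg_minute_features <- function(recording, kinematics = NULL,
                                cutoff_low_motion_hz = 4,
                                cutoff_high_motion_hz = 2.5,
                                smooth_s = 0.25, window_s = 60,
                                threshold = NULL,
                                bpm_min = 40, bpm_max = 180) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$sample_rate_hz
  if (is.null(kinematics)) kinematics <- compute_kinematics(recording)
  n_minutes <- length(recording$ppg) %/% round(60 * fs)
  if (n_minutes < 1)
    stop("recording shorter than one minute", call. = FALSE)
  motion <- classify_motion(kinematics$cumGyro, fs, window_s, threshold)
  filtered <- adaptive_lowpass(recording$ppg, motion,
                               cutoff_low_motion_hz, cutoff_high_motion_hz,
                               fs)
  w <- round(smooth_s * fs)
  if (w %% 2 == 0) w <- w + 1
  cleaned <- smooth_ppg(filtered, max(w, 1))
  beats <- detect_beats(cleaned, fs, bpm_min, bpm_max)
  mf <- minute_beat_features(beats$times, n_minutes, bpm_min, bpm_max)
  suppressMessages(impute_failures(mf))
}
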