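#' EMG band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass, the standard first
#' stage of surface-EMG conditioning: removes movement artefact and DC below
#' 20 Hz and high-frequency noise above 450 Hz while preserving the
#' physiological band. The forward-backward pass doubles the effective order
#' and cancels phase delay ("zero-lag" filtering).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz (default 1000).
#' @param low,high Band edges in Hz (defaults 20 and 450).
#' @param order Butterworth order per pass (default 4).
#' @return Filtered numeric vector of the same length.
#' @export
emg_bandpass <- function(x, fs = 1000, low = 20, high = 450, order = 4) {
  if (!is.numeric(x) || length(x) < 3 * order) {
    abort("`x` must be a numeric signal of length >= 3 * order.")
  }
  if (fs <= 2 * high) abort("Sampling rate must exceed twice the upper band edge.")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Power-line notch filter
#'
#' Zero-phase narrow Butterworth band-stop centred on the mains frequency
#' (default 50 Hz, 1 Hz bandwidth, Q = 50), removing line interference while
#' leaving adjacent EMG content essentially untouched.
#'
#' @inheritParams emg_bandpass
#' @param f0 Notch centre frequency in Hz.
#' @param bandwidth Stop-band width in Hz.
#' @export
emg_notch <- function(x, fs = 1000, f0 = 50, bandwidth = 1) {
  if (f0 >= fs / 2) abort("Notch frequency must be below the Nyquist rate.")
  bf <- signal::butter(2, c(f0 - bandwidth / 2, f0 + bandwidth / 2) / (fs / 2),
                       type = "stop")
  as.numeric(signal::filtfilt(bf, x))
}

#' Full-wave rectification and envelope smoothing
#'
#' Takes the absolute value of the conditioned signal and smooths it with a
#' zero-phase low-pass Butterworth filter (default 20 Hz cutoff, comparable
#' to a 25 ms moving average), producing the linear envelope used as the
#' muscle activation signal. Tiny negative excursions from filtering are
#' clipped to zero.
#'
#' @inheritParams emg_bandpass
#' @param cutoff Low-pass cutoff in Hz (default 20).
#' @export
rectify_envelope <- function(x, fs = 1000, cutoff = 20, order = 4) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  y <- as.numeric(signal::filtfilt(bf, abs(x)))
  pmax(y, 0)
}

#' Normalize an envelope to MVIC
#'
#' Divides the envelope by the muscle's maximum voluntary isometric
#' contraction reference amplitude, expressing activation as a fraction of
#' MVIC (values above 1 are possible during maximal dynamic efforts).
#'
#' @param x Numeric envelope.
#' @param mvic_value Positive MVIC reference amplitude.
#' @export
normalize_mvic <- function(x, mvic_value) {
  assert_scalar_number(mvic_value, "mvic_value")
  if (mvic_value <= 0) abort("`mvic_value` must be positive.")
  x / mvic_value
}

#' Time-normalize an envelope onto the movement cycle
#'
#' Cubic-spline resampling of the `[onset, offset]` window onto `n_points`
#' equally spaced samples representing 0-100% of the movement cycle.
#' Endpoints are preserved exactly.
#'
#' @param x Numeric envelope.
#' @param onset,offset Sample indices delimiting the movement (defaults: the
#'   whole signal).
#' @param n_points Number of output samples (default 101, i.e. 0-100%
#'   inclusive).
#' @export
time_normalize <- function(x, onset = 1, offset = length(x), n_points = 101) {
  if (offset <= onset || onset < 1 || offset > length(x)) {
    abort("`onset` must precede `offset` within the signal.")
  }
  idx <- onset:offset
  out <- spline(idx, x[idx], method = "fmm",
                xout = seq(onset, offset, length.out = n_points))$y
  out[1] <- x[onset]
  out[n_points] <- x[offset]
  out
}

#' Signal-to-noise ratio estimate
#'
#' `10 * log10(RMS_active^2 / RMS_quiet^2)` in dB, comparing an active
#' segment against a quiet (baseline) segment; trials below the `threshold`
#' (default 20 dB) are flagged as failing the quality screen. A silent quiet
#' segment yields `+Inf`, not an error.
#'
#' @param x Numeric signal.
#' @param active_idx,quiet_idx Index vectors for the two segments (must be
#'   disjoint and non-empty).
#' @param threshold Flagging threshold in dB.
#' @return A list with `snr_db` and logical `pass`.
#' @export
snr_estimate <- function(x, active_idx, quiet_idx, threshold = 20) {
  if (length(active_idx) == 0 || length(quiet_idx) == 0) {
    abort("Both segments must be non-empty.")
  }
  if (length(intersect(active_idx, quiet_idx)) > 0) {
    abort("Active and quiet segments must be disjoint.")
  }
  rms_a <- sqrt(mean(x[active_idx]^2))
  rms_q <- sqrt(mean(x[quiet_idx]^2))
  snr <- if (rms_q == 0) Inf else 10 * log10(rms_a^2 / rms_q^2)
  list(snr_db = snr, pass = snr >= threshold)
}

#' Full EMG conditioning chain
#'
#' Band-pass (20-450 Hz), notch (50 Hz), full-wave rectification with 20 Hz
#' low-pass smoothing, optional MVIC normalization, and cubic-spline time
#' normalization onto the 0-100% cycle.
#'
#' @inheritParams emg_bandpass
#' @inheritParams time_normalize
#' @param notch_f0 Notch centre in Hz (NULL skips the notch).
#' @param lp_cutoff Envelope low-pass cutoff in Hz.
#' @param mvic_value Optional MVIC reference; NULL skips normalization.
#' @return Numeric envelope of length `n_points`.
#' @export
preprocess_emg <- function(x, fs = 1000, low = 20, high = 450, order = 4,
                           notch_f0 = 50, lp_cutoff = 20,
                           mvic_value = NULL, onset = 1, offset = length(x),
                           n_points = 101) {
  y <- emg_bandpass(x, fs = fs, low = low, high = high, order = order)
  if (!is.null(notch_f0)) y <- emg_notch(y, fs = fs, f0 = notch_f0)
  y <- rectify_envelope(y, fs = fs, cutoff = lp_cutoff, order = order)
  if (!is.null(mvic_value)) y <- normalize_mvic(y, mvic_value)
  # the spline resample can undershoot slightly near sharp transients
  pmax(time_normalize(y, onset = onset, offset = offset, n_points = n_points), 0)
}

#' Condition a multi-channel EMG recording into an activation matrix
#'
#' Applies [preprocess_emg()] to every column of a samples-by-muscles data
#' frame (one channel per column, header of muscle labels) and assembles the
#' envelopes into an [activation_matrix()].
#'
#' @param df Data frame of raw signals, one column per muscle; an optional
#'   `time` column is dropped.
#' @param mvic Optional named vector of MVIC references (names = muscle
#'   labels).
#' @inheritParams preprocess_emg
#' @inheritParams activation_matrix
#' @return An [activation_matrix()].
#' @export
preprocess_trial <- function(df, fs = 1000, mvic = NULL, n_points = 101,
                             subject_id = NA_character_,
                             trial_id = NA_character_, ...) {
  df <- df[, setdiff(names(df), "time"), drop = FALSE]
  env <- vapply(names(df), function(lab) {
    mv <- if (!is.null(mvic)) unname(mvic[lab]) else NULL
    preprocess_emg(df[[lab]], fs = fs, mvic_value = mv, n_points = n_points, ...)
  }, numeric(n_points))
  activation_matrix(t(env), muscle_labels = names(df),
                    subject_id = subject_id, trial_id = trial_id,
                    modality = "emg")
}
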