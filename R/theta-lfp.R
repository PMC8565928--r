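#' Band-pass filter an LFP trace in the theta band
#'
#' 3rd-order Butterworth between 4 and 12 Hz, applied forward-backward
#' (zero phase distortion; the effective order doubles, which is accepted
#' because phase fidelity is essential for phase coding).
#'
#' @param lfp numeric vector.
#' @param fs sampling rate (Hz); must exceed twice the upper band edge.
#' @param band band edges (Hz).
#' @return filtered trace, same length as `lfp`.
#' @export
bandpass_theta <- function(lfp, fs, band = c(4, 12)) {
  abort_if(fs <= 2 * band[2], "sampling rate too low for the theta band")
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, lfp))
}

analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}

#' Instantaneous theta phase from a filtered trace
#'
#' Angle of the analytic signal (Hilbert transform), with the convention
#' that LFP peaks map to 0/360 degrees and troughs to 180 degrees.
#'
#' @param filtered band-limited trace (see [bandpass_theta()]).
#' @return phase in degrees, \[0, 360).
#' @export
theta_phase <- function(filtered) {
  abort_if(all(filtered == 0), "phase undefined for an all-zero trace")
  (Arg(analytic_signal(filtered)) * 180 / pi) %% 360
}

#' Instantaneous theta amplitude
#'
#' @param filtered band-limited trace.
#' @return envelope (modulus of the analytic signal).
#' @export
theta_amplitude <- function(filtered) {
  Mod(analytic_signal(filtered))
}

#' Mask of significant theta oscillation
#'
#' A sample is significant when the instantaneous theta amplitude exceeds
#' the 97th percentile of the amplitude distribution of a shuffled
#' surrogate: the LFP high-pass filtered at 1 Hz (3rd-order Butterworth),
#' its time stamps randomly permuted (a single permutation of the full
#' trace), then passed through the same theta band-pass.
#'
#' @param lfp raw LFP trace.
#' @param fs sampling rate (Hz).
#' @param seed optional RNG seed for the permutation.
#' @param percentile surrogate percentile, default 0.97.
#' @return logical vector, TRUE where theta is significant.
#' @export
significant_theta_mask <- function(lfp, fs, seed = NULL, percentile = 0.97) {
  if (!is.null(seed)) set.seed(seed)
  amp <- theta_amplitude(bandpass_theta(lfp, fs))
  hp <- signal::butter(3, 1 / (fs / 2), type = "high")
  surro <- as.numeric(signal::filtfilt(hp, lfp))
  surro <- surro[sample.int(length(surro))]
  surro_amp <- theta_amplitude(bandpass_theta(surro, fs))
  thr <- quantile(surro_amp, percentile, names = FALSE, type = 7)
  amp > thr
}

#' Segment a phase series into theta cycles
#'
#' Cycles span 0 to 360 degrees of the (offset-shifted) phase. A cycle is
#' significant only if every sample it contains is significant; analyses
#' use significant cycles exclusively. Boundary times are interpolated
#' between samples.
#'
#' @param t sample times (s).
#' @param phase phase series (deg).
#' @param mask logical significance mask (default all TRUE).
#' @param offset global phase offset (deg) added to the phase before
#'   cutting, so boundaries fall where `phase + offset` crosses 0/360.
#' @return tibble with `cycle`, `start_t`, `end_t`, `period`,
#'   `significant`.
#' @export
segment_cycles <- function(t, phase, mask = NULL, offset = 0) {
  mask <- mask %||% rep(TRUE, length(t))
  ph <- (phase + offset) %% 360
  n <- length(ph)
  wrap <- which(diff(ph) < -180)
  cross <- t[wrap] + (360 - ph[wrap]) / (ph[wrap + 1] + 360 - ph[wrap]) *
    (t[wrap + 1] - t[wrap])
  tol <- 360 * stats::median(diff(t)) * 12  # within one sample of a boundary
  if (length(ph) > 0 && ph[1] < tol) cross <- c(t[1], cross)
  if (ph[n] > 360 - tol) cross <- c(cross, t[n])
  if (length(cross) < 2) {
    return(tibble::tibble(cycle = integer(), start_t = numeric(),
                          end_t = numeric(), period = numeric(),
                          significant = logical()))
  }
  start_t <- cross[-length(cross)]
  end_t <- cross[-1]
  sig <- vapply(seq_along(start_t), function(i) {
    all(mask[t >= start_t[i] & t < end_t[i]])
  }, logical(1))
  tibble::tibble(cycle = seq_along(start_t), start_t = start_t,
                 end_t = end_t, period = end_t - start_t,
                 significant = sig)
}

#' Optimize the session-wide theta phase offset
#'
#' Phase precession clouds often wrap around 0/360 degrees because the
#' filtered-LFP phase does not mark the true boundaries of theta cycles.
#' This scans candidate offsets (-60 to 60 degrees in 2-degree steps),
#' rotates all clouds' phases by each candidate, refits the wrapped
#' orthogonal regression, and returns the offset with the lowest mean
#' orthogonal error across fields. Ties are broken toward 0.
#'
#' @param clouds list of precession clouds (tibbles with `position_norm`,
#'   `phase_norm`); clouds with fewer than `min_spikes` points are
#'   ignored.
#' @param offsets candidate offsets (deg).
#' @param min_spikes minimum cloud size, default 12.
#' @return optimal offset (deg).
#' @export
optimize_session_phase_offset <- function(clouds,
                                          offsets = seq(-60, 60, by = 2),
                                          min_spikes = 12) {
  clouds <- purrr::keep(clouds, ~ nrow(.x) >= min_spikes)
  abort_if(length(clouds) == 0, "no eligible fields for offset optimization")
  err <- vapply(offsets, function(o) {
    mean(vapply(clouds, function(cl) {
      rotated <- cl
      rotated$phase_norm <- (cl$phase_norm + o / 360) %% 1
      fit_odr_wrapped(rotated)$error
    }, numeric(1)))
  }, numeric(1))
  best <- err <= min(err) + 1e-12
  cand <- offsets[best]
  cand[which.min(abs(cand))]
}
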