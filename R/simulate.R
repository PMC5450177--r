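# Annotated synthetic ECG: morphology-parameterized beat trains, an
# AP-template-driven forward signal with known (k, h_R, h_L), and the
# noise/artifact model. Every generator is fully reproducible from its
# seed, and annotations carry the ground truth the detectors and the
# inverse fit are scored against.

#' Simulation configuration
#'
#' @param fs Sampling frequency in Hz (>= 100; default 200, matching the
#'   band-scheduling worked examples).
#' @param duration Record length in seconds (>= 2).
#' @param heart_rate Mean heart rate in bpm (30--220).
#' @param hr_jitter_bpm Standard deviation of beat-to-beat heart-rate
#'   jitter (0 = perfectly regular rhythm).
#' @param qrs_amplitude,t_amplitude Peak amplitudes in mV (textbook
#'   surface-lead ratio of about 5:1 by default).
#' @param qrs_width,t_width Wave widths in seconds.
#' @param noise_snr_db White-noise level as signal-to-noise ratio in dB,
#'   or \code{NA} for none.
#' @param powerline_hz Powerline interference frequency (50, 60 or
#'   \code{NA}); amplitude \code{powerline_amp}.
#' @param baseline_drift_amp,baseline_drift_freq Sinusoidal baseline
#'   wander amplitude (mV) and frequency (Hz); amplitude \code{NA} or 0
#'   disables it.
#' @param seed Integer seed driving every random element.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(fs = 200, duration = 30, heart_rate = 60,
                       hr_jitter_bpm = 0, qrs_amplitude = 1.0,
                       t_amplitude = 0.2, qrs_width = 0.10, t_width = 0.14,
                       noise_snr_db = NA, powerline_hz = NA,
                       powerline_amp = 0.05, baseline_drift_amp = NA,
                       baseline_drift_freq = 0.3, seed = 1L) {
  if (fs < 100) stop("fs must be >= 100 Hz")
  if (duration < 2) stop("duration must be >= 2 s")
  if (heart_rate < 30 || heart_rate > 220)
    stop("heart_rate must lie in [30, 220] bpm")
  if (!is.na(powerline_hz) && !powerline_hz %in% c(50, 60))
    stop("powerline_hz must be 50, 60 or NA")
  structure(as.list(environment()), class = "sim_config")
}

# dimensionless kernels, truncated to compact support so distant waves
# do not leak into each other's peaks
gauss_kernel <- function(dt, width) {
  s <- width / 4
  ifelse(abs(dt) <= 2 * width, exp(-0.5 * (dt / s)^2), 0)
}

mexican_hat_kernel <- function(dt, width) {   # zero-area biphasic spike
  s <- width / 4
  u <- dt / s
  ifelse(abs(dt) <= 2 * width, (1 - u^2) * exp(-0.5 * u^2), 0)
}

beat_schedule <- function(config) {
  rr_mean <- 60 / config$heart_rate
  n_max <- ceiling(config$duration / rr_mean) + 5
  rr <- rep(rr_mean, n_max)
  if (config$hr_jitter_bpm > 0) {
    hr <- config$heart_rate + stats::rnorm(n_max, 0, config$hr_jitter_bpm)
    hr <- pmin(pmax(hr, 30), 220)
    rr <- 60 / hr
  }
  r <- 0.5 + cumsum(c(0, rr))
  r[r < config$duration - 0.5]
}

#' Generate a morphology-parameterized ECG beat train
#'
#' Each beat is a positive Gaussian R lobe (peak exactly
#' \code{qrs_amplitude} at the scheduled R time) flanked by small negative
#' Q and S lobes, followed by a Gaussian T wave; configured noise terms
#' are added by [corrupt()].
#'
#' @param config A [sim_config()].
#' @return List with \code{signal} (mV), \code{t} (seconds), \code{fs}
#'   and \code{annotations} (data frame: \code{beat}, \code{r_time},
#'   \code{t_time}).
#' @export
#' @examples
#' rec <- generate_beats(sim_config(duration = 10, seed = 42))
#' nrow(rec$annotations)
generate_beats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  t <- seq(0, config$duration - 1 / config$fs, by = 1 / config$fs)
  r_times <- beat_schedule(config)
  t_offset <- 0.30   # R-to-T-peak interval, seconds
  sig <- numeric(length(t))
  for (r in r_times) {
    sig <- sig + config$qrs_amplitude *
      (gauss_kernel(t - r, config$qrs_width)
       - 0.15 * gauss_kernel(t - r + 0.8 * config$qrs_width, config$qrs_width / 2)
       - 0.12 * gauss_kernel(t - r - 0.8 * config$qrs_width, config$qrs_width / 2)) +
      config$t_amplitude * gauss_kernel(t - r - t_offset, config$t_width)
  }
  sig <- corrupt(sig, config)
  ann <- data.frame(beat = seq_along(r_times), r_time = r_times,
                    t_time = r_times + t_offset)
  list(signal = sig, t = t, fs = config$fs, annotations = ann)
}

# unit-time repolarization wave of the scaled AP pair: the surface ECG is
# the right-minus-left epicardial potential difference
repol_wave <- function(templates, params, tau) {
  ap_forward(templates$right, tau, k = 1, h = params$h_R) -
    ap_forward(templates$left, tau, k = 1, h = params$h_L)
}

#' True beat features implied by AP parameters
#'
#' Evaluates the forward model exactly: the repolarization wave is
#' \code{d(tau) = h_R C_R(tau) - h_L C_L(tau)} in template time, realized
#' at 1/k speed. The T peak sits at \code{tau*/k} after the beat onset
#' with amplitude \code{d(tau*)}, and the beat energy integral is
#' \code{(h_R Phi_R - h_L Phi_L)/k}. Per-beat read-time jitter emulates a
#' detector reading amplitude and latency at a slightly off-peak sample:
#' both are read at the same jittered time, so the features stay exactly
#' on the model surface.
#'
#' @param params List with \code{k}, \code{h_R}, \code{h_L}.
#' @param templates Templates from [build_default_templates()].
#' @param n_beats Number of beats.
#' @param read_jitter_s SD of the read-time jitter in template-time
#'   seconds (default 0.008).
#' @param feature_noise Relative SD of multiplicative noise applied to
#'   the measured T amplitude, latency and integral (0 = noise-free).
#' @param seed Integer seed.
#' @return Data frame with columns \code{t_amp}, \code{latency_s},
#'   \code{delta} (plus \code{true_k} etc. as attributes).
#' @export
generate_ap_features <- function(params, templates = build_default_templates(),
                                 n_beats = 40, read_jitter_s = 0.008,
                                 feature_noise = 0, seed = 1L) {
  set.seed(seed)
  tau_grid <- seq(0, templates$right$duration, by = 1e-4)
  d <- repol_wave(templates, params, tau_grid)
  tau_star <- tau_grid[which.max(d)]
  u1 <- params$h_R * template_integral(templates$right, 1) -
        params$h_L * template_integral(templates$left, 1)
  eps <- stats::rnorm(n_beats, 0, read_jitter_s)
  eps <- pmin(pmax(eps, -2.5 * read_jitter_s), 2.5 * read_jitter_s)
  tau_read <- pmin(pmax(tau_star + eps, 0), templates$right$duration)
  t_amp <- repol_wave(templates, params, tau_read)
  latency <- tau_read / params$k
  delta <- rep(u1 / params$k, n_beats)
  if (feature_noise > 0) {
    t_amp <- t_amp * (1 + stats::rnorm(n_beats, 0, feature_noise))
    latency <- latency * (1 + stats::rnorm(n_beats, 0, feature_noise))
    delta <- delta * (1 + stats::rnorm(n_beats, 0, feature_noise))
  }
  out <- data.frame(t_amp = t_amp, latency_s = latency, delta = delta)
  attr(out, "true_params") <- params
  out
}

#' Generate an ECG record driven by scaled AP templates
#'
#' Per beat: a zero-area biphasic depolarization spike at the beat onset
#' (so an R peak exists and the spike does not bias the beat integral),
#' plus the realized repolarization difference wave
#' \code{h_R C_R(k tau) - h_L C_L(k tau)} from the onset. Beats generated
#' this way, passed through [detect_beats()] and [fit_ap()], permit
#' recovery of the generating parameters.
#'
#' @param params List with \code{k}, \code{h_R}, \code{h_L} (all > 0);
#'   \code{k} is referenced to the mean RR interval.
#' @param templates Templates from [build_default_templates()].
#' @param config A [sim_config()]; \code{qrs_amplitude} scales the spike
#'   and the template units map to mV one-to-one.
#' @param rate_adapt If TRUE (default), the per-beat time scale follows
#'   the square-root rate dependence of ventricular repolarization
#'   (Bazett-like): \code{k_i = k / sqrt(RR_i / mean RR)}. With a
#'   jittered rhythm this produces the beat-to-beat latency variation
#'   that makes the three parameters jointly identifiable; a perfectly
#'   regular clean record carries one latency only and cannot separate
#'   the time scale from the amplitude pair.
#' @return As [generate_beats()], with annotation columns \code{t_time},
#'   \code{t_amp}, \code{latency_s}, \code{delta} and element
#'   \code{true_params}.
#' @export
generate_from_ap <- function(params, templates = build_default_templates(),
                             config = sim_config(), rate_adapt = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            params$k > 0, params$h_R > 0, params$h_L > 0)
  set.seed(config$seed)
  t <- seq(0, config$duration - 1 / config$fs, by = 1 / config$fs)
  onsets <- beat_schedule(config)
  rr <- diff(onsets)
  rr_prev <- c(mean(rr), rr)              # interval preceding each beat
  k_i <- if (rate_adapt) params$k / sqrt(rr_prev / mean(rr_prev))
         else rep(params$k, length(onsets))
  tau_grid <- seq(0, templates$right$duration, by = 1e-4)
  d <- repol_wave(templates, params, tau_grid)
  tau_star <- tau_grid[which.max(d)]
  u1 <- params$h_R * template_integral(templates$right, 1) -
        params$h_L * template_integral(templates$left, 1)
  sig <- numeric(length(t))
  for (j in seq_along(onsets)) {
    tau <- (t - onsets[j]) * k_i[j]
    inside <- tau >= 0 & tau <= templates$right$duration
    w <- numeric(length(t))
    w[inside] <- repol_wave(templates, params, tau[inside])
    sig <- sig + w +
      config$qrs_amplitude * mexican_hat_kernel(t - onsets[j], config$qrs_width)
  }
  sig <- corrupt(sig, config)
  ann <- data.frame(beat = seq_along(onsets), r_time = onsets,
                    t_time = onsets + tau_star / k_i,
                    t_amp = max(d), latency_s = tau_star / k_i,
                    delta = u1 / k_i, k_beat = k_i)
  structure(list(signal = sig, t = t, fs = config$fs, annotations = ann,
                 true_params = params), class = "ap_record")
}

#' Add configured corruptions to a clean signal
#'
#' White noise at a target SNR (realized exactly, the empirical noise
#' power is normalized), a powerline sinusoid, and sinusoidal baseline
#' wander, as switched on in the configuration. With all terms off the
#' signal is returned unchanged.
#'
#' @param signal Clean signal (mV).
#' @param config A [sim_config()]; uses the current RNG stream (seed it
#'   or call from a generator).
#' @return Corrupted signal.
#' @export
corrupt <- function(signal, config) {
  n <- length(signal)
  if (n == 0L) stop("empty signal")
  t <- (seq_len(n) - 1L) / config$fs
  out <- signal
  if (!is.na(config$noise_snr_db)) {
    p_sig <- mean(signal^2)
    noise <- stats::rnorm(n)
    noise <- noise * sqrt(p_sig / 10^(config$noise_snr_db / 10) / mean(noise^2))
    out <- out + noise
  }
  if (!is.na(config$powerline_hz))
    out <- out + config$powerline_amp * sin(2 * pi * config$powerline_hz * t)
  if (!is.na(config$baseline_drift_amp) && config$baseline_drift_amp > 0)
    out <- out + config$baseline_drift_amp *
      sin(2 * pi * config$baseline_drift_freq * t)
  out
}
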