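# R / T peak localization from band-extracted wavelet coefficients:
# windowed energy -> adaptive 0-1 extraction function -> run midpoints,
# then per-beat eigenvalue assembly on the baseline-corrected signal.

#' Detector configuration
#'
#' @param lambda Forgetting factor of the adaptive threshold update,
#'   in (0, 0.25].
#' @param r_duration_s Assumed R-wave duration T; the energy window is
#'   L = T/2 expressed in subband samples (default 0.10 s).
#' @param m0 Initial threshold (amplitude units of the subband
#'   coefficients), or \code{NA} to self-calibrate: the squared threshold
#'   starts at \code{m0_frac} times the maximum windowed energy over the
#'   first \code{calib_s} seconds.
#' @param m0_frac,calib_s Self-calibration fraction (default 0.3) and
#'   window (default 2 s).
#' @param refractory_s Minimum peak separation (default 0.25 s, the
#'   physiological upper heart-rate bound).
#' @param qrs_band,t_band Frequency bands (Hz) for the QRS complex and
#'   the T wave, as \code{c(low, high)}.
#' @param t_search Fractional RR window after the R peak searched for the
#'   T peak, as \code{c(start_s, frac_rr)}: the window is
#'   \code{(r + start_s, r + frac_rr * RR]}.
#' @param baseline_window_s Median-filter window for baseline removal.
#' @return Object of class \code{detector_config}.
#' @export
detector_config <- function(lambda = 0.125, r_duration_s = 0.10, m0 = NA,
                            m0_frac = 0.3, calib_s = 2,
                            refractory_s = 0.25,
                            qrs_band = c(10, 20), t_band = c(3, 8),
                            t_search = c(0.08, 0.6),
                            baseline_window_s = 0.6) {
  if (lambda <= 0 || lambda > 0.25) stop("lambda must lie in (0, 0.25]")
  if (refractory_s <= 0) stop("refractory_s must be positive")
  if (!is.na(m0) && m0 <= 0) stop("m0 must be positive")
  structure(as.list(environment()), class = "detector_config")
}

#' Trailing windowed energy of a coefficient sequence
#'
#' \code{E(t) = sum_{j=0}^{L} chi^2(t - j)}, with out-of-range samples
#' treated as zero; same length as the input.
#'
#' @param chi Coefficient sequence.
#' @param L Window extent (>= 1); the window covers L + 1 samples.
#' @return Non-negative energy sequence.
#' @export
windowed_energy <- function(chi, L) {
  if (length(chi) == 0L) stop("empty sequence")
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  cs <- cumsum(c(0, chi^2))
  idx <- seq_along(chi)
  cs[idx + 1L] - cs[pmax(idx - L - 1L, 0L) + 1L]
}

#' Adaptive 0-1 extraction function
#'
#' Binarizes a windowed-energy sequence against a self-adjusting squared
#' threshold: \code{Z(t) = 1} iff \code{E(t) >= M^2}, and on every
#' triggering sample the squared threshold relaxes toward the observed
#' energy, \code{M^2 <- M^2 (1 - lambda) + lambda E(t)}. Tracking the
#' threshold in energy units keeps the comparison and the update
#' dimensionally consistent. The whole operation is invariant under
#' jointly rescaling the coefficients by c and \code{m0} by c.
#'
#' @param E Energy sequence (from [windowed_energy()]).
#' @param m0 Initial threshold in amplitude units (> 0); the initial
#'   squared threshold is \code{m0^2}.
#' @param lambda Forgetting factor in \[0, 0.25\] (0 freezes the
#'   threshold; useful in tests).
#' @return List with \code{Z} (integer 0/1 vector) and \code{m_final}
#'   (amplitude units).
#' @export
binarize_adaptive <- function(E, m0, lambda = 0.125) {
  if (is.na(m0) || m0 <= 0) stop("m0 must be positive")
  if (lambda < 0 || lambda > 0.25) stop("lambda must lie in [0, 0.25]")
  m2 <- m0^2
  Z <- integer(length(E))
  for (t in seq_along(E)) {
    if (E[t] >= m2) {
      Z[t] <- 1L
      m2 <- m2 * (1 - lambda) + lambda * E[t]
    }
  }
  list(Z = Z, m_final = sqrt(m2))
}

#' Midpoints of the 0-1 extraction runs
#'
#' Each maximal run of 1s \[a, b\] is located at its midpoint
#' \code{floor((a + b) / 2)} (0-based indices). Runs whose midpoints fall
#' closer than the refractory distance are merged, keeping the run with
#' the larger peak energy.
#'
#' @param Z 0-1 vector.
#' @param refractory_samples Minimum separation in samples (0 disables
#'   merging).
#' @param E Optional energy sequence used to rank runs when merging;
#'   defaults to run length.
#' @return Strictly increasing integer vector of 0-based midpoint indices.
#' @export
localize_midpoints <- function(Z, refractory_samples = 0, E = NULL) {
  stopifnot(all(Z %in% c(0L, 1L)))
  r <- rle(Z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values == 1L)
  if (length(runs) == 0L) return(integer(0))
  a <- starts[runs] - 1L; b <- ends[runs] - 1L   # 0-based
  mid <- (a + b) %/% 2L
  score <- if (is.null(E)) (b - a + 1) else
    vapply(seq_along(a), function(i) max(E[(a[i] + 1L):(b[i] + 1L)]), numeric(1))
  if (refractory_samples > 0 && length(mid) > 1L) {
    keep <- rep(TRUE, length(mid))
    i <- 1L
    while (i < length(mid)) {
      j <- i + 1L
      while (j <= length(mid) && keep[j] == FALSE) j <- j + 1L
      if (j > length(mid)) break
      if (keep[i] && mid[j] - mid[i] < refractory_samples) {
        if (score[j] > score[i]) { keep[i] <- FALSE; i <- j }
        else keep[j] <- FALSE
      } else i <- j
    }
    mid <- mid[keep]
  }
  mid
}

#' Remove baseline wander by median filtering
#'
#' @param x Signal.
#' @param fs Sampling frequency (Hz).
#' @param window_s Median window in seconds (default 0.6).
#' @return Baseline-corrected signal.
#' @export
baseline_correct <- function(x, fs, window_s = 0.6) {
  k <- round(window_s * fs)
  if (k %% 2 == 0) k <- k + 1
  if (k >= length(x)) return(x - stats::median(x))
  x - stats::runmed(x, k, endrule = "median")
}

# localize one band: extract -> windowed energy -> adaptive 0-1 ->
# midpoints -> times (seconds). Returns empty when the subband is flat.
#
# Because the trigger-conditioned threshold update only ever raises the
# squared threshold, a single pass over a long record ratchets it toward
# the largest burst and starts missing ordinary beats; the record is
# therefore processed in blocks (config$calib_s * 2 seconds), each
# self-calibrated from its own windowed-energy maximum. mask_times
# silences the energy around already-located events (used to keep QRS
# leakage out of the T band).
localize_band <- function(x, fs, band, config, spec,
                          mask_times = NULL, mask_halfwidth_s = 0.12) {
  sb <- extract_band(x, fs, band, spec)
  fs_sub <- fs / sb$decimation
  L <- max(1L, ceiling(config$r_duration_s / 2 * fs_sub))
  E <- windowed_energy(sb$coefficients, L)
  if (!is.null(mask_times) && length(mask_times) > 0) {
    tcoef <- subband_time(sb, seq_along(E) - 1L)
    for (mt in mask_times)
      E[abs(tcoef - mt) <= mask_halfwidth_s + L / fs_sub / 2] <- 0
  }
  gmax <- max(E)
  if (gmax <= 0) return(list(times = numeric(0), flat = TRUE))
  block <- max(4L, ceiling(2 * config$calib_s * fs_sub))
  starts <- seq(1L, length(E), by = block)
  Z <- integer(length(E))
  for (s in starts) {
    e <- E[s:min(s + block - 1L, length(E))]
    m0 <- if (is.na(config$m0)) sqrt(config$m0_frac * max(e)) else config$m0
    if (m0 <= 0 || max(e) < 1e-4 * gmax) next  # silent block: no triggers
    Z[s:(s + length(e) - 1L)] <- binarize_adaptive(e, m0, config$lambda)$Z
  }
  mids <- localize_midpoints(Z, round(config$refractory_s * fs_sub), E)
  list(times = subband_time(sb, mids), flat = FALSE,
       energy = E, fs_sub = fs_sub, series = sb, mids = mids)
}

# parabolic refinement of an extremum on the sample grid
refine_peak <- function(x, fs, t0, halfwin_s, what = c("max", "absmax")) {
  what <- match.arg(what)
  n <- length(x)
  i0 <- max(1L, round(t0 * fs) + 1L - round(halfwin_s * fs))
  i1 <- min(n, round(t0 * fs) + 1L + round(halfwin_s * fs))
  if (i1 <= i0) return(NULL)
  seg <- x[i0:i1]
  ip <- if (what == "absmax") which.max(abs(seg)) else which.max(seg)
  i <- i0 + ip - 1L
  amp <- x[i]; tpk <- (i - 1L) / fs
  if (i > 1L && i < n) {  # parabolic interpolation around the vertex
    y1 <- x[i - 1L]; y2 <- x[i]; y3 <- x[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && abs(den) > 1e-12 && sign(den) == -sign(y2)) {
      d <- 0.5 * (y1 - y3) / den
      if (abs(d) <= 1) {
        tpk <- tpk + d / fs
        amp <- y2 - 0.25 * (y1 - y3) * d
      }
    }
  }
  list(time = tpk, amp = amp, index = i)
}

# Search-back rescue: the critically sampled detail branch is
# shift-variant, so a beat falling unfavourably on the decimation grid
# can drop well below the block threshold. Overlong RR gaps are
# re-scanned and the strongest in-gap energy peak is accepted when it
# clears a relaxed fraction of the typical beat energy.
rescue_gaps <- function(times, E, tcoef, rr_factor = 1.6, accept_frac = 0.12,
                        bias_s = 0) {
  if (length(times) < 3) return(times)
  for (pass in 1:12) {
    rr_med <- stats::median(diff(times))
    gaps <- which(diff(times) > rr_factor * rr_med)
    if (length(gaps) == 0) break
    peak_e <- stats::median(vapply(times, function(tt)
      max(E[abs(tcoef - tt) <= 0.1], 0), numeric(1)))
    added <- FALSE
    for (g in gaps) {
      in_gap <- which(tcoef > times[g] + 0.45 * rr_med &
                      tcoef < times[g + 1] - 0.45 * rr_med)
      if (length(in_gap) == 0) next
      i <- in_gap[which.max(E[in_gap])]
      if (E[i] >= accept_frac * peak_e) {
        # the trailing energy window peaks about L/2 samples after the
        # burst center; compensate before inserting
        times <- sort(c(times, tcoef[i] - bias_s))
        added <- TRUE
      }
    }
    if (!added) break
  }
  times
}

#' Detect beats and assemble per-beat eigenvalues
#'
#' Runs the full localization pipeline: band extraction for the QRS
#' (10--20 Hz) and T (3--8 Hz) bands, windowed-energy binarization with
#' the adaptive threshold, run-midpoint localization mapped back to
#' record time, and peak refinement on the baseline-corrected signal.
#' Each T peak is paired with the nearest preceding R peak inside the
#' configured search window; the beat energy integral Delta is the
#' trapezoidal integral of the corrected signal from the R onset (last
#' zero crossing within 80 ms before the R peak) to the rest time (first
#' time after the T peak where the signal stays near baseline for 40 ms).
#'
#' @param x ECG signal (mV).
#' @param fs Sampling frequency (Hz); the record must span >= 2 s.
#' @param config A [detector_config()].
#' @param spec A [wavelet_spec()].
#' @return Data frame of class \code{beat_features} with columns
#'   \code{r_time}, \code{r_amp}, \code{t_time}, \code{t_amp},
#'   \code{latency_s}, \code{delta}, \code{rr_s}; attribute
#'   \code{flatline} flags records with no detectable R activity.
#' @export
detect_beats <- function(x, fs, config = detector_config(),
                         spec = wavelet_spec()) {
  if (length(x) < 2 * fs) stop("record must span at least 2 seconds")
  xc <- baseline_correct(x, fs, config$baseline_window_s)
  empty <- data.frame(r_time = numeric(0), r_amp = numeric(0),
                      t_time = numeric(0), t_amp = numeric(0),
                      latency_s = numeric(0), delta = numeric(0),
                      rr_s = numeric(0))
  qrs <- localize_band(xc, fs, ecg_band(config$qrs_band[1], config$qrs_band[2], fs),
                       config, spec)
  if (qrs$flat || length(qrs$times) == 0L) {
    attr(empty, "flatline") <- TRUE
    class(empty) <- c("beat_features", class(empty))
    return(empty)
  }
  tcoef_q <- subband_time(qrs$series, seq_along(qrs$energy) - 1L)
  L_q <- max(1L, ceiling(config$r_duration_s / 2 * qrs$fs_sub))
  qrs$times <- rescue_gaps(qrs$times, qrs$energy, tcoef_q,
                           bias_s = L_q / 2 / qrs$fs_sub)
  twave <- localize_band(xc, fs, ecg_band(config$t_band[1], config$t_band[2], fs),
                         config, spec, mask_times = qrs$times)

  r_ref <- lapply(qrs$times, function(tt)
    refine_peak(xc, fs, tt, halfwin_s = 0.10, what = "absmax"))
  r_time <- vapply(r_ref, `[[`, numeric(1), "time")
  r_amp <- vapply(r_ref, `[[`, numeric(1), "amp")
  ord <- order(r_time)
  r_time <- r_time[ord]; r_amp <- r_amp[ord]
  # drop duplicate refinements closer than the refractory period
  if (length(r_time) > 1L) {
    keep <- c(TRUE, diff(r_time) >= config$refractory_s)
    r_time <- r_time[keep]; r_amp <- r_amp[keep]
  }
  nb <- length(r_time)
  rr <- c(diff(r_time), NA)
  rr_med <- stats::median(diff(r_time))
  t_time <- t_amp <- delta <- rep(NA_real_, nb)

  tcoef_t <- subband_time(twave$series, seq_along(twave$energy) - 1L)
  for (i in seq_len(nb)) {
    rr_i <- if (is.na(rr[i])) rr_med else rr[i]
    if (is.na(rr_i)) next
    rr_i <- min(rr_i, rr_med, na.rm = TRUE)  # a dropout must not widen the window
    # never let the search window run into the next QRS complex
    win_end <- r_time[i] + config$t_search[2] * rr_i
    if (i < nb) win_end <- min(win_end, r_time[i + 1L] - 0.15)
    win <- c(r_time[i] + config$t_search[1], win_end)
    if (diff(win) <= 0) next
    cand <- twave$times[twave$times > win[1] & twave$times <= win[2]]
    t0 <- if (length(cand) > 0L) {
      ce <- vapply(cand, function(ct)
        max(twave$energy[abs(tcoef_t - ct) <= 0.05], 0), numeric(1))
      cand[which.max(ce)]
    } else {
      # fall back to the strongest in-window T-band energy
      in_win <- which(tcoef_t > win[1] & tcoef_t <= win[2])
      if (length(in_win) == 0L) next
      tcoef_t[in_win[which.max(twave$energy[in_win])]]
    }
    # refine over the whole window: the subband grid is coarse (one
    # coefficient per 2^level samples) and a +-1-coefficient error can
    # exceed a fixed refinement radius
    tr <- refine_peak(xc, fs, mean(win), halfwin_s = diff(win) / 2,
                      what = "max")
    if (is.null(tr) || tr$time <= r_time[i] + config$t_search[1] ||
        tr$time > win[2] + 0.08) next
    t_time[i] <- tr$time; t_amp[i] <- tr$amp

    # R onset: where the corrected signal last departed baseline (stayed
    # within 2% of the R amplitude for 20 ms) before the R peak; falls
    # back to the last pre-peak zero crossing
    ir <- round(r_time[i] * fs) + 1L
    lo <- max(1L, ir - round(0.25 * fs))
    onset <- NA_integer_
    if (ir - lo > 2) {
      quiet <- abs(xc[lo:ir]) <= 0.02 * abs(r_amp[i])
      hold0 <- max(1L, round(0.02 * fs))
      runs <- rle(quiet)
      ends <- cumsum(runs$lengths)
      ok <- which(runs$values & runs$lengths >= hold0)
      if (length(ok) > 0) onset <- lo + ends[ok[length(ok)]] - 1L
    }
    if (is.na(onset)) {
      lo2 <- max(1L, ir - round(0.08 * fs))
      zc <- which(diff(sign(xc[lo2:ir])) != 0)
      onset <- if (length(zc) > 0) lo2 + zc[length(zc)] - 1L else lo2
    }
    # rest: first time after the T peak where the signal stays within
    # 10% of the T amplitude of baseline for 40 ms
    it <- tr$index
    hi_lim <- if (i < nb) round((r_time[i + 1L]) * fs) - round(0.02 * fs)
              else length(xc)
    hi_lim <- min(hi_lim, length(xc))
    thresh <- 0.1 * abs(tr$amp)
    hold <- max(1L, round(0.04 * fs))
    rest <- hi_lim
    if (it < hi_lim) {
      below <- abs(xc[it:hi_lim]) < thresh
      runs <- rle(below)
      pos <- cumsum(runs$lengths) - runs$lengths + 1L
      ok <- which(runs$values & runs$lengths >= hold)
      if (length(ok) > 0) rest <- min(it + pos[ok[1]] - 1L + hold - 1L, hi_lim)
    }
    if (rest > onset + 1L) {
      tt <- (onset:rest - 1L) / fs
      delta[i] <- pracma::trapz(tt, xc[onset:rest])
    }
  }
  out <- data.frame(r_time = r_time, r_amp = r_amp, t_time = t_time,
                    t_amp = t_amp, latency_s = t_time - r_time,
                    delta = delta, rr_s = rr)
  attr(out, "flatline") <- FALSE
  class(out) <- c("beat_features", class(out))
  out
}
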