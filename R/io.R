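# Record I/O (signal CSV and WFDB format 212) and the single-pass
# analysis pipeline.

#' Read an ECG record
#'
#' CSV records carry the sampling frequency as a \code{"# fs_hz="}
#' comment line followed by \code{time_s,voltage_mv} rows; WFDB records
#' are a \code{.hea} text header plus a format-212 \code{.dat} file.
#'
#' @param path File path (for WFDB, the \code{.hea} file or the record
#'   name without extension).
#' @param format \code{"csv"} or \code{"wfdb"}; guessed from the
#'   extension when missing.
#' @return Object of class \code{ecg_record}: \code{signal} (mV),
#'   \code{fs}, \code{lead}, \code{source}.
#' @export
read_record <- function(path, format = c("guess", "csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.hea$", path) || !grepl("\\.csv$", path)) "wfdb" else "csv"
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 5L)
  m <- regmatches(head_lines, regexec("#\\s*fs_hz=([0-9.]+)", head_lines))
  fs <- NA_real_
  for (mm in m) if (length(mm) == 2) fs <- as.numeric(mm[2])
  if (is.na(fs))
    stop("CSV record missing '# fs_hz=' metadata; refusing to guess a sampling rate")
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "voltage_mv") %in% names(d)))
    stop("CSV record must have columns time_s, voltage_mv")
  if (any(diff(d$time_s) <= 0)) stop("non-monotone time column")
  if (any(!is.finite(d$voltage_mv))) stop("non-finite voltages in record")
  structure(list(signal = d$voltage_mv, fs = fs, lead = "I",
                 source = c(path = path, format = "csv")),
            class = "ecg_record")
}

#' Write an ECG record
#'
#' @param signal Signal in mV.
#' @param fs Sampling frequency (Hz).
#' @param path Output path (for WFDB, the record name; \code{.hea} and
#'   \code{.dat} are created).
#' @param format \code{"csv"} or \code{"wfdb"}.
#' @param adc_gain WFDB quantization gain in units/mV (default 200).
#' @return The path, invisibly.
#' @export
write_record <- function(signal, fs, path, format = c("csv", "wfdb"),
                         adc_gain = 200) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs_hz=%g", fs), con)
    utils::write.csv(data.frame(time_s = (seq_along(signal) - 1) / fs,
                                voltage_mv = signal),
                     con, row.names = FALSE)
  } else {
    write_record_wfdb(signal, fs, path, adc_gain)
  }
  invisible(path)
}

# WFDB format 212: two 12-bit two's-complement samples packed into 3
# bytes. Single-signal records pack consecutive samples of the one lead.
write_record_wfdb <- function(signal, fs, record, adc_gain = 200) {
  adc <- as.integer(round(signal * adc_gain))
  if (any(adc < -2048 | adc > 2047))
    stop("signal exceeds the 12-bit range at this adc_gain")
  if (length(adc) %% 2 == 1L) adc <- c(adc, adc[length(adc)])
  u <- ifelse(adc < 0, adc + 4096L, adc)      # 12-bit two's complement
  s1 <- u[seq(1, length(u), by = 2)]
  s2 <- u[seq(2, length(u), by = 2)]
  b1 <- s1 %% 256L
  b2 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
  b3 <- s2 %% 256L
  bytes <- as.raw(rbind(b1, b2, b3))
  dat <- paste0(record, ".dat")
  hea <- paste0(record, ".hea")
  writeBin(bytes, dat)
  base <- basename(record)
  writeLines(c(sprintf("%s 1 %g %d", base, fs, length(adc)),
               sprintf("%s.dat 212 %d 11 0 %d 0 0 MLII", base, adc_gain,
                       adc[1])),
             hea)
  invisible(record)
}

read_record_wfdb <- function(path) {
  record <- sub("\\.hea$", "", path)
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop("no such WFDB header: ", hea)
  lines <- readLines(hea)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("malformed WFDB header line: ", lines[1])
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  if (is.na(fs) || fs <= 0) stop("malformed WFDB header: bad sampling frequency")
  if (nsig != 1L) stop("only single-signal WFDB records are supported")
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (sig[2] != "212")
    stop("unsupported WFDB format code: ", sig[2], " (only 212)")
  adc_gain <- as.numeric(sig[3])
  if (is.na(adc_gain) || adc_gain <= 0) adc_gain <- 200
  dat <- paste0(record, ".dat")
  bytes <- as.integer(readBin(dat, "raw", n = file.size(dat)))
  ntrip <- length(bytes) %/% 3L
  b1 <- bytes[3 * seq_len(ntrip) - 2]
  b2 <- bytes[3 * seq_len(ntrip) - 1]
  b3 <- bytes[3 * seq_len(ntrip)]
  s1 <- b1 + 256L * (b2 %% 16L)
  s2 <- b3 + 256L * (b2 %/% 16L)
  u <- as.vector(rbind(s1, s2))
  adc <- ifelse(u > 2047L, u - 4096L, u)
  adc <- adc[seq_len(min(nsamp, length(adc)))]
  lead <- if (length(sig) >= 9) sig[length(sig)] else "I"
  structure(list(signal = adc / adc_gain, fs = fs, lead = lead,
                 source = c(path = hea, format = "wfdb")),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s), lead %s\n",
              length(x$signal), x$fs, length(x$signal) / x$fs, x$lead))
  invisible(x)
}

#' Write / read a beat-features table
#'
#' @param beats A \code{beat_features} data frame from [detect_beats()].
#' @param path CSV path.
#' @return For reading, the data frame.
#' @export
write_beats_csv <- function(beats, path) {
  utils::write.csv(as.data.frame(beats), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  utils::read.csv(path)
}

#' Run the full analysis pipeline on a record
#'
#' Chains beat detection (QRS and T subband extraction share the same
#' decomposition scheme: an approximation cascade differing only in the
#' level of the final detail branch), the inverse AP fit, and
#' classification, recording per-stage timings.
#'
#' @param record An \code{ecg_record} (or list with \code{signal},
#'   \code{fs}).
#' @param config A [detector_config()].
#' @param templates Templates from [build_default_templates()].
#' @param spec A [wavelet_spec()].
#' @return Object of class \code{ecg_report}: \code{beats}, \code{fit}
#'   (NULL if too few complete beats), \code{label}, \code{flags},
#'   \code{timings} (seconds per stage).
#' @export
run_pipeline <- function(record, config = detector_config(),
                         templates = build_default_templates(),
                         spec = wavelet_spec()) {
  t0 <- proc.time()[["elapsed"]]
  beats <- detect_beats(record$signal, record$fs, config, spec)
  t1 <- proc.time()[["elapsed"]]
  fit <- NULL; label <- NA_character_; flags <- NULL
  ok <- sum(stats::complete.cases(beats[, c("t_amp", "latency_s", "delta")]))
  if (ok >= 2) {
    fit <- fit_ap(beats, templates)
    cls <- classify(fit, flags = TRUE)
    label <- cls$label; flags <- cls$advisory
  }
  t2 <- proc.time()[["elapsed"]]
  structure(list(beats = beats, fit = fit, label = label, flags = flags,
                 flatline = isTRUE(attr(beats, "flatline")),
                 timings = c(detect = t1 - t0, fit = t2 - t1)),
            class = "ecg_report")
}

#' @export
print.ecg_report <- function(x, ...) {
  cat(sprintf("<ecg_report> %d beats%s\n", nrow(x$beats),
              if (x$flatline) " (flat-line record)" else ""))
  if (!is.null(x$fit))
    cat(sprintf("  fit: k %.3f h_R %.3f h_L %.3f -> %s\n",
                x$fit$k, x$fit$h_R, x$fit$h_L, x$label))
  invisible(x)
}

#' Serialize a fit/classification result to JSON
#'
#' @param fit An \code{ap_fit}.
#' @param path Optional output path; when NULL the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  cls <- classify(fit, flags = TRUE)
  out <- list(k = fit$k, h_R = fit$h_R, h_L = fit$h_L,
              label = cls$label, advisory_flags = as.list(cls$advisory),
              rounds_used = fit$rounds_used, converged = fit$converged,
              residual_norm = fit$residual_norm)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
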