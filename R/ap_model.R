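# Epicardial action-potential templates and the two-parameter scaling
# forward model F(t; k, h) = h * C(k t) consumed by the inverse fit.

#' Construct an action-potential template
#'
#' A template is a sampled transmembrane-potential waveform on a uniform
#' time grid, normalized so the resting potential is 0 and the upstroke
#' peak is 1 (the physical mV scale cancels in the fitted amplitude
#' ratios). Invariants enforced: value 0 at time 0, return to within 0.02
#' of rest at the end, a single global maximum inside the first 5% of the
#' duration (fast upstroke), and values within \[-0.1, 1\].
#'
#' @param side \code{"left"} or \code{"right"} epicardial wall.
#' @param grid Strictly increasing time samples in seconds starting at 0.
#' @param values Potential at each grid point (normalized units).
#' @return Object of class \code{ap_template}.
#' @export
ap_template <- function(side, grid, values) {
  side <- match.arg(side, c("left", "right"))
  stopifnot(length(grid) == length(values), length(grid) >= 3)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (abs(grid[1]) > 1e-12) stop("grid must start at time 0")
  if (abs(values[1]) > 1e-9) stop("template must start at rest (value 0)")
  dur <- grid[length(grid)]
  if (values[length(values)] > 0.02)
    stop("template must return to rest: final value exceeds 0.02")
  if (any(values > 1 + 1e-9) || any(values < -0.1 - 1e-9))
    stop("template values outside [-0.1, 1]")
  imax <- which.max(values)
  if (grid[imax] > 0.05 * dur)
    stop("upstroke peak must occur within the first 5% of the duration")
  structure(list(side = side, grid = grid, values = values, duration = dur),
            class = "ap_template")
}

#' @export
print.ap_template <- function(x, ...) {
  cat(sprintf("<ap_template> %s epicardium, %.0f ms, %d samples, peak %.3f\n",
              x$side, 1000 * x$duration, length(x$grid), max(x$values)))
  invisible(x)
}

# Analytic epicardial AP phases: logistic upstroke, Gaussian phase-1 notch,
# logistic repolarization. Parameters control notch depth and plateau
# duration, which is where the left and right walls differ.
ap_waveform <- function(t, t_up = 0.004, s_up = 0.0012,
                        notch_depth = 0.15, t_notch = 0.035, w_notch = 0.010,
                        t_rep = 0.23, s_rep = 0.011, droop = 0.12) {
  dur <- max(t)
  shape <- function(tt) {
    up <- 1 / (1 + exp(-(tt - t_up) / s_up))
    notch <- 1 - notch_depth * exp(-((tt - t_notch) / w_notch)^2)
    rep_ <- 1 / (1 + exp((tt - t_rep) / s_rep))
    up * notch * rep_ * (1 - droop * tt / dur)  # slight phase-2 decay
  }
  v <- shape(t) - shape(0)   # pin the resting value exactly to 0
  v / max(v)                 # upstroke peak exactly 1
}

#' Packaged standard left/right epicardial templates
#'
#' Analytic templates built from logistic rise/decay terms reproducing the
#' canonical epicardial action-potential phases (fast upstroke, phase-1
#' notch, plateau, repolarization), sampled at 1 kHz over 0.30 s. The
#' right-wall template has a shallower notch and a longer plateau than the
#' left, so that the surface repolarization wave
#' \code{h_R C_R(k t) - h_L C_L(k t)} is a distinct positive deflection at
#' unit parameters and the unit-scale integrals differ
#' (\code{Phi_R / Phi_L} about 1.4), which is what identifies \code{k}
#' from the beat energy integral.
#'
#' @param duration Template support in seconds (default 0.30, a typical
#'   epicardial APD90).
#' @param fs_template Template sampling rate in Hz (default 1000).
#' @return List with elements \code{left} and \code{right}.
#' @export
#' @examples
#' tpl <- build_default_templates()
#' tpl$right
build_default_templates <- function(duration = 0.30, fs_template = 1000) {
  grid <- seq(0, duration, by = 1 / fs_template)
  sc <- duration / 0.30   # stretch the phase layout with the duration
  right <- ap_waveform(grid, t_up = 0.004 * sc, notch_depth = 0.10,
                       t_notch = 0.035 * sc, t_rep = 0.250 * sc,
                       s_rep = 0.010 * sc)
  left <- ap_waveform(grid, t_up = 0.004 * sc, notch_depth = 0.25,
                      t_notch = 0.035 * sc, t_rep = 0.185 * sc,
                      s_rep = 0.012 * sc)
  list(left = ap_template("left", grid, left),
       right = ap_template("right", grid, right))
}

#' Scaled action-potential forward model
#'
#' Evaluates \code{h * C(k t)}: the template compressed in time by
#' \code{k} and scaled in amplitude by \code{h}, with linear interpolation
#' on the template grid and 0 beyond its support.
#'
#' @param template An [ap_template()].
#' @param t Time(s) in seconds, >= 0 (vectorized).
#' @param k Time-scale factor > 0 (k < 1 stretches the waveform).
#' @param h Amplitude factor > 0.
#' @return Potential in template units.
#' @export
ap_forward <- function(template, t, k = 1, h = 1) {
  if (k <= 0 || h <= 0) stop("k and h must be positive")
  tau <- k * t
  out <- numeric(length(t))
  inside <- tau >= 0 & tau <= template$duration
  if (any(inside))
    out[inside] <- stats::approx(template$grid, template$values,
                                 xout = tau[inside], rule = 2)$y
  h * out
}

#' Time integral of the scaled template
#'
#' Trapezoidal integral of \code{C(k t)} over its support; by change of
#' variables this equals the unit-scale integral divided by \code{k}.
#'
#' @param template An [ap_template()].
#' @param k Time-scale factor > 0.
#' @return Integral in potential x seconds.
#' @export
template_integral <- function(template, k = 1) {
  if (k <= 0) stop("k must be positive")
  pracma::trapz(template$grid, template$values) / k
}

#' Read or write a template as a two-column CSV
#'
#' Format: a header comment line \code{"# side=left"} (or right) followed
#' by \code{time_s,value} rows.
#'
#' @param path File path.
#' @param template For writing, an [ap_template()].
#' @return For reading, an [ap_template()].
#' @export
read_template_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("#\\s*side=(left|right)", first))[[1]]
  if (length(m) < 2) stop("template file missing '# side=' header")
  d <- utils::read.csv(path, comment.char = "#")
  ap_template(m[2], d$time_s, d$value)
}

#' @rdname read_template_csv
#' @export
write_template_csv <- function(template, path) {
  writeLines(sprintf("# side=%s", template$side), path)
  suppressWarnings(utils::write.table(
    data.frame(time_s = template$grid, value = template$values),
    path, sep = ",", row.names = FALSE, col.names = TRUE, append = TRUE))
  invisible(path)
}
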