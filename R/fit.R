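# Inverse fit of the AP scaling parameters (k, h_R, h_L) to per-beat
# features, and the k-threshold disease classifier.

#' Template regressors at the measured T latencies
#'
#' Evaluates the unit-amplitude right and left templates at the
#' time-compressed latencies \code{k * (t_T - t_R)}: the design columns of
#' the T-amplitude regression \code{T = h_R Y1 - h_L Y2}. Latencies past
#' the template support yield 0 (with a warning), since the scaled AP has
#' already returned to rest there.
#'
#' @param templates List with \code{left}/\code{right} [ap_template()]s.
#' @param latencies Per-beat \code{t_T - t_R} in seconds.
#' @param k Current time-scale iterate (> 0); 1 on the first pass.
#' @return List with numeric vectors \code{Y1} (right), \code{Y2} (left).
#' @export
regressors <- function(templates, latencies, k = 1) {
  if (k <= 0) stop("k must be positive")
  out_of_support <- k * latencies > templates$right$duration
  if (any(out_of_support))
    warning(sprintf("%d latencies beyond the template support at k=%.3g; regressors set to 0",
                    sum(out_of_support), k))
  list(Y1 = ap_forward(templates$right, latencies, k = k, h = 1),
       Y2 = ap_forward(templates$left, latencies, k = k, h = 1))
}

#' Least-squares amplitude factors from T amplitudes
#'
#' Minimizes \code{sum((T_i - (h_R Y1_i - h_L Y2_i))^2)} over
#' \code{(h_R, h_L)} via the centered cross-product sums
#' \code{s11, s22, s12, s1y, s2y} (equivalently, the slope estimates of an
#' ordinary two-regressor linear model with intercept; the intercept
#' absorbs any constant lead offset in the measured amplitudes).
#'
#' @param T Measured per-beat T-wave amplitudes.
#' @param Y1,Y2 Regressors from [regressors()].
#' @return List with \code{h_R} and \code{h_L}.
#' @export
solve_h <- function(T, Y1, Y2) {
  n <- length(T)
  stopifnot(length(Y1) == n, length(Y2) == n)
  if (n < 2) stop("at least 2 beats required")
  s11 <- sum(Y1^2) - sum(Y1)^2 / n
  s22 <- sum(Y2^2) - sum(Y2)^2 / n
  s12 <- sum(Y1 * Y2) - sum(Y1) * sum(Y2) / n
  s1y <- sum(Y1 * T) - sum(Y1) * sum(T) / n
  s2y <- sum(Y2 * T) - sum(Y2) * sum(T) / n
  det <- s11 * s22 - s12^2
  if (!is.finite(det) || abs(det) <= 1e-12 * max(s11 * s22, 1e-300))
    stop("singular design: T-latency regressors are collinear or constant")
  list(h_R = (s1y * s22 - s2y * s12) / det,
       h_L = -(s11 * s2y - s12 * s1y) / det)
}

#' Least-squares time-scale factor from the beat energy integrals
#'
#' Fits the proportionality \code{Delta_i = k * u} with
#' \code{u = h_R Phi1 - h_L Phi2}, giving the slope
#' \code{k = mean(Delta) / u}.
#'
#' @param deltas Per-beat energy integrals.
#' @param h_R,h_L Current amplitude factors.
#' @param Phi1,Phi2 Template time integrals (right, left) at the scale the
#'   caller works in.
#' @return The least-squares slope.
#' @export
solve_k <- function(deltas, h_R, h_L, Phi1, Phi2) {
  u <- h_R * Phi1 - h_L * Phi2
  if (!is.finite(u) || abs(u) <= 1e-12)
    stop("degenerate amplitude balance: h_R*Phi1 - h_L*Phi2 is ~0, k not identifiable")
  mean(deltas) / u
}

# Amplitude factors given a fixed time scale: weighted least squares on
# the simultaneous system
#   T_i     = h_R C_R(k lat_i) - h_L C_L(k lat_i)
#   Delta_i = (h_R Phi_R - h_L Phi_L) / k
# The Delta rows supply the (Phi_R, -Phi_L) direction, which keeps the
# system full-rank even when the latencies (and hence the T regressors)
# barely vary across beats. Each block is normalized by the mean square
# of its observable so the two equations carry comparable weight.
solve_h_joint <- function(Tm, Y1, Y2, dl, Phi1, Phi2, k) {
  wT <- 1 / sqrt(max(mean(Tm^2), 1e-300))
  wD <- 1 / sqrt(max(mean(dl^2), 1e-300))
  X <- rbind(cbind(wT * Y1, -wT * Y2),
             cbind(rep(wD * Phi1 / k, length(dl)),
                   rep(-wD * Phi2 / k, length(dl))))
  y <- c(wT * Tm, wD * dl)
  beta <- stats::.lm.fit(X, y)$coefficients
  list(h_R = beta[1], h_L = beta[2],
       sse_t = sum((Tm - (beta[1] * Y1 - beta[2] * Y2))^2) * wT^2,
       sse_d = sum((dl - (beta[1] * Phi1 - beta[2] * Phi2) / k)^2) * wD^2)
}

#' Fit the AP scaling parameters to per-beat features
#'
#' Fits the simultaneous-equations model
#' \code{T_i = h_R C_R(k lat_i) - h_L C_L(k lat_i)},
#' \code{Delta_i = (h_R Phi_R - h_L Phi_L) / k} by iterated least
#' squares. Because time compression by \code{k} divides the AP time
#' integral by \code{k}, the per-beat integral varies as \code{1/k}; the
#' T-amplitude equation then separates \code{h_R} from \code{h_L}.
#'
#' The time scale is profiled first: for each candidate \code{k} the
#' amplitude pair is solved by linear least squares over both equations
#' jointly, and \code{k} minimizes the profiled residual over a bracket
#' derived from the measured latencies (the unit-parameter
#' repolarization peak sits at \code{tau*} in template time, so
#' \code{tau*/median(latency)} locates the scale to first order).
#' Alternating rounds then polish the triple -- amplitude solve at the
#' current \code{k}, time-scale update from the energy-integral slope
#' ([solve_k()]) -- until the largest relative parameter change drops
#' below \code{tol} or \code{max_rounds} is reached.
#'
#' @param beats Data frame of beat features with columns \code{t_amp},
#'   \code{latency_s}, \code{delta} (as produced by [detect_beats()] or
#'   [generate_ap_features()]); rows with missing values are dropped.
#' @param templates Templates from [build_default_templates()].
#' @param tol Relative convergence tolerance (default 1e-6).
#' @param max_rounds Maximum polish rounds (default 50).
#' @return Object of class \code{ap_fit}: \code{k}, \code{h_R},
#'   \code{h_L}, \code{rounds_used}, \code{converged},
#'   \code{residual_norm}, \code{history} (per-round estimates),
#'   \code{n_beats}.
#' @export
fit_ap <- function(beats, templates = build_default_templates(),
                   tol = 1e-6, max_rounds = 50) {
  beats <- beats[stats::complete.cases(beats[, c("t_amp", "latency_s", "delta")]), ]
  n <- nrow(beats)
  if (n < 2) stop("at least 2 beats with complete features are required")
  Tm <- beats$t_amp; lat <- beats$latency_s; dl <- beats$delta
  Phi1 <- template_integral(templates$right, 1)
  Phi2 <- template_integral(templates$left, 1)
  dur <- templates$right$duration

  dref <- templates$right$values - templates$left$values
  tau_star <- templates$right$grid[which.max(dref)]
  k_seed <- tau_star / stats::median(lat)

  objective <- function(k) {
    Y <- suppressWarnings(regressors(templates, lat, k))
    if (all(Y$Y1 == 0 & Y$Y2 == 0)) return(list(obj = Inf))
    h <- solve_h_joint(Tm, Y$Y1, Y$Y2, dl, Phi1, Phi2, k)
    # amplitude factors are physical scalings: only positive solutions
    # are admissible iterates
    if (!is.finite(h$h_R) || !is.finite(h$h_L) || h$h_R <= 0 || h$h_L <= 0)
      return(list(obj = Inf))
    c(h, obj = h$sse_t + h$sse_d)
  }
  k_lo <- max(0.2, 0.4 * k_seed)
  k_hi <- min(2.5 * k_seed, 0.98 * dur / stats::median(lat))
  grid <- exp(seq(log(k_lo), log(k_hi), length.out = 80))
  obj <- vapply(grid, function(k) objective(k)$obj, numeric(1))
  if (all(!is.finite(obj)))
    stop("no admissible time scale: features inconsistent with the templates")
  i <- which.min(obj)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  k <- stats::optimize(function(k) objective(k)$obj,
                       interval = bracket, tol = 1e-9)$minimum
  h <- objective(k)
  if (!is.finite(h$obj)) { k <- grid[i]; h <- objective(k) }
  h_R <- h$h_R; h_L <- h$h_L

  # One alternation round as a scalar map on k: amplitude solve at the
  # current scale, then the time scale from the energy-integral slope
  # (Delta = (h_R Phi1 - h_L Phi2)/k inverts the fitted slope).
  gmap <- function(kc) {
    Y <- suppressWarnings(regressors(templates, lat, kc))
    h <- solve_h_joint(Tm, Y$Y1, Y$Y2, dl, Phi1, Phi2, kc)
    if (!is.finite(h$h_R) || !is.finite(h$h_L) || h$h_R <= 0 || h$h_L <= 0)
      return(kc)
    kn <- try(1 / solve_k(dl, h$h_R, h$h_L, Phi1, Phi2), silent = TRUE)
    if (inherits(kn, "try-error") || !is.finite(kn) ||
        kn <= 0 || kn > 1.1 * k_hi) kc else kn
  }
  hist <- data.frame(round = integer(), k = double(),
                     h_R = double(), h_L = double())
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    prev <- c(k, h_R, h_L)
    # Steffensen-accelerated fixed-point step on the alternation map
    k1 <- gmap(k); k2 <- gmap(k1)
    denom <- k2 - 2 * k1 + k
    k_acc <- if (is.finite(denom) && abs(denom) > 1e-14)
      k - (k1 - k)^2 / denom else k2
    k <- if (is.finite(k_acc) && k_acc > 0 && k_acc < 1.1 * k_hi) k_acc else k2
    Y <- suppressWarnings(regressors(templates, lat, k))
    h <- solve_h_joint(Tm, Y$Y1, Y$Y2, dl, Phi1, Phi2, k)
    if (is.finite(h$h_R) && is.finite(h$h_L) && h$h_R > 0 && h$h_L > 0) {
      h_R <- h$h_R; h_L <- h$h_L
    }
    hist <- rbind(hist, data.frame(round = round, k = k, h_R = h_R, h_L = h_L))
    if (max(abs(c(k, h_R, h_L) - prev) / pmax(abs(prev), 1e-12)) < tol) {
      converged <- TRUE
      break
    }
  }
  Yf <- suppressWarnings(regressors(templates, lat, k))
  resid <- Tm - (h_R * Yf$Y1 - h_L * Yf$Y2)
  structure(list(k = k, h_R = h_R, h_L = h_L,
                 rounds_used = nrow(hist), converged = converged,
                 residual_norm = sqrt(sum(resid^2)), history = hist,
                 n_beats = n),
            class = "ap_fit")
}

#' @export
print.ap_fit <- function(x, ...) {
  cat(sprintf("<ap_fit> k = %.3f, h_R = %.3f, h_L = %.3f (%d beats, %d rounds%s, residual %.3g)\n",
              x$k, x$h_R, x$h_L, x$n_beats, x$rounds_used,
              if (x$converged) "" else ", NOT converged", x$residual_norm))
  cat("label:", classify(x), "\n")
  invisible(x)
}

#' Classify cardiac state from the fitted scaling parameters
#'
#' The primary decision uses the time-scale factor alone:
#' myocardial ischemia when \code{k < k_low} (default 0.9), heart failure
#' when \code{k > k_high} (default 1.2), otherwise normal. Reduced
#' amplitude factors (\code{h_R < h_R_flag}, \code{h_L < h_L_flag}) are
#' reported as advisory flags, not used in the decision.
#'
#' @param params An \code{ap_fit} or any list with \code{k}, \code{h_R},
#'   \code{h_L}.
#' @param k_low,k_high Decision thresholds on k.
#' @param h_R_flag,h_L_flag Advisory amplitude thresholds.
#' @param flags If TRUE return a list with the label and advisory flags.
#' @return The label (character), or a list when \code{flags = TRUE}.
#' @export
#' @examples
#' classify(list(k = 0.71, h_R = 0.97, h_L = 0.95))  # myocardial_ischemia
#' classify(list(k = 1.79, h_R = 0.81, h_L = 0.83))  # heart_failure
classify <- function(params, k_low = 0.9, k_high = 1.2,
                     h_R_flag = 0.95, h_L_flag = 0.96, flags = FALSE) {
  stopifnot(is.finite(params$k))
  label <- if (params$k < k_low) "myocardial_ischemia"
           else if (params$k > k_high) "heart_failure"
           else "normal"
  if (!flags) return(label)
  list(label = label,
       advisory = c(low_h_R = isTRUE(params$h_R < h_R_flag),
                    low_h_L = isTRUE(params$h_L < h_L_flag)))
}

#' Per-class accuracy of the classifier on labelled parameter rows
#'
#' Applies [classify()] to each \code{(k, h_R, h_L)} row and compares
#' against the recorded clinical label.
#'
#' @param rows Data frame with columns \code{k}, \code{h_R}, \code{h_L},
#'   \code{clinical} (values among the three labels).
#' @param ... Threshold arguments passed to [classify()].
#' @return Data frame with one row per class: \code{n}, \code{correct},
#'   \code{accuracy_pct} (one decimal).
#' @export
classify_table <- function(rows, ...) {
  stopifnot(nrow(rows) > 0)
  pred <- vapply(seq_len(nrow(rows)), function(i)
    classify(list(k = rows$k[i], h_R = rows$h_R[i], h_L = rows$h_L[i]), ...),
    character(1))
  out <- do.call(rbind, lapply(split(seq_len(nrow(rows)), rows$clinical),
    function(idx) {
      data.frame(clinical = rows$clinical[idx[1]],
                 n = length(idx),
                 correct = sum(pred[idx] == rows$clinical[idx]))
    }))
  out$accuracy_pct <- round(100 * out$correct / out$n, 1)
  rownames(out) <- NULL
  out
}
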