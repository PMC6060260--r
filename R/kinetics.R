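# Transient kinetics: peak, time to peak, initial slope, exponential decay
# (single vs double, fast-tau convention), 2-s AUC, and stimulus-response
# curve fits (4-parameter logistic; linear sub-range).

#' Peak response and time to peak
#'
#' @param trace A normalized [trace()].
#' @param stim_onset_s Onset on the trace's time base (normalized traces:
#'   0).
#' @return `list(peak =, time_to_peak_s =)`: `max post-onset F/F0 - 1` and
#'   its time measured from onset (ties resolved to the earliest sample).
#' @export
measure_peak <- function(trace, stim_onset_s = 0) {
  post <- trace$times_s > stim_onset_s
  if (!any(post)) stop("protocol error: no post-onset samples")
  v <- trace$values[post]
  t <- trace$times_s[post]
  i <- which.max(v)                       # first maximum on ties
  list(peak = v[i] - 1, time_to_peak_s = t[i] - stim_onset_s)
}

#' Initial slope of the response
#'
#' Least-squares slope of F/F0 versus time over the first `n_points`
#' post-onset samples.
#'
#' @param trace A normalized [trace()].
#' @param stim_onset_s Onset on the trace's time base.
#' @param n_points Number of post-onset samples used (default 3, >= 2).
#' @return Slope in F/F0 per second.
#' @export
measure_initial_slope <- function(trace, stim_onset_s = 0, n_points = 3) {
  stopifnot(n_points >= 2)
  post <- which(trace$times_s > stim_onset_s)
  if (length(post) < n_points) {
    stop("protocol error: fewer than n_points post-onset samples")
  }
  idx <- post[seq_len(n_points)]
  t <- trace$times_s[idx]; y <- trace$values[idx]
  unname(stats::lm.fit(cbind(1, t), y)$coefficients[2])
}

# Corrected Akaike information criterion for a least-squares fit with k
# estimated parameters (+1 for the error variance). The per-point variance
# is floored so that numerically perfect fits do not produce unbounded
# likelihoods.
.aicc <- function(rss, n, k, scale) {
  s2 <- max(rss / n, (1e-8 * scale)^2)
  kk <- k + 1
  n * log(s2) + 2 * kk + 2 * kk * (kk + 1) / max(n - kk - 1, 1)
}

#' Fit the post-peak fluorescence decay
#'
#' Fits `y(t) = 1 + sum_i a_i exp(-(t - t_peak)/tau_i)` with one and with
#' two components (multi-start nonlinear least squares) and selects between
#' them by small-sample-corrected AIC. The fast phase of decay is the
#' single tau or the faster of the two.
#'
#' @param trace A normalized [trace()].
#' @param peak_time_s Peak time on the trace's time base; the fit uses
#'   samples at `t >= peak_time_s` (>= 6 required).
#' @return `list(model =, amps =, taus_s =, fast_tau_s =,
#'   selection_score =)`; `selection_score` is `AICc(single) -
#'   AICc(double)` (positive favors the double model).
#' @export
fit_decay <- function(trace, peak_time_s) {
  sel <- trace$times_s >= peak_time_s
  if (sum(sel) < 6) stop("protocol error: need >= 6 post-peak samples")
  s <- trace$times_s[sel] - peak_time_s
  y <- trace$values[sel] - 1
  scale <- max(abs(y))
  f1 <- .fit_exp_sum(s, y, 1, offset = FALSE)
  f2 <- .fit_exp_sum(s, y, 2, offset = FALSE)
  if (is.null(f1) && is.null(f2)) {
    stop("fit failure: decay fit did not converge (residual diagnostics ",
         "unavailable from any start)")
  }
  n <- length(y)
  a1c <- if (!is.null(f1)) .aicc(f1$rss, n, 2, scale) else Inf
  a2c <- if (!is.null(f2)) .aicc(f2$rss, n, 4, scale) else Inf
  score <- a1c - a2c
  pick_single <- a1c <= a2c
  if (!pick_single) {
    # identifiability guard: a component with near-equal tau, negligible
    # amplitude, or a time constant below ~3 sampling intervals (too few
    # samples within one tau to characterize a decay) is not a
    # distinguishable double process
    p2 <- as.list(stats::coef(f2$fit))
    amps2 <- c(p2$A1, p2$A2); taus2 <- c(p2$T1, p2$T2)
    dt_med <- stats::median(diff(s))
    if (!is.null(f1) &&
        (max(taus2) / min(taus2) < 1.5 ||
         min(amps2) / sum(amps2) < 0.05 ||
         min(taus2) < 3 * dt_med)) {
      pick_single <- TRUE
    }
  }
  if (pick_single) {
    p <- as.list(stats::coef(f1$fit))
    list(model = "single", amps = p$A1, taus_s = p$T1, fast_tau_s = p$T1,
         selection_score = score)
  } else {
    p <- as.list(stats::coef(f2$fit))
    taus <- c(p$T1, p$T2); amps <- c(p$A1, p$A2)
    ord <- order(taus)
    list(model = "double", amps = amps[ord], taus_s = taus[ord],
         fast_tau_s = min(taus), selection_score = score)
  }
}

#' Area under the curve after stimulation
#'
#' Trapezoidal integral of `F/F0 - 1` over `[onset, onset + duration]`,
#' with linear interpolation at the window endpoints.
#'
#' @param trace A normalized [trace()].
#' @param stim_onset_s Window start on the trace's time base.
#' @param duration_s Window length, seconds (default 2, the standard
#'   post-stimulus integration window).
#' @return AUC in F/F0 * s.
#' @export
area_under_curve <- function(trace, stim_onset_s = 0, duration_s = 2) {
  t0 <- stim_onset_s; t1 <- stim_onset_s + duration_s
  if (min(trace$times_s) > t0 + 1e-9 || max(trace$times_s) < t1 - 1e-9) {
    stop("protocol error: integration window exceeds the trace")
  }
  inner <- trace$times_s[trace$times_s > t0 & trace$times_s < t1]
  grid <- sort(unique(c(t0, inner, t1)))
  vals <- stats::approx(trace$times_s, trace$values, xout = grid)$y
  pracma::trapz(grid, vals - 1)
}

#' Kinetic summary of one normalized trace
#'
#' @param trace A normalized [trace()].
#' @param stim_onset_s Onset on the trace's time base.
#' @param auc_duration_s AUC window, seconds.
#' @param slope_points Samples used for the initial slope.
#' @param fit_decay_model Fit the post-peak decay (set `FALSE` to skip the
#'   nonlinear fit for speed).
#' @return One-row `data.frame`: `roi_id, peak, time_to_peak_s,
#'   initial_slope_per_s, fast_tau_s, decay_model, auc`.
#' @export
kinetics_summary <- function(trace, stim_onset_s = 0, auc_duration_s = 2,
                             slope_points = 3, fit_decay_model = TRUE) {
  pk <- measure_peak(trace, stim_onset_s)
  slope <- measure_initial_slope(trace, stim_onset_s, slope_points)
  auc <- area_under_curve(trace, stim_onset_s, auc_duration_s)
  fast_tau <- NA_real_; model <- NA_character_
  if (fit_decay_model) {
    fit <- try(fit_decay(trace, stim_onset_s + pk$time_to_peak_s),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      fast_tau <- fit$fast_tau_s; model <- fit$model
    }
  }
  data.frame(roi_id = trace$id, peak = pk$peak,
             time_to_peak_s = pk$time_to_peak_s,
             initial_slope_per_s = slope, fast_tau_s = fast_tau,
             decay_model = model, auc = auc, stringsAsFactors = FALSE)
}

#' Fit a 4-parameter logistic stimulus-response curve
#'
#' `y = base + (top - base) / (1 + exp((x50 - x) / rate))`, by multi-start
#' nonlinear least squares (starts spread over the x quantiles).
#'
#' @param x Abscissa values (e.g. stimulus intensity, volts); >= 5 points.
#' @param y Responses.
#' @return `list(base =, top =, x50 =, rate =, degenerate =)`.
#' @export
fit_sigmoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (stats::sd(x) == 0) stop("fit failure: degenerate abscissa spread")
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    return(list(base = mean(y), top = mean(y), x50 = stats::median(x),
                rate = 1, degenerate = TRUE))
  }
  span <- max(x) - min(x)
  best <- NULL
  for (x50_0 in stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)) {
    for (rate0 in span * c(0.05, 0.15, 0.4)) {
      fit <- try(suppressWarnings(minpack.lm::nlsLM(
        y ~ base + (top - base) / (1 + exp((x50 - x) / rate)),
        data = data.frame(x = x, y = y),
        start = list(base = min(y), top = max(y), x50 = x50_0,
                     rate = rate0),
        lower = c(-Inf, -Inf, -Inf, span * 1e-4),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
        silent = TRUE)
      if (!inherits(fit, "try-error")) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit,
                                                          rss = rss)
      }
    }
  }
  if (is.null(best)) stop("fit failure: sigmoid fit did not converge")
  p <- as.list(stats::coef(best$fit))
  if (p$top < p$base) {                   # normalize orientation
    tmp <- p$top; p$top <- p$base; p$base <- tmp
  }
  list(base = p$base, top = p$top, x50 = p$x50, rate = p$rate,
       degenerate = FALSE)
}

#' Ordinary least squares restricted to a linear sub-range
#'
#' Line of best fit over the points with `x < x_max` (the sub-range where a
#' stimulus-response relationship is linear before saturation).
#'
#' @param x,y Data.
#' @param x_max Cutoff; >= 2 points must satisfy `x < x_max`.
#' @return `list(slope =, intercept =, r =, n =)` with `r` the Pearson
#'   correlation over the fitted points.
#' @export
fit_linear_range <- function(x, y, x_max = Inf) {
  sel <- x < x_max
  if (sum(sel) < 2) stop("parameter error: < 2 points below the cutoff")
  xs <- x[sel]; ys <- y[sel]
  co <- stats::lm.fit(cbind(1, xs), ys)$coefficients
  r <- if (stats::sd(xs) > 0 && stats::sd(ys) > 0) stats::cor(xs, ys) else NA_real_
  list(slope = unname(co[2]), intercept = unname(co[1]), r = r,
       n = sum(sel))
}
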