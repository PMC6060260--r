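# Photobleach modeling and F/F0 normalization.
#
# Bleaching of the indicator under continuous illumination follows a
# double-exponential decline. It is measured on control acquisitions taken
# without synaptic activation (stimulus intensity zero) and removed from
# stimulated recordings by dividing each trace by the fitted curve --
# divisive rather than subtractive, because bleaching scales the emitted
# fluorescence multiplicatively.

#' Photobleach model
#'
#' `B(t) = a1 * exp(-t/tau1) + a2 * exp(-t/tau2) + c`, normalized so that
#' `B(0) = a1 + a2 + c = 1`. By convention `tau1 <= tau2` (fast component
#' first); the constructor swaps components if needed.
#'
#' @param a1,a2 Amplitude fractions of the fast and slow components (>= 0).
#' @param tau1_s,tau2_s Time constants, seconds (> 0).
#' @param c Constant (non-bleaching) fraction (>= 0).
#' @param form Descriptor of how the model was obtained: `"double"`,
#'   `"single"` (a2 fixed at 0) or `"constant"`.
#' @return An object of class `bleach_model`.
#' @export
bleach_model <- function(a1, tau1_s, a2 = 0, tau2_s = Inf, c = 0,
                         form = "double") {
  stopifnot(tau1_s > 0, tau2_s > 0, a1 >= 0, a2 >= 0, c >= 0)
  if (tau2_s < tau1_s) {          # enforce fast-first ordering
    tmp <- tau1_s; tau1_s <- tau2_s; tau2_s <- tmp
    tmp <- a1; a1 <- a2; a2 <- tmp
  }
  total <- a1 + a2 + c
  if (total <= 0) stop("bleach model must have positive value at t = 0")
  structure(list(a1 = a1 / total, tau1_s = tau1_s, a2 = a2 / total,
                 tau2_s = tau2_s, c = c / total, form = form),
            class = "bleach_model")
}

#' Evaluate a bleach model
#' @param model A [bleach_model()].
#' @param t Times in seconds.
#' @return `B(t)`, with `B(0) = 1`.
#' @export
bleach_value <- function(model, t) {
  e2 <- if (is.finite(model$tau2_s)) exp(-t / model$tau2_s) else 1
  model$a1 * exp(-t / model$tau1_s) + model$a2 * e2 + model$c
}

#' Identity (no-bleach) model
#' @return A [bleach_model()] with `B(t) = 1` for all `t`.
#' @export
flat_bleach <- function() bleach_model(0, 1, 0, 2, 1, form = "constant")

#' @export
print.bleach_model <- function(x, ...) {
  cat(sprintf(
    "<bleach_model %s> a1=%.4f tau1=%.3gs a2=%.4f tau2=%.3gs c=%.4f\n",
    x$form, x$a1, x$tau1_s, x$a2, x$tau2_s, x$c))
  invisible(x)
}

# Multi-start nonlinear least squares for sums of decaying exponentials,
# optionally with a constant offset. Returns the best converged nlsLM fit
# (list(fit, rss)), or NULL if every start fails.
.fit_exp_sum <- function(t, y, n_comp, n_starts = 6, offset = TRUE) {
  span <- max(t) - min(t)
  taus <- exp(seq(log(span / 50), log(span * 2), length.out = n_starts))
  amp0 <- max(y) - min(y)
  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- if (n_comp == 1) list(A1 = amp0, T1 = taus[i]) else {
      j <- min(i + 2, n_starts)
      list(A1 = amp0 / 2, T1 = taus[i], A2 = amp0 / 2, T2 = taus[j])
    }
    lower <- if (n_comp == 1) c(0, span * 1e-4) else
      c(0, span * 1e-4, 0, span * 1e-4)
    rhs <- if (n_comp == 1) "A1 * exp(-t / T1)" else
      "A1 * exp(-t / T1) + A2 * exp(-t / T2)"
    if (offset) {
      start$C <- min(y)
      lower <- c(lower, 0)
      rhs <- paste(rhs, "+ C")
    }
    fm <- stats::as.formula(paste("y ~", rhs))
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      fm, data = data.frame(t = t, y = y), start = start, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Fit a photobleach model to a no-stimulus control trace
#'
#' Fits `F(t) = F0 * (a1 exp(-t/tau1) + a2 exp(-t/tau2) + c)` by multi-start
#' nonlinear least squares (log-spaced tau initializations) and returns the
#' normalized model with `B(0) = 1`. If the double-exponential fit fails to
#' converge from every start, a single exponential is fitted instead and the
#' result's `form` records this. A trace with negligible relative variation
#' yields the constant model.
#'
#' @param control A raw-stage [trace()] with >= 10 positive samples.
#' @return A [bleach_model()].
#' @export
fit_bleach_model <- function(control) {
  if (control$stage != "raw") stop("control trace must be raw stage")
  if (length(control$values) < 10) stop("need >= 10 samples to fit bleaching")
  if (any(control$values <= 0)) stop("domain error: non-positive control trace")
  t <- control$times_s - control$times_s[1]
  y <- control$values
  if (stats::sd(y) / mean(y) < 1e-9) {
    return(bleach_model(0, 1, 0, 2, 1, form = "constant"))
  }
  best <- .fit_exp_sum(t, y, n_comp = 2)
  form <- "double"
  if (is.null(best)) {
    best <- .fit_exp_sum(t, y, n_comp = 1)
    form <- "single"
  }
  if (is.null(best)) {
    stop("fit failure: bleach model did not converge from any start")
  }
  p <- as.list(stats::coef(best$fit))
  if (form == "double") {
    bleach_model(p$A1, p$T1, p$A2, p$T2, p$C, form = form)
  } else {
    bleach_model(p$A1, p$T1, 0, Inf, p$C, form = form)
  }
}

#' Divide a trace by its bleach curve
#'
#' @param trace A raw-stage [trace()].
#' @param model A normalized [bleach_model()] (`B(0) = 1`).
#' @return A `bleach_corrected`-stage [trace()]: `values / B(times)`.
#' @export
correct_bleach <- function(trace, model) {
  if (trace$stage != "raw") stop("correct_bleach expects a raw-stage trace")
  b <- bleach_value(model, trace$times_s - trace$times_s[1])
  if (any(b <= 0)) stop("model-domain error: B(t) <= 0 at a sample time")
  trace(trace$times_s, trace$values / b, stage = "bleach_corrected",
        id = trace$id)
}

#' Subtract background fluorescence from a trace
#'
#' Background may be a scalar (e.g. the mean autofluorescence measured in a
#' wild-type slice) or a trace on the same time base (e.g. a neighboring
#' background ROI). Values are not clipped: negative results are retained so
#' downstream estimators stay unbiased.
#'
#' @param trace A [trace()].
#' @param background Scalar or [trace()] with an identical time base.
#' @return A [trace()] at the same stage.
#' @export
subtract_background <- function(trace, background) {
  bg <- if (inherits(background, "trace")) {
    if (length(background$values) != length(trace$values)) {
      stop("shape error: background trace length mismatch")
    }
    background$values
  } else {
    stopifnot(is.numeric(background), length(background) == 1)
    background
  }
  out <- trace
  out$values <- trace$values - bg
  out
}

#' Normalize a trace to its pre-stimulus baseline (F/F0)
#'
#' F0 is the mean of all samples strictly before the stimulus onset; the
#' values become `F / F0` and the times are re-referenced so that the last
#' pre-onset sample is t = 0 (data are plotted relative to the onset of
#' stimulation).
#'
#' @param trace A raw or bleach-corrected [trace()].
#' @param stim_onset_s Stimulus onset, seconds on the trace's time base.
#' @return A normalized-stage [trace()] with `f0` recorded.
#' @export
compute_f_over_f0 <- function(trace, stim_onset_s) {
  if (!trace$stage %in% c("raw", "bleach_corrected")) {
    stop("compute_f_over_f0 expects a raw or bleach_corrected trace")
  }
  pre <- trace$times_s < stim_onset_s
  if (!any(pre)) stop("protocol error: no pre-onset samples")
  if (sum(pre) < 2) stop("protocol error: need >= 2 pre-onset samples")
  f0 <- mean(trace$values[pre])
  if (f0 <= 0) stop("domain error: F0 <= 0")
  t0 <- max(trace$times_s[pre])
  trace(trace$times_s - t0, trace$values / f0, stage = "normalized",
        f0 = f0, id = trace$id)
}
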