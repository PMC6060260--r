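# Shared fixtures and independent brute-force oracles.

# Random T x H x W stack of 16-bit integers.
random_int_stack <- function(tn, h, w, seed = 1) {
  set.seed(seed)
  array(sample(0:65535, tn * h * w, replace = TRUE), c(tn, h, w))
}

# Noiseless normalized trace: flat baseline, then single-exponential decay
# from a peak at `peak_time`.
decay_trace <- function(amp, tau, peak_time = 1, t_max = 9, dt = 0.02,
                        noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, t_max, by = dt)
  vals <- ifelse(times >= peak_time,
                 1 + amp * exp(-(times - peak_time) / tau), 1)
  if (noise_sd > 0) vals <- vals + rnorm(length(times), sd = noise_sd)
  trace(times, vals, stage = "normalized", f0 = 1)
}

# Brute-force per-pixel mean over an ROI, frame by frame (independent of
# extract_traces' vectorized path).
naive_roi_means <- function(frames, px) {
  vapply(seq_len(dim(frames)[1]), function(t) {
    mean(vapply(seq_len(nrow(px)),
                function(i) frames[t, px[i, 1] + 1, px[i, 2] + 1],
                numeric(1)))
  }, numeric(1))
}

# Closed-form OLS slope via the normal equations.
naive_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Direct covariance-formula Pearson correlation.
naive_pearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}
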