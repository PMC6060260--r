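test_that("peak and time-to-peak follow the post-onset maximum", {
  flat <- trace(0:5, rep(1, 6), stage = "normalized", f0 = 1)
  pk <- measure_peak(flat, 0.5)
  expect_equal(pk$peak, 0)

  tr <- trace(0:3, c(1, 1, 1.4, 1.2), stage = "normalized", f0 = 1)
  pk2 <- measure_peak(tr, stim_onset_s = 1.5)
  expect_equal(pk2$peak, 0.4)
  expect_equal(pk2$time_to_peak_s, 0.5)

  ties <- trace(0:4, c(1, 1.4, 1.4, 1.2, 1), stage = "normalized", f0 = 1)
  expect_equal(measure_peak(ties, 0.5)$time_to_peak_s, 0.5)
  expect_error(measure_peak(flat, 10), "protocol")
})

test_that("peak of a noiseless transient equals the closed form", {
  stim <- stimulus_protocol(1, 10, 20)
  times <- seq(0, 5, by = 0.01)
  vals <- 1 + transient_response(times, stim, 0.1, 1, Inf)
  tr <- trace(times - 1, vals, stage = "normalized", f0 = 1)
  # closed form: decay-weighted sum of increments at the last stimulus
  tk <- (0:9) / 20
  expected <- sum(0.1 * exp(-(max(tk) - tk) / 1))
  expect_equal(measure_peak(tr, 0)$peak, expected, tolerance = 1e-9)
})

test_that("initial slope matches the closed-form regression", {
  flat <- trace(0:9 / 10, rep(1, 10), stage = "normalized", f0 = 1)
  expect_equal(measure_initial_slope(flat, 0.05), 0)
  lin <- trace(0:9 / 10, 1 + 0.5 * (0:9 / 10), stage = "normalized",
               f0 = 1)
  expect_equal(measure_initial_slope(lin, 0.05), 0.5, tolerance = 1e-9)
  set.seed(23)
  for (i in 1:10) {
    times <- cumsum(runif(12, 0.05, 0.2))
    vals <- 1 + rnorm(12, 0, 0.3)
    tr <- trace(times, vals, stage = "normalized", f0 = 1)
    n_pts <- sample(3:6, 1)
    idx <- which(times > times[2])[seq_len(n_pts)]
    expect_equal(measure_initial_slope(tr, times[2], n_pts),
                 naive_slope(times[idx], vals[idx]), tolerance = 1e-9)
  }
  expect_error(measure_initial_slope(flat, 0.85, 3), "protocol")
})

test_that("decay fits recover noiseless generating parameters", {
  single <- decay_trace(0.5, 0.5)
  f1 <- fit_decay(single, 1)
  expect_equal(f1$model, "single")
  expect_equal(f1$fast_tau_s, 0.5, tolerance = 0.01)

  dbl <- trace(seq(0, 12, by = 0.02),
               1 + 0.3 * exp(-seq(0, 12, by = 0.02) / 0.3) +
                 0.3 * exp(-seq(0, 12, by = 0.02) / 3),
               stage = "normalized", f0 = 1)
  f2 <- fit_decay(dbl, 0)
  expect_equal(f2$model, "double")
  expect_equal(f2$fast_tau_s, 0.3, tolerance = 0.05)
  expect_equal(f2$fast_tau_s, min(f2$taus_s))
})

test_that("noisy single-exponential taus are recovered within 10%", {
  errs <- vapply(1:20, function(s) {
    tr <- decay_trace(0.5, 0.5, noise_sd = 0.01, seed = 100 + s)
    pk <- measure_peak(tr, 0.9)
    fit <- fit_decay(tr, 0.9 + pk$time_to_peak_s)
    abs(fit$fast_tau_s - 0.5) / 0.5
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("AUC integrates F/F0 - 1 over the 2-s window", {
  flat <- trace(seq(-1, 3, 0.1), rep(1, 41), stage = "normalized", f0 = 1)
  expect_equal(area_under_curve(flat, 0, 2), 0)

  step <- trace(seq(-1, 3, 0.1), c(rep(1, 10), rep(1.5, 31)),
                stage = "normalized", f0 = 1)
  expect_equal(area_under_curve(step, 0, 2), 1.0, tolerance = 1e-9)

  set.seed(3)
  vals <- 1 + c(rep(0, 10), abs(rnorm(31, 0.3, 0.1)))
  tr1 <- trace(seq(-1, 3, 0.1), vals, stage = "normalized", f0 = 1)
  tr2 <- trace(seq(-1, 3, 0.1), 1 + 2 * (vals - 1),
               stage = "normalized", f0 = 1)
  expect_equal(area_under_curve(tr2, 0, 2),
               2 * area_under_curve(tr1, 0, 2), tolerance = 1e-9)
  expect_error(area_under_curve(flat, 2, 2), "protocol")
})

test_that("peak, slope and AUC are invariant to a time-axis shift", {
  set.seed(4)
  times <- (-20:80) / 20                  # exact binary sample times
  vals <- 1 + 0.6 * (times > 0) * exp(-pmax(times, 0) / 0.8) +
    rnorm(length(times), 0, 0.01)
  t1 <- trace(times, vals, stage = "normalized", f0 = 1)
  t2 <- trace(times + 13.7, vals, stage = "normalized", f0 = 1)
  expect_equal(measure_peak(t1, 0)$peak, measure_peak(t2, 13.7)$peak)
  expect_equal(measure_peak(t1, 0)$time_to_peak_s,
               measure_peak(t2, 13.7)$time_to_peak_s, tolerance = 1e-9)
  expect_equal(measure_initial_slope(t1, 0), measure_initial_slope(t2, 13.7),
               tolerance = 1e-9)
  expect_equal(area_under_curve(t1, 0), area_under_curve(t2, 13.7),
               tolerance = 1e-9)
})

test_that("sigmoid fits recover a noiseless logistic and its symmetry", {
  x <- seq(0, 70, by = 5)
  y <- 0 + (1 - 0) / (1 + exp((30 - x) / 5))
  fit <- fit_sigmoid(x, y)
  expect_equal(fit$base, 0, tolerance = 0.02)
  expect_equal(fit$top, 1, tolerance = 0.02)
  expect_equal(fit$x50, 30, tolerance = 0.02 * 30)
  expect_equal(fit$rate, 5, tolerance = 0.02 * 5)
  expect_equal(fit$x50, 30, tolerance = 1e-6)  # symmetry point, exact data

  const <- fit_sigmoid(x, rep(2, length(x)))
  expect_true(const$degenerate)
  expect_equal(const$top, const$base)
})

test_that("linear-range fits equal the closed-form normal equations", {
  x <- 0:10
  fit <- fit_linear_range(x, 2 * x + 1, x_max = 50)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1)

  two <- fit_linear_range(x, c(5, 9, rep(0, 9)), x_max = 1.5)
  expect_equal(two$slope, 4)
  expect_equal(two$intercept, 5)

  set.seed(5)
  for (i in 1:10) {
    xs <- runif(30, 0, 100); ys <- 3 * xs + rnorm(30, 0, 10)
    cutoff <- 60
    fit <- fit_linear_range(xs, ys, cutoff)
    sel <- xs < cutoff
    expect_equal(fit$slope, naive_slope(xs[sel], ys[sel]),
                 tolerance = 1e-9)
  }
  expect_error(fit_linear_range(x, 2 * x, x_max = 0.5), "parameter")
})

test_that("kinetics_summary bundles consistent per-trace measures", {
  tr <- decay_trace(0.5, 0.8, peak_time = 1, t_max = 6)
  row <- kinetics_summary(tr, stim_onset_s = 0.5)
  expect_equal(row$peak, 0.5, tolerance = 1e-9)
  expect_equal(row$time_to_peak_s, 0.5, tolerance = 1e-9)
  expect_equal(row$fast_tau_s, 0.8, tolerance = 0.01)
  expect_equal(row$decay_model, "single")
  expect_gt(row$auc, 0)
})
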