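test_that("a constant control yields the no-bleach model", {
  tr <- trace(seq(0, 10, by = 0.1), rep(100, 101))
  m <- fit_bleach_model(tr)
  expect_lt(m$a1 + m$a2, 1e-6)
  expect_equal(m$c, 1, tolerance = 1e-6)
})

test_that("noiseless double-exponential parameters are recovered to 1%", {
  truth <- bleach_model(0.6, 5, 0.4, 50, 0)
  t <- seq(0, 100, by = 0.5)
  tr <- trace(t, 120 * bleach_value(truth, t))
  m <- fit_bleach_model(tr)
  expect_equal(m$a1, 0.6, tolerance = 0.01)
  expect_equal(m$tau1_s, 5, tolerance = 0.01)
  expect_equal(m$a2, 0.4, tolerance = 0.01)
  expect_equal(m$tau2_s, 50, tolerance = 0.01)
  expect_lt(m$c, 0.01)
})

test_that("the normalized bleach model is invariant to trace scale", {
  truth <- bleach_model(0.5, 3, 0.3, 30, 0.2)
  t <- seq(0, 60, by = 0.25)
  base <- 80 * bleach_value(truth, t)
  m1 <- fit_bleach_model(trace(t, base))
  m2 <- fit_bleach_model(trace(t, base * 17.3))
  for (f in c("a1", "tau1_s", "a2", "tau2_s", "c")) {
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-9)
  }
})

test_that("divisive correction cancels pure bleach exactly", {
  model <- bleach_model(0.6, 5, 0.4, 50, 0)
  t <- seq(0, 80, by = 0.4)
  tr <- trace(t, 100 * bleach_value(model, t))
  out <- correct_bleach(tr, model)
  expect_equal(out$values, rep(100, length(t)), tolerance = 1e-12)
  expect_equal(out$stage, "bleach_corrected")
  ident <- correct_bleach(tr, flat_bleach())
  expect_identical(ident$values, tr$values)
})

test_that("fit-then-correct flattens a noiseless simulated control", {
  bl <- bleach_model(0.6, 5, 0.4, 50, 0)
  st <- simulate_bleach_control(noise_model(background_level = 100), bl,
                                shape = c(200, 1, 1),
                                frame_interval_s = 0.5, seed = 1)
  tr <- trace(frame_times(st), as.vector(st$green))
  out <- correct_bleach(tr, fit_bleach_model(tr))
  expect_lt(max(abs(out$values / mean(out$values) - 1)), 1e-6)
})

test_that("correcting the true model leaves no pre-stimulus slope", {
  bl <- bleach_model(0.3, 4, 0.2, 40, 0.5)
  b <- bouton_spec(center = c(8, 8), amp_per_stim = 0.2)
  stim <- stimulus_protocol(3, 10, 20)
  mv <- simulate_movie(list(b), stim, noise_model(background_level = 10),
                       bl, c(60, 16, 16), 0.1, seed = 1)
  tr <- trace(frame_times(mv$stack), mv$stack$green[, 9, 9])
  out <- correct_bleach(tr, bl)
  pre <- out$times_s < 3
  expect_lt(abs(naive_slope(out$times_s[pre], out$values[pre]) /
                mean(out$values[pre])), 1e-6)
})

test_that("background subtraction is pointwise and never clips", {
  tr <- trace(0:4, rep(10, 5))
  expect_identical(subtract_background(tr, 0)$values, tr$values)
  expect_equal(subtract_background(tr, 4)$values, rep(6, 5))
  expect_equal(subtract_background(tr, 15)$values, rep(-5, 5))
  bg <- trace(0:4, 1:5)
  expect_equal(subtract_background(tr, bg)$values, 10 - (1:5))
  expect_error(subtract_background(tr, trace(0:3, 1:4)), "shape")
})

test_that("subtracting the true background enlarges F/F0 responses", {
  # algebra: (s + b)/(s0 + b) < 1 + (s - s0)/s0 whenever s > s0, b > 0
  t <- seq(0, 5, by = 0.1)
  sig <- 20 * (1 + 0.4 * (t >= 2) * exp(-(t - 2)))
  with_bg <- trace(t, sig + 30)
  raw_peak <- max(compute_f_over_f0(with_bg, 2)$values)
  sub_peak <- max(compute_f_over_f0(subtract_background(with_bg, 30),
                                    2)$values)
  expect_gt(sub_peak, raw_peak)
  expect_equal(sub_peak, 1.4, tolerance = 1e-9)
})

test_that("F/F0 uses the pre-onset mean and re-references time", {
  tr <- trace(0:4, c(98, 102, 150, 120, 110))
  out <- compute_f_over_f0(tr, stim_onset_s = 1.5)
  expect_equal(out$f0, 100)
  expect_equal(out$values[3], 1.5)
  expect_equal(out$times_s, -1:3)         # last pre-onset sample at t = 0
  expect_equal(mean(out$values[out$times_s <= 0]), 1, tolerance = 1e-12)

  const <- compute_f_over_f0(trace(0:9, rep(100, 10)), 5.5)
  expect_true(all(const$values == 1))
  expect_equal(const$f0, 100)
})

test_that("F/F0 guards its preconditions", {
  expect_error(compute_f_over_f0(trace(0:4, rep(1, 5)), 0.5), "2 pre-onset")
  expect_error(compute_f_over_f0(trace(0:4, rep(1, 5)), -1), "pre-onset")
  expect_error(compute_f_over_f0(trace(0:4, c(-2, -2, 1, 1, 1)), 1.5),
               "F0")
  norm <- compute_f_over_f0(trace(0:4, rep(2, 5)), 2.5)
  expect_error(compute_f_over_f0(norm, 1), "raw or bleach_corrected")
})

test_that("the normalized-trace baseline contract holds on random traces", {
  set.seed(42)
  for (i in 1:50) {
    len <- sample(20:80, 1)
    times <- cumsum(runif(len, 0.05, 0.2))
    vals <- runif(len, 10, 500)
    onset <- times[sample(5:(len - 2), 1)] + 0.01
    out <- compute_f_over_f0(trace(times, vals), onset)
    expect_lt(abs(mean(out$values[out$times_s <= 0]) - 1), 1e-9)
  }
})
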