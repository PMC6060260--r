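test_that("a bouton-free noiseless movie is constant background", {
  mv <- simulate_movie(list(), stim = NULL,
                       noise = noise_model(background_level = 40),
                       bleach = flat_bleach(), shape = c(5, 8, 8),
                       frame_interval_s = 0.1, seed = 1)
  expect_true(all(mv$stack$green == 40))
  expect_true(all(mv$stack$red == 40))
})

test_that("a single noiseless responder reaches the closed-form peak F/F0", {
  b <- bouton_spec(center = c(10, 10), green_rest = 50, responder = TRUE,
                   amp_per_stim = 0.5, tau_decay_s = 1)
  stim <- stimulus_protocol(onset_time_s = 0.5, n_stimuli = 1)
  mv <- simulate_movie(list(b), stim, noise_model(), flat_bleach(),
                       shape = c(20, 21, 21), frame_interval_s = 0.1,
                       seed = 1)
  ctr <- mv$stack$green[, 11, 11]
  f0 <- mean(ctr[1:5])                    # frames before the 0.5-s stimulus
  # closed form: c(t) = 0.5 exp(-(t - 0.5)) at frame times
  t <- (0:19) * 0.1
  expected <- 1 + 0.5 * exp(-(t - 0.5)) * (t >= 0.5)
  expect_equal(ctr / f0, expected, tolerance = 1e-12)
  expect_equal(max(ctr / f0), 1.5, tolerance = 1e-12)
})

test_that("generators are bit-deterministic in (parameters, seed)", {
  b <- random_bouton_field(5, 32, 32, seed = 4)
  stim <- stimulus_protocol(0.5, 5, 20)
  nz <- noise_model(photon_gain = 2, read_sigma = 3, background_level = 30)
  m1 <- simulate_movie(b, stim, nz, flat_bleach(), c(10, 32, 32), 0.1,
                       seed = 7)
  m2 <- simulate_movie(b, stim, nz, flat_bleach(), c(10, 32, 32), 0.1,
                       seed = 7)
  expect_identical(m1$stack$green, m2$stack$green)
  expect_identical(m1$stack$red, m2$stack$red)
  m3 <- simulate_movie(b, stim, nz, flat_bleach(), c(10, 32, 32), 0.1,
                       seed = 8)
  expect_false(identical(m1$stack$green, m3$stack$green))
})

test_that("bleach control frame mean follows the bleach curve exactly", {
  bl <- bleach_model(0.6, 5, 0.4, 50, 0)
  st <- simulate_bleach_control(noise_model(background_level = 100), bl,
                                shape = c(11, 4, 4), frame_interval_s = 0.5,
                                seed = 1)
  fm <- apply(st$green, 1, mean)
  # direct evaluation at t = 5 s (frame 11)
  expect_equal(fm[11] / fm[1], 0.6 * exp(-1) + 0.4 * exp(-0.1),
               tolerance = 1e-12)
})

test_that("noisy controls share their expectation across seeds", {
  bl <- bleach_model(0.6, 5, 0.4, 50, 0)
  nz <- noise_model(read_sigma = 5, background_level = 100)
  m <- vapply(1:2, function(s) {
    st <- simulate_bleach_control(nz, bl, shape = c(100, 8, 8),
                                  frame_interval_s = 0.1, seed = s)
    mean(st$green)
  }, numeric(1))
  se <- 5 / sqrt(100 * 64)
  expect_lt(abs(m[1] - m[2]), 3 * sqrt(2) * se)
})

test_that("noiseless movies conserve total intensity frame by frame", {
  boutons <- random_bouton_field(8, 32, 64, seed = 9, green_rest = 60,
                                 amp_per_stim = 0.2, tau_decay_s = 0.8)
  stim <- stimulus_protocol(0.5, 5, 20)
  bl <- bleach_model(0.3, 2, 0.2, 20, 0.5)
  mv <- simulate_movie(boutons, stim, noise_model(background_level = 25),
                       bl, shape = c(15, 32, 64), frame_interval_s = 0.1,
                       seed = 2)
  times <- (0:14) * 0.1
  for (t in 1:15) {
    expected <- (sum(mv$truth$background) +
                 sum(mv$truth$green_templates_sum *
                     (1 + mv$truth$c_t[t, ]))) *
      bleach_value(bl, times[t])
    expect_equal(sum(mv$stack$green[t, , ]), expected,
                 tolerance = 1e-6)
  }
})

test_that("the red channel carries no stimulus-locked component", {
  boutons <- random_bouton_field(6, 32, 32, seed = 5, amp_per_stim = 0.3)
  stim <- stimulus_protocol(0.3, 8, 20)
  mv <- simulate_movie(boutons, stim, noise_model(background_level = 20),
                       flat_bleach(), c(30, 32, 32), 0.1, seed = 3)
  red_mean <- apply(mv$stack$red, 1, mean)
  reg <- rowMeans(mv$truth$c_t)           # transient regressor
  expect_equal(naive_slope(reg, red_mean), 0, tolerance = 1e-9)
})

test_that("tile grids are exact crops when vignette and noise are off", {
  set.seed(6)
  truth <- matrix(runif(100 * 100, 50, 150), 100, 100)
  layout <- plan_mosaic_layout(c(100, 100), 2, 2, overlap_frac = 0.1)
  # layout arithmetic: tile = ceil(100 / (2 - 0.1)) = 53
  expect_equal(layout$tile_shape, c(53L, 53L))
  grid <- simulate_tile_grid(truth, layout, vignette_strength = 0,
                             noise = noise_model(), seed = 1)
  expect_length(grid$tiles, 4)
  o <- layout$origins
  for (i in 1:4) {
    expect_identical(grid$tiles[[i]],
                     truth[o[i, 1] + 1:53, o[i, 2] + 1:53])
  }
})

test_that("vignette attenuates tile corners to 1 - strength", {
  truth <- matrix(100, 60, 60)
  layout <- mosaic_layout(1, 1, c(60, 60))
  grid <- simulate_tile_grid(truth, layout, vignette_strength = 0.5,
                             noise = noise_model(), seed = 1)
  tl <- grid$tiles[[1]]
  ctr <- tl[30, 30] / 100                 # near-center pixel
  expect_equal(tl[1, 1] / 100, 0.5, tolerance = 1e-9)
  expect_gt(ctr, 0.99)
  expect_error(simulate_tile_grid(truth, layout, vignette_strength = 1.2,
                                  noise = noise_model(), seed = 1),
               "parameter")
})

test_that("line profiles hit their target correlation", {
  p1 <- simulate_line_profiles(50, rho = 1, seed = 1)
  expect_equal(naive_pearson(p1$a, p1$b), 1, tolerance = 1e-9)
  p0 <- simulate_line_profiles(1e5, rho = 0, seed = 2)
  expect_lt(abs(naive_pearson(p0$a, p0$b)), 0.01)
  p9 <- simulate_line_profiles(1e4, rho = 0.9, seed = 3)
  r <- naive_pearson(p9$a, p9$b)
  expect_gt(r, 0.88); expect_lt(r, 0.92)  # Fisher-z interval for n = 1e4
  expect_error(simulate_line_profiles(10, rho = 1.5), "rho")
})

test_that("out-of-frame boutons and too-short stacks are rejected", {
  b <- bouton_spec(center = c(40, 5))
  expect_error(simulate_movie(list(b), NULL, noise_model(), flat_bleach(),
                              c(5, 32, 32), 0.1, seed = 1), "outside")
  b2 <- bouton_spec(center = c(5, 5))
  stim <- stimulus_protocol(2, 10, 20)
  expect_error(simulate_movie(list(b2), stim, noise_model(), flat_bleach(),
                              c(5, 32, 32), 0.1, seed = 1), "too short")
})
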