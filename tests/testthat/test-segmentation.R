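test_that("temporal averaging matches the brute-force per-pixel mean", {
  stack <- random_int_stack(100, 6, 7, seed = 8) * 1.0
  avg <- temporal_average(stack)
  naive <- matrix(0, 6, 7)
  for (r in 1:6) for (c in 1:7) naive[r, c] <- mean(stack[, r, c])
  expect_equal(avg, naive, tolerance = 1e-9)
  expect_equal(temporal_average(stack, c(4, 4)), stack[4, , ] * 1)
  const <- array(1, c(3, 4, 4))
  expect_true(all(temporal_average(const, c(1, 3)) == 1))
  expect_error(temporal_average(stack, c(5, 3)), "parameter")
})

test_that("a constant image produces no puncta", {
  expect_length(detect_puncta(matrix(7, 20, 20)), 0)
})

test_that("single spots are found within 1 px over seeds", {
  for (seed in 1:20) {
    b <- list(bouton_spec(center = c(14.3, 17.8), green_rest = 100,
                          responder = FALSE))
    mv <- simulate_movie(b, NULL,
                         noise_model(read_sigma = 10,
                                     background_level = 30),
                         flat_bleach(), c(100, 32, 40), 0.1, seed = seed)
    det <- detect_puncta(temporal_average(mv$stack))
    expect_length(det, 1)
    expect_lt(sqrt(sum((det[[1]]$center - c(14.3, 17.8))^2)), 1.5)
  }
})

test_that("two spots 10 px apart are resolved as two puncta", {
  b <- list(bouton_spec(center = c(12, 15), green_rest = 100,
                        responder = FALSE),
            bouton_spec(center = c(12, 25), green_rest = 100,
                        responder = FALSE))
  mv <- simulate_movie(b, NULL,
                       noise_model(read_sigma = 10, background_level = 30),
                       flat_bleach(), c(100, 32, 40), 0.1, seed = 2)
  det <- detect_puncta(temporal_average(mv$stack))
  expect_length(det, 2)
  m <- match_puncta(det, rbind(c(12, 15), c(12, 25)), radius_px = 1.5)
  expect_equal(m$n_matched, 2L)
})

test_that("raising k_sd never increases the detection count", {
  set.seed(31)
  img <- matrix(rnorm(60 * 60, 100, 5), 60, 60)
  for (ctr in list(c(10, 10), c(30, 40), c(50, 20))) {
    img <- img + 80 * exp(-(outer((0:59 - ctr[1])^2,
                                  (0:59 - ctr[2])^2, "+")) / (2 * 1.5^2))
  }
  counts <- vapply(c(1, 2, 3, 5, 8, 15),
                   function(k) length(detect_puncta(
                     img, segmentation_params(k_sd = k))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is invariant to a constant intensity offset", {
  set.seed(32)
  img <- matrix(rnorm(40 * 40, 50, 4), 40, 40) +
    60 * exp(-(outer((0:39 - 20)^2, (0:39 - 20)^2, "+")) / 4.5)
  d1 <- detect_puncta(img)
  d2 <- detect_puncta(img + 1234.5)
  expect_equal(length(d1), length(d2))
  for (i in seq_along(d1)) expect_equal(d1[[i]]$center, d2[[i]]$center)
})

test_that("fixed 3x3 ROIs crop at borders and hug their center", {
  rois <- make_fixed_rois(list(c(5, 5), c(0, 0)), c(10, 10))
  expect_equal(nrow(rois[[1]]$pixels), 9)
  expect_equal(nrow(rois[[2]]$pixels), 4)
  for (r in rois) {
    expect_true(all(abs(r$pixels[, 1] - r$center[1]) <= 1))
    expect_true(all(abs(r$pixels[, 2] - r$center[2]) <= 1))
  }
  expect_error(make_fixed_rois(list(c(12, 5)), c(10, 10)), "parameter")
})

test_that("background ROIs sit at the offset and never touch puncta", {
  p <- make_fixed_rois(list(c(10, 10)), c(21, 21))
  p[[1]]$kind <- "punctum"; p[[1]]$id <- "p001"
  bg <- pick_background_rois(p, c(21, 21), offset_px = 4, seed = 1)
  expect_length(bg, 1)
  d <- sqrt(sum((bg[[1]]$center - c(10, 10))^2))
  expect_lt(abs(d - 4), 1)                # grid rounding on diagonals
  overlap <- merge(as.data.frame(bg[[1]]$pixels),
                   as.data.frame(p[[1]]$pixels))
  expect_equal(nrow(overlap), 0)
})

test_that("dense fields still place background ROIs for >= 90% of puncta", {
  frac <- vapply(1:10, function(s) {
    boutons <- random_bouton_field(50, 64, 512, min_spacing_px = 6,
                                   seed = s, responder = FALSE)
    centers <- lapply(boutons, function(b) round(b$center))
    p <- make_fixed_rois(centers, c(64, 512))
    for (i in seq_along(p)) p[[i]]$kind <- "punctum"
    bg <- pick_background_rois(p, c(64, 512), offset_px = 4, seed = s)
    length(bg) / length(p)
  }, numeric(1))
  expect_true(all(frac >= 0.9))
})

test_that("extracted traces equal the brute-force ROI means", {
  stack <- random_int_stack(20, 10, 12, seed = 13) * 1.0
  px <- cbind(c(2, 2, 3, 7), c(4, 5, 4, 9))
  r <- roi("a", px, center = c(2, 4))
  tr <- extract_traces(stack, list(r), frame_interval_s = 0.5)[[1]]
  expect_equal(tr$values, naive_roi_means(stack, px), tolerance = 1e-9)
  expect_equal(tr$times_s, (0:19) * 0.5)

  one <- roi("b", cbind(6, 6), center = c(6, 6))
  tr1 <- extract_traces(stack, list(one))[[1]]
  expect_identical(tr1$values, stack[, 7, 7])

  unif <- array(3.5, c(4, 10, 12))
  tru <- extract_traces(unif, list(r))[[1]]
  expect_true(all(tru$values == 3.5))

  bad <- roi("c", cbind(9, 30), center = c(9, 30))
  expect_error(extract_traces(stack, list(bad)), "shape")
})
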