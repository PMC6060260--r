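# Synthetic two-channel movies, bleach-only controls, vignetted tile grids
# and correlated line profiles, all with recorded ground truth.
#
# The generator emulates the statistical structure of slice recordings:
# punctate boutons on an autofluorescent background, stimulus-train-driven
# green transients with exponential decay and a saturation plateau, a
# calcium-independent red channel, multiplicative double-exponential
# bleaching in both channels, and Poisson + Gaussian camera noise. Every
# generator is a pure function of (parameters, seed).

# Evaluate expr with a temporarily seeded RNG, restoring global state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic bouton specification
#'
#' One presynaptic bouton: a 2-D Gaussian spot with a resting green
#' brightness, a calcium-independent red brightness, and (for responders)
#' a stimulus-locked green transient.
#'
#' @param center Sub-pixel (row, col), 0-based.
#' @param psf_sigma_px Spot width (Gaussian sigma, pixels).
#' @param green_rest Resting green peak brightness (fluorescence units).
#' @param red_level Red peak brightness.
#' @param responder Logical: does the bouton respond to stimulation?
#' @param amp_per_stim F/F0 increment contributed by each stimulus.
#' @param tau_decay_s Transient decay time constant, seconds.
#' @param saturation_cap Maximum summed transient, F/F0 units (the response
#'   plateaus at high stimulus counts).
#' @return An object of class `bouton_spec`.
#' @export
bouton_spec <- function(center, psf_sigma_px = 1.5, green_rest = 100,
                        red_level = 150, responder = TRUE,
                        amp_per_stim = 0.1, tau_decay_s = 1,
                        saturation_cap = 2) {
  stopifnot(psf_sigma_px > 0, green_rest > 0, red_level > 0,
            amp_per_stim >= 0, tau_decay_s > 0,
            saturation_cap >= amp_per_stim)
  structure(list(center = as.numeric(center), psf_sigma_px = psf_sigma_px,
                 green_rest = green_rest, red_level = red_level,
                 responder = isTRUE(responder), amp_per_stim = amp_per_stim,
                 tau_decay_s = tau_decay_s, saturation_cap = saturation_cap),
            class = "bouton_spec")
}

#' Camera / background noise model
#'
#' Noise is applied in two stages: a Poisson stage (`photon_gain` expected
#' counts per intensity unit; 0 disables it) followed by additive Gaussian
#' read noise of SD `read_sigma` (intensity units). The autofluorescent
#' background has mean `background_level`; when `background_smoothness_px`
#' is positive it is a Gaussian-smoothed random field with that correlation
#' length and a fixed 10% relative SD, otherwise it is uniform.
#'
#' @param photon_gain Counts per intensity unit for the Poisson stage (>= 0).
#' @param read_sigma Additive Gaussian SD, intensity units (>= 0).
#' @param background_level Mean background intensity (>= 0).
#' @param background_smoothness_px Spatial correlation length, pixels.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_gain = 0, read_sigma = 0,
                        background_level = 0, background_smoothness_px = 0) {
  stopifnot(photon_gain >= 0, read_sigma >= 0, background_level >= 0,
            background_smoothness_px >= 0)
  structure(list(photon_gain = photon_gain, read_sigma = read_sigma,
                 background_level = background_level,
                 background_smoothness_px = background_smoothness_px),
            class = "noise_model")
}

#' Stimulus-train transient, F/F0 units
#'
#' Each stimulus at time `t_k` adds `amp_per_stim` which then decays as
#' `exp(-(t - t_k) / tau_decay_s)`; the sum is clipped at `saturation_cap`
#' (responses plateau at high stimulus counts).
#'
#' @param times_s Evaluation times, seconds.
#' @param stim A [stimulus_protocol()] (or `NULL` for no stimulation).
#' @param amp_per_stim Increment per stimulus.
#' @param tau_decay_s Decay constant, seconds.
#' @param saturation_cap Clip level for the summed transient.
#' @return Numeric vector `c(t)`, zero before the first stimulus.
#' @export
transient_response <- function(times_s, stim, amp_per_stim, tau_decay_s,
                               saturation_cap = Inf) {
  if (is.null(stim) || stim$n_stimuli == 0 || amp_per_stim == 0) {
    return(numeric(length(times_s)))
  }
  tk <- stimulus_times(stim)
  dt <- outer(times_s, tk, "-")            # time since each stimulus
  resp <- amp_per_stim * exp(-dt / tau_decay_s) * (dt >= 0)
  pmin(rowSums(resp), saturation_cap)
}

# Render Gaussian spots by analytic integration of the continuous profile
# over unit pixel areas (pixel r covers [r-0.5, r+0.5]); sub-pixel centers
# therefore produce correctly shifted centroids. `amp` is the peak of the
# continuous profile. Returns an H x W matrix.
.render_spot <- function(h, w, center, sigma, amp) {
  half <- ceiling(5 * sigma)
  rows <- max(0, floor(center[1] - half)):min(h - 1, ceiling(center[1] + half))
  cols <- max(0, floor(center[2] - half)):min(w - 1, ceiling(center[2] + half))
  if (!length(rows) || !length(cols)) return(matrix(0, h, w))
  wr <- stats::pnorm((rows + 0.5 - center[1]) / sigma) -
        stats::pnorm((rows - 0.5 - center[1]) / sigma)
  wc <- stats::pnorm((cols + 0.5 - center[2]) / sigma) -
        stats::pnorm((cols - 0.5 - center[2]) / sigma)
  out <- matrix(0, h, w)
  out[rows + 1, cols + 1] <- amp * 2 * pi * sigma^2 * outer(wr, wc)
  out
}

# Smooth autofluorescent background field (deterministic given the RNG
# state). Uniform when smoothness is 0.
.render_background <- function(h, w, noise) {
  if (noise$background_level == 0) return(matrix(0, h, w))
  if (noise$background_smoothness_px <= 0) {
    return(matrix(noise$background_level, h, w))
  }
  raw <- matrix(stats::rnorm(h * w), h, w)
  sm <- .gaussian_blur(raw, sigma = noise$background_smoothness_px)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  pmax(noise$background_level * (1 + 0.1 * sm), 0)
}

# Poisson + Gaussian noise on an array of expected intensities.
.apply_noise <- function(x, noise) {
  if (noise$photon_gain > 0) {
    x <- stats::rpois(length(x), lambda = pmax(x, 0) * noise$photon_gain) /
      noise$photon_gain
  }
  if (noise$read_sigma > 0) {
    x <- x + stats::rnorm(length(x), sd = noise$read_sigma)
  }
  x
}

#' Simulate a two-channel bouton movie with ground truth
#'
#' Green signal per bouton is `green_rest * (1 + c(t))` where `c(t)` is the
#' clipped stimulus-train transient ([transient_response()]; zero for
#' non-responders). The red channel carries only `red_level` per bouton.
#' Both channels sit on the autofluorescent background, are multiplied by
#' their channel's bleach curve (normalized to 1 at t = 0), and receive
#' noise last. Identical (parameters, seed) give bit-identical stacks.
#'
#' @param boutons List of [bouton_spec()].
#' @param stim A [stimulus_protocol()] or `NULL`.
#' @param noise A [noise_model()].
#' @param bleach Green-channel [bleach_model()].
#' @param shape `c(T, H, W)` frames per channel and frame geometry.
#' @param frame_interval_s Seconds per frame within one channel.
#' @param seed Integer seed.
#' @param bleach_red Red-channel [bleach_model()]; default is a weakened
#'   copy of `bleach` (amplitude fractions scaled by 0.3).
#' @return `list(stack =, truth =)`: a [two_channel_stack()] and a ground
#'   truth record (bouton specs and labels, bleach models, transient matrix
#'   `c_t`, background field, seed).
#' @export
simulate_movie <- function(boutons, stim, noise, bleach,
                           shape = c(60, 64, 512), frame_interval_s = 0.098,
                           seed = 1, bleach_red = NULL) {
  tn <- shape[1]; h <- shape[2]; w <- shape[3]
  for (b in boutons) {
    if (b$center[1] < 0 || b$center[1] > h - 1 ||
        b$center[2] < 0 || b$center[2] > w - 1) {
      stop("parameter error: bouton center outside frame")
    }
  }
  times <- (seq_len(tn) - 1) * frame_interval_s
  if (!is.null(stim) && stim$n_stimuli > 0) {
    last <- max(stimulus_times(stim))
    if (max(times) < last) {
      stop("parameter error: stack too short for the stimulus protocol")
    }
  }
  if (is.null(bleach_red)) {
    bleach_red <- bleach_model(0.3 * bleach$a1, bleach$tau1_s,
                               0.3 * bleach$a2, bleach$tau2_s,
                               bleach$c + 0.7 * (bleach$a1 + bleach$a2),
                               form = bleach$form)
  }
  .with_seed(seed, {
    bg <- .render_background(h, w, noise)
    n_b <- length(boutons)
    g_tmpl <- lapply(boutons, function(b)
      .render_spot(h, w, b$center, b$psf_sigma_px, b$green_rest))
    r_tmpl <- lapply(boutons, function(b)
      .render_spot(h, w, b$center, b$psf_sigma_px, b$red_level))
    c_t <- matrix(0, tn, max(n_b, 1))     # transient per frame per bouton
    for (i in seq_len(n_b)) {
      b <- boutons[[i]]
      if (b$responder) {
        c_t[, i] <- transient_response(times, stim, b$amp_per_stim,
                                       b$tau_decay_s, b$saturation_cap)
      }
    }
    bg_vec <- as.vector(bg)
    g_mat <- vapply(g_tmpl, as.vector, numeric(h * w))
    r_mat <- vapply(r_tmpl, as.vector, numeric(h * w))
    bgl <- bleach_value(bleach, times)
    brl <- bleach_value(bleach_red, times)
    green <- array(0, c(tn, h, w)); red <- array(0, c(tn, h, w))
    for (t in seq_len(tn)) {
      gf <- bg_vec
      rf <- bg_vec
      if (n_b > 0) {
        gf <- gf + as.vector(g_mat %*% (1 + c_t[t, ]))
        rf <- rf + rowSums(r_mat)
      }
      green[t, , ] <- gf * bgl[t]
      red[t, , ] <- rf * brl[t]
    }
    green <- array(.apply_noise(green, noise), dim(green))
    red <- array(.apply_noise(red, noise), dim(red))
    green[green < 0] <- 0
    red[red < 0] <- 0
    stack <- two_channel_stack(green, red, frame_interval_s, stim)
    truth <- list(boutons = boutons,
                  responder = vapply(boutons, function(b) b$responder,
                                     logical(1)),
                  bleach_green = bleach, bleach_red = bleach_red,
                  c_t = c_t[, seq_len(n_b), drop = FALSE],
                  background = bg, seed = seed,
                  green_templates_sum = if (n_b) vapply(g_tmpl, sum,
                                                        numeric(1)) else numeric(0))
    list(stack = stack, truth = truth)
  })
}

#' Simulate a no-stimulus bleach control acquisition
#'
#' Same generative model as [simulate_movie()] but without stimulation, so
#' the only temporal structure is the bleach curve: the expected frame-mean
#' green equals `mean(background + spots) * B(t)`.
#'
#' @inheritParams simulate_movie
#' @return A [two_channel_stack()] (no stimulus component).
#' @export
simulate_bleach_control <- function(noise, bleach, shape = c(100, 64, 512),
                                    frame_interval_s = 0.098, seed = 1,
                                    boutons = list(), bleach_red = NULL) {
  simulate_movie(boutons, stim = NULL, noise = noise, bleach = bleach,
                 shape = shape, frame_interval_s = frame_interval_s,
                 seed = seed, bleach_red = bleach_red)$stack
}

#' Simulate a vignetted, overlapping tile grid from a truth image
#'
#' Each tile is a crop of the truth image multiplied by a shared radial
#' vignette (Gaussian falloff from 1 at the tile center to
#' `1 - vignette_strength` at the corners), plus noise.
#'
#' @param truth_image H x W truth image (matrix).
#' @param layout A [mosaic_layout()] whose tiles cover the truth image (use
#'   [plan_mosaic_layout()] to derive one).
#' @param vignette_strength Fractional corner attenuation in `[0, 1)`.
#' @param noise A [noise_model()] (`background_level` unused here).
#' @param seed Integer seed.
#' @return `list(tiles =, truth =)`: list of tile matrices (row-major tile
#'   order) and a truth record with the vignette image, tile origins and
#'   seed.
#' @export
simulate_tile_grid <- function(truth_image, layout, vignette_strength = 0.5,
                               noise = noise_model(), seed = 1) {
  if (vignette_strength < 0 || vignette_strength >= 1) {
    stop("parameter error: vignette_strength must be in [0, 1)")
  }
  th <- layout$tile_shape[1]; tw <- layout$tile_shape[2]
  vig <- vignette_field(th, tw, vignette_strength)
  .with_seed(seed, {
    tiles <- lapply(seq_len(nrow(layout$origins)), function(i) {
      r0 <- layout$origins[i, 1]; c0 <- layout$origins[i, 2]
      crop <- truth_image[r0 + seq_len(th), c0 + seq_len(tw), drop = FALSE]
      tile <- crop * vig
      matrix(.apply_noise(tile, noise), th, tw)
    })
    list(tiles = tiles,
         truth = list(vignette = vig, layout = layout, seed = seed))
  })
}

#' Radial Gaussian vignette field
#'
#' Value 1 at the image center, falling off as a Gaussian of the distance
#' from the center, reaching `1 - strength` at the corners.
#'
#' @param h,w Field dimensions.
#' @param strength Corner attenuation in `[0, 1)`; 0 gives a flat field.
#' @return H x W matrix in `(0, 1]`.
#' @export
vignette_field <- function(h, w, strength) {
  if (strength == 0) return(matrix(1, h, w))
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  d2 <- outer((0:(h - 1) - cr)^2, (0:(w - 1) - cc)^2, "+")
  sigma2 <- max(d2) / (-2 * log(1 - strength))
  exp(-d2 / (2 * sigma2))
}

#' Simulate a pair of correlated intensity line profiles
#'
#' Bivariate Gaussian pairs with population correlation `rho`, shifted and
#' scaled to positive mean intensities — a stand-in for intensity profiles
#' read along a line through a double-stained section.
#'
#' @param n Number of samples along the line (>= 3).
#' @param rho Target population correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @return A `profile_pair` (see [profile_pair()]).
#' @export
simulate_line_profiles <- function(n, rho, seed = 1) {
  if (n < 3) stop("parameter error: n must be >= 3")
  if (abs(rho) > 1) stop("parameter error: rho must be in [-1, 1]")
  .with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    zb <- rho * z1 + sqrt(1 - rho^2) * z2
    profile_pair(distance = seq_len(n) - 1,
                 a = 100 + 25 * z1, b = 100 + 25 * zb)
  })
}

#' Simulate a labeled set of normalized bouton traces
#'
#' Trace-level generator used to validate classification and kinetics
#' without rendering full movies: responders carry the stimulus-train
#' transient, non-responders are flat, all traces receive i.i.d. Gaussian
#' noise (SD in F/F0 units) and are then passed through the real
#' [compute_f_over_f0()] path.
#'
#' @param n Number of traces.
#' @param responder_frac Fraction of responders (rounded to a count).
#' @param stim A [stimulus_protocol()].
#' @param amp_per_stim,tau_decay_s,saturation_cap Transient parameters.
#' @param noise_sd Gaussian noise SD in F/F0 units.
#' @param times_s Sample times covering pre- and post-onset epochs.
#' @param seed Integer seed.
#' @return `list(traces =, labels =, onset_s =)`: normalized traces (times
#'   re-referenced so the last pre-onset sample is 0), true responder
#'   labels, and the re-referenced onset (0).
#' @export
simulate_trace_set <- function(n, responder_frac, stim,
                               amp_per_stim = 0.05, tau_decay_s = 1,
                               saturation_cap = 2, noise_sd = 0.02,
                               times_s = seq(0, 6, by = 0.098), seed = 1) {
  n_resp <- round(n * responder_frac)
  labels <- c(rep(TRUE, n_resp), rep(FALSE, n - n_resp))
  resp <- transient_response(times_s, stim, amp_per_stim, tau_decay_s,
                             saturation_cap)
  .with_seed(seed, {
    labels <- sample(labels)
    traces <- lapply(seq_len(n), function(i) {
      v <- 100 * (1 + (if (labels[i]) resp else 0) +
                    stats::rnorm(length(times_s), sd = noise_sd))
      compute_f_over_f0(trace(times_s, pmax(v, 1e-6), stage = "raw",
                              id = sprintf("roi%03d", i)),
                        stim_onset_s = stim$onset_time_s)
    })
    list(traces = traces, labels = labels, onset_s = 0)
  })
}

#' Random bouton field with minimum spacing
#'
#' Rejection-samples sub-pixel bouton centers inside a margin with a
#' minimum pairwise (Euclidean) spacing.
#'
#' @param n Number of boutons.
#' @param h,w Frame dimensions.
#' @param min_spacing_px Minimum center-to-center distance.
#' @param margin_px Margin kept clear of the frame edges.
#' @param seed Integer seed.
#' @param ... Passed to [bouton_spec()] for every bouton.
#' @return List of [bouton_spec()].
#' @export
random_bouton_field <- function(n, h, w, min_spacing_px = 6, margin_px = 4,
                                seed = 1, ...) {
  .with_seed(seed, {
    centers <- matrix(NA_real_, 0, 2)
    guard <- 0
    while (nrow(centers) < n && guard < 20000) {
      guard <- guard + 1
      cand <- c(stats::runif(1, margin_px, h - 1 - margin_px),
                stats::runif(1, margin_px, w - 1 - margin_px))
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - cand[1])^2 +
                   (centers[, 2] - cand[2])^2)) >= min_spacing_px) {
        centers <- rbind(centers, cand)
      }
    }
    if (nrow(centers) < n) {
      stop("parameter error: could not place ", n,
           " boutons with the requested spacing")
    }
    lapply(seq_len(n), function(i) bouton_spec(center = centers[i, ], ...))
  })
}
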