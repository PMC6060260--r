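# Ground-truth recovery benchmarks. Each function sets up the synthetic
# study conditions, runs the corresponding analysis stage, and returns the
# recovery metrics. They back both the acceptance tests and
# scripts/acceptance.R, so the measured quantities are always produced by
# the same code path.

#' Bleach-correction fidelity benchmark
#'
#' Noiseless arm: a double-exponential bleach control (tau = 5 s / 50 s) is
#' fitted and divisively corrected; the corrected trace should be constant.
#' Noisy arm: controls with Gaussian noise of 2% of the mean over
#' `n_seeds` seeds; the fast time constant should be recovered.
#'
#' @param n_seeds Seeds for the noisy arm.
#' @param base_seed Offset added to every seed.
#' @return `list(flatness_rel =, tau1_rel_err_median =, tau1_rel_err_max =,
#'   n =)`: maximum relative deviation of the corrected noiseless trace
#'   from its mean, and the median/max relative error of tau1 over seeds.
#' @export
benchmark_bleach <- function(n_seeds = 20, base_seed = 0) {
  bleach <- bleach_model(0.6, 5, 0.4, 50, 0)
  shape <- c(200, 1, 1)
  dt <- 0.25                              # 50-s control window
  noiseless <- simulate_bleach_control(
    noise_model(background_level = 100), bleach, shape = shape,
    frame_interval_s = dt, seed = base_seed + 1)
  ctrl <- trace(frame_times(noiseless), as.vector(noiseless$green),
                stage = "raw", id = "ctrl")
  fit0 <- fit_bleach_model(ctrl)
  corr <- correct_bleach(ctrl, fit0)
  flat <- max(abs(corr$values / mean(corr$values) - 1))
  errs <- vapply(seq_len(n_seeds), function(s) {
    st <- simulate_bleach_control(
      noise_model(read_sigma = 2, background_level = 100), bleach,
      shape = shape, frame_interval_s = dt, seed = base_seed + 100 + s)
    tr <- trace(frame_times(st), as.vector(st$green), stage = "raw")
    fit <- fit_bleach_model(tr)
    abs(fit$tau1_s - bleach$tau1_s) / bleach$tau1_s
  }, numeric(1))
  list(flatness_rel = flat, tau1_rel_err_median = stats::median(errs),
       tau1_rel_err_max = max(errs), n = n_seeds)
}

#' F/F0 baseline contract benchmark
#'
#' Random positive traces with random onsets are normalized; the pre-onset
#' mean of every normalized trace must be 1.
#'
#' @param n Number of random traces.
#' @param base_seed Seed.
#' @return `list(max_abs_dev =, n =)`.
#' @export
benchmark_f0_contract <- function(n = 1000, base_seed = 0) {
  devs <- .with_seed(base_seed + 7, {
    vapply(seq_len(n), function(i) {
      len <- sample(20:120, 1)
      dt <- stats::runif(1, 0.02, 0.5)
      times <- (seq_len(len) - 1) * dt
      vals <- stats::runif(len, 10, 1000)
      onset <- times[sample(3:(len - 1), 1)] + dt / 2
      ntr <- compute_f_over_f0(trace(times, vals, stage = "raw"), onset)
      abs(mean(ntr$values[ntr$times_s <= 0]) - 1)
    }, numeric(1))
  })
  list(max_abs_dev = max(devs), n = n)
}

#' Segmentation recovery benchmark
#'
#' Synthetic resting bouton fields (64 x 512, spot amplitude 8x the pixel
#' noise SD of the movie frames, spacing >= 6 px) are temporally averaged
#' over 100 frames and segmented with default parameters; detections are
#' matched to true centers within 2 px.
#'
#' @param n_seeds Number of fields.
#' @param base_seed Seed offset.
#' @param n_boutons Boutons per field.
#' @return `list(recall =, precision =, n =)` (means over fields).
#' @export
benchmark_segmentation <- function(n_seeds = 20, base_seed = 0,
                                   n_boutons = 40) {
  params <- segmentation_params()
  res <- vapply(seq_len(n_seeds), function(s) {
    boutons <- random_bouton_field(n_boutons, 64, 512, min_spacing_px = 6,
                                   margin_px = 5,
                                   seed = base_seed + 1000 + s,
                                   green_rest = 80, responder = FALSE)
    mv <- simulate_movie(boutons, stim = NULL,
                         noise = noise_model(read_sigma = 10,
                                             background_level = 50),
                         bleach = flat_bleach(), shape = c(100, 64, 512),
                         frame_interval_s = 0.098,
                         seed = base_seed + 2000 + s)
    avg <- temporal_average(mv$stack)
    det <- detect_puncta(avg, params)
    truth <- t(vapply(boutons, function(b) b$center, numeric(2)))
    m <- match_puncta(det, truth, radius_px = 2)
    c(m$recall, m$precision)
  }, numeric(2))
  list(recall = mean(res[1, ]), precision = mean(res[2, ]), n = n_seeds)
}

#' Responder-classification recovery benchmark
#'
#' Labeled trace sets (n traces, 30% responders, 10 stimuli at 20 Hz,
#' Gaussian noise in F/F0 units) are classified; on pure-noise sets with
#' `min_response` at 5x the noise SD no responder may be reported.
#'
#' @param n_seeds Trace sets per arm.
#' @param base_seed Seed offset.
#' @param n Traces per set.
#' @param noise_sd Baseline noise SD, F/F0 units.
#' @return `list(prop_abs_err_max =, accuracy_min =, accuracy_mean =,
#'   false_responders =, n =)`.
#' @export
benchmark_classification <- function(n_seeds = 20, base_seed = 0, n = 100,
                                     noise_sd = 0.02) {
  stim <- stimulus_protocol(1, 10, 20)
  prop_err <- numeric(n_seeds); acc <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    set <- simulate_trace_set(n, 0.3, stim, amp_per_stim = 0.05,
                              tau_decay_s = 1, noise_sd = noise_sd,
                              seed = base_seed + 3000 + s)
    res <- classify_responders(set$traces, stim_onset_s = 0,
                               stim_window_s = 2)
    prop_err[s] <- abs(res$proportion - mean(set$labels))
    acc[s] <- mean(res$labels == set$labels)
  }
  false_resp <- 0L
  for (s in seq_len(n_seeds)) {
    set <- simulate_trace_set(n, 0, stim, amp_per_stim = 0,
                              noise_sd = noise_sd,
                              seed = base_seed + 4000 + s)
    res <- classify_responders(set$traces, stim_onset_s = 0,
                               stim_window_s = 2,
                               min_response = 5 * noise_sd)
    false_resp <- false_resp + sum(res$labels)
  }
  list(prop_abs_err_max = max(prop_err), accuracy_min = min(acc),
       accuracy_mean = mean(acc), false_responders = false_resp,
       n = n_seeds)
}

#' Decay-kinetics recovery benchmark
#'
#' Single-exponential decay traces at peak SNR `snr` across a range of
#' time constants; reports the per-tau median relative error of the
#' recovered fast tau and the single/double model-selection rate on
#' true-single traces.
#'
#' @param taus True decay constants, seconds.
#' @param n_seeds Seeds per tau.
#' @param snr Peak amplitude over noise SD.
#' @param base_seed Seed offset.
#' @return `list(tau_rel_err_median =, tau_rel_err_median_worst =,
#'   single_rate =, n =)`; `tau_rel_err_median` is a named vector per tau,
#'   `single_rate` the fraction of fits selecting the single model.
#' @export
benchmark_kinetics <- function(taus = c(0.2, 0.5, 1, 2), n_seeds = 20,
                               snr = 10, base_seed = 0) {
  amp <- 0.5
  dt <- 0.02
  med <- stats::setNames(numeric(length(taus)), paste0("tau", taus))
  singles <- 0L; total <- 0L
  for (k in seq_along(taus)) {
    tau <- taus[k]
    errs <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      errs[s] <- .with_seed(base_seed + 5000 + 97 * k + s, {
        times <- seq(0, 1 + 8, by = dt)
        clean <- ifelse(times >= 1, 1 + amp * exp(-(times - 1) / tau), 1)
        vals <- clean + stats::rnorm(length(times), sd = amp / snr)
        tr <- trace(times, vals, stage = "normalized", f0 = 1)
        pk <- measure_peak(tr, stim_onset_s = 0.9)
        fit <- fit_decay(tr, 0.9 + pk$time_to_peak_s)
        if (fit$model == "single") singles <- singles + 1L
        total <- total + 1L
        abs(fit$fast_tau_s - tau) / tau
      })
    }
    med[k] <- stats::median(errs)
  }
  list(tau_rel_err_median = med, tau_rel_err_median_worst = max(med),
       single_rate = singles / total, n = n_seeds)
}

#' Flat-field and stitching benchmark
#'
#' Uniform-truth tiles under a strength-0.5 vignette (noiseless): the
#' reference should match the true vignette and correction should flatten
#' the tiles; exact noiseless crops of a structured truth should stitch
#' back to the truth.
#'
#' @param base_seed Seed (used for the structured stitching truth).
#' @return `list(cv_reduction =, ref_correlation =, stitch_max_abs_err =)`.
#' @export
benchmark_flatfield <- function(base_seed = 0) {
  layout <- plan_mosaic_layout(c(1000, 1000), 3, 3, overlap_frac = 0.15)
  truth_u <- matrix(100, 1000, 1000)
  grid <- simulate_tile_grid(truth_u, layout, vignette_strength = 0.5,
                             noise = noise_model(), seed = base_seed + 11)
  ref <- build_flatfield_reference(grid$tiles, kernel_px = 121)
  cv <- function(x) stats::sd(x) / mean(x)
  cv_unc <- mean(vapply(grid$tiles, cv, numeric(1)))
  cv_cor <- mean(vapply(grid$tiles,
                        function(tl) cv(apply_flatfield(tl, ref)),
                        numeric(1)))
  rho <- stats::cor(as.vector(ref$image), as.vector(grid$truth$vignette))
  truth_s <- .with_seed(base_seed + 12, {
    .gaussian_blur(matrix(stats::rnorm(1000 * 1000), 1000, 1000), 6) * 40 +
      200
  })
  grid2 <- simulate_tile_grid(truth_s, layout, vignette_strength = 0,
                              noise = noise_model(), seed = base_seed + 13)
  mosaic <- stitch_grid(grid2$tiles, layout)
  err <- max(abs(mosaic - truth_s[seq_len(nrow(mosaic)),
                                  seq_len(ncol(mosaic))]))
  list(cv_reduction = cv_unc / cv_cor, ref_correlation = rho,
       stitch_max_abs_err = err)
}

#' Pipeline determinism benchmark
#'
#' Runs the end-to-end pipeline twice with an identical config + seed and
#' compares the output checksums.
#'
#' @param seed Pipeline seed.
#' @param dir Scratch directory for the two runs (default a tempdir).
#' @return `list(identical =, n_outputs =)`.
#' @export
benchmark_determinism <- function(seed = 1, dir = tempfile("detrun")) {
  cfg <- pipeline_config(seed = seed)
  r1 <- run_pipeline(cfg, file.path(dir, "run1"))
  r2 <- run_pipeline(cfg, file.path(dir, "run2"))
  list(identical = identical(unname(unlist(r1$checksums)),
                             unname(unlist(r2$checksums))),
       n_outputs = length(r1$checksums))
}
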