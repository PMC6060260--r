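# End-to-end pipeline: synthetic acquisition (or a stack on disk) through
# bleach correction, segmentation, F/F0, classification and kinetics, with
# a manifest that makes any output traceable to a config + seed.

#' Default pipeline configuration
#'
#' A nested list with one section per stage; every parameter has a default
#' so a config serializes and reproduces a run exactly. Override any entry
#' via `...` using the same nesting, e.g.
#' `pipeline_config(synthetic = list(n_boutons = 20))` (unnamed entries of
#' a section fall back to defaults).
#'
#' @param seed Integer seed for the whole run.
#' @param ... Named sections whose named entries override the defaults.
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    synthetic = list(
      n_boutons = 30, responder_frac = 0.4, shape = c(80, 64, 256),
      frame_interval_s = 0.098, min_spacing_px = 6, margin_px = 5,
      psf_sigma_px = 1.5, green_rest = 100, red_level = 150,
      amp_per_stim = 0.06, tau_decay_s = 1, saturation_cap = 2,
      stim = list(onset_time_s = 2, n_stimuli = 10, frequency_hz = 20,
                  intensity_v = 20),
      noise = list(photon_gain = 0, read_sigma = 4, background_level = 50,
                   background_smoothness_px = 0),
      bleach = list(a1 = 0.15, tau1_s = 5, a2 = 0.1, tau2_s = 50,
                    c = 0.75),
      control_frames = 120),
    segmentation = list(k_sd = 3, min_area_px = 2, max_area_px = 100,
                        connectivity = 8, background_offset_px = 4),
    classification = list(stim_window_s = 2, min_response = NA),
    kinetics = list(auc_duration_s = 2, slope_points = 3,
                    fit_decay = TRUE))
  over <- list(...)
  for (sec in names(over)) {
    for (key in names(over[[sec]])) cfg[[sec]][[key]] <- over[[sec]][[key]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / parse a pipeline config (YAML)
#'
#' Round trip is byte-identical: `config_to_yaml(parse_config(s))`
#' reproduces `s`.
#'
#' @param config A [pipeline_config()].
#' @return YAML string.
#' @export
config_to_yaml <- function(config) {
  yaml::as.yaml(unclass(config))
}

#' @rdname config_to_yaml
#' @param text YAML string produced by [config_to_yaml()].
#' @export
parse_config <- function(text) {
  cfg <- yaml::yaml.load(text)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic acquisition
#'
#' Generates a bleach-only control and a stimulated movie from the config,
#' then runs: bleach model fit on the control -> divisive bleach correction
#' -> temporal-average segmentation (Laplacian SD threshold) -> 3x3
#' background ROI selection -> trace extraction -> background subtraction
#' -> F/F0 -> responder classification -> kinetic summaries for responders.
#' All tables are written under `output_dir` together with a manifest
#' (config echo, seed, md5 checksum per output file): identical config +
#' seed give identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a summary list: `n_rois`, `n_responders`,
#'   `proportion`, `bleach`, `manifest_path`, `checksums`.
#' @export
run_pipeline <- function(config, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  syn <- config$synthetic
  stim <- stimulus_protocol(syn$stim$onset_time_s, syn$stim$n_stimuli,
                            syn$stim$frequency_hz, syn$stim$intensity_v)
  noise <- noise_model(syn$noise$photon_gain, syn$noise$read_sigma,
                       syn$noise$background_level,
                       syn$noise$background_smoothness_px)
  bl <- syn$bleach
  bleach <- bleach_model(bl$a1, bl$tau1_s, bl$a2, bl$tau2_s, bl$c)
  boutons <- random_bouton_field(
    syn$n_boutons, syn$shape[2], syn$shape[3], syn$min_spacing_px,
    syn$margin_px, seed = config$seed + 101,
    psf_sigma_px = syn$psf_sigma_px, green_rest = syn$green_rest,
    red_level = syn$red_level, amp_per_stim = syn$amp_per_stim,
    tau_decay_s = syn$tau_decay_s, saturation_cap = syn$saturation_cap)
  n_resp <- round(syn$n_boutons * syn$responder_frac)
  resp_lab <- rep(c(TRUE, FALSE),
                  c(n_resp, syn$n_boutons - n_resp))
  for (i in seq_along(boutons)) boutons[[i]]$responder <- resp_lab[i]

  # stage 1: control acquisition and bleach model
  control <- simulate_bleach_control(
    noise, bleach, shape = c(syn$control_frames, syn$shape[2],
                             syn$shape[3]),
    frame_interval_s = syn$frame_interval_s, seed = config$seed + 202)
  ctrl_trace <- trace(frame_times(control),
                      apply(control$green, 1, mean), stage = "raw",
                      id = "control_frame_mean")
  bfit <- fit_bleach_model(ctrl_trace)

  # stage 2: stimulated acquisition
  movie <- simulate_movie(boutons, stim, noise, bleach, shape = syn$shape,
                          frame_interval_s = syn$frame_interval_s,
                          seed = config$seed + 303)
  stack <- movie$stack

  # stage 3: segmentation on the temporal average
  seg <- config$segmentation
  params <- segmentation_params(seg$k_sd, seg$min_area_px, seg$max_area_px,
                                seg$connectivity)
  avg <- temporal_average(stack)
  puncta <- detect_puncta(avg, params)
  bg_rois <- pick_background_rois(puncta, dim(avg), seg$background_offset_px,
                                  seed = config$seed + 404)

  # stage 4: traces -> bleach correction -> background subtraction -> F/F0
  raw <- extract_traces(stack, puncta)
  bg_raw <- extract_traces(stack, bg_rois)
  bg_by_id <- stats::setNames(bg_raw,
                              sub("^bg_", "", vapply(bg_raw, `[[`, "", "id")))
  norm <- list()
  kept <- character(0)
  for (tr in raw) {
    corr <- correct_bleach(tr, bfit)
    if (!is.null(bg_by_id[[tr$id]])) {
      corr <- subtract_background(corr, correct_bleach(bg_by_id[[tr$id]],
                                                       bfit))
    }
    ntr <- try(compute_f_over_f0(corr, stim$onset_time_s), silent = TRUE)
    if (!inherits(ntr, "try-error")) {
      norm[[length(norm) + 1]] <- ntr
      kept <- c(kept, tr$id)
    }
  }

  # stage 5: classification and kinetics
  cls <- config$classification
  min_resp <- if (is.na(cls$min_response)) NULL else cls$min_response
  if (length(norm)) {
    res <- classify_responders(norm, stim_onset_s = 0,
                               stim_window_s = cls$stim_window_s,
                               min_response = min_resp)
  } else {
    res <- list(labels = logical(0), proportion = 0, n_total = 0L)
  }
  kin <- config$kinetics
  kin_rows <- lapply(which(res$labels), function(i)
    kinetics_summary(norm[[i]], stim_onset_s = 0,
                     auc_duration_s = kin$auc_duration_s,
                     slope_points = kin$slope_points,
                     fit_decay_model = kin$fit_decay))
  kin_df <- if (length(kin_rows)) do.call(rbind, kin_rows) else
    data.frame(roi_id = character(), peak = numeric(),
               time_to_peak_s = numeric(), initial_slope_per_s = numeric(),
               fast_tau_s = numeric(), decay_model = character(),
               auc = numeric(), stringsAsFactors = FALSE)

  # stage 6: outputs and manifest
  paths <- c(rois = file.path(output_dir, "rois.csv"),
             traces = file.path(output_dir, "traces_normalized.csv"),
             labels = file.path(output_dir, "labels.csv"),
             kinetics = file.path(output_dir, "kinetics.csv"),
             bleach = file.path(output_dir, "bleach_model.json"))
  write_rois(puncta, paths["rois"])
  write_traces(norm, paths["traces"])
  utils::write.csv(data.frame(roi_id = kept, responder = res$labels,
                              stringsAsFactors = FALSE),
                   paths["labels"], row.names = FALSE)
  utils::write.csv(kin_df, paths["kinetics"], row.names = FALSE)
  jsonlite::write_json(bfit[c("a1", "tau1_s", "a2", "tau2_s", "c", "form")],
                       paths["bleach"], auto_unbox = TRUE, digits = NA)
  sums <- as.list(tools::md5sum(unname(paths)))
  names(sums) <- basename(names(sums))
  manifest <- list(config = unclass(config), seed = config$seed,
                   n_rois = length(puncta),
                   n_traces = length(norm),
                   n_responders = sum(res$labels),
                   proportion = res$proportion,
                   checksums = sums)
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(n_rois = length(puncta), n_responders = sum(res$labels),
                 proportion = res$proportion, bleach = bfit,
                 truth = movie$truth, manifest_path = manifest_path,
                 checksums = sums))
}
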