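#!/usr/bin/env Rscript
# Single-bouton analysis: Laplacian-threshold segmentation of the temporal
# average, background ROI selection, bleach-corrected background-subtracted
# F/F0 traces, and responder classification, scored against ground truth.
# Requires 01_simulate.R and 02_bleach_correction.R.

library(boutonca)
dat <- "results/data"
out <- "results/boutons"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

stack <- read_stack(file.path(dat, "movie.tif"), file.path(dat, "movie.yml"))
truth <- jsonlite::read_json(file.path(dat, "ground_truth.json"),
                             simplifyVector = TRUE)
bl <- jsonlite::read_json(file.path("results/bleach", "bleach_model.json"))
model <- bleach_model(bl$a1, bl$tau1_s, bl$a2, bl$tau2_s, bl$c)

avg <- temporal_average(stack)
puncta <- detect_puncta(avg, segmentation_params())
m <- match_puncta(puncta, truth$centers, radius_px = 2)
cat(sprintf("detected %d puncta (true %d): recall %.2f precision %.2f\n",
            length(puncta), nrow(truth$centers), m$recall, m$precision))

bg_rois <- pick_background_rois(puncta, dim(avg), offset_px = 4, seed = seed)
raw <- extract_traces(stack, puncta)
bg <- extract_traces(stack, bg_rois)
bg_ids <- sub("^bg_", "", vapply(bg, function(r) r$id, character(1)))
norm <- list()
for (tr in raw) {
  corr <- correct_bleach(tr, model)
  j <- match(tr$id, bg_ids)
  if (!is.na(j)) corr <- subtract_background(corr, correct_bleach(bg[[j]],
                                                                  model))
  norm[[length(norm) + 1]] <- compute_f_over_f0(corr,
                                                stack$stim$onset_time_s)
}
res <- classify_responders(norm, stim_onset_s = 0, stim_window_s = 2)
cat(sprintf("responder proportion: %.2f (%d / %d ROIs); true fraction %.2f\n",
            res$proportion, sum(res$labels), res$n_total,
            mean(truth$responder)))

write_rois(puncta, file.path(out, "rois.csv"),
           file.path(out, "roi_pixels.json"))
write_traces(norm, file.path(out, "traces_ff0.csv"))
utils::write.csv(
  data.frame(roi_id = vapply(norm, function(t) t$id, character(1)),
             responder = res$labels),
  file.path(out, "labels.csv"), row.names = FALSE)
raster <- build_raster(norm, sort_by = "peak")
utils::write.csv(raster, file.path(out, "raster_ff0.csv"),
                 row.names = FALSE)
cat(sprintf("wrote %d F/F0 traces and the peak-sorted %dx%d raster to %s\n",
            length(norm), nrow(raster), ncol(raster), out))
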