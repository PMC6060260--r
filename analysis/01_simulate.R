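#!/usr/bin/env Rscript
# Generate the synthetic study data: a stimulated two-channel bouton movie,
# its no-stimulus bleach control, and the ground-truth record. Writes the
# acquisition as an interleaved 16-bit TIFF + YAML sidecar, the way a real
# acquisition would arrive.

library(boutonca)
seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

stim <- stimulus_protocol(onset_time_s = 2, n_stimuli = 10,
                          frequency_hz = 20, intensity_v = 20)
noise <- noise_model(read_sigma = 4, background_level = 50)
bleach <- bleach_model(0.15, 5, 0.1, 50, 0.75)
boutons <- random_bouton_field(30, 64, 256, min_spacing_px = 6,
                               margin_px = 5, seed = seed,
                               green_rest = 100, amp_per_stim = 0.06)
n_resp <- 12                              # 40% responders
for (i in seq_along(boutons)) boutons[[i]]$responder <- i <= n_resp

mv <- simulate_movie(boutons, stim, noise, bleach,
                     shape = c(80, 64, 256), frame_interval_s = 0.098,
                     seed = seed + 1)
ctl <- simulate_bleach_control(noise, bleach, shape = c(120, 64, 256),
                               frame_interval_s = 0.098, seed = seed + 2)

write_stack(mv$stack, file.path(out, "movie.tif"),
            file.path(out, "movie.yml"))
write_stack(ctl, file.path(out, "control.tif"),
            file.path(out, "control.yml"))
truth <- list(
  seed = seed,
  centers = lapply(mv$truth$boutons, function(b) b$center),
  responder = mv$truth$responder,
  bleach = mv$truth$bleach_green[c("a1", "tau1_s", "a2", "tau2_s", "c")])
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote %d-frame movie (%d boutons, %d responders) and %d-frame control to %s\n",
            dim(mv$stack$green)[1], length(boutons), n_resp,
            dim(ctl$green)[1], out))
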