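#!/usr/bin/env Rscript
# Transient kinetics of responding boutons and stimulus-response curves:
# per-ROI peak / time-to-peak / initial slope / fast decay tau / 2-s AUC,
# a sigmoidal fit of responder recruitment versus stimulus intensity, and
# a linear fit of the sub-saturating response range.

library(boutonca)
out <- "results/kinetics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

# per-ROI kinetics of the responders found in 03_single_boutons.R
norm <- read_traces("results/boutons/traces_ff0.csv")
labels <- utils::read.csv("results/boutons/labels.csv")
rows <- lapply(norm[labels$responder], kinetics_summary, stim_onset_s = 0)
kin <- do.call(rbind, rows)
utils::write.csv(kin, file.path(out, "kinetics_responders.csv"),
                 row.names = FALSE)
cat(sprintf("kinetics of %d responders: mean peak %.3f, mean fast tau %.2f s, mean 2-s AUC %.3f\n",
            nrow(kin), mean(kin$peak), mean(kin$fast_tau_s, na.rm = TRUE),
            mean(kin$auc)))

# responder recruitment versus stimulus intensity: boutons are recruited
# with a sigmoidal dependence on intensity; classify at each intensity and
# fit the recruitment curve
intensities <- seq(0, 70, by = 10)
true_frac <- 0.8 / (1 + exp((30 - intensities) / 8))
prop <- vapply(seq_along(intensities), function(i) {
  stim <- stimulus_protocol(1, 10, 20, intensity_v = intensities[i])
  set <- simulate_trace_set(60, true_frac[i], stim, amp_per_stim = 0.05,
                            noise_sd = 0.02, seed = seed + 10 * i)
  classify_responders(set$traces, 0, 2)$proportion
}, numeric(1))
sig <- fit_sigmoid(intensities, prop)
utils::write.csv(data.frame(intensity_v = intensities,
                            true_fraction = true_frac,
                            proportion = prop),
                 file.path(out, "recruitment_curve.csv"), row.names = FALSE)
cat(sprintf("sigmoid fit of recruitment: base %.3f top %.3f x50 %.1f V rate %.1f V (truth 0 / 0.8 / 30 / 8)\n",
            sig$base, sig$top, sig$x50, sig$rate))

# linear sub-range: mean peak response versus intensity is linear below
# saturation; fit below the 50-V cutoff
set.seed(seed)
peak_resp <- 0.02 * pmin(intensities, 50) +
  stats::rnorm(length(intensities), 0, 0.01)
lin <- fit_linear_range(intensities, peak_resp, x_max = 50)
cat(sprintf("linear fit below 50 V: slope %.4f /V, intercept %.3f, r %.3f\n",
            lin$slope, lin$intercept, lin$r))
utils::write.csv(data.frame(intensity_v = intensities, peak = peak_resp,
                            below_cutoff = intensities < 50),
                 file.path(out, "linear_range.csv"), row.names = FALSE)
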