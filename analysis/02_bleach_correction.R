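#!/usr/bin/env Rscript
# Fit the photobleach model on the no-stimulus control and verify that
# divisive correction flattens it. Requires 01_simulate.R to have run.

library(boutonca)
dat <- "results/data"
out <- "results/bleach"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ctl <- read_stack(file.path(dat, "control.tif"),
                  file.path(dat, "control.yml"))
ctrl_trace <- trace(frame_times(ctl), apply(ctl$green, 1, mean),
                    id = "control_frame_mean")
model <- fit_bleach_model(ctrl_trace)
corrected <- correct_bleach(ctrl_trace, model)
flatness <- stats::sd(corrected$values) / mean(corrected$values)
truth <- jsonlite::read_json(file.path(dat, "ground_truth.json"))

jsonlite::write_json(model[c("a1", "tau1_s", "a2", "tau2_s", "c", "form")],
                     file.path(out, "bleach_model.json"),
                     auto_unbox = TRUE, digits = NA)
write_traces(list(ctrl_trace, corrected), file.path(out, "control_traces.csv"))

cat(sprintf("fitted %s bleach model: a1=%.3f tau1=%.2fs a2=%.3f tau2=%.1fs c=%.3f\n",
            model$form, model$a1, model$tau1_s, model$a2, model$tau2_s,
            model$c))
cat(sprintf("true model:              a1=%.3f tau1=%.2fs a2=%.3f tau2=%.1fs c=%.3f\n",
            truth$bleach$a1, truth$bleach$tau1_s, truth$bleach$a2,
            truth$bleach$tau2_s, truth$bleach$c))
cat(sprintf("corrected control CV: %.2e (raw CV %.2e)\n", flatness,
            stats::sd(ctrl_trace$values) / mean(ctrl_trace$values)))
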