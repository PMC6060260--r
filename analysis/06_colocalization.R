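#!/usr/bin/env Rscript
# Line-profile Pearson colocalization, emulating the marker-pair regimes of
# interest: strong presynaptic co-variation, strong vesicular-marker
# overlap, and absent postsynaptic overlap.

library(boutonca)
out <- "results/colocalization"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

pairs <- data.frame(
  comparison = c("red_vs_presynaptic", "red_vs_vesicular_glut",
                 "red_vs_vesicular_gaba", "red_vs_postsynaptic"),
  rho = c(0.94, 0.96, 0.92, 0.17),
  n = c(400, 400, 400, 120))

rows <- lapply(seq_len(nrow(pairs)), function(i) {
  p <- simulate_line_profiles(pairs$n[i], pairs$rho[i], seed = seed + i)
  res <- pearson_profile(p)
  data.frame(comparison = pairs$comparison[i], target_rho = pairs$rho[i],
             n = res$n, r = res$r, p_value = res$p)
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(out, "pearson_colocalization.csv"),
                 row.names = FALSE)
for (i in seq_len(nrow(tab))) {
  cat(sprintf("%-24s target rho %.2f -> r = %.3f (p = %.2g, n = %d)\n",
              tab$comparison[i], tab$target_rho[i], tab$r[i],
              tab$p_value[i], tab$n[i]))
}
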