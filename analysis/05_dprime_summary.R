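#!/usr/bin/env Rscript
# Summarise the benchmark records on the d-prime scale: per-condition
# median sensitivity of each model, and each alternative model's d-prime
# plotted (numerically) against the V1-simple model for the same
# condition. Run after analysis/03_benchmark_grid.R.
#
# Writes: results/dprime_summary.csv, results/dprime_vs_simple.csv

suppressPackageStartupMessages(library(earlyvision))

records <- load_results("results/benchmark_records.csv")
med <- summarize_grid(records)
write.csv(med, "results/dprime_summary.csv", row.names = FALSE)

wide <- stats::reshape(
  med[, c("model", "background", "scale_min", "rot_max", "median_d_prime")],
  idvar = c("background", "scale_min", "rot_max"),
  timevar = "model", direction = "wide")
names(wide) <- sub("median_d_prime\\.", "dprime_", names(wide))
if (!is.null(wide$dprime_simple)) {
  for (other in intersect(c("dprime_complex", "dprime_linear", "dprime_lgn"),
                          names(wide)))
    wide[[paste0(other, "_minus_simple")]] <-
      wide[[other]] - wide$dprime_simple
}
write.csv(wide, "results/dprime_vs_simple.csv", row.names = FALSE)
print(wide, digits = 3, row.names = FALSE)
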