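#!/usr/bin/env Rscript
# Simulated lesions of the V1-simple model under the reference condition
# (blurred-scene background, scaling to 50%, rotation to 45 degrees):
#   1. the full model, with per-repeat readout weights collected;
#   2. spatial-frequency channel knockouts (drop each single channel);
#   3. weight-sign-consistency selections: keep only units whose readout
#      weight sign was identical across all (or most) full-model repeats.
#
# Runtime: roughly 15-25 minutes on one CPU.
# Writes: results/lesion_records.csv, results/lesion_summary.csv,
#         results/consistent_units.json

suppressPackageStartupMessages(library(earlyvision))
dir.create("results", showWarnings = FALSE)

bc <- benchmark_config()
pool <- make_pool(bc$n_per_class, seed = bc$pool_seed)
scenes <- make_scene_pool(bc$scene_pool_n, seed = bc$scene_pool_seed)
bspec <- background_spec(bc$lesion$background, scene_pool = scenes)
nspec <- nuisance_spec(bc$lesion$scale_min, bc$lesion$rot_max)

message("full model under the reference condition (collecting weights)...")
base <- run_benchmark("lesion", pool = pool, scene_pool = scenes,
                      progress = TRUE)
W <- attr(base, "weights")[[1]]$simple
base$lesion <- "none"
all_rec <- list(base)

message("single-channel knockouts...")
for (ch in 1:4) {
  r <- run_lesion_experiment("simple", lesion_spec("drop_channels", ch),
                             pool, bspec, nspec,
                             base_seed = bc$lesion$base_seed, cfg = bc$cfg,
                             eval_per_class = bc$eval_per_class,
                             n_repeats = bc$n_repeats)
  all_rec[[length(all_rec) + 1L]] <- r
}

message("weight-sign-consistency lesions...")
kept_sets <- list()
for (t in c(bc$n_repeats, bc$n_repeats - 1L)) {
  for (mode in c("keep_consistent", "drop_consistent")) {
    r <- run_lesion_experiment("simple",
                               lesion_spec(mode, consistency_threshold = t),
                               pool, bspec, nspec,
                               base_seed = bc$lesion$base_seed, cfg = bc$cfg,
                               eval_per_class = bc$eval_per_class,
                               n_repeats = bc$n_repeats, base_weights = W)
    all_rec[[length(all_rec) + 1L]] <- r
    if (mode == "keep_consistent")
      kept_sets[[paste0("threshold_", t)]] <- attr(r, "kept_units")
  }
}

records <- do.call(rbind, all_rec)
save_results(records, "results/lesion_records.csv",
             base_seed = bc$lesion$base_seed)
med <- stats::aggregate(percent_correct ~ lesion, records, median)
names(med)[2] <- "median_percent_correct"
med$n_units <- c(setNames(vapply(kept_sets, length, 0L),
                          paste0("keep_consistent:t",
                                 sub("threshold_", "", names(kept_sets)))),
                 none = 7088)[med$lesion]
write.csv(med, "results/lesion_summary.csv", row.names = FALSE)
print(med, digits = 3, row.names = FALSE)
jsonlite::write_json(lapply(kept_sets, as.integer),
                     "results/consistent_units.json")
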