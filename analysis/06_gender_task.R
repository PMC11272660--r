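#!/usr/bin/env Rscript
# Fine-discrimination control task: classify male-like vs female-like
# synthetic faces with the V1-simple encoder, using the early-stopping
# protocol (train/validation/test split 50/10/40, up to 40 epochs, stop
# after 5 non-improving validation epochs). The gender differences in the
# generator are deliberately subtle, so performance sits far below the
# face/non-face task and collapses under large scale/rotation variation.
#
# Runtime: tens of minutes on one CPU (early stopping decides the epochs).
# Writes: results/gender_records.csv

suppressPackageStartupMessages(library(earlyvision))
dir.create("results", showWarnings = FALSE)

n_per_class <- 400L
n_repeats <- 3L
val_per_class <- 40L   # 10% of the pool per class (protocol uses the
                       # validation subset, scaled with the synthetic pool)
pool <- make_pool(n_per_class, task = "gender", seed = 4242)
scenes <- make_scene_pool(30, seed = 7)
cfg <- train_config("earlystop", per_class = 400L,
                    val_per_class = val_per_class)
banks <- list(simple = build_bank("simple"))

conditions <- list(
  list(bspec = background_spec("mid_gray"), nspec = nuisance_spec(1, 0)),
  list(bspec = background_spec("scene_blurred", scene_pool = scenes),
       nspec = nuisance_spec(0.5, 45)))

rows <- list()
for (cond in conditions) {
  for (i in seq_len(n_repeats)) {
    seed_i <- 9000L + i
    sp <- make_split(n_per_class, "tvt", seed = seed_i)
    train_pool <- earlyvision:::pool_subset(pool, sp$train)
    val_idx <- lapply(sp$validation, function(ix)
      earlyvision:::with_seed(seed_i, sample(ix, val_per_class)))
    val_pool <- earlyvision:::pool_subset(pool, val_idx)
    test_pool <- earlyvision:::pool_subset(pool, sp$test)
    fit <- train_readouts(banks, train_pool, cond$bspec, cond$nspec, cfg,
                          seed = seed_i, val_pool = val_pool)
    rec <- evaluate_readouts(fit, banks, test_pool, cond$bspec, cond$nspec,
                             n_per_class = 300L, seed = seed_i)
    rec$background <- cond$bspec$kind
    rec$scale_min <- cond$nspec$scale_min
    rec$rot_max <- cond$nspec$rot_max
    rec$rep <- i
    rec$seed <- seed_i
    rec$epochs_run <- fit$simple$epochs_run
    rows[[length(rows) + 1L]] <- rec
    message(sprintf("%s s%.1f r%d rep %d: %.3f (%d epochs)",
                    cond$bspec$kind, cond$nspec$scale_min,
                    cond$nspec$rot_max, i, rec$percent_correct,
                    fit$simple$epochs_run))
  }
}
records <- do.call(rbind, rows)
save_results(records, "results/gender_records.csv", base_seed = 9000)
print(stats::aggregate(percent_correct ~ background + rot_max, records,
                       median), digits = 3)
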