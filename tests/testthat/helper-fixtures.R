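# Shared fixtures, memoised across test files (testthat sources helpers
# once per run, so expensive objects are built at most once).

.ev_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.ev_cache[[name]])) .ev_cache[[name]] <- force(expr)
  .ev_cache[[name]]
}

new_stimulus_for_test <- function(pixels, alpha, label = "face") {
  earlyvision:::new_stimulus(pixels, alpha, label)
}

bank_of <- function(kind) {
  cached(paste0("bank_", kind), build_bank(kind))
}

# a small labelled pool for pipeline tests that train for real
tiny_pool <- function() cached("tiny_pool", make_pool(6, seed = 99))

# a fast training configuration for plumbing tests
tiny_cfg <- function() train_config("fixed", epochs = 1L, per_class = 4L,
                                    batch_size = 4L)

# Monte-Carlo stimulus samples reused by several statistical tests
face_samples <- function(n = 500) cached("face_samples", {
  lapply(seq_len(n), function(i) gen_face(seed = i))
})

nonface_samples <- function(n = 500) cached("nonface_samples", {
  lapply(seq_len(n), function(i) gen_nonface(seed = i + 10000))
})

stats_of <- function(stims) {
  vapply(stims, function(s) unlist(stim_stats(s)), numeric(4))
}

# direct dot-product oracle for one placement/kernel of a bank channel,
# independent of the package's separable correlation path
oracle_response <- function(canvas, bank, ci, gr, gc, kcol) {
  ch <- bank$channels[[ci]]
  S <- ch$support
  n1 <- ch$n1
  stopifnot(gr <= n1, gc <= n1)
  orow <- ch$offsets[gr] - ch$pad
  ocol <- ch$offsets[gc] - ch$pad
  x <- canvas * bank$gain / 255
  km <- matrix(ch$kernels[, kcol], S, S)
  rows <- (orow + 1):(orow + S)
  cols <- (ocol + 1):(ocol + S)
  vr <- rows >= 1 & rows <= nrow(x)
  vc <- cols >= 1 & cols <= ncol(x)
  sum(x[rows[vr], cols[vc], drop = FALSE] * km[vr, vc, drop = FALSE])
}

# packaged-benchmark records, computed once and shared by the acceptance
# tests (ordering, rotation series, lesion base with collected weights)
bench_ordering <- function() cached("bench_ordering", {
  run_benchmark("ordering", pool = bench_pool())
})

bench_rotation <- function() cached("bench_rotation", {
  run_benchmark("rotation", pool = bench_pool())
})

bench_lesion_base <- function() cached("bench_lesion_base", {
  run_benchmark("lesion", pool = bench_pool(),
                scene_pool = bench_scenes())
})

bench_pool <- function() cached("bench_pool", {
  bc <- benchmark_config()
  make_pool(bc$n_per_class, seed = bc$pool_seed)
})

bench_scenes <- function() cached("bench_scenes", {
  bc <- benchmark_config()
  make_scene_pool(bc$scene_pool_n, seed = bc$scene_pool_seed)
})

median_pc <- function(records, model_kind) {
  median(records$percent_correct[records$model == model_kind])
}
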