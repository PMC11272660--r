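#' The packaged reduced-scale synthetic benchmark
#'
#' The canonical configuration under which this package's ordering and
#' lesion claims are made: a 200-per-class synthetic face/non-face pool,
#' the fixed training protocol scaled down to 5 epochs with 300 resamples
#' per class per epoch, 300 evaluation resamples per class, and 10
#' independent split/train/test repeats per condition. Three parts are
#' defined: `ordering` (all four model kinds on a mid-gray background with
#' jitter only), `rotation` (the V1-simple model on mid-gray at 50%
#' scaling across the five rotation levels), and `lesion` (the reference
#' lesion condition: blurred-scene background, 50% scaling, 45 degree
#' rotation). Problem sizes are fixed here so every claim is reproducible
#' from the seeds below.
#'
#' @return a list of benchmark settings.
#' @export
benchmark_config <- function() {
  list(
    n_per_class = 200L,
    pool_seed = 42L,
    cfg = train_config("fixed", epochs = 5L, per_class = 300L),
    eval_per_class = 300L,
    n_repeats = 10L,
    scene_pool_n = 50L,
    scene_pool_seed = 7L,
    ordering = list(base_seed = 100L,
                    models = c("simple", "complex", "linear", "lgn"),
                    background = "mid_gray", scale_min = 1.0, rot_max = 0),
    rotation = list(base_seed = 200L, models = "simple",
                    background = "mid_gray", scale_min = 0.5,
                    rot_levels = c(0, 15, 45, 90, 180)),
    lesion = list(base_seed = 300L, model = "simple",
                  background = "scene_blurred", scale_min = 0.5,
                  rot_max = 45)
  )
}

#' Run one part of the packaged benchmark
#'
#' @param part `"ordering"`, `"rotation"` or `"lesion"` (the lesion part
#'   here runs the full model under the reference condition and collects
#'   the per-repeat weights needed by consistency lesions).
#' @param pool optional pregenerated pool (defaults to the benchmark pool).
#' @param scene_pool optional scene pool for scene backgrounds.
#' @param progress passed to [run_grid()].
#' @return the [run_grid()] record table (with weights attached for the
#'   lesion part).
#' @export
run_benchmark <- function(part = c("ordering", "rotation", "lesion"),
                          pool = NULL, scene_pool = NULL, progress = FALSE) {
  part <- match.arg(part)
  bc <- benchmark_config()
  if (is.null(pool)) pool <- make_pool(bc$n_per_class, seed = bc$pool_seed)
  pp <- bc[[part]]
  needs_scene <- pp$background %in% c("scene_high_contrast", "scene_blurred")
  if (needs_scene && is.null(scene_pool))
    scene_pool <- make_scene_pool(bc$scene_pool_n, seed = bc$scene_pool_seed)
  bspec <- background_spec(pp$background,
                           scene_pool = if (needs_scene) scene_pool)
  grid <- condition_grid(
    backgrounds = list(bspec),
    scale_levels = pp$scale_min,
    rot_levels = if (part == "rotation") pp$rot_levels else pp$rot_max,
    n_repeats = bc$n_repeats)
  run_grid(grid, if (part == "lesion") pp$model else pp$models, pool,
           base_seed = pp$base_seed, cfg = bc$cfg,
           eval_per_class = bc$eval_per_class,
           collect_weights = (part == "lesion"), progress = progress)
}
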