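#' Lesion specification
#'
#' Describes a simulated lesion of a filter bank: removal or exclusive
#' retention of whole spatial-frequency channels (`drop_channels`,
#' `keep_channels`), or selection by weight-sign consistency across the
#' repeats of a completed full-model experiment (`keep_consistent`,
#' `drop_consistent`), where a unit survives the selection iff its trained
#' readout weight had the same nonzero sign in at least
#' `consistency_threshold` of the runs.
#'
#' @param mode one of `"drop_channels"`, `"keep_channels"`,
#'   `"keep_consistent"`, `"drop_consistent"`.
#' @param channels integer subset of 1:4 (1 = lowest spatial frequency,
#'   wavelength 256 px) for the channel modes.
#' @param consistency_threshold integer in `[1, n_runs]` for the
#'   consistency modes.
#' @return an object of class `ev_lesion_spec`.
#' @export
lesion_spec <- function(mode = c("drop_channels", "keep_channels",
                                 "keep_consistent", "drop_consistent"),
                        channels = integer(0),
                        consistency_threshold = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("drop_channels", "keep_channels")) {
    channels <- as.integer(channels)
    if (length(channels) == 0 || !all(channels %in% 1:4))
      stop_param("channels must be a nonempty subset of 1:4")
  } else {
    if (is.null(consistency_threshold) || consistency_threshold < 1)
      stop_param("consistency modes require a threshold >= 1")
  }
  structure(list(mode = mode, channels = unique(channels),
                 consistency_threshold = consistency_threshold),
            class = "ev_lesion_spec")
}

#' Remove or retain whole spatial-frequency channels of a bank
#'
#' Returns a bank restricted to the kept channels; surviving kernels,
#' placements and unit ordering are untouched, only units are removed. The
#' downstream readout must be re-initialised and retrained on the reduced
#' bank.
#'
#' @param bank an [build_bank()] object.
#' @param spec an [lesion_spec()] with a channel mode.
#' @return a lesioned `ev_bank` whose `unit_count` equals the surviving
#'   units.
#' @export
apply_channel_lesion <- function(bank, spec) {
  if (!inherits(spec, "ev_lesion_spec") ||
      !spec$mode %in% c("drop_channels", "keep_channels"))
    stop_param("spec must be a channel-mode ev_lesion_spec")
  keep_ch <- if (spec$mode == "keep_channels") spec$channels
             else setdiff(1:4, spec$channels)
  if (length(keep_ch) == 0) stop_param("lesion would remove every channel")
  keep_ch <- sort(keep_ch)
  bank$channels <- bank$channels[keep_ch]
  keep_units <- bank$index_map$channel %in% keep_ch
  bank$index_map <- bank$index_map[keep_units, , drop = FALSE]
  # reindex channels to match the shortened channel list
  bank$index_map$channel <- match(bank$index_map$channel, keep_ch)
  bank$unit_count <- nrow(bank$index_map)
  bank$keep_idx <- NULL
  bank
}

#' Restrict a bank to an explicit set of units
#'
#' Unit-level lesion: the encoder still computes the full bank and then
#' keeps only the requested units (in their original order), so surviving
#' kernels are bit-identical to the full model's.
#'
#' @param bank an [build_bank()] object (unlesioned).
#' @param keep_units integer vector of unit indices to retain.
#' @return a lesioned `ev_bank`.
#' @export
apply_unit_lesion <- function(bank, keep_units) {
  keep_units <- sort(unique(as.integer(keep_units)))
  if (length(keep_units) == 0) stop_param("lesion would remove every unit")
  if (any(keep_units < 1 | keep_units > nrow(bank$index_map)))
    stop_param("keep_units out of range")
  bank$keep_idx <- keep_units
  bank$index_map <- bank$index_map[keep_units, , drop = FALSE]
  bank$unit_count <- length(keep_units)
  bank
}

#' Weight-sign consistency across model runs
#'
#' Given the trained readout weights of repeated full-model runs (one
#' column per run), computes each unit's weight-sign pattern and the set of
#' units whose sign is identical and nonzero in at least `threshold` runs.
#' Zero weights count as sign-inconsistent. Kept sets are nested:
#' kept(t1) is a subset of kept(t2) whenever t1 > t2.
#'
#' @param weights numeric matrix, units x runs.
#' @param threshold integer in `[1, ncol(weights)]`.
#' @return list with `sign` (units x runs matrix in -1/0/+1), `kept`
#'   (integer unit indices) and `threshold`.
#' @export
consistency_sets <- function(weights, threshold) {
  if (!is.matrix(weights) || ncol(weights) < 1)
    stop_param("weights must be a units x runs matrix with >= 1 run")
  if (threshold < 1 || threshold > ncol(weights))
    stop_param("threshold must be in [1, n_runs]")
  s <- sign(weights)
  n_pos <- rowSums(s > 0)
  n_neg <- rowSums(s < 0)
  list(sign = s, kept = which(n_pos >= threshold | n_neg >= threshold),
       threshold = as.integer(threshold))
}

#' Run a lesion experiment
#'
#' Builds the lesioned bank prescribed by `spec` (for consistency modes,
#' from the trained weights of a completed full-model experiment), then
#' re-initialises and retrains the readout under the given condition with
#' the same repeated-split protocol as [run_grid()], emitting the same
#' record schema. With an identity lesion (keep all channels/units) and
#' identical seeds, the records reproduce the full model's bit-for-bit.
#'
#' @param model_kind the model kind to lesion (e.g. `"simple"`).
#' @param spec an [lesion_spec()].
#' @param pool labelled stimulus pool.
#' @param bspec,nspec the evaluation condition (reference: blurred-scene
#'   background, scaling to 50%, rotation to 45 degrees).
#' @param base_seed,cfg,eval_per_class,n_repeats as in [run_grid()].
#' @param base_weights units x runs matrix of full-model weights (required
#'   for the consistency modes).
#' @param canvas_size canvas side in px.
#' @return data.frame of performance records with a `lesion` column; the
#'   kept unit indices are attached as attribute `"kept_units"`.
#' @export
run_lesion_experiment <- function(model_kind, spec, pool, bspec, nspec,
                                  base_seed, cfg = train_config(),
                                  eval_per_class = 1500L, n_repeats = 100L,
                                  base_weights = NULL, canvas_size = 340L) {
  full <- build_bank(model_kind, canvas_size)
  if (spec$mode %in% c("keep_consistent", "drop_consistent")) {
    if (is.null(base_weights))
      stop(errorCondition(
        "consistency modes require base_weights from a full-model run",
        class = c("ev_dependency_error", "error")))
    cs <- consistency_sets(base_weights, spec$consistency_threshold)
    kept_units <- if (spec$mode == "keep_consistent") cs$kept
                  else setdiff(seq_len(full$unit_count), cs$kept)
    bank <- apply_unit_lesion(full, kept_units)
  } else {
    bank <- apply_channel_lesion(full, spec)
    keep_ch <- if (spec$mode == "keep_channels") spec$channels
               else setdiff(1:4, spec$channels)
    kept_units <- which(full$index_map$channel %in% keep_ch)
  }
  grid <- condition_grid(backgrounds = list(bspec),
                         scale_levels = nspec$scale_min,
                         rot_levels = nspec$rot_max,
                         n_repeats = n_repeats)
  banks <- stats::setNames(list(bank), model_kind)
  rec <- run_grid(grid, model_kind, pool, base_seed, cfg = cfg,
                  eval_per_class = eval_per_class, canvas_size = canvas_size,
                  banks = banks)
  rec$lesion <- paste0(spec$mode,
                       if (length(spec$channels))
                         paste0(":", paste(spec$channels, collapse = "+"))
                       else paste0(":t", spec$consistency_threshold))
  attr(rec, "kept_units") <- kept_units
  rec
}
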