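RESULTS_MARKER <- "# earlyvision-results"
RESULTS_COLUMNS <- c("model", "background", "scale_min", "rot_max", "rep",
                     "percent_correct", "hit_rate", "false_alarm_rate",
                     "d_prime", "seed")

#' Write / read a stimulus as an 8-bit grayscale+alpha PNG
#'
#' @param s an `ev_stimulus`.
#' @param path output path.
#' @return `write_stimulus` returns `path` invisibly; `read_stimulus`
#'   returns an `ev_stimulus`.
#' @export
write_stimulus <- function(s, path) {
  arr <- array(0, c(nrow(s$pixels), ncol(s$pixels), 2))
  arr[, , 1] <- clip01(s$pixels / 255)
  arr[, , 2] <- clip01(s$alpha)
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_stimulus
#' @param label,sublabel labels to attach on read.
#' @export
read_stimulus <- function(path, label = "face", sublabel = NA_character_) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3 || dim(arr)[3] < 2)
    stop_format("expected a grayscale+alpha PNG: ", path)
  new_stimulus(arr[, , 1] * 255, arr[, , dim(arr)[3]], label, sublabel)
}

#' Write a stimulus set with a CSV manifest
#'
#' Saves each stimulus as `<prefix><i>.png` plus `<prefix>manifest.csv`
#' (filename, label, sublabel, seed columns).
#'
#' @param pool labelled pool from [make_pool()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param seed the seed recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_stimulus_set <- function(pool, dir, prefix = "stim_", seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s%04d.png", prefix, seq_along(pool$stimuli))
  for (i in seq_along(pool$stimuli))
    write_stimulus(pool$stimuli[[i]], file.path(dir, files[i]))
  man <- data.frame(filename = files, label = as.character(pool$label),
                    sublabel = vapply(pool$stimuli,
                                      function(s) as.character(s$sublabel), ""),
                    seed = seed)
  manifest <- file.path(dir, paste0(prefix, "manifest.csv"))
  write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Save / load performance-record tables
#'
#' Records are written as CSV at full (17 significant digit) precision so
#' that a write/read round trip is lossless, preceded by a marker line that
#' embeds the run-configuration hash and base seed. `load_results`
#' validates the marker and the column schema and raises a format error on
#' mismatch.
#'
#' @param records data.frame of performance records (see [run_grid()]).
#' @param path CSV path.
#' @param config_hash,base_seed provenance embedded in the artifact.
#' @return `save_results` returns `path` invisibly; `load_results` the
#'   records data.frame with attributes `config_hash` and `base_seed`.
#' @export
save_results <- function(records, path, config_hash = "", base_seed = NA) {
  missing_cols <- setdiff(RESULTS_COLUMNS, names(records))
  if (length(missing_cols) > 0)
    stop_format("records lack columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(records), RESULTS_COLUMNS)
  out <- records[, c(RESULTS_COLUMNS, extra), drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) format(x, digits = 17,
                                                  trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s config_hash=%s base_seed=%s", RESULTS_MARKER,
                     config_hash, base_seed), con)
  write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname save_results
#' @export
load_results <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, RESULTS_MARKER))
    stop_format("not an earlyvision results file (bad marker): ", path)
  df <- read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RESULTS_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop_format("results file lacks columns: ",
                paste(missing_cols, collapse = ", "))
  hash <- sub(".*config_hash=(\\S+).*", "\\1", header)
  seed <- sub(".*base_seed=(\\S+).*", "\\1", header)
  attr(df, "config_hash") <- hash
  attr(df, "base_seed") <- suppressWarnings(as.numeric(seed))
  df
}

#' Serialise / restore a trained readout as JSON
#'
#' @param r an `ev_readout`.
#' @param path JSON path.
#' @param config_hash,seed provenance fields.
#' @export
write_readout <- function(r, path, config_hash = "", seed = NA) {
  jsonlite::write_json(
    list(weights = r$w, bias = r$b, n_inputs = r$n_inputs,
         model_kind = if (is.null(r$model_kind)) NA else r$model_kind,
         config_hash = config_hash, seed = seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_readout
#' @export
read_readout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = j$weights, b = j$bias, n_inputs = j$n_inputs,
                 model_kind = j$model_kind), class = "ev_readout")
}

RUNCONFIG_KEYS <- c("experiment", "n_per_class", "task", "model_kinds",
                    "backgrounds", "scale_levels", "rot_levels", "n_repeats",
                    "protocol", "epochs", "per_class", "eval_per_class",
                    "base_seed", "output_dir")

#' Experiment run configuration
#'
#' A fully serialisable description of one experiment: generator pool size,
#' condition grid, model kinds, training protocol and seeds. Its MD5 hash
#' is embedded in every output artifact so results can be traced to the
#' exact configuration.
#'
#' @param experiment experiment name.
#' @param n_per_class stimuli per class in the generated pool.
#' @param task `"face"` or `"gender"`.
#' @param model_kinds character vector of model kinds.
#' @param backgrounds character vector of background kinds.
#' @param scale_levels,rot_levels,n_repeats condition grid.
#' @param protocol,epochs,per_class,eval_per_class training/evaluation
#'   protocol.
#' @param base_seed integer base seed.
#' @param output_dir directory for artifacts.
#' @return an object of class `ev_run_config`.
#' @export
run_config <- function(experiment = "benchmark", n_per_class = 200L,
                       task = "face", model_kinds = "simple",
                       backgrounds = "mid_gray",
                       scale_levels = c(1, 0.7, 0.5),
                       rot_levels = c(0, 15, 45, 90, 180),
                       n_repeats = 100L, protocol = "fixed",
                       epochs = NULL, per_class = NULL,
                       eval_per_class = 1500L, base_seed = 1L,
                       output_dir = "results") {
  cfg <- list(experiment = experiment, n_per_class = as.integer(n_per_class),
              task = task, model_kinds = model_kinds,
              backgrounds = backgrounds, scale_levels = scale_levels,
              rot_levels = rot_levels, n_repeats = as.integer(n_repeats),
              protocol = protocol, epochs = epochs, per_class = per_class,
              eval_per_class = as.integer(eval_per_class),
              base_seed = as.integer(base_seed), output_dir = output_dir)
  validate_run_config(cfg)
  class(cfg) <- "ev_run_config"
  cfg
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUNCONFIG_KEYS)
  if (length(unknown) > 0)
    stop_format("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!all(cfg$model_kinds %in% MODEL_KINDS))
    stop_param("unknown model kind: ",
               paste(setdiff(cfg$model_kinds, MODEL_KINDS), collapse = ", "))
  if (!all(cfg$backgrounds %in% BACKGROUND_KINDS))
    stop_param("unknown background kind: ",
               paste(setdiff(cfg$backgrounds, BACKGROUND_KINDS), collapse = ", "))
  if (!cfg$task %in% c("face", "gender")) stop_param("task must be face/gender")
  if (!cfg$protocol %in% c("fixed", "earlystop"))
    stop_param("protocol must be fixed/earlystop")
  invisible(cfg)
}

#' Write / read generator parameters as YAML
#'
#' Round-trips an [stim_params()] object through a plain-text key/value
#' file; reading re-validates, so corrupted or out-of-range files fail
#' fast.
#'
#' @param params an `ev_params` object.
#' @param path YAML path.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- yaml::read_yaml(path)
  known <- c("canvas", "target_side", "face", "nonface", "gender_effect")
  unknown <- setdiff(names(p), known)
  if (length(unknown) > 0)
    stop_format("unknown generator parameter keys: ",
                paste(unknown, collapse = ", "))
  stim_params(face = p$face, nonface = p$nonface,
              gender_effect = if (is.null(p$gender_effect)) 1
                              else p$gender_effect)
}

#' MD5 hash of a run configuration
#' @param cfg an `ev_run_config`.
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write / read a run configuration as YAML
#'
#' Reading validates strictly: unknown keys raise a format error.
#'
#' @param cfg an `ev_run_config`.
#' @param path YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUNCONFIG_KEYS)
  if (length(unknown) > 0)
    stop_format("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, cfg)
}
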