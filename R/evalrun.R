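#' Random class-wise split plan
#'
#' Partitions each class's indices uniformly at random into train/test
#' halves (`"half"`, 50/50) or train/validation/test (`"tvt"`, 50/10/40).
#' Index lists are disjoint and cover the pool, so evaluation is fully
#' cross-validated by construction.
#'
#' @param n_per_class pool size per class (scalar or length-2).
#' @param scheme `"half"` or `"tvt"`.
#' @param seed optional integer seed.
#' @return an object of class `ev_split` with per-class index lists
#'   `train`, `validation` (tvt only) and `test`.
#' @export
make_split <- function(n_per_class, scheme = c("half", "tvt"), seed = NULL) {
  scheme <- match.arg(scheme)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  min_n <- if (scheme == "half") 2L else 10L
  if (any(n_per_class < min_n))
    stop_param("n_per_class must be >= ", min_n, " for scheme '", scheme, "'")
  with_seed(seed, {
    plans <- lapply(n_per_class, function(n) {
      perm <- sample.int(n)
      if (scheme == "half") {
        k <- floor(n / 2)
        list(train = sort(perm[1:k]), validation = integer(0),
             test = sort(perm[(k + 1):n]))
      } else {
        k1 <- round(0.5 * n); k2 <- round(0.1 * n)
        list(train = sort(perm[1:k1]),
             validation = sort(perm[(k1 + 1):(k1 + k2)]),
             test = sort(perm[(k1 + k2 + 1):n]))
      }
    })
    structure(list(scheme = scheme,
                   train = lapply(plans, `[[`, "train"),
                   validation = lapply(plans, `[[`, "validation"),
                   test = lapply(plans, `[[`, "test")),
              class = "ev_split")
  })
}

# Subset a pool by a per-class index list (indices within each class).
pool_subset <- function(pool, per_class_idx) {
  cls <- levels(pool$label)
  global <- unlist(lapply(seq_along(cls), function(ci) {
    which(pool$label == cls[ci])[per_class_idx[[ci]]]
  }), use.names = FALSE)
  list(stimuli = pool$stimuli[global], label = droplevels(pool$label[global]))
}

#' Sensitivity index d-prime
#'
#' d' = Z(hit rate) - Z(false-alarm rate), with Z the inverse standard
#' normal CDF. Rates are clamped to \[0.005, 0.995\] before the transform
#' and the result is clipped to +/-5.15, so a symmetric 99.5%-correct
#' classifier sits exactly at the ceiling of 5.15 and antisymmetry
#' d'(h, f) = -d'(f, h) holds throughout.
#'
#' @param hit_rate,false_alarm_rate rates in \[0, 1\] (vectorised).
#' @return numeric d-prime value(s).
#' @export
dprime <- function(hit_rate, false_alarm_rate) {
  if (any(hit_rate < 0 | hit_rate > 1 | false_alarm_rate < 0 |
          false_alarm_rate > 1, na.rm = TRUE))
    stop_param("rates must be in [0, 1]")
  h <- pmin(pmax(hit_rate, 0.005), 0.995)
  f <- pmin(pmax(false_alarm_rate, 0.005), 0.995)
  pmin(pmax(qnorm(h) - qnorm(f), -5.15), 5.15)
}

#' Evaluate trained readouts on a test pool
#'
#' Resamples `n_per_class` stimuli per class with replacement, composes
#' each freshly under the given condition, feeds it through the encoder(s)
#' once, and scores percent correct, hit rate (positive class called
#' positive), false-alarm rate, and d-prime.
#'
#' @param readouts named list of `ev_readout` (or a single readout).
#' @param banks named list of [build_bank()] matching `readouts` (or one).
#' @param pool labelled test pool.
#' @param bspec,nspec condition (background and nuisance specs).
#' @param n_per_class evaluation resamples per class.
#' @param seed integer seed (evaluation sub-stream is derived from it).
#' @return data.frame with one row per model kind: `model`,
#'   `percent_correct`, `hit_rate`, `false_alarm_rate`, `d_prime`.
#' @export
evaluate_readouts <- function(readouts, banks, pool, bspec, nspec,
                              n_per_class = 1500L, seed = NULL) {
  single <- inherits(banks, "ev_bank")
  if (single) {
    banks <- stats::setNames(list(banks), banks$model_kind)
    readouts <- stats::setNames(list(readouts), names(banks))
  }
  if (length(pool$label) == 0) stop_param("test pool is empty")
  kinds <- names(banks)
  pos_level <- levels(pool$label)[1]
  idx_by_class <- split(seq_along(pool$label), pool$label)
  if (any(lengths(idx_by_class) == 0))
    stop_param("every class must be represented in the test pool")

  core <- make_encoder_core(banks)
  bg_static <- static_background(bspec)
  with_seed(if (is.null(seed)) NULL else substream(seed, "eval"), {
    draws <- unlist(lapply(idx_by_class, function(ix)
      ix[sample.int(length(ix), n_per_class, replace = TRUE)]),
      use.names = FALSE)
    is_pos <- pool$label[draws] == pos_level
    correct_pos <- stats::setNames(rep(0L, length(kinds)), kinds)
    called_pos_on_neg <- stats::setNames(rep(0L, length(kinds)), kinds)
    for (j in seq_along(draws)) {
      canvas <- present_canvas(pool$stimuli[[draws[j]]], nspec, bspec,
                               bg_static)
      fl <- core_features(canvas, core, banks)
      for (k in kinds) {
        pos_call <- (sum(fl[[k]] * readouts[[k]]$w) + readouts[[k]]$b) > 0
        if (is_pos[j] && pos_call) correct_pos[k] <- correct_pos[k] + 1L
        if (!is_pos[j] && pos_call)
          called_pos_on_neg[k] <- called_pos_on_neg[k] + 1L
      }
    }
    n_pos <- sum(is_pos); n_neg <- length(draws) - n_pos
    hit <- correct_pos / n_pos
    fa <- called_pos_on_neg / n_neg
    pc <- (correct_pos + (n_neg - called_pos_on_neg)) / length(draws)
    data.frame(model = kinds, percent_correct = unname(pc),
               hit_rate = unname(hit), false_alarm_rate = unname(fa),
               d_prime = dprime(unname(hit), unname(fa)),
               row.names = NULL)
  })
}

#' Condition grid
#'
#' The experimental design: a set of backgrounds crossed with scale levels
#' (fractions; 1.0 means no scale variation, 0.5 means down-scaling by up
#' to 50%) and rotation levels (degrees; maximum absolute rotation), each
#' cell repeated `n_repeats` times with independent splits.
#'
#' @param backgrounds list of [background_spec()] objects (or kind strings).
#' @param scale_levels,rot_levels numeric vectors of condition levels.
#' @param n_repeats independent split/train/test repeats per cell.
#' @return an object of class `ev_grid`.
#' @export
condition_grid <- function(backgrounds = list("mid_gray"),
                           scale_levels = c(1.0, 0.7, 0.5),
                           rot_levels = c(0, 15, 45, 90, 180),
                           n_repeats = 100L) {
  if (n_repeats < 1) stop_param("n_repeats must be >= 1")
  backgrounds <- lapply(backgrounds, function(b)
    if (inherits(b, "ev_background_spec")) b else background_spec(b))
  structure(list(backgrounds = backgrounds, scale_levels = scale_levels,
                 rot_levels = rot_levels, n_repeats = as.integer(n_repeats)),
            class = "ev_grid")
}

#' Run a condition grid of repeated split/train/test experiments
#'
#' For every (background, scale, rotation) cell and repeat i, draws a fresh
#' class-wise split with seed `base_seed + i`, trains the requested model
#' kinds on the training half (sharing the presentation stream across
#' kinds), and evaluates on the held-out half. Per-repeat seeding uses
#' independent sub-streams for split, initialisation, training and
#' evaluation, so any run is bit-for-bit reproducible from
#' `(grid, pool, base_seed, cfg)`.
#'
#' @param grid an [condition_grid()].
#' @param model_kinds character vector of model kinds to train.
#' @param pool labelled stimulus pool (the full set; splits are drawn from
#'   it per repeat).
#' @param base_seed integer base seed.
#' @param cfg an [train_config()].
#' @param eval_per_class test resamples per class per repeat.
#' @param canvas_size canvas side in px.
#' @param collect_weights if TRUE, attach trained weight matrices (unit x
#'   repeat, per model and condition) as attribute `"weights"`; needed for
#'   weight-consistency lesions.
#' @param banks optional prebuilt named list of banks (e.g. lesioned).
#' @param progress if TRUE, print one line per condition cell.
#' @return data.frame of performance records: one row per (model,
#'   condition, repeat) with percent correct, hit/false-alarm rates and
#'   d-prime.
#' @export
run_grid <- function(grid, model_kinds, pool, base_seed,
                     cfg = train_config(), eval_per_class = 1500L,
                     canvas_size = 340L, collect_weights = FALSE,
                     banks = NULL, progress = FALSE) {
  if (is.null(banks)) {
    banks <- lapply(model_kinds, build_bank, canvas_size = canvas_size)
    names(banks) <- model_kinds
  }
  n_class <- as.vector(table(pool$label))
  rows <- list()
  weights <- list()
  for (bi in seq_along(grid$backgrounds)) {
    bspec <- grid$backgrounds[[bi]]
    for (sc in grid$scale_levels) for (ro in grid$rot_levels) {
      nspec <- nuisance_spec(scale_min = sc, rot_max = ro)
      ckey <- sprintf("%s_s%g_r%g", bspec$kind, sc, ro)
      if (progress)
        message(sprintf("condition %s (%d repeats)", ckey, grid$n_repeats))
      wmat <- if (collect_weights)
        lapply(banks, function(b) matrix(NA_real_, b$unit_count,
                                         grid$n_repeats))
      for (i in seq_len(grid$n_repeats)) {
        seed_i <- base_seed + i
        split <- make_split(n_class, "half",
                            seed = substream(seed_i, "split"))
        train_pool <- pool_subset(pool, split$train)
        test_pool <- pool_subset(pool, split$test)
        stopifnot(!any(unlist(Map(intersect, split$train, split$test)) > 0))
        ro_fit <- train_readouts(banks, train_pool, bspec, nspec, cfg,
                                 seed = seed_i)
        rec <- evaluate_readouts(ro_fit, banks, test_pool, bspec, nspec,
                                 n_per_class = eval_per_class, seed = seed_i)
        rec$background <- bspec$kind
        rec$scale_min <- sc
        rec$rot_max <- ro
        rec$rep <- i
        rec$seed <- seed_i
        rows[[length(rows) + 1L]] <- rec
        if (collect_weights)
          for (k in names(banks)) wmat[[k]][, i] <- ro_fit[[k]]$w
      }
      if (collect_weights) weights[[ckey]] <- wmat
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("model", "background", "scale_min", "rot_max", "rep",
                 "percent_correct", "hit_rate", "false_alarm_rate",
                 "d_prime", "seed")]
  if (collect_weights) attr(out, "weights") <- weights
  out
}

#' Median performance per condition cell
#'
#' @param records output of [run_grid()].
#' @return data.frame with per-(model, condition) medians of percent
#'   correct and d-prime over repeats.
#' @export
summarize_grid <- function(records) {
  agg <- stats::aggregate(
    records[, c("percent_correct", "d_prime")],
    by = records[, c("model", "background", "scale_min", "rot_max")],
    FUN = median)
  names(agg)[names(agg) == "percent_correct"] <- "median_percent_correct"
  names(agg)[names(agg) == "d_prime"] <- "median_d_prime"
  agg[order(agg$model, agg$background, -agg$scale_min, agg$rot_max), ]
}
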