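#' Training configuration for the linear readout
#'
#' Two protocols are supported. `"fixed"` trains for exactly 10 epochs with
#' 1,500 resamples per class per epoch (the face vs non-face protocol);
#' `"earlystop"` trains for up to 40 epochs with 400 resamples per class
#' per epoch and stops when validation fraction-correct fails to improve
#' for 5 consecutive epochs, with a fixed 80 + 80 validation set (the
#' gender protocol). Both use binary cross-entropy on the logit, SGD with
#' learning rate 0.01 and classical momentum 0.9, batch size 64, and
#' shuffling.
#'
#' @param protocol `"fixed"` or `"earlystop"`.
#' @param epochs epochs for `"fixed"` / maximum epochs for `"earlystop"`.
#' @param per_class resamples (with replacement) per class per epoch.
#' @param lr,momentum,batch_size SGD hyperparameters.
#' @param patience consecutive non-improving epochs tolerated (`earlystop`).
#' @param val_per_class validation images per class (`earlystop`).
#' @return an object of class `ev_train_config`.
#' @export
train_config <- function(protocol = c("fixed", "earlystop"), epochs = NULL,
                         per_class = NULL, lr = 0.01, momentum = 0.9,
                         batch_size = 64L, patience = 5L,
                         val_per_class = 80L) {
  protocol <- match.arg(protocol)
  if (is.null(epochs)) epochs <- if (protocol == "fixed") 10L else 40L
  if (is.null(per_class)) per_class <- if (protocol == "fixed") 1500L else 400L
  if (epochs < 1 || per_class < 1 || batch_size < 1)
    stop_param("epochs, per_class and batch_size must be positive")
  if (lr < 0 || momentum < 0) stop_param("lr and momentum must be >= 0")
  if (protocol == "earlystop" && patience >= epochs)
    stop_param("patience must be smaller than the epoch limit")
  structure(list(protocol = protocol, epochs = as.integer(epochs),
                 per_class = as.integer(per_class), lr = lr,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 val_per_class = as.integer(val_per_class)),
            class = "ev_train_config")
}

#' Initialise a linear readout
#'
#' Weights follow the Kaiming-uniform rule for a linear layer,
#' w ~ U(-1/sqrt(n), +1/sqrt(n)) elementwise with n the fan-in; the bias
#' starts at zero.
#'
#' @param n_inputs number of encoder units feeding the readout.
#' @param seed optional integer seed.
#' @return an object of class `ev_readout` with fields `w`, `b`, `n_inputs`.
#' @export
init_readout <- function(n_inputs, seed = NULL) {
  if (!is.numeric(n_inputs) || length(n_inputs) != 1L || n_inputs < 1)
    stop_param("n_inputs must be a positive integer")
  bound <- 1 / sqrt(n_inputs)
  w <- with_seed(seed, runif(n_inputs, -bound, bound))
  structure(list(w = w, b = 0, n_inputs = as.integer(n_inputs)),
            class = "ev_readout")
}

#' Resample one training epoch from a labelled pool
#'
#' Draws `per_class` stimuli with replacement from each class and shuffles
#' the combined order. Downstream, every draw is paired with a fresh
#' nuisance/background realisation, so repeated draws of the same stimulus
#' still yield different inputs.
#'
#' @param pool list with `stimuli` and a two-level factor `label`.
#' @param per_class draws per class.
#' @param seed optional integer seed.
#' @return integer vector of pool indices, length `2 * per_class`.
#' @export
resample_epoch <- function(pool, per_class, seed = NULL) {
  idx_by_class <- split(seq_along(pool$label), pool$label)
  if (any(lengths(idx_by_class) == 0))
    stop_param("every class must be represented in the pool")
  with_seed(seed, {
    drawn <- unlist(lapply(idx_by_class, function(ix)
      ix[sample.int(length(ix), per_class, replace = TRUE)]),
      use.names = FALSE)
    drawn[sample.int(length(drawn))]
  })
}

# One SGD-with-momentum step on the binary cross-entropy-with-logits loss
# (mean reduction). Returns the updated state; errors on non-finite loss.
sgd_update <- function(st, X, y, lr, momentum) {
  z <- drop(X %*% st$w) + st$b
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  if (!is.finite(loss))
    stop_train("training diverged: non-finite loss (|w| max ",
               format(max(abs(st$w))), ")")
  g <- (plogis(z) - y) / length(y)
  st$vw <- momentum * st$vw + drop(crossprod(X, g))
  st$vb <- momentum * st$vb + sum(g)
  st$w <- st$w - lr * st$vw
  st$b <- st$b - lr * st$vb
  st$loss <- loss
  st
}

# Same update with features held column-wise (units x batch), which avoids
# transposing the batch feature matrix in the streaming trainer.
sgd_update_cols <- function(st, F, y, lr, momentum) {
  z <- drop(crossprod(F, st$w)) + st$b
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  if (!is.finite(loss))
    stop_train("training diverged: non-finite loss (|w| max ",
               format(max(abs(st$w))), ")")
  g <- (plogis(z) - y) / length(y)
  st$vw <- momentum * st$vw + drop(F %*% g)
  st$vb <- momentum * st$vb + sum(g)
  st$w <- st$w - lr * st$vw
  st$b <- st$b - lr * st$vb
  st$loss <- loss
  st
}

sgd_state <- function(readout) {
  list(w = readout$w, b = readout$b, vw = numeric(length(readout$w)),
       vb = 0, loss = NA_real_)
}

#' Train readouts for one or several model kinds on a shared stimulus stream
#'
#' Runs the configured protocol: each epoch resamples `per_class` stimuli
#' per class with replacement and composes every presentation freshly
#' (scale/rotation/jitter/background), so the model effectively never sees
#' the same input twice. When several model kinds are given, they are
#' trained concurrently on the identical presentation stream (the Gabor
#' family shares one set of raw filter responses), each with an independent
#' readout. Randomness is split into independent `init` and `train`
#' sub-streams of `seed`.
#'
#' @param banks named list of [build_bank()] objects (names = model kinds),
#'   or a single bank.
#' @param pool labelled training pool (`stimuli`, two-level `label`; the
#'   first level is the positive class).
#' @param bspec a [background_spec()].
#' @param nspec a [nuisance_spec()].
#' @param cfg an [train_config()].
#' @param seed integer seed; the run is bit-for-bit reproducible.
#' @param val_pool fixed validation pool (required for `"earlystop"`).
#' @return named list of `ev_readout` objects (one per bank), each carrying
#'   `epochs_run`; or a single readout if a single bank was given.
#' @export
train_readouts <- function(banks, pool, bspec, nspec, cfg, seed,
                           val_pool = NULL) {
  single <- inherits(banks, "ev_bank")
  if (single) banks <- stats::setNames(list(banks), banks$model_kind)
  if (!inherits(cfg, "ev_train_config")) stop_param("cfg must be an ev_train_config")
  if (cfg$protocol == "earlystop" && is.null(val_pool))
    stop_param("earlystop protocol requires a validation pool")
  kinds <- names(banks)
  y01 <- as.integer(pool$label == levels(pool$label)[1])

  states <- with_seed(substream(seed, "init"), {
    lapply(banks, function(b) sgd_state(init_readout(b$unit_count)))
  })
  active <- stats::setNames(rep(TRUE, length(kinds)), kinds)
  best <- stats::setNames(rep(-Inf, length(kinds)), kinds)
  streak <- stats::setNames(rep(0L, length(kinds)), kinds)
  epochs_run <- stats::setNames(rep(0L, length(kinds)), kinds)

  core <- make_encoder_core(banks)
  bg_static <- static_background(bspec)
  feats_for_stim <- function(s)
    core_features(present_canvas(s, nspec, bspec, bg_static), core, banks)

  with_seed(substream(seed, "train"), {
    # fixed validation canvases, composed once (earlystop only)
    val <- NULL
    if (cfg$protocol == "earlystop") {
      vf <- lapply(val_pool$stimuli, feats_for_stim)
      val <- list(
        X = lapply(kinds, function(k)
          do.call(rbind, lapply(vf, `[[`, k))),
        y = as.integer(val_pool$label == levels(val_pool$label)[1]))
      names(val$X) <- kinds
    }

    for (ep in seq_len(cfg$epochs)) {
      if (!any(active)) break
      order_idx <- resample_epoch(pool, cfg$per_class)
      n_items <- length(order_idx)
      pos <- 1L
      while (pos <= n_items) {
        take <- order_idx[pos:min(pos + cfg$batch_size - 1L, n_items)]
        pos <- pos + cfg$batch_size
        fl <- lapply(take, function(i) feats_for_stim(pool$stimuli[[i]]))
        yb <- y01[take]
        for (k in kinds[active])
          states[[k]] <- sgd_update_cols(
            states[[k]],
            vapply(fl, `[[`, numeric(banks[[k]]$unit_count), k),
            yb, cfg$lr, cfg$momentum)
      }
      for (k in kinds[active]) epochs_run[k] <- ep
      if (cfg$protocol == "earlystop") {
        for (k in kinds[active]) {
          zs <- drop(val$X[[k]] %*% states[[k]]$w) + states[[k]]$b
          acc <- mean((zs > 0) == (val$y == 1))
          if (acc > best[k]) { best[k] <- acc; streak[k] <- 0L }
          else streak[k] <- streak[k] + 1L
          if (streak[k] >= cfg$patience) active[k] <- FALSE
        }
      }
    }
  })

  out <- lapply(kinds, function(k) {
    structure(list(w = states[[k]]$w, b = states[[k]]$b,
                   n_inputs = length(states[[k]]$w),
                   epochs_run = epochs_run[[k]],
                   model_kind = banks[[k]]$model_kind),
              class = "ev_readout")
  })
  names(out) <- kinds
  if (single) out[[1]] else out
}

#' @rdname train_readouts
#' @param bank a single [build_bank()] object.
#' @export
train_readout <- function(bank, pool, bspec, nspec, cfg, seed,
                          val_pool = NULL) {
  train_readouts(bank, pool, bspec, nspec, cfg, seed, val_pool)
}

#' Train a readout on a fixed feature matrix
#'
#' Same loss, optimiser and resampling protocol as [train_readouts()], but
#' over precomputed feature rows instead of freshly composed stimuli.
#' Useful for controlled experiments (separable synthetic features, label
#' shuffles) and for probing the optimiser.
#'
#' @param X numeric matrix, one feature row per item.
#' @param y two-level factor, or 0/1 vector (1 = positive class).
#' @param cfg an [train_config()].
#' @param seed integer seed.
#' @param X_val,y_val fixed validation data (`earlystop` only).
#' @return an `ev_readout` carrying `epochs_run`.
#' @export
fit_logistic_sgd <- function(X, y, cfg = train_config(), seed = NULL,
                             X_val = NULL, y_val = NULL) {
  if (is.factor(y)) y <- as.integer(y == levels(y)[1])
  if (nrow(X) != length(y)) stop_param("X and y lengths differ")
  if (cfg$protocol == "earlystop" && (is.null(X_val) || is.null(y_val)))
    stop_param("earlystop protocol requires validation data")
  if (!is.null(y_val) && is.factor(y_val))
    y_val <- as.integer(y_val == levels(y_val)[1])

  st <- with_seed(substream(if (is.null(seed)) 0 else seed, "init"),
                  sgd_state(init_readout(ncol(X))))
  epochs_run <- 0L
  with_seed(if (is.null(seed)) NULL else substream(seed, "train"), {
    best <- -Inf; streak <- 0L
    pool <- list(label = factor(ifelse(y == 1, "pos", "neg"),
                                levels = c("pos", "neg")))
    for (ep in seq_len(cfg$epochs)) {
      idx <- resample_epoch(pool, cfg$per_class)
      pos <- 1L
      while (pos <= length(idx)) {
        take <- idx[pos:min(pos + cfg$batch_size - 1L, length(idx))]
        pos <- pos + cfg$batch_size
        st <- sgd_update(st, X[take, , drop = FALSE], y[take],
                         cfg$lr, cfg$momentum)
      }
      epochs_run <- ep
      if (cfg$protocol == "earlystop") {
        acc <- mean(((drop(X_val %*% st$w) + st$b) > 0) == (y_val == 1))
        if (acc > best) { best <- acc; streak <- 0L } else streak <- streak + 1L
        if (streak >= cfg$patience) break
      }
    }
  })
  structure(list(w = st$w, b = st$b, n_inputs = ncol(X),
                 epochs_run = epochs_run), class = "ev_readout")
}

#' Predict the class of a feature vector
#'
#' The positive label is returned iff `w . f + b > 0`; exact ties go to the
#' negative class.
#'
#' @param r an `ev_readout`.
#' @param f a feature vector (or matrix, one row per item).
#' @param labels length-2 character vector `(positive, negative)`.
#' @return character vector of labels.
#' @export
predict_readout <- function(r, f, labels = c("face", "nonface")) {
  if (is.matrix(f)) {
    if (ncol(f) != r$n_inputs) stop_param("feature dimension mismatch")
    z <- drop(f %*% r$w) + r$b
  } else {
    if (length(f) != r$n_inputs) stop_param("feature dimension mismatch")
    z <- sum(f * r$w) + r$b
  }
  ifelse(z > 0, labels[1], labels[2])
}

#' @export
print.ev_readout <- function(x, ...) {
  cat(sprintf("<ev_readout%s> %d inputs, bias %.4g%s\n",
              if (is.null(x$model_kind)) "" else paste0(" ", x$model_kind),
              x$n_inputs, x$b,
              if (is.null(x$epochs_run)) ""
              else sprintf(", %d epochs", x$epochs_run)))
  invisible(x)
}
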