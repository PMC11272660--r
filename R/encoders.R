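MODEL_KINDS <- c("simple", "complex", "linear", "lgn")
BANK_LAMBDAS <- c(256L, 128L, 64L, 32L)

#' Oriented Gabor kernel
#'
#' Gaussian envelope (SD = 0.4 * lambda) times a sinusoidal carrier of
#' wavelength `lambda`, on a square support of round(1.5 * lambda) px.
#' Orientation 0 is vertical (carrier varies horizontally); phase is in
#' degrees. The kernel is mean-subtracted (zero DC, so uniform inputs give
#' zero response) and scaled to unit L2 norm, which bounds feature
#' magnitudes so a fixed readout learning rate is stable.
#'
#' @param lambda carrier wavelength in px.
#' @param theta orientation in degrees (0 = vertical, increasing towards
#'   the 45 degree oblique).
#' @param phase carrier phase in degrees.
#' @return a support x support numeric matrix.
#' @export
gabor_kernel <- function(lambda, theta, phase) {
  S <- round(1.5 * lambda)
  sigma <- 0.4 * lambda
  v <- seq_len(S) - (S + 1) / 2
  X <- matrix(v, S, S, byrow = TRUE)   # x: right
  Y <- matrix(v, S, S)                 # y: down
  th <- theta * pi / 180
  u <- X * cos(th) + Y * sin(th)       # carrier axis
  k <- exp(-(X^2 + Y^2) / (2 * sigma^2)) *
    cos(2 * pi * u / lambda + phase * pi / 180)
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

#' Difference-of-Gaussians (LGN-like) kernel
#'
#' On-centre kernel = G(sigma_c) - 0.2 * G(sigma_s) with unit-integral
#' Gaussians, sigma_c = lambda / 12 and sigma_s = 5 * sigma_c, truncated to
#' the same support as the matching Gabor channel (round(1.5 * lambda));
#' the off-centre kernel is its negation. Gains weight the integrated
#' sensitivity of each Gaussian, giving a pre-normalisation kernel sum near
#' 0.8 (centre-dominated, "on-centre"). Unit L2 normalisation is applied
#' last; no DC removal (centre-surround filters respond to luminance).
#'
#' @param lambda preferred wavelength in px.
#' @param polarity `"on"` or `"off"`.
#' @return a support x support numeric matrix.
#' @export
dog_kernel <- function(lambda, polarity = c("on", "off")) {
  polarity <- match.arg(polarity)
  S <- round(1.5 * lambda)
  sc <- lambda / 12
  ss <- 5 * sc
  v <- seq_len(S) - (S + 1) / 2
  r2 <- outer(v^2, v^2, "+")
  g <- function(sig) exp(-r2 / (2 * sig^2)) / (2 * pi * sig^2)
  k <- g(sc) - 0.2 * g(ss)
  if (polarity == "off") k <- -k
  k / sqrt(sum(k^2))
}

# Raw (pre-normalisation) DoG, used only to verify the integrated-gain
# convention in tests.
dog_kernel_raw <- function(lambda) {
  S <- round(1.5 * lambda)
  sc <- lambda / 12; ss <- 5 * sc
  v <- seq_len(S) - (S + 1) / 2
  r2 <- outer(v^2, v^2, "+")
  exp(-r2 / (2 * sc^2)) / (2 * pi * sc^2) -
    0.2 * exp(-r2 / (2 * ss^2)) / (2 * pi * ss^2)
}

# Channel geometry: placements tile the canvas at stride lambda/2 with the
# grid centred. When the support exceeds the canvas (lambda = 256 on a 340
# canvas), the canvas is symmetrically zero-padded so that a
# floor(canvas/stride)+1 grid exists with its centres centred on the canvas
# -- the only convention consistent with the printed 3 x 3 x 16 count.
channel_geometry <- function(lambda, canvas_size) {
  S <- as.integer(round(1.5 * lambda))
  stride <- as.integer(lambda / 2)
  if (S <= canvas_size) {
    n1 <- (canvas_size - S) %/% stride + 1L
    margin <- (canvas_size - (S + (n1 - 1L) * stride)) %/% 2L
    list(support = S, stride = stride, n1 = n1,
         offsets = margin + stride * (0:(n1 - 1L)),   # 0-based, canvas coords
         pad = 0L, padded = canvas_size)
  } else {
    n1 <- canvas_size %/% stride + 1L
    padded <- S + (n1 - 1L) * stride
    pad <- (padded - canvas_size) %/% 2L
    list(support = S, stride = stride, n1 = n1,
         offsets = stride * (0:(n1 - 1L)),            # 0-based, padded coords
         pad = pad, padded = padded)
  }
}


#' Build a filter bank
#'
#' Constructs the full set of placed kernels for one model kind on a square
#' canvas: four spatial-frequency channels (wavelengths 256, 128, 64, 32 px
#' in one-octave steps), each tiling the canvas at a stride of half its
#' wavelength. On the default 340 px canvas the per-channel placement grids
#' are 3x3, 3x3, 8x8 and 19x19, giving 7,088 simple-cell units
#' (144/144/1,024/5,776 across channels), 1,772 complex units, 3,544 linear
#' units, and 886 LGN units (18/18/128/722).
#'
#' @param model_kind `"simple"`, `"complex"`, `"linear"` or `"lgn"`.
#' @param canvas_size canvas side in px (default 340; other sizes give
#'   recomputed counts).
#' @param gain global response gain applied to every unit's linear
#'   response (identically across model kinds, so model comparisons are
#'   unaffected). With unit-L2 kernels and pixels mapped to \[0, 1\], the
#'   default of 2 is calibrated once so that readout training at the fixed
#'   learning rate plateaus within about 10 epochs of the full protocol,
#'   the regime the training procedure assumes.
#' @return an object of class `ev_bank` with fields `model_kind`,
#'   `canvas_size`, `gain`, `channels` (geometry, kernels and their
#'   separable factorisation), `unit_count`, `index_map` (one row per
#'   unit), and `keep_idx` (non-NULL after a unit-level lesion).
#' @export
build_bank <- function(model_kind = c("simple", "complex", "linear", "lgn"),
                       canvas_size = 340L, gain = 2) {
  model_kind <- match.arg(model_kind)
  canvas_size <- as.integer(canvas_size)
  if (!is.numeric(gain) || gain <= 0) stop_param("gain must be positive")
  thetas <- c(0, 45, 90, 135)
  channels <- lapply(seq_along(BANK_LAMBDAS), function(ci) {
    lambda <- BANK_LAMBDAS[ci]
    geom <- channel_geometry(lambda, canvas_size)
    kernels <- if (model_kind == "lgn") {
      matrix(as.vector(dog_kernel(lambda, "on")), ncol = 1)
    } else {
      # one column per (theta, phase in {0, 90}); the other phases are
      # exact negations and are derived at assembly time
      do.call(cbind, lapply(thetas, function(th)
        cbind(as.vector(gabor_kernel(lambda, th, 0)),
              as.vector(gabor_kernel(lambda, th, 90)))))
    }
    c(geom, list(lambda = lambda, kernels = kernels),
      factorize_kernels(kernels, geom$support))
  })
  map <- bank_index_map(model_kind, channels)
  structure(list(model_kind = model_kind, canvas_size = canvas_size,
                 gain = gain, channels = channels, unit_count = nrow(map),
                 index_map = map, keep_idx = NULL),
            class = "ev_bank")
}

# Units are ordered channel-major (lambda 256 first), then placement in
# row-major grid order, then within-placement: simple = theta x phase
# {0,90,180,270} (phase fastest), complex = theta, linear = theta x phase
# {0,90}, lgn = on/off.
bank_index_map <- function(model_kind, channels) {
  thetas <- c(0, 45, 90, 135)
  per <- switch(model_kind,
    simple = expand.grid(phase = c(0, 90, 180, 270), theta = thetas)[, 2:1],
    complex = data.frame(theta = thetas, phase = NA_real_),
    linear = expand.grid(phase = c(0, 90), theta = thetas)[, 2:1],
    lgn = data.frame(theta = NA_real_, phase = NA_real_,
                     polarity = c("on", "off")))
  if (is.null(per$polarity)) per$polarity <- NA_character_
  maps <- lapply(seq_along(channels), function(ci) {
    ch <- channels[[ci]]
    grid <- expand.grid(col = seq_len(ch$n1), row = seq_len(ch$n1))[, 2:1]
    n_per <- nrow(per)
    data.frame(channel = ci, lambda = ch$lambda,
               row = rep(grid$row, each = n_per),
               col = rep(grid$col, each = n_per),
               theta = rep(per$theta, nrow(grid)),
               phase = rep(per$phase, nrow(grid)),
               polarity = rep(per$polarity, nrow(grid)))
  })
  out <- do.call(rbind, maps)
  out$unit <- seq_len(nrow(out))
  out[, c("unit", "channel", "lambda", "row", "col", "theta", "phase",
          "polarity")]
}

# Exact joint separable factorisation of a channel's kernels, used by the
# strided correlation. A 2-D Gabor is analytically rank <= 2 (3 with the
# DC correction) and a DoG is rank 2, and the kernels of one channel share
# their row space (same Gaussian envelope, a handful of carrier
# frequencies), so a common orthonormal row basis U (S x r, r ~ 8)
# reconstructs every kernel to machine precision: K_k = U %*% B_k with
# B_k = t(U) %*% K_k. Responses then need one small GEMM per row offset
# and one GEMV per placement. `colweights` stacks vec(B_k) per kernel.
factorize_kernels <- function(kernels, S) {
  K <- ncol(kernels)
  stacked <- matrix(kernels, nrow = S)            # S x (S * K)
  sv <- svd(stacked, nv = 0)
  r <- max(1L, sum(sv$d > sv$d[1] * 1e-13))
  U <- sv$u[, seq_len(r), drop = FALSE]
  B <- matrix(0, r * S, K)
  for (k in seq_len(K))
    B[, k] <- as.vector(crossprod(U, matrix(kernels[, k], S, S)))
  list(rowbasis = U, colweights = B, rank = r)
}

# Raw per-channel linear responses: list of P x K matrices, K = 8 for the
# Gabor family (theta-major (phase0, phase90) pairs) or 1 for LGN (on).
# The canvas is mapped to [0, 1] before filtering.
encode_raw <- function(canvas, bank) {
  if (!identical(dim(canvas), c(bank$canvas_size, bank$canvas_size)))
    stop_param("canvas shape does not match the bank's canvas size")
  cpp_encode_channels(canvas * (bank$gain / 255), bank$channels)
}

# Shared encoder core for models evaluated on the same canvases: the Gabor
# family (simple/complex/linear) shares one set of raw quadrature
# responses, and the DoG kernel is appended as an extra response column so
# a single strided-correlation pass serves every kind.
make_encoder_core <- function(banks) {
  kinds <- vapply(banks, function(b) b$model_kind, "")
  gi <- which(kinds != "lgn")[1]
  li <- which(kinds == "lgn")[1]
  ref <- banks[[if (is.na(gi)) li else gi]]
  channels <- ref$channels
  if (!is.na(gi) && !is.na(li)) {
    for (i in seq_along(channels)) {
      g <- banks[[gi]]$channels[[i]]; l <- banks[[li]]$channels[[i]]
      S <- g$support
      rg <- g$rank; rl <- l$rank; r <- rg + rl
      Kg <- ncol(g$colweights); Kl <- ncol(l$colweights)
      # concatenated (non-orthogonal) basis still reconstructs exactly
      Bfull <- array(0, c(r, S, Kg + Kl))
      Bfull[seq_len(rg), , seq_len(Kg)] <- array(g$colweights, c(rg, S, Kg))
      Bfull[rg + seq_len(rl), , Kg + seq_len(Kl)] <-
        array(l$colweights, c(rl, S, Kl))
      channels[[i]]$kernels <- cbind(g$kernels, l$kernels)
      channels[[i]]$rowbasis <- cbind(g$rowbasis, l$rowbasis)
      channels[[i]]$colweights <- matrix(Bfull, r * S, Kg + Kl)
      channels[[i]]$rank <- r
    }
  }
  gains <- vapply(banks, function(b) b$gain, 0)
  if (any(gains != ref$gain))
    stop_param("all banks in one run must share the same response gain")
  list(channels = channels, n_channels = length(channels),
       canvas_size = ref$canvas_size, gain = ref$gain)
}

# Per-bank feature vectors from one canvas via the shared core. Banks with
# a different channel structure (channel-lesioned among full banks) fall
# back to their own encoding pass.
core_features <- function(canvas, core, banks) {
  raw <- cpp_encode_channels(canvas * (core$gain / 255), core$channels)
  lapply(banks, function(b) {
    f <- if (length(b$channels) != core$n_channels) {
      features_from_raw(encode_raw(canvas, b), b$model_kind)
    } else {
      features_from_raw(raw, b$model_kind)
    }
    if (!is.null(b$keep_idx)) f[b$keep_idx] else f
  })
}

# Fast presentation path: draws the nuisance/background/jitter random
# variates in exactly the order compose_stimulus() does, then fuses
# warp + composite in one C++ pass. Background kinds that depend on the
# transformed stimulus fall back to the reference path.
FAST_BG_KINDS <- c("mid_gray", "pink_noise", "pixelated_white",
                   "pixelated_binary", "scene_high_contrast", "scene_blurred")

present_canvas <- function(s, n, bspec, bg_static = NULL) {
  if (is.null(bg_static) && !bspec$kind %in% FAST_BG_KINDS)
    return(compose_stimulus(s, n, bspec))
  identity <- n$scale_min == 1 && n$rot_max == 0
  if (identity) {
    co <- 1; si <- 0
  } else {
    u <- runif(1, n$scale_min, 1)
    rho <- runif(1, -n$rot_max, n$rot_max) * pi / 180
    co <- cos(rho) / u; si <- sin(rho) / u
  }
  bg <- if (!is.null(bg_static)) bg_static else make_background(bspec)
  jmax <- n$jitter_max
  jitter <- sample.int(2L * jmax + 1L, 2L, replace = TRUE) - jmax - 1L
  margin <- (nrow(bg) - nrow(s$pixels)) %/% 2L
  cpp_warp_composite(s$pixels, s$alpha, bg, co, si, -si, co,
                     margin + jitter[2], margin + jitter[1], identity)
}

static_background <- function(bspec, size = 340L) {
  if (bspec$kind == "mid_gray") make_background(bspec, size = size) else NULL
}

# Assemble one model kind's feature vector from raw channel responses
# (first 8 columns = theta-major quadrature pairs for the Gabor kinds;
# last column = DoG for lgn).
features_from_raw <- function(raw, model_kind) {
  cpp_assemble_features(raw, match(model_kind, MODEL_KINDS) - 1L,
                        ncol(raw[[1]]) - 1L)
}

#' Encode a canvas into a feature vector
#'
#' Maps luminance to \[0, 1\], computes every placed kernel's dot product
#' with its patch, and applies the model kind's output stage: simple and
#' LGN units half-rectify each response; complex units sum the four
#' rectified phase responses per (location, wavelength, orientation), which
#' equals |r0| + |r90| of the two quadrature phases; the linear variant
#' returns raw responses for phases 0 and 90 only. If the bank carries a
#' unit-level lesion (`keep_idx`), the feature vector is restricted to the
#' surviving units.
#'
#' @param canvas a canvas matrix matching the bank's canvas size.
#' @param bank an [build_bank()] object.
#' @return numeric feature vector of length `bank$unit_count`.
#' @export
encode <- function(canvas, bank) {
  f <- features_from_raw(encode_raw(canvas, bank), bank$model_kind)
  if (!is.null(bank$keep_idx)) f[bank$keep_idx] else f
}

#' @export
print.ev_bank <- function(x, ...) {
  counts <- table(factor(x$index_map$lambda, levels = BANK_LAMBDAS))
  cat(sprintf("<ev_bank %s> canvas %d px, %d units (%s)%s\n",
              x$model_kind, x$canvas_size, x$unit_count,
              paste(counts, collapse = ", "),
              if (is.null(x$keep_idx)) ""
              else sprintf(" [lesioned: %d kept]", length(x$keep_idx))))
  invisible(x)
}
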