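BACKGROUND_KINDS <- c("mid_gray", "image_mean_gray", "pink_noise",
                      "pixelated_white", "pixelated_binary",
                      "pixelated_image_sampled", "scene_high_contrast",
                      "scene_blurred")

#' Background specification
#'
#' One of the eight background types composited behind every stimulus:
#' uniform mid gray (128), uniform gray at the stimulus's mean foreground
#' luminance, full-resolution 1/f (pink) noise, pixelated (4 x 4 px block)
#' white/binary/image-sampled noise, high-contrast scenes, and blurred
#' scenes (contrast halved about the scene mean, then Gaussian-blurred with
#' SD 3 px). Scene kinds can draw from a pregenerated [make_scene_pool()];
#' otherwise a fresh scene is synthesised per call.
#'
#' @param kind one of the eight background kinds.
#' @param block_size block side in px for the pixelated kinds; must divide
#'   the canvas size.
#' @param blur_sd,contrast_factor blurred-scene parameters (px, unitless).
#' @param scene_pool optional pool from [make_scene_pool()].
#' @return an object of class `ev_background_spec`.
#' @export
background_spec <- function(kind, block_size = 4L, blur_sd = 3,
                            contrast_factor = 0.5, scene_pool = NULL) {
  if (length(kind) != 1L || !kind %in% BACKGROUND_KINDS)
    stop_param("unknown background kind: ", paste(kind, collapse = ", "))
  if (block_size < 1) stop_param("block_size must be >= 1")
  structure(list(kind = kind, block_size = as.integer(block_size),
                 blur_sd = blur_sd, contrast_factor = contrast_factor,
                 scene_pool = scene_pool),
            class = "ev_background_spec")
}

#' Nuisance specification
#'
#' Scale is drawn uniformly from `[scale_min, 1]` (isotropic down-scaling
#' only), rotation uniformly from `[-rot_max, +rot_max]` degrees, and the
#' position jitter as independent integers from `[-jitter_max, +jitter_max]`
#' px per axis. The default jitter bound of 42 px exactly exhausts the
#' margin of a 256 px window on a 340 px canvas, so the foreground is always
#' fully contained.
#'
#' @param scale_min lower scale bound, in (0, 1].
#' @param rot_max maximum absolute rotation, degrees in \[0, 180\].
#' @param jitter_max maximum absolute jitter per axis, px.
#' @return an object of class `ev_nuisance_spec`.
#' @export
nuisance_spec <- function(scale_min = 1, rot_max = 0, jitter_max = 42L) {
  if (scale_min <= 0 || scale_min > 1)
    stop_param("scale_min must be in (0, 1]")
  if (rot_max < 0 || rot_max > 180)
    stop_param("rot_max must be in [0, 180] degrees")
  if (jitter_max < 0) stop_param("jitter_max must be >= 0")
  structure(list(scale_min = scale_min, rot_max = rot_max,
                 jitter_max = as.integer(jitter_max)),
            class = "ev_nuisance_spec")
}

#' Pregenerate a pool of scene backgrounds
#'
#' Synthesises `n` histogram-equalised scenes and their blurred companions
#' (contrast scaled by `contrast_factor` about each scene's own mean, then
#' Gaussian blur of SD `blur_sd` px). Scene-kind backgrounds are sampled
#' from this fixed pool per presentation, mirroring the use of a fixed
#' landscape image set.
#'
#' @param n number of scenes.
#' @param size canvas side in px.
#' @param blur_sd,contrast_factor blurred-set parameters.
#' @param seed optional integer seed.
#' @return list with elements `high` and `blurred`, each a list of matrices.
#' @export
make_scene_pool <- function(n, size = 340L, blur_sd = 3,
                            contrast_factor = 0.5, seed = NULL) {
  if (n < 1) stop_param("n must be >= 1")
  with_seed(seed, {
    high <- lapply(seq_len(n), function(i) gen_scene(size))
    blurred <- lapply(high, scene_blur, blur_sd = blur_sd,
                      contrast_factor = contrast_factor)
    list(high = high, blurred = blurred)
  })
}

# Contrast reduction about the scene's own mean, then Gaussian blur.
scene_blur <- function(scene, blur_sd = 3, contrast_factor = 0.5) {
  m <- mean(scene)
  gaussian_blur(m + (scene - m) * contrast_factor, blur_sd)
}

# Separable Gaussian blur with replicate-style boundary handling (rows of
# the band matrix renormalised), so constants are preserved exactly.
gaussian_blur <- function(img, sd) {
  if (sd <= 0) return(img)
  r <- ceiling(4 * sd)
  k <- exp(-((-r):r)^2 / (2 * sd^2))
  n <- nrow(img)
  B <- matrix(0, n, n)
  for (d in (-r):r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    B[cbind(i[ok], j[ok])] <- k[d + r + 1]
  }
  B <- B / rowSums(B)
  B %*% img %*% t(B)
}

#' Build a background canvas
#'
#' @param spec a [background_spec()].
#' @param stim the stimulus to be placed (required for `image_mean_gray` and
#'   `pixelated_image_sampled`, whose values derive from its foreground).
#' @param size canvas side in px.
#' @param seed optional integer seed; otherwise the current RNG stream is
#'   consumed, so backgrounds differ across presentations.
#' @return a `size` x `size` numeric matrix in \[0, 255\].
#' @export
make_background <- function(spec, stim = NULL, size = 340L, seed = NULL) {
  if (!inherits(spec, "ev_background_spec"))
    stop_param("spec must be an ev_background_spec")
  size <- as.integer(size)
  with_seed(seed, {
    switch(spec$kind,
      mid_gray = matrix(128, size, size),
      image_mean_gray = {
        if (is.null(stim)) stop_param("image_mean_gray requires a stimulus")
        fg <- stim$alpha > 0
        if (!any(fg)) stop_input("stimulus has an empty alpha mask")
        matrix(mean(stim$pixels[fg]), size, size)
      },
      pink_noise = {
        tex <- pink_noise_field(size)
        clip255(128 + tex / sd_pop(tex) * 40)
      },
      pixelated_white = pixelate(sample(0:255, blocks2(size, spec$block_size),
                                        replace = TRUE), size, spec$block_size),
      pixelated_binary = pixelate(sample(c(0, 255), blocks2(size, spec$block_size),
                                         replace = TRUE), size, spec$block_size),
      pixelated_image_sampled = {
        if (is.null(stim))
          stop_param("pixelated_image_sampled requires a stimulus")
        fg <- stim$alpha > 0
        if (!any(fg)) stop_input("stimulus has an empty alpha mask")
        pixelate(sample(stim$pixels[fg], blocks2(size, spec$block_size),
                        replace = TRUE), size, spec$block_size)
      },
      scene_high_contrast = {
        if (!is.null(spec$scene_pool))
          spec$scene_pool$high[[sample.int(length(spec$scene_pool$high), 1)]]
        else gen_scene(size)
      },
      scene_blurred = {
        if (!is.null(spec$scene_pool))
          spec$scene_pool$blurred[[sample.int(length(spec$scene_pool$blurred), 1)]]
        else scene_blur(gen_scene(size), spec$blur_sd, spec$contrast_factor)
      })
  })
}

blocks2 <- function(size, block) {
  if (size %% block != 0)
    stop_param("block_size must divide the canvas size")
  (size %/% block)^2
}

# Expand per-block values to a pixel canvas with origin-aligned blocks.
pixelate <- function(values, size, block) {
  nb <- size %/% block
  v <- matrix(values, nb, nb)
  v[rep(seq_len(nb), each = block), rep(seq_len(nb), each = block)]
}

#' Apply scale and rotation nuisances to a stimulus
#'
#' Draws an isotropic scale factor u ~ U\[scale_min, 1\] and a rotation
#' angle ~ U\[-rot_max, +rot_max\] and applies the composed scale-then-rotate
#' map about the 256 x 256 canvas centre to both pixels and alpha, via a
#' single inverse-mapped bilinear resampling with transparent (zero) fill.
#' Alpha becomes fractional coverage after interpolation. With
#' `scale_min = 1` and `rot_max = 0` the input is returned bit-exactly.
#'
#' @param s an `ev_stimulus`.
#' @param n an [nuisance_spec()].
#' @param seed optional integer seed.
#' @return the transformed `ev_stimulus`.
#' @export
transform_stim <- function(s, n, seed = NULL) {
  if (!inherits(n, "ev_nuisance_spec")) stop_param("n must be an ev_nuisance_spec")
  if (n$scale_min == 1 && n$rot_max == 0) return(s)
  with_seed(seed, {
    u <- runif(1, n$scale_min, 1)
    rho <- runif(1, -n$rot_max, n$rot_max) * pi / 180
    # forward map: rotate(scale(p)); inverse: (1/u) * R(-rho)
    co <- cos(rho) / u; si <- sin(rho) / u
    w <- cpp_warp_pair(s$pixels, s$alpha, co, si, -si, co)
    s$pixels <- w$pixels
    s$alpha <- w$alpha
    s
  })
}

#' Composite a stimulus onto a background canvas
#'
#' Places the stimulus's 256 x 256 window at the canvas centre plus an
#' integer jitter drawn uniformly from `[-jitter_max, +jitter_max]` per
#' axis, and alpha-blends: out = alpha * foreground + (1 - alpha) *
#' background. Background pixels are conserved wherever alpha = 0, and the
#' window always lies fully inside the canvas.
#'
#' @param s an `ev_stimulus` (256 x 256).
#' @param bg a background canvas matrix (e.g. 340 x 340).
#' @param jitter_max maximum absolute jitter per axis, px; must not exceed
#'   the window margin.
#' @param jitter optional integer vector `c(jx, jy)` to fix the jitter.
#' @param seed optional integer seed.
#' @return the composed canvas matrix.
#' @export
place_on_canvas <- function(s, bg, jitter_max = 42L, jitter = NULL,
                            seed = NULL) {
  nr <- nrow(s$pixels)
  margin <- (nrow(bg) - nr) / 2
  if (margin < 0 || margin != floor(margin))
    stop_param("background canvas must exceed the stimulus by an even margin")
  if (jitter_max > margin)
    stop_param("jitter_max exceeds the canvas margin (", margin, " px)")
  with_seed(seed, {
    if (is.null(jitter))
      jitter <- sample.int(2L * jitter_max + 1L, 2L, replace = TRUE) -
        jitter_max - 1L
    if (any(abs(jitter) > jitter_max)) stop_param("jitter out of range")
    cpp_composite(bg, s$pixels, s$alpha,
                  as.integer(margin + jitter[2]),
                  as.integer(margin + jitter[1]))
  })
}

#' Compose one presentation canvas
#'
#' Convenience wrapper: applies scale/rotation nuisances, builds a fresh
#' background (for stimulus-dependent kinds, from the transformed
#' stimulus), and composites with jitter. Consumes the current RNG stream
#' unless `seed` is given.
#'
#' @inheritParams transform_stim
#' @param bspec a [background_spec()].
#' @param size canvas side in px.
#' @return the composed canvas matrix.
#' @export
compose_stimulus <- function(s, n, bspec, size = 340L, seed = NULL) {
  with_seed(seed, {
    st <- transform_stim(s, n)
    bg <- make_background(bspec, stim = st, size = size)
    place_on_canvas(st, bg, jitter_max = n$jitter_max)
  })
}
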