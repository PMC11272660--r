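#' Generator parameters for the synthetic stimulus sets
#'
#' Bundles the per-class target distributions (elongation, luminance, RMS
#' contrast) and the face feature-geometry ranges used by [gen_face()] and
#' [gen_nonface()]. Defaults emulate the low-level statistics of curated
#' face and non-face photograph sets: matched mean luminance (~103 on the
#' 0-255 scale after luminance matching) and RMS contrast (~41.5), a narrow
#' face fraction-filled distribution with mean near 0.56 against a broad
#' non-face one near 0.43, and elongation-ratio means near 1.66 (faces) and
#' 2.51 (non-faces). Non-faces are generated darker by design (mean ~89.6)
#' so that [match_luminance_sets()] recovers the canonical ~15% luminance
#' lift that equates the two classes.
#'
#' Geometry ranges are expressed in coordinates normalised to the foreground
#' half-extent (so features scale with the face outline).
#'
#' @param face,nonface named lists overriding individual class parameters;
#'   see Details in the package vignette.
#' @param gender_effect multiplier on the male-like/female-like feature
#'   differences (0 disables the sub-classes' distinguishing features).
#' @return an object of class `ev_params`.
#' @export
stim_params <- function(face = list(), nonface = list(), gender_effect = 1) {
  p <- list(
    canvas = 256L,
    target_side = 246L,
    face = list(
      elong_offset = 1.05, elong_meanlog = -0.90, elong_sdlog = 0.92,
      shape_n = c(3.0, 4.5),
      eye_dx = c(0.35, 0.48), eye_dy = c(-0.38, -0.22),
      eye_rx = c(0.10, 0.16), eye_ry = c(0.06, 0.10),
      mouth_y = c(0.38, 0.52), mouth_w = c(0.25, 0.40), mouth_h = c(0.04, 0.08),
      lum = c(103, 14), contrast = c(41.5, 6)
    ),
    nonface = list(
      elong_offset = 1.0, elong_meanlog = 0.12, elong_sdlog = 0.75,
      n_shapes = c(2L, 5L), oval_prob = 0.25,
      lum = c(89.6, 14), contrast = c(33.5, 6)
    ),
    gender_effect = gender_effect
  )
  p$face[names(face)] <- face
  p$nonface[names(nonface)] <- nonface
  validate_params(p)
  class(p) <- "ev_params"
  p
}

validate_params <- function(p) {
  chk_pair <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
      stop_param(nm, " must be two finite numbers")
  }
  for (cl in c("face", "nonface")) {
    q <- p[[cl]]
    chk_pair(q$lum, paste0(cl, "$lum")); chk_pair(q$contrast, paste0(cl, "$contrast"))
    if (q$lum[2] < 0 || q$contrast[2] < 0)
      stop_param(cl, ": target SDs must be >= 0")
    if (q$lum[1] < 0 || q$lum[1] > 255)
      stop_param(cl, ": mean luminance target outside [0, 255]")
    if (q$contrast[1] < 0) stop_param(cl, ": contrast target must be >= 0")
    if (q$elong_sdlog < 0) stop_param(cl, ": elong_sdlog must be >= 0")
    if (q$elong_offset < 1) stop_param(cl, ": elongation offset must be >= 1")
  }
  rng <- p$face[c("shape_n", "eye_dx", "eye_dy", "eye_rx", "eye_ry",
                  "mouth_y", "mouth_w", "mouth_h")]
  for (nm in names(rng)) {
    chk_pair(rng[[nm]], paste0("face$", nm))
    if (rng[[nm]][1] > rng[[nm]][2]) stop_param("face$", nm, " range not ascending")
  }
  if (p$nonface$oval_prob < 0 || p$nonface$oval_prob > 1)
    stop_param("nonface$oval_prob must be in [0, 1]")
  invisible(p)
}

new_stimulus <- function(pixels, alpha, label, sublabel = NA_character_) {
  structure(list(pixels = pixels, alpha = alpha, label = label,
                 sublabel = sublabel), class = "ev_stimulus")
}

#' @export
print.ev_stimulus <- function(x, ...) {
  st <- stim_stats(x)
  cat(sprintf(
    "<ev_stimulus %s%s> %dx%d  fill %.3f  elong %.2f  lum %.1f  rms %.1f\n",
    x$label, if (is.na(x$sublabel)) "" else paste0("/", x$sublabel),
    nrow(x$pixels), ncol(x$pixels), st$fraction_filled, st$elongation,
    st$mean_luminance, st$rms_contrast))
  invisible(x)
}

runif1 <- function(r) runif(1, r[1], r[2])

# Binary superellipse mask |dx|^n + |dy|^n <= 1 on the 256 canvas; the
# vertical extent is exactly `side` px by construction (bounds fall on
# half-integers, pixel centres on integers).
superellipse_mask <- function(width, side, n, canvas = 256L) {
  ctr <- (canvas + 1) / 2
  ry <- abs(((1:canvas) - ctr) / (side / 2))^n
  rx <- abs(((1:canvas) - ctr) / (width / 2))^n
  outer(ry, rx, "+") <= 1
}

# Normalised foreground coordinates (x right, y down, in units of the
# foreground half-extent) for every canvas pixel.
norm_coords <- function(width, side, canvas = 256L) {
  ctr <- (canvas + 1) / 2
  dx <- matrix(((1:canvas) - ctr) / (width / 2), canvas, canvas, byrow = TRUE)
  dy <- matrix(((1:canvas) - ctr) / (side / 2), canvas, canvas)
  list(dx = dx, dy = dy)
}

# Standardise foreground pixels to a target (mean, population SD) pair and
# clip to the display range. Clipping shrinks the realised SD, so the
# affine correction is iterated a few times; with heavy-tailed patterns the
# realised contrast converges to within a few percent of the target.
standardize_foreground <- function(z, mask, mean_t, sd_t) {
  v <- z[mask]
  for (it in 1:3) {
    s <- sd_pop(v)
    if (s < .Machine$double.eps) { v <- rep(mean_t, length(v)); break }
    v <- clip255(mean_t + (v - mean(v)) / s * sd_t)
  }
  out <- matrix(0, nrow(z), ncol(z))
  out[mask] <- v
  out
}

#' Generate one synthetic face-like stimulus
#'
#' Draws an oval (superellipse) foreground whose largest side is exactly
#' 246 px, containing bilateral dark eye blobs, a mouth bar, and smooth
#' shading, then standardises the foreground luminance to per-stimulus
#' targets drawn from the class distribution. The elongation ratio is drawn
#' from a shifted log-normal whose joint behaviour with the oval fill factor
#' reproduces the class means of fraction filled and elongation.
#'
#' @param params an [stim_params()] object.
#' @param sublabel `"none"`, `"male-like"` or `"female-like"`; the gendered
#'   variants differ in brow shading, eye size and mouth thickness.
#' @param seed optional integer; when given, the stimulus is a pure function
#'   of `(params, sublabel, seed)` and the caller's RNG state is untouched.
#' @return an `ev_stimulus` with binary alpha and label `"face"`.
#' @export
gen_face <- function(params = stim_params(),
                     sublabel = c("none", "male-like", "female-like"),
                     seed = NULL) {
  validate_params(params)
  sublabel <- match.arg(sublabel)
  with_seed(seed, {
    fp <- params$face
    g <- params$gender_effect *
      switch(sublabel, none = 0, `male-like` = 1, `female-like` = -1)
    side <- params$target_side
    e <- fp$elong_offset + rlnorm(1, fp$elong_meanlog, fp$elong_sdlog)
    if (g > 0) e <- 1 + (e - 1) * (1 + 0.05 * g)   # male-like slightly longer
    width <- max(24L, round(side / e))
    n <- runif1(fp$shape_n)
    mask <- superellipse_mask(width, side, n)
    co <- norm_coords(width, side)
    dx <- co$dx; dy <- co$dy

    # smooth shading + features, in arbitrary contrast units
    z <- 0.5 - runif(1, 0.2, 0.6) * (dx^2 + dy^2) / 2 +
      rnorm(1, 0, 0.12) * dy + rnorm(1, 0, 0.12) * dx
    ex <- runif1(fp$eye_dx); ey <- runif1(fp$eye_dy)
    erx <- runif1(fp$eye_rx) * (1 - 0.15 * g)      # female-like larger eyes
    ery <- runif1(fp$eye_ry) * (1 - 0.15 * g)
    eye <- ((dx - ex)^2 / erx^2 + (dy - ey)^2 / ery^2 <= 1) |
           ((dx + ex)^2 / erx^2 + (dy - ey)^2 / ery^2 <= 1)
    z[eye] <- z[eye] - 1.5
    my <- runif1(fp$mouth_y); mw <- runif1(fp$mouth_w) * (1 + 0.15 * g)
    mh <- runif1(fp$mouth_h) * (1 + 0.25 * g)
    mouth <- abs(dx) <= mw & abs(dy - my) <= mh
    z[mouth] <- z[mouth] - 1.1
    if (g > 0) {                                   # male-like brow band
      brow <- abs(dx) <= ex + erx & dy >= ey - 0.20 & dy <= ey - 0.10
      z[brow] <- z[brow] - 0.7 * min(g, 1)
    }
    nose <- abs(dx) <= 0.06 & dy >= ey + 0.08 & dy <= my - 0.12
    z[nose] <- z[nose] + 0.35

    mean_t <- clip255(rnorm(1, fp$lum[1], fp$lum[2]))
    sd_t <- max(5, rnorm(1, fp$contrast[1], fp$contrast[2]))
    pix <- standardize_foreground(z, mask, mean_t, sd_t)
    new_stimulus(pix, mask * 1, "face",
                 if (sublabel == "none") NA_character_ else sublabel)
  })
}

# Union-of-ellipses mask on a working grid, tight-cropped.
blob_union_mask <- function(k, canvas = 256L) {
  X <- matrix(1:canvas, canvas, canvas, byrow = TRUE)
  Y <- matrix(1:canvas, canvas, canvas)
  m <- matrix(FALSE, canvas, canvas)
  ctr <- (canvas + 1) / 2
  for (i in seq_len(k)) {
    cx <- ctr + runif(1, -45, 45)
    cy <- ctr + runif(1, -45, 45)
    a <- runif(1, 25, 80); b <- runif(1, 25, 80)
    th <- runif(1, 0, pi)
    xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
    yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
    m <- m | (xr^2 / a^2 + yr^2 / b^2 <= 1)
  }
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
}

# Occupancy-preserving (max-pool) resize of a binary mask to H x W. The
# contiguous window partition guarantees the output bounding box spans the
# full target extent whenever the input box is tight.
resize_mask_max <- function(mask, H, W) {
  pool_rows <- function(m, H) {
    h <- nrow(m)
    if (h == H) return(m)
    starts <- floor((0:(H - 1)) * h / H) + 1
    ends <- pmax(starts, ceiling((1:H) * h / H))
    A <- matrix(0, H, h)                 # window indicator, small
    for (i in seq_len(H)) A[i, starts[i]:ends[i]] <- 1
    (A %*% m) > 0
  }
  t(pool_rows(t(pool_rows(mask, H)), W))
}

#' Generate one synthetic non-face stimulus
#'
#' Foregrounds are unions of random ellipses (or, with probability
#' `oval_prob`, a single oval/circular shape, emulating the deliberate
#' inclusion of oval objects in curated non-face sets), rescaled so the
#' largest bounding-box side is exactly 246 px. Elongation is drawn from a
#' broad shifted log-normal; the foreground carries a smooth random texture
#' standardised to the class luminance/contrast targets (darker on average
#' than faces, so that set-level luminance matching applies a ~15% lift).
#'
#' @inheritParams gen_face
#' @return an `ev_stimulus` with binary alpha and label `"nonface"`.
#' @export
gen_nonface <- function(params = stim_params(), seed = NULL) {
  validate_params(params)
  with_seed(seed, {
    np <- params$nonface
    side <- params$target_side
    canvas <- params$canvas
    e <- np$elong_offset + rlnorm(1, np$elong_meanlog, np$elong_sdlog)
    short <- max(16L, round(side / e))
    transpose <- runif(1) < 0.5

    if (runif(1) < np$oval_prob) {
      n <- runif(1, 1.7, 3.2)
      mask_small <- superellipse_mask(short, side, n, canvas)
      rr <- range(which(rowSums(mask_small) > 0))
      cc <- range(which(colSums(mask_small) > 0))
      core <- mask_small[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    } else {
      k <- sample(np$n_shapes[1]:np$n_shapes[2], 1)
      core <- blob_union_mask(k, canvas)
      core <- resize_mask_max(core, side, short)
    }
    if (transpose) core <- t(core)

    mask <- matrix(FALSE, canvas, canvas)
    r0 <- floor((canvas - nrow(core)) / 2)
    c0 <- floor((canvas - ncol(core)) / 2)
    mask[r0 + seq_len(nrow(core)), c0 + seq_len(ncol(core))] <- core

    co <- norm_coords(ncol(core), nrow(core), canvas)
    f1 <- runif(1, 0.4, 1.6); f2 <- runif(1, 0.4, 1.6); ph <- runif(1, 0, 2 * pi)
    z <- rnorm(1, 0, 0.6) * co$dx + rnorm(1, 0, 0.6) * co$dy +
      runif(1, 0.3, 1.0) * sin(pi * (f1 * co$dx + f2 * co$dy) + ph)
    mean_t <- clip255(rnorm(1, np$lum[1], np$lum[2]))
    sd_t <- max(5, rnorm(1, np$contrast[1], np$contrast[2]))
    pix <- standardize_foreground(z, mask, mean_t, sd_t)
    new_stimulus(pix, mask * 1, "nonface")
  })
}

#' Generate a scene-like background texture
#'
#' A horizon split plus 1/f-amplitude-spectrum texture and a few random
#' edges, histogram-equalised so the empirical luminance CDF is uniform on
#' \[0, 255\] (the treatment applied to over/under-exposed landscape
#' photographs before use as backgrounds).
#'
#' @param size side of the square output in px (>= 64).
#' @param seed optional integer seed.
#' @return a `size` x `size` numeric matrix with values in \[0, 255\].
#' @export
gen_scene <- function(size = 340L, seed = NULL) {
  if (!is.numeric(size) || length(size) != 1L || size < 64)
    stop_param("size must be a single integer >= 64")
  size <- as.integer(size)
  with_seed(seed, {
    horizon <- round(runif(1, 0.3, 0.7) * size)
    base <- matrix(runif(1, 80, 170), size, size)
    base[(horizon + 1):size, ] <- runif(1, 80, 170)

    tex <- pink_noise_field(size)
    tex <- tex / sd_pop(tex) * 30

    img <- base + tex
    for (i in seq_len(sample(2:4, 1))) {    # a few hard-edged patches
      r <- sort(sample.int(size, 2)); c <- sort(sample.int(size, 2))
      img[r[1]:r[2], c[1]:c[2]] <- img[r[1]:r[2], c[1]:c[2]] + runif(1, -60, 60)
    }
    n <- length(img)
    eq <- (rank(img, ties.method = "first") - 0.5) / n * 255
    matrix(eq, size, size)
  })
}

# Zero-mean 1/f-amplitude texture via FFT filtering of white noise.
pink_noise_field <- function(size) {
  w <- matrix(rnorm(size * size), size, size)
  fx <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  f <- sqrt(outer(fx^2, fx^2, "+"))
  amp <- 1 / pmax(f, 1 / size)
  amp[1, 1] <- 0
  tex <- Re(fft(fft(w) * amp, inverse = TRUE)) / (size * size)
  tex - mean(tex)
}

#' Low-level statistics of a stimulus
#'
#' Mean luminance and RMS contrast (population SD, 0-255 scale) are computed
#' over foreground pixels only (alpha > 0); fraction filled is the share of
#' foreground pixels in the full 256 x 256 canvas; elongation is the larger
#' of width/height and height/width of the foreground bounding box.
#'
#' @param s an `ev_stimulus`.
#' @return a list with `mean_luminance`, `rms_contrast`, `fraction_filled`,
#'   `elongation`.
#' @export
stim_stats <- function(s) {
  fg <- s$alpha > 0
  if (!any(fg)) stop_input("stimulus has an empty alpha mask")
  v <- s$pixels[fg]
  rr <- range(which(rowSums(fg) > 0)); cc <- range(which(colSums(fg) > 0))
  h <- rr[2] - rr[1] + 1; w <- cc[2] - cc[1] + 1
  list(mean_luminance = mean(v),
       rms_contrast = sd_pop(v),
       fraction_filled = sum(fg) / length(fg),
       elongation = max(w / h, h / w))
}

#' Match the mean foreground luminance of two stimulus sets
#'
#' Computes the ratio of set A's average foreground mean luminance to set
#' B's, multiplies every foreground pixel of B by that factor (clipping to
#' \[0, 255\]), and returns both the factor and the adjusted set. This is the
#' set-level luminance equation step applied to the non-face class.
#'
#' @param setA,setB lists of `ev_stimulus` objects.
#' @return list with `factor` and `setB` (adjusted).
#' @export
match_luminance_sets <- function(setA, setB) {
  if (length(setA) == 0 || length(setB) == 0)
    stop_param("both stimulus sets must be nonempty")
  mA <- mean(vapply(setA, function(s) mean(s$pixels[s$alpha > 0]), 0))
  mB <- mean(vapply(setB, function(s) mean(s$pixels[s$alpha > 0]), 0))
  factor <- mA / mB
  setB <- lapply(setB, function(s) {
    fg <- s$alpha > 0
    s$pixels[fg] <- clip255(s$pixels[fg] * factor)
    s
  })
  list(factor = factor, setB = setB)
}

#' Generate a labelled face/non-face stimulus pool
#'
#' Generates `n_per_class` faces and non-faces and applies
#' [match_luminance_sets()] so the two classes have matched mean foreground
#' luminance, mirroring the construction of the benchmark image sets. For
#' the gender task (`task = "gender"`) the pool holds male-like and
#' female-like faces instead.
#'
#' @param n_per_class stimuli per class.
#' @param params an [stim_params()] object.
#' @param task `"face"` (face vs non-face) or `"gender"`.
#' @param seed optional integer seed.
#' @return list with `stimuli` (list) and `label` (factor; first level is
#'   the "signal" class scored as a hit).
#' @export
make_pool <- function(n_per_class, params = stim_params(),
                      task = c("face", "gender"), seed = NULL) {
  task <- match.arg(task)
  if (n_per_class < 1) stop_param("n_per_class must be >= 1")
  with_seed(seed, {
    if (task == "face") {
      faces <- lapply(seq_len(n_per_class), function(i) gen_face(params))
      nonfaces <- lapply(seq_len(n_per_class), function(i) gen_nonface(params))
      nonfaces <- match_luminance_sets(faces, nonfaces)$setB
      list(stimuli = c(faces, nonfaces),
           label = factor(rep(c("face", "nonface"), each = n_per_class),
                          levels = c("face", "nonface")))
    } else {
      males <- lapply(seq_len(n_per_class),
                      function(i) gen_face(params, "male-like"))
      females <- lapply(seq_len(n_per_class),
                        function(i) gen_face(params, "female-like"))
      list(stimuli = c(males, females),
           label = factor(rep(c("male-like", "female-like"),
                              each = n_per_class),
                          levels = c("male-like", "female-like")))
    }
  })
}
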