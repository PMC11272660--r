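test_that("generators are pure functions of (params, seed)", {
  expect_identical(gen_face(seed = 3), gen_face(seed = 3))
  expect_identical(gen_nonface(seed = 4), gen_nonface(seed = 4))
  expect_identical(gen_scene(128, seed = 5), gen_scene(128, seed = 5))
  expect_identical(gen_face(seed = 3, sublabel = "male-like"),
                   gen_face(seed = 3, sublabel = "male-like"))
  # the caller's RNG stream is untouched
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(gen_face(seed = 3)); b <- runif(1)
  expect_identical(a, b)
})

test_that("foreground geometry invariants hold by construction", {
  for (s in c(face_samples()[1:20], nonface_samples()[1:20])) {
    expect_identical(dim(s$pixels), c(256L, 256L))
    expect_identical(dim(s$alpha), c(256L, 256L))
    expect_true(all(s$alpha %in% c(0, 1)))          # binary at generation
    fg <- s$alpha > 0
    expect_true(any(fg))                             # nonempty, in canvas
    rr <- range(which(rowSums(fg) > 0))
    cc <- range(which(colSums(fg) > 0))
    expect_equal(max(diff(rr), diff(cc)) + 1L, 246L) # largest side 246 px
    expect_true(all(s$pixels >= 0 & s$pixels <= 255))
  }
})

test_that("stim_stats matches closed-form values on constructed stimuli", {
  uniform <- new_stimulus_for_test(matrix(128, 256, 256), matrix(1, 256, 256))
  st <- stim_stats(uniform)
  expect_equal(st$mean_luminance, 128)
  expect_equal(st$rms_contrast, 0)
  expect_equal(st$fraction_filled, 1)
  expect_equal(st$elongation, 1)

  rect_alpha <- matrix(0, 256, 256); rect_alpha[, 1:128] <- 1
  rect <- new_stimulus_for_test(matrix(100, 256, 256) * rect_alpha, rect_alpha)
  st <- stim_stats(rect)
  expect_equal(st$fraction_filled, 0.5)
  expect_equal(st$elongation, 2)

  # two-point {0, 255} luminance: mean 127.5, population SD 127.5
  half <- matrix(0, 256, 256); half[, 1:128] <- 255
  twopoint <- new_stimulus_for_test(half, matrix(1, 256, 256))
  st <- stim_stats(twopoint)
  expect_equal(st$mean_luminance, 127.5)
  expect_equal(st$rms_contrast, 127.5)

  empty <- new_stimulus_for_test(matrix(0, 256, 256), matrix(0, 256, 256))
  expect_error(stim_stats(empty), class = "ev_input_error")
})

test_that("face class statistics land on the curated-set targets", {
  st <- stats_of(face_samples())
  expect_gt(mean(st["fraction_filled", ]), 0.50)
  expect_lt(mean(st["fraction_filled", ]), 0.62)
  expect_gt(mean(st["elongation", ]), 1.4)
  expect_lt(mean(st["elongation", ]), 1.9)
})

test_that("non-face shapes are broader than faces and include ovals", {
  stf <- stats_of(face_samples())
  stn <- stats_of(nonface_samples())
  expect_gt(sd(stn["elongation", ]), sd(stf["elongation", ]))
  expect_gt(mean(stn["elongation", ]), mean(stf["elongation", ]))
})

test_that("scene textures are histogram-equalised", {
  sc <- gen_scene(340, seed = 11)
  expect_identical(dim(sc), c(340L, 340L))
  expect_true(all(sc >= 0 & sc <= 255))
  frac_dark <- mean(sc < 127)
  expect_gt(frac_dark, 0.45)
  expect_lt(frac_dark, 0.55)
  expect_error(gen_scene(32), class = "ev_param_error")
})

test_that("luminance matching recovers a constructed scale factor", {
  A <- face_samples()[1:20]
  expect_equal(match_luminance_sets(A, A)$factor, 1.0)

  B <- lapply(A, function(s) {
    fg <- s$alpha > 0
    s$pixels[fg] <- s$pixels[fg] / 1.15
    s
  })
  m <- match_luminance_sets(A, B)
  expect_equal(m$factor, 1.15, tolerance = 1e-10)
  # post-adjustment set means agree to better than 1%
  mean_fg <- function(set) mean(vapply(set, function(s)
    mean(s$pixels[s$alpha > 0]), 0))
  expect_lt(abs(mean_fg(A) - mean_fg(m$setB)) / mean_fg(A), 0.01)
  expect_error(match_luminance_sets(list(), A), class = "ev_param_error")
})

test_that("pooled classes are luminance- and contrast-matched", {
  pool <- cached("match_pool", make_pool(150, seed = 77))
  st <- stats_of(pool$stimuli)
  f <- pool$label == "face"
  lum <- c(mean(st["mean_luminance", f]), mean(st["mean_luminance", !f]))
  rms <- c(mean(st["rms_contrast", f]), mean(st["rms_contrast", !f]))
  expect_lt(abs(lum[1] - lum[2]) / lum[1], 0.02)
  expect_lt(abs(rms[1] - rms[2]) / rms[1], 0.02)
})

test_that("gender sub-labels produce systematically different faces", {
  m <- gen_face(seed = 8, sublabel = "male-like")
  f <- gen_face(seed = 8, sublabel = "female-like")
  expect_identical(m$sublabel, "male-like")
  expect_identical(f$sublabel, "female-like")
  expect_false(identical(m$pixels, f$pixels))
  pool <- make_pool(3, task = "gender", seed = 5)
  expect_setequal(levels(pool$label), c("male-like", "female-like"))
})

test_that("invalid generator parameters are rejected", {
  expect_error(stim_params(face = list(lum = c(300, 5))),
               class = "ev_param_error")
  expect_error(stim_params(face = list(contrast = c(40, -1))),
               class = "ev_param_error")
  expect_error(stim_params(nonface = list(oval_prob = 2)),
               class = "ev_param_error")
  expect_error(stim_params(face = list(eye_dx = c(0.5, 0.1))),
               class = "ev_param_error")
})
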