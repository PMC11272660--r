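test_that("uniform backgrounds hit their defining constants", {
  bg <- make_background(background_spec("mid_gray"))
  expect_true(all(bg == 128))
  expect_identical(dim(bg), c(340L, 340L))

  s <- face_samples()[[1]]
  bg2 <- make_background(background_spec("image_mean_gray"), stim = s)
  expect_equal(bg2[1, 1], mean(s$pixels[s$alpha > 0]))
  expect_true(all(bg2 == bg2[1, 1]))
  expect_error(make_background(background_spec("image_mean_gray")),
               class = "ev_param_error")
})

test_that("pixelated backgrounds are block-constant with the right values", {
  blocks <- function(bg) {
    # constant within each origin-aligned 4x4 block
    anchors <- bg[seq(1, 340, by = 4), seq(1, 340, by = 4)]
    expanded <- anchors[rep(1:85, each = 4), rep(1:85, each = 4)]
    expect_identical(bg, expanded)
    as.vector(anchors)
  }
  bin <- make_background(background_spec("pixelated_binary"), seed = 2)
  expect_true(all(blocks(bin) %in% c(0, 255)))

  wht <- make_background(background_spec("pixelated_white"), seed = 2)
  vals <- blocks(wht)
  expect_true(all(vals >= 0 & vals <= 255 & vals == round(vals)))

  s <- face_samples()[[1]]
  smp <- make_background(background_spec("pixelated_image_sampled"),
                         stim = s, seed = 2)
  expect_true(all(blocks(smp) %in% s$pixels[s$alpha > 0]))
})

test_that("pink noise is full-resolution with the stated moments", {
  bg <- make_background(background_spec("pink_noise"), seed = 3)
  expect_true(all(bg >= 0 & bg <= 255))
  expect_lt(abs(mean(bg) - 128), 4)
  s <- sqrt(mean((bg - mean(bg))^2))
  expect_gt(s, 30); expect_lt(s, 45)
  # not block-constant: neighbouring pixels differ almost everywhere
  expect_gt(mean(bg[, 1:339] != bg[, 2:340]), 0.9)
})

test_that("blur and contrast scaling fix constant scenes", {
  const <- matrix(77, 340, 340)
  out <- earlyvision:::scene_blur(const)
  expect_equal(out, const, tolerance = 1e-12)
  # and halve deviations about the mean before blurring
  sc <- matrix(100, 340, 340); sc[1:170, ] <- 140
  out <- earlyvision:::scene_blur(sc, blur_sd = 0)   # contrast step only
  expect_equal(mean(out), mean(sc))
  expect_equal(max(out) - min(out), (max(sc) - min(sc)) / 2)
})

test_that("scene backgrounds draw deterministically from a pool", {
  sp <- make_scene_pool(3, seed = 10)
  spec <- background_spec("scene_blurred", scene_pool = sp)
  b1 <- make_background(spec, seed = 4)
  b2 <- make_background(spec, seed = 4)
  expect_identical(b1, b2)
  expect_true(any(vapply(sp$blurred, function(m) identical(m, b1), TRUE)))
  expect_error(background_spec("no_such_kind"), class = "ev_param_error")
})

test_that("nuisance identity returns the stimulus bit-exactly", {
  s <- face_samples()[[2]]
  expect_identical(transform_stim(s, nuisance_spec(1, 0), seed = 1), s)
})

test_that("rotating a centred disc preserves its foreground area", {
  xy <- outer(((1:256) - 128.5)^2, ((1:256) - 128.5)^2, "+")
  disc <- (xy <= 80^2) * 1
  s <- new_stimulus_for_test(disc * 200, disc)
  for (seed in 1:3) {
    t <- transform_stim(s, nuisance_spec(1, 180), seed = seed)
    expect_lt(abs(sum(t$alpha > 0.5) - sum(disc)) / sum(disc), 0.01)
  }
})

test_that("down-scaling shrinks foreground area by the square of the factor", {
  s <- face_samples()[[3]]
  for (seed in 1:3) {
    n <- nuisance_spec(scale_min = 0.5, rot_max = 0)
    u <- with(list(), {   # replicate the draw the transform makes
      earlyvision:::with_seed(seed, runif(1, 0.5, 1))
    })
    t <- transform_stim(s, n, seed = seed)
    ratio <- sum(t$alpha) / sum(s$alpha)
    expect_lt(abs(ratio - u^2) / u^2, 0.05)
  }
})

test_that("compositing places the window with jitter and conserves background", {
  s <- new_stimulus_for_test(matrix(200, 256, 256), matrix(1, 256, 256))
  bg <- make_background(background_spec("mid_gray"))
  out <- place_on_canvas(s, bg, jitter = c(0, 0))
  expect_equal(out[42 + 1:256, 42 + 1:256], s$pixels)
  expect_true(all(out[1:42, ] == 128) && all(out[, 1:42] == 128))

  transp <- new_stimulus_for_test(matrix(200, 256, 256), matrix(0, 256, 256))
  expect_equal(place_on_canvas(transp, bg, jitter = c(13, -20)), bg)

  # extreme jitter still keeps all foreground inside the canvas
  sface <- face_samples()[[1]]
  for (j in list(c(-42, -42), c(42, 42), c(-42, 42))) {
    out <- place_on_canvas(sface, bg, jitter = j)
    expect_identical(dim(out), c(340L, 340L))
  }
  expect_error(place_on_canvas(sface, bg, jitter_max = 43L),
               class = "ev_param_error")
})

test_that("composition is deterministic given a seed", {
  s <- face_samples()[[4]]
  n <- nuisance_spec(0.5, 90)
  b <- background_spec("pixelated_binary")
  expect_identical(compose_stimulus(s, n, b, seed = 21),
                   compose_stimulus(s, n, b, seed = 21))
})
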