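test_that("Kaiming-uniform initialisation respects its bound and seeds", {
  r <- init_readout(7088, seed = 5)
  expect_identical(r$b, 0)
  expect_true(all(abs(r$w) <= 1 / sqrt(7088)))
  expect_identical(r$w, init_readout(7088, seed = 5)$w)
  expect_false(identical(r$w, init_readout(7088, seed = 6)$w))
  expect_error(init_readout(0), class = "ev_param_error")
})

test_that("epoch resampling draws the right class composition", {
  pool <- list(label = factor(rep(c("face", "nonface"), c(40, 60)),
                              levels = c("face", "nonface")))
  idx <- resample_epoch(pool, 1500, seed = 2)
  expect_length(idx, 3000)
  expect_equal(sum(idx <= 40), 1500)    # faces drawn exactly per_class times
  expect_equal(sum(idx > 40), 1500)

  small <- list(label = factor(c("face", "nonface"),
                               levels = c("face", "nonface")))
  expect_setequal(resample_epoch(small, 1, seed = 1), c(1L, 2L))

  empty <- list(label = factor("face", levels = c("face", "nonface")))
  expect_error(resample_epoch(empty, 5), class = "ev_param_error")
})

test_that("with-replacement draws are uniform over the class", {
  pool <- list(label = factor(rep("a", 100), levels = c("a", "b")))
  idx_by <- split(seq_along(pool$label), pool$label)
  draws <- earlyvision:::with_seed(31, {
    idx_by$a[sample.int(100, 10000, replace = TRUE)]
  })
  freq <- tabulate(draws, 100)
  sd_bin <- sqrt(10000 * (1 / 100) * (99 / 100))
  expect_true(all(abs(freq - 100) < 4 * sd_bin))
})

test_that("SGD separates linearly separable feature blobs", {
  set.seed(11)
  n <- 150
  X <- rbind(matrix(rnorm(n * 20, mean = +0.6), n, 20),
             matrix(rnorm(n * 20, mean = -0.6), n, 20))
  y <- rep(c(1, 0), each = n)
  cfg <- train_config("fixed", epochs = 10, per_class = 300)
  r <- fit_logistic_sgd(X, y, cfg, seed = 3)
  acc <- mean(((X %*% r$w + r$b) > 0) == (y == 1))
  expect_gte(acc, 0.95)
})

test_that("label-shuffled features stay at chance on held-out data", {
  set.seed(12)
  X <- matrix(rnorm(1000 * 20), 1000, 20)
  y <- sample(rep(c(1, 0), 500))          # labels carry no signal
  tr <- 1:500; te <- 501:1000
  cfg <- train_config("fixed", epochs = 5, per_class = 250)
  r <- fit_logistic_sgd(X[tr, ], y[tr], cfg, seed = 4)
  acc <- mean(((X[te, ] %*% r$w + r$b) > 0) == (y[te] == 1))
  expect_gte(acc, 0.45)
  expect_lte(acc, 0.55)
})

test_that("early stopping waits out exactly the patience window", {
  set.seed(13)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rep(c(1, 0), 20)
  # lr = 0: validation accuracy can never improve after the first epoch
  cfg <- train_config("earlystop", epochs = 40, per_class = 10, lr = 0,
                      patience = 5)
  r <- fit_logistic_sgd(X, y, cfg, seed = 5, X_val = X, y_val = y)
  expect_identical(r$epochs_run, 6L)      # 1 baseline + 5 non-improving
})

test_that("divergent training raises a classed error", {
  set.seed(14)
  X <- matrix(rnorm(40 * 5, sd = 1000), 40, 5)
  y <- rep(c(1, 0), 20)
  cfg <- train_config("fixed", epochs = 5, per_class = 20, lr = 1e307)
  expect_error(fit_logistic_sgd(X, y, cfg, seed = 6),
               class = "ev_train_error")
})

test_that("prediction follows the logit sign with ties to non-face", {
  r <- structure(list(w = rep(0, 4), b = 1, n_inputs = 4L),
                 class = "ev_readout")
  expect_identical(predict_readout(r, rep(5, 4)), "face")
  r$b <- 0
  expect_identical(predict_readout(r, rep(5, 4)), "nonface")  # exact tie

  set.seed(15)
  r2 <- structure(list(w = rnorm(4), b = 0.3, n_inputs = 4L),
                  class = "ev_readout")
  F <- matrix(rnorm(40), 10, 4)
  p1 <- predict_readout(r2, F)
  r3 <- r2; r3$w <- -r3$w; r3$b <- -r3$b
  p2 <- predict_readout(r3, F)
  expect_true(all(p1 != p2))              # antisymmetry off the boundary
  expect_error(predict_readout(r2, rep(1, 5)), class = "ev_param_error")
})

test_that("full streaming training runs are bit-for-bit reproducible", {
  pool <- tiny_pool()
  bs <- background_spec("mid_gray")
  ns <- nuisance_spec(0.7, 45)
  banks <- list(simple = bank_of("simple"), lgn = bank_of("lgn"))
  r1 <- train_readouts(banks, pool, bs, ns, tiny_cfg(), seed = 17)
  r2 <- train_readouts(banks, pool, bs, ns, tiny_cfg(), seed = 17)
  expect_identical(r1$simple$w, r2$simple$w)
  expect_identical(r1$lgn$w, r2$lgn$w)
  expect_true(all(is.finite(r1$simple$w)))
})

test_that("training configuration is validated", {
  expect_error(train_config("fixed", epochs = 0), class = "ev_param_error")
  expect_error(train_config("earlystop", epochs = 4, patience = 5),
               class = "ev_param_error")
  expect_identical(train_config("fixed")$epochs, 10L)
  expect_identical(train_config("fixed")$per_class, 1500L)
  expect_identical(train_config("earlystop")$per_class, 400L)
  expect_identical(train_config("earlystop")$epochs, 40L)
})
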