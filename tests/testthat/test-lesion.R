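test_that("channel lesions remove exactly the targeted units", {
  simple <- bank_of("simple")
  keep_all <- apply_channel_lesion(simple, lesion_spec("keep_channels", 1:4))
  expect_equal(keep_all$unit_count, 7088L)

  drop32 <- apply_channel_lesion(simple, lesion_spec("drop_channels", 4))
  expect_equal(drop32$unit_count, 7088L - 5776L)   # 1,312

  only32 <- apply_channel_lesion(simple, lesion_spec("keep_channels", 4))
  expect_equal(only32$unit_count, 5776L)

  # dropping 3 of 4 channels keeps exactly one channel's units
  one <- apply_channel_lesion(simple, lesion_spec("drop_channels", c(1, 2, 4)))
  expect_setequal(unique(one$index_map$lambda), 64)
  expect_equal(one$unit_count, 1024L)

  expect_error(apply_channel_lesion(simple, lesion_spec("drop_channels", 1:4)),
               class = "ev_param_error")
  expect_error(lesion_spec("drop_channels", integer(0)),
               class = "ev_param_error")
})

test_that("lesioning never alters surviving kernels", {
  simple <- bank_of("simple")
  les <- apply_channel_lesion(simple, lesion_spec("drop_channels", c(1, 2)))
  expect_identical(les$channels[[1]]$kernels, simple$channels[[3]]$kernels)
  expect_identical(les$channels[[2]]$kernels, simple$channels[[4]]$kernels)

  unit_les <- apply_unit_lesion(simple, c(5, 100, 7000))
  expect_identical(unit_les$channels, simple$channels)
  expect_equal(unit_les$unit_count, 3L)
  set.seed(20)
  cv <- matrix(runif(340 * 340, 0, 255), 340, 340)
  f_full <- encode(cv, simple)
  f_les <- encode(cv, unit_les)
  expect_identical(f_les, f_full[c(5, 100, 7000)])
})

test_that("sign-consistency selection is monotone and null-calibrated", {
  set.seed(21)
  W <- matrix(rnorm(200 * 10), 200, 10)
  W[1:5, ] <- abs(W[1:5, ])            # 5 units always positive
  cs10 <- consistency_sets(W, 10)
  expect_true(all(1:5 %in% cs10$kept))

  # kept sets are nested as the threshold relaxes
  k10 <- consistency_sets(W, 10)$kept
  k9 <- consistency_sets(W, 9)$kept
  k8 <- consistency_sets(W, 8)$kept
  expect_true(all(k10 %in% k9) && all(k9 %in% k8))

  # all runs sharing signs keeps every unit at any threshold
  Wsame <- matrix(rep(rnorm(50), 10), 50, 10)
  expect_length(consistency_sets(Wsame, 10)$kept, 50)

  # zero weights count as sign-inconsistent
  Wz <- Wsame; Wz[1, 1] <- 0
  expect_false(1 %in% consistency_sets(Wz, 10)$kept)
  expect_true(1 %in% consistency_sets(Wz, 9)$kept)

  # i.i.d. random signs at threshold 90/100: binomial tail ~3e-9 per unit,
  # so the kept set is empty
  set.seed(22)
  Wnull <- matrix(sample(c(-1, 1), 7088 * 100, replace = TRUE), 7088, 100)
  expect_length(consistency_sets(Wnull, 90)$kept, 0)

  expect_error(consistency_sets(W, 11), class = "ev_param_error")
})

test_that("identity lesions reproduce full-model records bit-for-bit", {
  pool <- tiny_pool()
  bs <- background_spec("mid_gray")
  ns <- nuisance_spec(0.7, 45)
  grid <- condition_grid(backgrounds = list(bs), scale_levels = 0.7,
                         rot_levels = 45, n_repeats = 1)
  base <- run_grid(grid, "lgn", pool, base_seed = 70, cfg = tiny_cfg(),
                   eval_per_class = 10)
  les <- run_lesion_experiment("lgn", lesion_spec("keep_channels", 1:4),
                               pool, bs, ns, base_seed = 70,
                               cfg = tiny_cfg(), eval_per_class = 10,
                               n_repeats = 1)
  expect_equal(les[, names(base)], base)
  expect_match(les$lesion[1], "keep_channels")
})

test_that("consistency lesions require completed base runs", {
  expect_error(
    run_lesion_experiment("simple", lesion_spec("keep_consistent",
                                                consistency_threshold = 5),
                          tiny_pool(), background_spec("mid_gray"),
                          nuisance_spec(1, 0), base_seed = 1),
    class = "ev_dependency_error")
})
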