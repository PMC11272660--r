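test_that("Gabor kernels have the prescribed support, symmetry and norm", {
  k0 <- gabor_kernel(32, 0, 0)
  expect_identical(dim(k0), c(48L, 48L))            # round(1.5 * 32)
  expect_identical(dim(gabor_kernel(256, 0, 0)), c(384L, 384L))
  expect_equal(sum(k0^2), 1)
  expect_lt(abs(mean(k0)), 1e-15)                   # zero DC

  # 180 degree phase shift negates the carrier, hence the whole kernel
  for (th in c(0, 45, 90, 135)) {
    expect_equal(gabor_kernel(32, th, 180), -gabor_kernel(32, th, 0))
    expect_equal(gabor_kernel(32, th, 270), -gabor_kernel(32, th, 90))
  }

  # theta = 90 kernel is the 90-degree rotation of theta = 0
  rot90 <- function(m) t(m)[nrow(m):1, ]
  expect_equal(gabor_kernel(32, 90, 0), rot90(gabor_kernel(32, 0, 0)),
               tolerance = 1e-12)
})

test_that("DoG kernels follow the integrated-gain centre-surround layout", {
  on <- dog_kernel(64, "on")
  off <- dog_kernel(64, "off")
  expect_identical(dim(on), c(96L, 96L))
  expect_equal(off, -on)
  expect_equal(sum(on^2), 1)
  # radially symmetric: invariant under 90-degree rotation
  rot90 <- function(m) t(m)[nrow(m):1, ]
  expect_equal(on, rot90(on), tolerance = 1e-12)
  # pre-normalisation mass: centre gain 1 minus surround gain 0.2 times the
  # surround mass surviving the square truncation at +/-1.8 sigma_s per
  # axis (support/sigma_s = 1.5*lambda / (5*lambda/12) = 3.6 for every
  # channel), i.e. 1 - 0.2 * (2*pnorm(1.8) - 1)^2 ~= 0.828
  want <- 1 - 0.2 * (2 * pnorm(1.8) - 1)^2
  for (lam in c(32, 64, 128, 256)) {
    s <- sum(earlyvision:::dog_kernel_raw(lam))
    expect_lt(abs(s - want), 0.005)
  }
})

test_that("bank unit counts and grids match the architecture", {
  simple <- bank_of("simple")
  expect_equal(simple$unit_count, 7088L)
  # lambda = 32 channel tiles a 19 x 19 grid: floor((340 - 48)/16) + 1
  expect_length(simple$channels[[4]]$offsets, 19L)
  expect_equal(nrow(simple$index_map), 7088L)
  expect_error(build_bank("simple", gain = -1), class = "ev_param_error")
})

test_that("zero input produces exactly zero features for every model kind", {
  black <- matrix(0, 340, 340)
  for (kind in c("simple", "complex", "linear", "lgn"))
    expect_identical(unique(encode(black, bank_of(kind))), 0)
})

test_that("uniform input silences valid-placement DC-free V1 kernels", {
  uni <- matrix(130, 340, 340)
  for (kind in c("simple", "complex", "linear")) {
    b <- bank_of(kind)
    f <- encode(uni, b)
    # fully-contained channels see a uniform patch and a zero-DC kernel;
    # the zero-padded lambda = 256 channel legitimately responds, because
    # its kernels only integrate to zero over their full support
    valid <- b$index_map$lambda != 256
    expect_lt(max(abs(f[valid])), 1e-10)
  }
  expect_gt(max(encode(uni, bank_of("lgn"))), 0.1)
})

test_that("encoding matches direct dot-product oracles to 1e-10 relative", {
  set.seed(404)
  canvas <- matrix(runif(340 * 340, 0, 255), 340, 340)
  bank <- bank_of("simple")
  raw <- earlyvision:::encode_raw(canvas, bank)
  # every channel, incl. the zero-padded lambda = 256 corner placement
  cases <- list(c(1, 1, 1), c(1, 3, 3), c(2, 2, 1), c(3, 5, 8), c(4, 19, 10))
  for (cs in cases) {
    ci <- cs[1]; gr <- cs[2]; gc <- cs[3]
    n1 <- bank$channels[[ci]]$n1
    for (kcol in c(1, 4, 8)) {
      want <- oracle_response(canvas, bank, ci, gr, gc, kcol)
      got <- raw[[ci]][(gr - 1) * n1 + gc, kcol]
      expect_lt(abs(got - want), 1e-10 * max(1, abs(want)))
    }
  }
  lgn <- bank_of("lgn")
  raw_l <- earlyvision:::encode_raw(canvas, lgn)
  want <- oracle_response(canvas, lgn, 4, 7, 7, 1)
  expect_lt(abs(raw_l[[4]][(7 - 1) * 19 + 7, 1] - want), 1e-10 * max(1, abs(want)))
})

test_that("complex features equal |r0| + |r90| of the quadrature pair", {
  set.seed(7)
  canvas <- matrix(runif(340 * 340, 0, 255), 340, 340)
  cx <- bank_of("complex")
  fc <- encode(canvas, cx)
  # oracle from unrectified phase responses at a lambda=64 placement
  map <- cx$index_map
  i <- which(map$lambda == 64 & map$row == 3 & map$col == 5 & map$theta == 45)
  ci <- map$channel[i]
  n1 <- cx$channels[[ci]]$n1
  r0 <- oracle_response(canvas, cx, ci, 3, 5, (2 - 1) * 2 + 1)  # theta 45, phase 0
  r90 <- oracle_response(canvas, cx, ci, 3, 5, (2 - 1) * 2 + 2)
  expect_equal(fc[i], abs(r0) + abs(r90), tolerance = 1e-10)
})

test_that("simple, linear and LGN stages are mutually consistent", {
  set.seed(8)
  canvas <- matrix(runif(340 * 340, 0, 255), 340, 340)
  fs <- encode(canvas, bank_of("simple"))
  fc <- encode(canvas, bank_of("complex"))
  fl <- encode(canvas, bank_of("linear"))
  fg <- encode(canvas, bank_of("lgn"))

  # summing simple units over the 4 phases reproduces complex exactly
  sums <- rowSums(matrix(fs, ncol = 4, byrow = TRUE))
  expect_equal(sums, fc, tolerance = 1e-12)

  # simple units are the rectified +/- halves of the linear responses
  m <- bank_of("simple")$index_map
  lin_map <- bank_of("linear")$index_map
  expect_equal(fs[m$phase %in% c(0, 90)], pmax(fl, 0), tolerance = 1e-12)
  expect_equal(fs[m$phase %in% c(180, 270)], pmax(-fl, 0), tolerance = 1e-12)

  # all rectified kinds are nonnegative; linear is signed
  expect_true(all(fs >= 0) && all(fc >= 0) && all(fg >= 0))
  expect_true(any(fl < 0))

  # LGN off units are the rectified negation of the on responses
  off <- fg[seq(2, length(fg), by = 2)]
  on <- fg[seq(1, length(fg), by = 2)]
  expect_true(all(pmin(on, off) == 0 | abs(pmin(on, off)) < 1e-14))
})

test_that("the linear encoding is positively homogeneous", {
  set.seed(9)
  canvas <- matrix(runif(340 * 340, 0, 255), 340, 340)
  lin <- bank_of("linear")
  f1 <- encode(canvas, lin)
  f2 <- encode(0.37 * canvas, lin)
  expect_equal(f2, 0.37 * f1, tolerance = 1e-10)
})

test_that("canvas shape mismatches are rejected", {
  expect_error(encode(matrix(0, 100, 100), bank_of("simple")),
               class = "ev_param_error")
})
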