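test_that("Gabor bank has evenly spaced, DC-free, unit-norm kernels", {
  bank <- build_gabor_bank(sigma = 8, wavelength = 12, n_orientations = 8,
                           support = 33)
  expect_length(bank$kernels, 8)
  expect_equal(bank$orientations, seq(0, 157.5, by = 22.5))
  for (k in bank$kernels) {
    expect_lt(abs(mean(k)), 1e-10)
    expect_equal(sum(k^2), 1, tolerance = 1e-12)
    expect_equal(dim(k), c(33L, 33L))
  }
  expect_error(build_gabor_bank(sigma = -1), "positive")
  expect_error(build_gabor_bank(wavelength = 0), "positive")
  expect_error(build_gabor_bank(support = 32), "odd")
  expect_error(build_gabor_bank(n_orientations = 1), "at least 2")
})

test_that("matched gratings select their own kernel over the whole bank", {
  bank <- build_gabor_bank()
  pyr1 <- function(f) build_pyramid(f, 1L)
  for (t in c(1L, 3L, 6L)) {
    g <- make_grating(64, 12, bank$orientations[t])
    raw <- oriented_responses(pyr1(g), bank)[[1]]
    strength <- apply(abs(raw), 3, mean)
    expect_equal(which.max(strength), t)
  }
})

test_that("constant images give zero response for every kernel", {
  bank <- build_gabor_bank(sigma = 4, wavelength = 6, support = 17)
  raw <- oriented_responses(build_pyramid(matrix(0.37, 32, 32), 1L), bank)[[1]]
  expect_lt(max(abs(raw)), 1e-12)
})

test_that("impulse response at the finest scale reproduces the kernel", {
  bank <- build_gabor_bank(sigma = 4, wavelength = 6, support = 17)
  f <- matrix(0, 48, 48); f[24, 24] <- 1
  raw <- oriented_responses(build_pyramid(f, 1L), bank)[[1]]
  for (t in seq_along(bank$kernels)) {
    patch <- raw[16:32, 16:32, t]
    flipped <- bank$kernels[[t]][17:1, 17:1]
    expect_equal(patch, flipped, tolerance = 1e-10)
  }
})

test_that("pyramid levels halve with ceiling dims and preserve constants", {
  p <- build_pyramid(matrix(0.42, 100, 80), 4L)
  expect_equal(lapply(p$levels, dim),
               list(c(100L, 80L), c(50L, 40L), c(25L, 20L), c(13L, 10L)))
  for (L in p$levels) expect_lt(max(abs(L - 0.42)), 1e-6)
  # n_scales = 1 is the identity
  f <- matrix(runif(32 * 32), 32, 32)
  expect_identical(build_pyramid(f, 1L)$levels[[1]], f)
  # depth reduced with a warning when the coarsest level would drop below 8 px
  expect_warning(p2 <- build_pyramid(f, 8L), "reduced")
  expect_equal(p2$n_scales, 3L)
  expect_error(build_pyramid(matrix(0.5, 8, 8)), "at least 16x16")
  expect_error(build_pyramid(matrix(2, 32, 32)), "\\[0,1\\]")
})

test_that("downsample/upsample round trip of a smooth image stays accurate", {
  x <- seq(0, 1, length.out = 64)
  f <- outer(x, x, function(a, b) 0.5 + 0.3 * sin(2 * pi * a) * cos(2 * pi * b))
  p <- build_pyramid(f, 2L)
  back <- lanczos_resize(p$levels[[2]], 64, 64)
  expect_lt(sqrt(mean((back - f)^2)), 0.02)
})

test_that("optimal orientation is the exhaustive argmax with first-index ties", {
  set.seed(11)
  raw <- array(rnorm(6 * 5 * 8), dim = c(6, 5, 8))
  opt <- optimal_orientation(raw)
  for (i in 1:6) for (j in 1:5) {
    v <- raw[i, j, ]
    expect_equal(opt$angle_index[i, j], which.max(abs(v)))
    expect_equal(opt$signed[i, j], v[which.max(abs(v))])
  }
  # exhaustive example: responses (+0.2, -0.5, +0.1, 0, ...) -> -0.5 at index 2
  raw2 <- array(0, dim = c(1, 1, 8)); raw2[1, 1, 1:3] <- c(0.2, -0.5, 0.1)
  opt2 <- optimal_orientation(raw2)
  expect_equal(opt2$signed[1, 1], -0.5)
  expect_equal(opt2$angle_index[1, 1], 2L)
  # ties and the all-zero case go to the lowest index
  raw3 <- array(0.3, dim = c(1, 1, 8))
  expect_equal(optimal_orientation(raw3)$angle_index[1, 1], 1L)
  raw4 <- array(0, dim = c(2, 2, 8))
  expect_true(all(optimal_orientation(raw4)$angle_index == 1L))
  expect_true(all(optimal_orientation(raw4)$signed == 0))
})

test_that("rotating a bar by one bank step shifts the winning orientation", {
  bank <- build_gabor_bank()
  for (t in seq_along(bank$orientations)) {
    f <- make_bar_frame(96, bank$orientations[t])
    raw <- oriented_responses(build_pyramid(f, 1L), bank)[[1]]
    opt <- optimal_orientation(raw)
    expect_equal(opt$angle_index[48, 48], t)
    expect_lt(opt$signed[48, 48], 0)  # dark bar: negative center response
  }
})

test_that("polarity split is a nonnegative exact decomposition", {
  set.seed(7)
  s <- matrix(rnorm(400), 20, 20)
  pol <- split_polarity(s)
  expect_true(all(pol$pos >= 0) && all(pol$neg >= 0))
  expect_identical(pol$pos - pol$neg, s)
  expect_true(all(pol$pos * pol$neg == 0))   # at most one side active
  expect_equal(split_polarity(matrix(-0.5, 1, 1)),
               list(pos = matrix(0, 1, 1), neg = matrix(0.5, 1, 1)))
})

test_that("noise floor gates the bottom percentile and nothing else", {
  m <- matrix(c(1:100), 10, 10)
  nf <- noise_floor(m / 100, percentile = 0.05)
  expect_equal(nf$thr, 0.05)                      # type-1 quantile of 1..100
  expect_equal(sum(nf$clean == 0), 4)             # 1..4 zeroed, 5 kept
  kept <- nf$clean[nf$clean > 0]
  expect_identical(sort(kept), sort(m[m >= 5] / 100))  # survivors untouched
  # all-zero map unchanged with thr 0
  z <- matrix(0, 4, 4)
  expect_identical(noise_floor(z), list(clean = z, thr = 0))
  # a single nonzero entry survives (quantile of a singleton is itself)
  s <- matrix(0, 3, 3); s[2, 2] <- 0.3
  expect_identical(noise_floor(s)$clean, s)
  # property: removes at most ceil(p * N_nonzero)
  set.seed(21)
  for (i in 1:20) {
    x <- matrix(runif(64), 8, 8) * (runif(64) > 0.3)
    p <- runif(1, 0.01, 0.4)
    out <- noise_floor(x, p)
    expect_lte(sum(x > 0) - sum(out$clean > 0), ceiling(p * sum(x > 0)))
    expect_identical(out$clean[out$clean > 0], x[out$clean > 0])
  }
  # max-fraction variant
  expect_equal(noise_floor(m / 100, 0.05, mode = "max_fraction")$thr, 0.95)
})

test_that("Naka-Rushton is a monotone gain with exact half-saturation", {
  expect_equal(naka_rushton(0.1, n = 2, sigma_nr = 0.1), 0.5, tolerance = 1e-13)
  expect_equal(naka_rushton(0.3, n = 2, sigma_nr = 0.1), 0.9)  # 0.09/0.10
  expect_equal(naka_rushton(0), 0)
  cc <- seq(0.001, 2, length.out = 200)
  r <- naka_rushton(cc)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < 1))
  # alternative parameter reading: sigma given as sigma^n
  expect_equal(naka_rushton(sqrt(0.1), n = 2, sigma_nr = 0.1,
                            sigma_is_power = TRUE), 0.5, tolerance = 1e-13)
  expect_error(naka_rushton(-0.1), "nonnegative")
  expect_error(naka_rushton(0.1, n = 0.5), ">= 1")
})

test_that("edge decomposition bundles per-scale channels consistently", {
  cfg <- default_config()
  f <- make_bar_frame(64, 0)
  pyr <- build_pyramid(f, 2L)
  bank <- build_gabor_bank()
  ed <- edge_decompose(pyr, bank, cfg)
  expect_s3_class(ed, "edge_stack")
  expect_length(ed$per_scale, 2)
  for (es in ed$per_scale) {
    expect_true(all(es$pos >= 0) && all(es$neg >= 0))
    expect_true(all(es$nr$pos >= 0 & es$nr$pos < 1))
    expect_true(all(es$nr$neg >= 0 & es$nr$neg < 1))
  }
})
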