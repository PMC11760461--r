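test_that("additive masks have the stated symmetries and zeroed RF disk", {
  m0 <- additive_mask(0, sigma_x = 6, sigma_y = 2, rf_radius = 3)
  expect_equal(sum(m0), 1, tolerance = 1e-12)
  expect_equal(m0, m0[rev(seq_len(nrow(m0))), ], tolerance = 1e-12)  # even in y
  # elongated along x for theta = 0
  h <- (nrow(m0) + 1) / 2
  expect_gt(m0[h, h + 8], m0[h + 8, h])
  # theta = 90 is the transpose of theta = 0
  m90 <- additive_mask(90, sigma_x = 6, sigma_y = 2, rf_radius = 3)
  expect_equal(m90, t(m0), tolerance = 1e-10)
  # the classical-RF disk is zero (no self-facilitation)
  off <- abs(seq_len(nrow(m0)) - h)
  inside <- outer(off^2, off^2, `+`) <= 9
  expect_true(all(m0[inside] == 0))
  # an RF radius beyond the support empties the mask, with a warning
  expect_warning(me <- additive_mask(0, 1, 1, rf_radius = 50, support = 9),
                 "empty")
  expect_true(all(me == 0))
})

test_that("a single inducer projects a scaled, centered additive mask", {
  masks <- additive_masks_for_scale(c(0, 90), sigma_x = 4, sigma_y = 4,
                                    rf_radius = 2, support = 17)
  nr <- matrix(0, 40, 40); nr[20, 20] <- 0.6
  ang <- matrix(1L, 40, 40)
  fields <- induce_additive(nr, ang, masks, a = 0.5)
  expect_equal(fields[[1]]$induced[12:28, 12:28], 0.5 * 0.6 * masks[[1]],
               tolerance = 1e-12)
  # channel 2 has no sources (angle map is all channel 1)
  expect_true(all(fields[[2]]$own == 0) && all(fields[[2]]$induced == 0))
  # zero response and zero strength both give zero fields
  expect_true(all(induce_additive(nr * 0, ang, masks, 1)[[1]]$induced == 0))
  expect_true(all(induce_additive(nr, ang, masks, 0)[[1]]$induced == 0))
})

test_that("collinear flankers reinforce the gap more than orthogonal ones", {
  masks <- additive_masks_for_scale(c(0, 90), sigma_x = 6, sigma_y = 2,
                                    rf_radius = 3, support = 25)
  n <- 60; mid <- 30
  one_bar <- matrix(0, n, n); one_bar[mid, 10:24] <- 0.8
  two_coll <- one_bar; two_coll[mid, 36:50] <- 0.8
  ang <- matrix(1L, n, n)
  lf1 <- collinear_sum(induce_additive(one_bar, ang, masks, 1))[, , 1]
  lf2 <- collinear_sum(induce_additive(two_coll, ang, masks, 1))[, , 1]
  gap <- cbind(mid, 27:33)
  # superposition: the second bar strictly raises LF in the gap
  expect_true(all(lf2[gap] > lf1[gap]))
  # an orthogonal second bar contributes to its own channel, not the gap's
  two_orth <- one_bar; orth_src <- matrix(0, n, n); orth_src[22:36, 43] <- 0.8
  ang_mix <- matrix(1L, n, n); ang_mix[22:36, 43] <- 2L
  lf_orth <- collinear_sum(induce_additive(two_orth + orth_src, ang_mix,
                                           masks, 1))[, , 1]
  expect_true(all(lf_orth[gap] < lf2[gap]))
  expect_equal(lf_orth[gap], lf1[gap], tolerance = 1e-12)
})

test_that("percentile soft threshold gates, scales, and degenerates as specified", {
  # all-zero input stays zero
  z <- matrix(0, 5, 5)
  expect_identical(percentile_soft_threshold(z, 99)$lf_thr, z)
  # gamma = 99 on 100 distinct values: only the top value has gate factor > 1/2
  v <- matrix(seq(0.01, 1, by = 0.01), 10, 10)
  st <- percentile_soft_threshold(v, 99)
  expect_equal(st$thr, 0.99)
  expect_equal(sum(v > st$thr), 1)            # the activated set
  expect_equal(which(st$lf_thr == max(st$lf_thr)), which(v == 1))
  # below-threshold values are exactly zero; at-threshold is halved
  expect_true(all(st$lf_thr[v < 0.99] == 0))
  expect_equal(st$lf_thr[v == 0.99], 0.99 * 0.5, tolerance = 1e-12)
  # infinite steepness recovers the hard threshold
  sh <- percentile_soft_threshold(v, 90, steepness = Inf)
  expect_identical(sh$lf_thr, v * (v >= sh$thr))
  # constant nonzero field: threshold equals it and the output is half
  cst <- matrix(0.4, 4, 4)
  expect_message(sc <- percentile_soft_threshold(cst, 95), "constant")
  expect_equal(sc$thr, 0.4)
  expect_equal(sc$lf_thr, cst / 2, tolerance = 1e-12)
  expect_error(percentile_soft_threshold(v, 0), "in \\(0,100\\)")
})

test_that("noise-only input survives the threshold at no more than the quota", {
  set.seed(5)
  f <- matrix(runif(96 * 96), 96, 96)
  cfg <- default_config()
  ed <- edge_decompose(build_pyramid(f, 1L), build_gabor_bank(), cfg)
  lf <- lateral_facilitation(ed, c(96L, 96L), cfg)
  gam <- cfg$lf$gamma_percentile[1]
  for (p in c("pos", "neg")) {
    ch <- lf$per_scale[[1]]$lf_thr[[p]]
    for (t in seq_len(dim(ch)[3])) {
      expect_lte(mean(ch[, , t] > 0), (100 - gam) / 100 + 0.02)
    }
  }
})

test_that("polarity recombination and power-root pairs are exact inverses", {
  set.seed(13)
  pos <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  neg <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  expect_identical(recombine_polarities(pos, neg), pos - neg)
  # m1 = 1 is a plain sum
  s <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  expect_equal(recombine_orientations(s, 1L), s[, , 1] + s[, , 2] + s[, , 3],
               tolerance = 1e-12)
  # a single nonzero orientation passes through unchanged for any m1
  s1 <- array(0, dim = c(3, 3, 4)); s1[, , 2] <- matrix(rnorm(9), 3, 3)
  for (m1 in 1:3) {
    expect_equal(recombine_orientations(s1, m1), s1[, , 2], tolerance = 1e-12)
  }
  # two orientations +0.3 / -0.1 with m1 = 2: T = 0.08, T' = sqrt(0.08)
  s2 <- array(0, dim = c(1, 1, 8)); s2[1, 1, 1] <- 0.3; s2[1, 1, 2] <- -0.1
  expect_equal(recombine_orientations(s2, 2L)[1, 1], sqrt(0.08),
               tolerance = 1e-12)
  # m1 > 1 never flips the sign when all orientations agree
  s3 <- array(abs(rnorm(2 * 2 * 4)), dim = c(2, 2, 4))
  expect_true(all(recombine_orientations(s3, 3L) > 0))
})

test_that("scale recombination restores range and is positively homogeneous", {
  one <- list(matrix(0.37, 8, 8))
  r <- recombine_scales(one, c(8L, 8L), tau = 1, m2 = 2, gamma_norm = 1 / 8)
  expect_equal(r$texture, (1 / 8) * one[[1]], tolerance = 1e-12)
  # all-zero scales give an exactly zero texture
  zz <- recombine_scales(list(matrix(0, 8, 8), matrix(0, 4, 4)), c(8L, 8L))
  expect_true(all(zz$texture == 0))
  # two equal scales +0.2 with tau = 1, m2 = 2, gamma = 1/8
  two <- list(matrix(0.2, 4, 4), matrix(0.2, 4, 4))
  r2 <- recombine_scales(two, c(4L, 4L))
  expect_equal(r2$texture[1, 1], (1 / 8) * sqrt(0.08), tolerance = 1e-12)
  # homogeneity: scaling the inputs by lambda scales TE by lambda
  set.seed(31)
  maps <- list(matrix(abs(rnorm(16)), 4, 4), matrix(abs(rnorm(16)), 4, 4))
  base <- recombine_scales(maps, c(4L, 4L))$texture
  scaled <- recombine_scales(lapply(maps, `*`, 2.5), c(4L, 4L))$texture
  expect_equal(scaled, 2.5 * base, tolerance = 1e-12)
  # literal-power variant skips the root
  rl <- recombine_scales(one, c(8L, 8L), literal_power = TRUE)
  expect_equal(rl$texture, (1 / 8) * one[[1]]^2, tolerance = 1e-12)
})

test_that("a zero edge stack propagates to an exactly zero texture", {
  cfg <- default_config()
  f <- matrix(0.5, 48, 48)
  ed <- suppressWarnings(edge_decompose(build_pyramid(f, 3L),
                                        build_gabor_bank(), cfg))
  lf <- lateral_facilitation(ed, c(48L, 48L), cfg)
  for (ps in lf$per_scale) {
    expect_true(all(ps$lf_thr$pos == 0) && all(ps$lf_thr$neg == 0))
    expect_true(all(ps$t_prime == 0))
  }
  expect_true(all(lf$texture == 0))
})
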