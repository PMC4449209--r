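test_that("compose has identity as two-sided unit and adds translations", {
  t <- random_affine()
  expect_equal(homog(compose(at_identity(), t)), homog(t))
  expect_equal(homog(compose(t, at_identity())), homog(t))
  s <- compose(at_translation(1, 0), at_translation(0, 1))
  expect_equal(s$translation, c(1, 1))
  expect_equal(s$matrix, diag(2))
})

test_that("compose matches the homogeneous-matrix product oracle and is associative", {
  set.seed(1)
  for (i in 1:20) {
    a <- random_affine(); b <- random_affine(); c <- random_affine()
    expect_equal(homog(compose(a, b)), homog(a) %*% homog(b), tolerance = 1e-12)
    expect_equal(homog(compose(compose(a, b), c)),
                 homog(compose(a, compose(b, c))), tolerance = 1e-12)
  }
})

test_that("compose sets the rigid flag iff both inputs are rigid", {
  expect_true(compose(random_rigid(), random_rigid())$rigid)
  expect_false(compose(random_rigid(), random_affine())$rigid)
})

test_that("at_apply maps points exactly", {
  expect_equal(at_apply(at_identity(), c(3, 4)), matrix(c(3, 4), 1))
  expect_equal(at_apply(at_rotation(pi / 2), c(1, 0)), matrix(c(0, 1), 1),
               tolerance = 1e-12)
  set.seed(2)
  t <- random_affine()
  pts <- matrix(stats::runif(20, -100, 100), 10, 2)
  manual <- t(apply(pts, 1, function(p) (homog(t) %*% c(p, 1))[1:2]))
  expect_equal(at_apply(t, pts), manual, tolerance = 1e-12)
  expect_equal(nrow(at_apply(t, pts)), 10)
})

test_that("fit_rigid recovers an exact rigid map and the identity", {
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  g <- compose(at_translation(5, 3), at_rotation(30 * pi / 180))
  dst <- at_apply(g, src)
  f <- fit_rigid(src, dst)
  expect_equal(homog(f), homog(g), tolerance = 1e-12)
  expect_true(f$rigid)
  expect_equal(max(pairwise_error(f, data.frame(x_fixed_um = dst[, 1],
                                                y_fixed_um = dst[, 2],
                                                x_moving_um = src[, 1],
                                                y_moving_um = src[, 2]))), 0,
               tolerance = 1e-12)
  id <- fit_rigid(src, src)
  expect_equal(homog(id), diag(3), tolerance = 1e-12)
})

test_that("fit_rigid matches the closed-form Procrustes oracle on noisy pairs", {
  set.seed(3)
  for (i in 1:20) {
    g <- random_rigid()
    src <- matrix(stats::runif(40, 0, 200), 20, 2)
    dst <- at_apply(g, src) + matrix(stats::rnorm(40, 0, 1), 20, 2)
    f <- fit_rigid(src, dst)
    o <- procrustes_oracle(src, dst)
    expect_lt(max(abs(f$matrix - o$matrix)), 1e-9)
    expect_lt(max(abs(f$translation - o$translation)), 1e-9)
    expect_equal(det(f$matrix), 1, tolerance = 1e-9)
  }
})

test_that("fit_rigid guards reflection and rejects degenerate input", {
  # mirrored correspondences cannot be explained by a proper rotation
  src <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  dst <- cbind(-src[, 1], src[, 2])
  f <- fit_rigid(src, dst)
  expect_equal(det(f$matrix), 1, tolerance = 1e-9)
  expect_error(fit_rigid(rbind(c(1, 1), c(1, 1)), rbind(c(0, 0), c(2, 2))),
               "degenerate")
})

test_that("fit_rigid is equivariant under a common rigid pre-transform", {
  set.seed(4)
  src <- matrix(stats::runif(30, 0, 100), 15, 2)
  dst <- at_apply(random_rigid(), src) + matrix(stats::rnorm(30, 0, 0.5), 15, 2)
  t0 <- fit_rigid(src, dst)
  g <- random_rigid()
  t1 <- fit_rigid(at_apply(g, src), at_apply(g, dst))
  expect_equal(homog(t1), homog(compose(g, compose(t0, at_invert(g)))),
               tolerance = 1e-9)
})

test_that("fit_affine interpolates 3 pairs, matches the normal-equations oracle, rejects collinear input", {
  g <- random_affine()
  src <- rbind(c(0, 0), c(50, 5), c(10, 80))
  dst <- at_apply(g, src)
  expect_equal(homog(fit_affine(src, dst)), homog(g), tolerance = 1e-9)
  expect_equal(homog(fit_affine(src, src)), diag(3), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    src <- matrix(stats::runif(100, 0, 300), 50, 2)
    dst <- at_apply(random_affine(), src) + matrix(stats::rnorm(100, 0, 2), 50, 2)
    f <- fit_affine(src, dst)
    o <- affine_oracle(src, dst)
    expect_lt(max(abs(f$matrix - o$matrix)), 1e-9)
    expect_lt(max(abs(f$translation - o$translation)), 1e-9)
  }
  line <- cbind(1:5, 2 * (1:5))
  expect_error(fit_affine(line, line + 1), "collinear|degenerate")
})

test_that("affine residual never exceeds rigid residual on the same pairs", {
  set.seed(6)
  for (i in 1:10) {
    src <- matrix(stats::runif(60, 0, 200), 30, 2)
    dst <- at_apply(random_affine(), src) + matrix(stats::rnorm(60, 0, 3), 30, 2)
    pr <- data.frame(x_fixed_um = dst[, 1], y_fixed_um = dst[, 2],
                     x_moving_um = src[, 1], y_moving_um = src[, 2])
    expect_lte(sum(pairwise_error(fit_affine(src, dst), pr)^2),
               sum(pairwise_error(fit_rigid(src, dst), pr)^2) + 1e-9)
  }
})

test_that("at_invert inverts exactly", {
  expect_equal(homog(at_invert(at_identity())), diag(3))
  expect_equal(at_invert(at_translation(2, -5))$translation, c(-2, 5))
  set.seed(7)
  for (i in 1:10) {
    t <- random_affine()
    expect_lt(max(abs(homog(compose(t, at_invert(t))) - diag(3))), 1e-10)
  }
  expect_error(affine2d(matrix(c(1, 2, 2, 4), 2, 2)), "singular")
})

test_that("transform JSON serialization round-trips with um units", {
  t <- random_affine()
  js <- transform_to_json(t)
  expect_match(as.character(js), '"um"')
  t2 <- transform_from_json(js)
  expect_equal(homog(t2), homog(t), tolerance = 1e-12)
  f <- tempfile(fileext = ".json")
  transform_to_json(t, f)
  expect_equal(homog(transform_from_json(f)), homog(t), tolerance = 1e-12)
})

test_that("transform_chain composes cumulative transforms anchored at section 1", {
  set.seed(8)
  pw <- list(random_affine(), random_affine(), random_affine())
  ch <- transform_chain(pw)
  expect_equal(homog(ch$cumulative[[1]]), diag(3))
  # cumulative[k] = pairwise[1] o ... o pairwise[k-1], innermost applied last
  expect_equal(homog(ch$cumulative[[4]]),
               homog(pw[[1]]) %*% homog(pw[[2]]) %*% homog(pw[[3]]),
               tolerance = 1e-12)
  expect_length(ch$pairwise, 3)
  js <- chain_to_json(ch)
  ch2 <- chain_from_json(js)
  expect_equal(homog(ch2$cumulative[[4]]), homog(ch$cumulative[[4]]),
               tolerance = 1e-12)
})

test_that("resample_image is exact at identity and integer shifts, bilinear at half-pixel", {
  set.seed(9)
  px <- array(stats::runif(30 * 20 * 3, 0, 255), c(30, 20, 3))
  img <- section_image(px, spacing = 1)
  out <- resample_image(img, at_identity())
  expect_identical(out$pixels, img$pixels)
  # integer-pixel translation: content shifted, vacated margin white
  sh <- resample_image(img, at_translation(3, 0))
  expect_equal(sh$pixels[, 4:20, ], img$pixels[, 1:17, ])
  expect_true(all(sh$pixels[, 1:3, ] == 255))
  # half-pixel shift of a step edge: edge becomes the mean of its neighbours
  step <- flat_section(5, 4, c(0, 0, 0))
  step$pixels[, 3:4, ] <- 200
  half <- resample_image(step, at_translation(-0.5, 0))
  expect_equal(half$pixels[3, 2, 1], 100)   # straddles the 0|200 edge
  expect_equal(half$pixels[3, 1, 1], 0)
})

test_that("round-trip resampling reproduces the interior of a smooth image", {
  # analytically smooth (Gaussian bump) so interpolation error stays tiny
  xy <- expand.grid(r = 1:60, c = 1:60)
  g <- matrix(128 + 100 * exp(-((xy$c - 30)^2 + (xy$r - 30)^2) / 200), 60, 60)
  img <- section_image(array(rep(g, 3), c(60, 60, 3)), spacing = 1)
  t <- compose(at_translation(2.3, -1.7), at_rotation(0.1, c(30, 30)))
  back <- resample_image(resample_image(img, t), at_invert(t))
  interior <- back$pixels[15:45, 15:45, 1] - img$pixels[15:45, 15:45, 1]
  expect_lt(max(abs(interior)), 2)
})
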