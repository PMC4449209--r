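# builds a white section with colored square blobs at given pixel positions
blob_section <- function(H = 200, W = 200, spacing = 0.25, blobs = list()) {
  s <- flat_section(H, W, c(255, 255, 255), spacing = spacing)
  for (b in blobs) s <- paint_rect(s, b$rows, b$cols, b$rgb)
  s
}

dark_blue <- c(60, 100, 190)    # green 39% of 255

test_that("segment_nuclei applies the combined color and area criteria", {
  # 10 x 10 px at 0.25 um/px = 6.25 um^2: inside [6, 160]
  s <- blob_section(blobs = list(list(rows = 51:60, cols = 91:100, rgb = dark_blue)))
  lm <- segment_nuclei(s)
  expect_equal(nrow(lm), 1)
  # centroid forced by symmetry: pixel centres 51..60 -> 55.5 -> (55.5-1)*0.25
  expect_equal(lm$y_um, 54.5 * 0.25)
  expect_equal(lm$x_um, 94.5 * 0.25)
  expect_equal(lm$area_um2, 100 * 0.25^2)
  # 7 x 7 px = 3.06 um^2 < 6: rejected by the area floor
  s2 <- blob_section(blobs = list(list(rows = 51:57, cols = 91:97, rgb = dark_blue)))
  expect_equal(nrow(segment_nuclei(s2)), 0)
  # green at 90% of 255: rejected by the color threshold
  s3 <- blob_section(blobs = list(list(rows = 51:60, cols = 91:100,
                                       rgb = c(60, 0.9 * 255, 190))))
  expect_equal(nrow(segment_nuclei(s3)), 0)
  # 60 x 60 px = 225 um^2 > 160: rejected by the area ceiling
  s4 <- blob_section(blobs = list(list(rows = 51:110, cols = 91:150, rgb = dark_blue)))
  expect_equal(nrow(segment_nuclei(s4)), 0)
})

test_that("segmentation components are 8-connected", {
  # two 8 x 8 blobs touching only at a corner must form one component
  s <- blob_section(blobs = list(list(rows = 41:48, cols = 41:48, rgb = dark_blue),
                                 list(rows = 49:56, cols = 49:56, rgb = dark_blue)))
  lm <- segment_nuclei(s)
  expect_equal(nrow(lm), 1)
  expect_equal(lm$area_um2, 128 * 0.25^2)
})

test_that("filter_debris removes background-surrounded blobs and keeps tissue-surrounded ones", {
  blob <- list(rows = 91:100, cols = 91:100, rgb = dark_blue)
  # blob on bare white slide: ring mean 100%, SD 0 -> debris
  s_bg <- blob_section(blobs = list(blob))
  lm <- segment_nuclei(s_bg)
  expect_equal(nrow(filter_debris(lm, s_bg)), 0)
  # blob inside tissue-colored surround (green 86%): mean criterion fails -> kept
  s_ti <- flat_section(200, 200, c(240, 0.86 * 255, 190), spacing = 0.25)
  s_ti <- paint_rect(s_ti, blob$rows, blob$cols, blob$rgb)
  lm2 <- segment_nuclei(s_ti)
  expect_equal(nrow(filter_debris(lm2, s_ti)), 1)
  # blob touching the image border: ring clipped to the image, no error
  s_bd <- blob_section(blobs = list(list(rows = 1:10, cols = 1:10, rgb = dark_blue)))
  lm3 <- segment_nuclei(s_bd)
  expect_equal(nrow(filter_debris(lm3, s_bd)), 0)   # still background-like
})

test_that("extract_neighborhood converts units, pads white, and is window/leveled", {
  s <- flat_section(120, 120, c(255, 255, 255), spacing = 0.25)
  nb <- extract_neighborhood(s, c(15, 15), side = 250)
  expect_equal(dim(nb), c(1000, 1000))          # 250 um / 0.25 um per px
  expect_true(all(nb == 255))                   # uniform white stays white
  s2 <- flat_section(100, 100, c(250, 232, 240), spacing = 1)
  nb2 <- extract_neighborhood(s2, c(50, 50), side = 40)
  expect_equal(dim(nb2), c(40, 40))
  expect_true(all(nb2 == window_level(232, 14, 235)))
  # identical sections yield identical neighborhoods, MSE 0
  ph <- small_phantom()
  p <- c(350, 350)
  a <- extract_neighborhood(ph$stack[[1]], p)
  b <- extract_neighborhood(ph$stack[[1]], p)
  expect_equal(mse_metric(a, b), 0)
})

test_that("match_nuclei gates at T and selects the most similar neighborhood", {
  sp <- 1
  mk_lm <- function(xy, section) data.frame(section_index = section,
                                            x_um = xy[, 1], y_um = xy[, 2],
                                            area_um2 = 10,
                                            label = seq_len(nrow(xy)))
  # both sections share the same textured content: candidate 1 sits at p's
  # exact position (identical neighborhood), candidate 2 on a blank region
  set.seed(30)
  tex <- smooth_test_image(400, 400, seed = 30, base = 233, amp = 4)
  sI <- section_image(array(rep(tex, 3), c(400, 400, 3)), sp)
  sI$pixels[196:204, 196:204, ] <- rep(dark_blue, each = 81)
  sI$pixels[100:180, 100:180, ] <- 255        # blank slide region
  sI$pixels[136:144, 136:144, 2] <- 100       # dot inside the blank region
  sJ <- sI
  lmI <- mk_lm(cbind(199, 199), 1L)
  lmJ <- mk_lm(rbind(c(199, 199), c(139, 139)), 2L)
  cs <- match_nuclei(lmI, lmJ, sI, sJ, init = at_identity(), gate_T_um = 100)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$idx_J, 1)                   # identical-neighborhood candidate
  expect_equal(cs$score, 0, tolerance = 1e-9)
  # nearest candidate beyond T yields no pair
  lmJ_far <- mk_lm(cbind(199 + 150, 199), 2L)
  cs2 <- match_nuclei(lmI, lmJ_far, sI, sJ, init = at_identity(), gate_T_um = 100)
  expect_equal(nrow(cs2), 0)
})

test_that("no returned correspondence violates the gating distance", {
  ph <- small_phantom()
  lm1 <- filter_debris(segment_nuclei(ph$stack[[1]]), ph$stack[[1]])
  lm2 <- filter_debris(segment_nuclei(ph$stack[[2]]), ph$stack[[2]])
  init <- ph$truth$pairwise[[1]]
  cs <- match_nuclei(lm1, lm2, ph$stack[[1]], ph$stack[[2]], init = init,
                     gate_T_um = 60)
  expect_gt(nrow(cs), 10)
  mapped <- at_apply(init, cbind(cs$xJ_um, cs$yJ_um))
  d <- sqrt((cs$xI_um - mapped[, 1])^2 + (cs$yI_um - mapped[, 2])^2)
  expect_true(all(d <= 60))
  expect_true(all(cs$score >= 0))
})

test_that("select_best_correspondences keeps the smallest k scores deterministically", {
  set.seed(31)
  fake <- data.frame(idx_I = 1:250, idx_J = 1:250,
                     xI_um = stats::runif(250, 0, 500),
                     yI_um = stats::runif(250, 0, 500),
                     xJ_um = 0, yJ_um = 0, xJ_mapped_um = 0, yJ_mapped_um = 0,
                     dist_um = 0,
                     score = sample(c(stats::runif(240, 10, 1000), rep(5, 10))))
  class(fake) <- c("correspondence_set", "data.frame")
  best <- select_best_correspondences(fake, 100)
  expect_equal(nrow(best), 100)
  expect_lte(max(best$score), min(fake$score[!paste(fake$idx_I) %in% paste(best$idx_I)]))
  # ties broken by (score, y, x): matches an explicit sort oracle
  ord <- order(fake$score, fake$yI_um, fake$xI_um)
  expect_equal(best$idx_I, fake$idx_I[ord[1:100]])
  few <- fake[1:40, ]; class(few) <- class(fake)
  expect_equal(nrow(select_best_correspondences(few, 100)), 40)
  one <- fake[1, ]; class(one) <- class(fake)
  expect_error(select_best_correspondences(one, 100), "unregistrable")
})

test_that("register_landmarks recovers a known rigid map and composes with the init", {
  set.seed(32)
  g <- compose(at_translation(12, -7), at_rotation(0.04, c(100, 100)))
  pI <- matrix(stats::runif(200, 0, 500), 100, 2)
  pJ <- at_apply(at_invert(g), pI)            # raw section-J coordinates
  cs <- data.frame(idx_I = 1:100, idx_J = 1:100,
                   xI_um = pI[, 1], yI_um = pI[, 2],
                   xJ_um = pJ[, 1], yJ_um = pJ[, 2],
                   xJ_mapped_um = pJ[, 1], yJ_mapped_um = pJ[, 2],
                   dist_um = 0, score = 0)
  class(cs) <- c("correspondence_set", "data.frame")
  attr(cs, "init") <- at_identity()
  t <- register_landmarks(cs, "rigid")
  expect_lt(max(abs(homog(t) - homog(g))), 1e-6)
  # with a non-trivial init the returned transform still maps raw J -> I
  init <- at_translation(5, 5)
  mapped <- at_apply(init, pJ)
  cs2 <- cs
  cs2$xJ_mapped_um <- mapped[, 1]; cs2$yJ_mapped_um <- mapped[, 2]
  attr(cs2, "init") <- init
  t2 <- register_landmarks(cs2, "rigid")
  expect_lt(max(abs(homog(t2) - homog(g))), 1e-6)
  expect_error(register_landmarks(cs[1, ], "rigid"), "unregistrable")
})

test_that("rigid landmark fits from jittered centroids have sub-0.1 um translation bias", {
  set.seed(33)
  g <- compose(at_translation(20, 10), at_rotation(0.03, c(250, 250)))
  biases <- t(vapply(1:100, function(i) {
    pI <- matrix(stats::runif(200, 0, 500), 100, 2)
    pJ <- at_apply(at_invert(g), pI)
    jit <- matrix(stats::rnorm(200, 0, 0.5), 100, 2)
    fit <- fit_rigid(pJ + jit, pI)
    fit$translation - g$translation
  }, numeric(2)))
  expect_lt(max(abs(colMeans(biases))), 0.1)
})

test_that("register_landmarks output is equivariant to a rigid perturbation of section J", {
  set.seed(34)
  pI <- matrix(stats::runif(120, 0, 400), 60, 2)
  pJ <- pI + matrix(stats::rnorm(120, 0, 0.3), 60, 2)
  mk <- function(pj) {
    cs <- data.frame(idx_I = 1:60, idx_J = 1:60, xI_um = pI[, 1], yI_um = pI[, 2],
                     xJ_um = pj[, 1], yJ_um = pj[, 2],
                     xJ_mapped_um = pj[, 1], yJ_mapped_um = pj[, 2],
                     dist_um = 0, score = 0)
    class(cs) <- c("correspondence_set", "data.frame")
    attr(cs, "init") <- at_identity()
    cs
  }
  t0 <- register_landmarks(mk(pJ), "rigid")
  gp <- random_rigid()
  t1 <- register_landmarks(mk(at_apply(gp, pJ)), "rigid")
  expect_lt(max(abs(homog(t1) - homog(compose(t0, at_invert(gp))))), 1e-8)
})

test_that("phantom segmentation recall and precision reach 0.9 at default stain parameters", {
  ph <- small_phantom()
  s <- ph$stack[[1]]
  lm <- filter_debris(segment_nuclei(s), s)
  # ground-truth in-plane footprints with detectable area on section 1
  nuc <- ph$truth$nuclei
  Tk <- ph$truth$spec$thickness_um
  r <- nuc$diameter / 2
  d_out <- pmax(0 - nuc$z, nuc$z - Tk, 0)
  vis <- which(d_out < r)
  rad <- sqrt(r[vis]^2 - d_out[vis]^2)
  det_ok <- which(pi * rad^2 >= 6.5 & pi * rad^2 <= 150)
  gt <- cbind(nuc$x[vis][det_ok], nuc$y[vis][det_ok])
  # match detected to ground truth within 2 um (section 1 is unperturbed)
  dmat <- sqrt(outer(gt[, 1], lm$x_um, "-")^2 + outer(gt[, 2], lm$y_um, "-")^2)
  recall <- mean(apply(dmat, 1, min) < 2)
  precision <- mean(apply(dmat, 2, min) < 2)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})
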