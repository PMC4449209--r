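# Independent oracles and fixture builders shared across test files.
# Oracles deliberately use different arithmetic than the implementation.

# 3x3 homogeneous matrix of a transform
homog <- function(t) rbind(cbind(t$matrix, t$translation), c(0, 0, 1))

# random affine transform with a well-conditioned linear part
random_affine <- function() {
  repeat {
    M <- matrix(stats::runif(4, -1, 1), 2, 2) + diag(2)
    if (abs(det(M)) > 0.2) break
  }
  affine2d(M, stats::runif(2, -50, 50))
}

random_rigid <- function() {
  th <- stats::runif(1, -pi, pi)
  affine2d(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
           stats::runif(2, -50, 50), rigid = TRUE)
}

# closed-form 2D Procrustes oracle via the atan2 angle formula (no SVD)
procrustes_oracle <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  th <- atan2(sum(A[, 1] * B[, 2] - A[, 2] * B[, 1]),
              sum(A[, 1] * B[, 1] + A[, 2] * B[, 2]))
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  list(matrix = R, translation = cd - as.vector(R %*% cs))
}

# explicit normal-equations affine oracle
affine_oracle <- function(src, dst) {
  X <- cbind(src, 1)
  beta <- solve(t(X) %*% X, t(X) %*% dst)     # 3 x 2
  list(matrix = t(beta[1:2, ]), translation = beta[3, ])
}

# brute-force double-loop MSE oracle
mse_oracle <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  s / length(a)
}

# smooth band-limited grayscale test image (0-255)
smooth_test_image <- function(H = 90, W = 90, seed = 42, base = 180, amp = 40) {
  set.seed(seed)
  g <- matrix(stats::rnorm(12 * 12, 0, amp), 12, 12)
  rr <- seq(1, 12, length.out = H); cc <- seq(1, 12, length.out = W)
  f <- matrix(histo3d:::bilinear_sample(g, rep(rr, times = W), rep(cc, each = H), 0), H, W)
  pmin(pmax(base + f, 0), 255)
}

# uniform-color RGB section
flat_section <- function(H, W, rgb, spacing = 1, index = 1L) {
  px <- array(0, c(H, W, 3))
  for (i in 1:3) px[, , i] <- rgb[i]
  section_image(px, spacing = spacing, index = index)
}

# paint an axis-aligned rectangle of a color into a section (pixel indices)
paint_rect <- function(section, rows, cols, rgb) {
  for (i in 1:3) section$pixels[rows, cols, i] <- rgb[i]
  section
}

# small two-section phantom reused by nucleus/reconstruction tests (memoized)
.fixture_env <- new.env(parent = emptyenv())
small_phantom <- function() {
  if (is.null(.fixture_env$ph)) {
    spec <- phantom_spec(n_sections = 2, width_um = 700, height_um = 700,
                         nucleus_density_mm2 = 200, max_translation_um = 15,
                         max_rotation_deg = 2, seed = 21)
    .fixture_env$ph <- generate_phantom(spec)
  }
  .fixture_env$ph
}
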