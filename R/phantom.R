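#' Synthetic serial-section phantom specification
#'
#' Describes a simulated block of tissue cut into serial 5 um sections and
#' scanned in brightfield: white slide background, a lightly stained tissue
#' slab carrying a smooth 3D texture, DAB-brown vessel walls following
#' straight 3D centerlines at known inclinations, and hematoxylin-blue
#' nuclei rendered as spheres (diameter near the 5 um section thickness,
#' truncated just below it so a nucleus is bisected by at most one cutting
#' plane and appears on exactly two adjacent sections). Each section is
#' perturbed by a known random rigid (optionally affine) transform that a
#' reconstruction must recover.
#'
#' The tissue green level (about 91% of 255) sits between the nucleus color
#' threshold (80%) and the slide-background criterion (95%), and the tissue
#' texture lives inside the 14/235 window/level band used by block matching,
#' so the phantom exercises every stage of the pipeline at its default
#' parameters.
#'
#' @param n_sections number of serial sections.
#' @param width_um,height_um image extents, micrometres.
#' @param spacing_um pixel spacing, micrometres per pixel.
#' @param thickness_um section thickness, micrometres.
#' @param nucleus_density_mm2 expected nuclei per mm^2 whose centre lies
#'   within any one section slab.
#' @param nucleus_diameter_mean_um,nucleus_diameter_sd_um diameter
#'   distribution (normal, truncated to `nucleus_diameter_range_um`).
#' @param nucleus_diameter_range_um hard truncation bounds; the upper bound
#'   must stay below `thickness_um`.
#' @param vessels list of vessel definitions: each a list with `p0_um`
#'   (x, y at z = 0), `angle_deg` (inclination to the z axis), `azimuth_deg`,
#'   `lumen_radius_um`, `wall_um`.
#' @param max_translation_um,max_rotation_deg per-section rigid perturbation
#'   bounds (independent uniform draws; section 1 stays unperturbed).
#' @param max_affine maximum shear/scale deviation of the perturbation's
#'   linear part (0 = rigid perturbations only).
#' @param tissue_margin_frac white margin around the tissue slab as a
#'   fraction of each extent.
#' @param texture_amplitude_shared,texture_amplitude_section intensity SD of
#'   the smooth tissue texture shared across sections / independent per
#'   section.
#' @param texture_scale_um correlation length of the texture.
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param colors named list of RGB triplets (0-255): `background`, `tissue`,
#'   `nucleus`, `vessel`.
#' @param reference_fraction fraction of bisected nuclei assigned to the
#'   withheld reference split (the rest form the registration-visible
#'   split).
#' @param seed RNG seed; the same spec always generates bit-identical
#'   stacks.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_sections = 2,
                         width_um = 2000, height_um = 2000,
                         spacing_um = 1, thickness_um = 5,
                         nucleus_density_mm2 = 80,
                         nucleus_diameter_mean_um = 5,
                         nucleus_diameter_sd_um = 0.4,
                         nucleus_diameter_range_um = c(3.6, 4.98),
                         vessels = list(list(p0_um = c(width_um / 2, height_um / 2),
                                             angle_deg = 30, azimuth_deg = 0,
                                             lumen_radius_um = 15, wall_um = 8)),
                         max_translation_um = 50,
                         max_rotation_deg = 5,
                         max_affine = 0,
                         tissue_margin_frac = 0.10,
                         texture_amplitude_shared = 8,
                         texture_amplitude_section = 1.5,
                         texture_scale_um = 60,
                         noise_sd = 3,
                         colors = list(background = c(255, 255, 255),
                                       tissue = c(248, 232, 238),
                                       nucleus = c(70, 110, 200),
                                       vessel = c(150, 95, 45)),
                         reference_fraction = 0.5,
                         seed = 1L) {
  stopifnot(n_sections >= 1, width_um > 0, height_um > 0, spacing_um > 0,
            thickness_um > 0, nucleus_density_mm2 > 0,
            nucleus_diameter_range_um[2] < thickness_um,
            reference_fraction > 0, reference_fraction < 1)
  for (v in vessels) {
    if (v$p0_um[1] < 0 || v$p0_um[1] > width_um ||
        v$p0_um[2] < 0 || v$p0_um[2] > height_um)
      stop("phantom_spec: vessel entry point outside the slab")
  }
  spec <- as.list(environment())
  structure(spec, class = "phantom_spec")
}

# linear indices of the pixels of a disk (centre in um, radius um) within an
# H x W raster at `sp` um/px
disk_idx <- function(H, W, cx, cy, r, sp) {
  c0 <- max(1L, floor(cx / sp + 1 - r / sp)); c1 <- min(W, ceiling(cx / sp + 1 + r / sp))
  r0 <- max(1L, floor(cy / sp + 1 - r / sp)); r1 <- min(H, ceiling(cy / sp + 1 + r / sp))
  if (c0 > c1 || r0 > r1) return(integer())
  cols <- c0:c1; rows <- r0:r1
  dx2 <- (((cols - 1) * sp) - cx)^2
  dy2 <- (((rows - 1) * sp) - cy)^2
  m <- outer(dy2, dx2, "+") <= r^2
  which(m) -> loc
  if (length(loc) == 0) return(integer())
  rr <- (loc - 1L) %% length(rows) + 1L
  cc <- (loc - 1L) %/% length(rows) + 1L
  (cols[cc] - 1L) * H + rows[rr]
}

# smooth random field: coarse iid normal grid bilinearly upsampled
smooth_field <- function(H, W, sp, scale_um, amplitude) {
  gh <- max(2L, ceiling(H * sp / scale_um) + 1L)
  gw <- max(2L, ceiling(W * sp / scale_um) + 1L)
  g <- matrix(stats::rnorm(gh * gw, 0, amplitude), gh, gw)
  rr <- seq(1, gh, length.out = H)
  cc <- seq(1, gw, length.out = W)
  matrix(bilinear_sample(g, rep(rr, times = W), rep(cc, each = H), fill = 0), H, W)
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Places nuclei uniformly in the 3D tissue slab, renders every section's
#' intersection with its 5 um slab (tissue, texture, vessel annuli, nucleus
#' disks) in an unperturbed world frame, then warps each rendered section by
#' the inverse of its ground-truth perturbation so that registration must
#' recover it, and finally adds clipped Gaussian pixel noise. Fully
#' reproducible from the spec's seed.
#'
#' A nucleus bisected by the cutting plane between sections k and k + 1
#' leaves a disk centred on the same world (x, y) on both sections, so its
#' rendered centroids are exactly homologous; the set of bisected nuclei is
#' split (per nucleus) into a registration-visible and a withheld reference
#' split.
#'
#' @param spec [phantom_spec()].
#' @return List of class `phantom`: `stack` (list of [section_image()]) and
#'   `truth` with elements `pairwise` / `cumulative` (ground-truth
#'   [affine2d] lists; cumulative is relative to section 1), `nuclei` (3D
#'   table with split labels), `pairs` (per cutting plane, homologous local
#'   coordinates on both adjacent sections plus split), `vessel_centroids`
#'   (per vessel, per section local centerline position), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  sp <- spec$spacing_um
  H <- round(spec$height_um / sp); W <- round(spec$width_um / sp)
  Tk <- spec$thickness_um
  n <- spec$n_sections
  center <- c(spec$width_um / 2, spec$height_um / 2)

  # ground-truth perturbations; section 1 is the untransformed base
  G <- vector("list", n)
  G[[1]] <- at_identity()
  if (n > 1) for (k in 2:n) {
    th <- stats::runif(1, -1, 1) * spec$max_rotation_deg * pi / 180
    tr <- stats::runif(2, -1, 1) * spec$max_translation_um
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    M <- if (spec$max_affine > 0)
      R %*% (diag(2) + matrix(stats::runif(4, -1, 1) * spec$max_affine, 2, 2))
    else R
    G[[k]] <- affine2d(M, center - as.vector(M %*% center) + tr,
                       rigid = spec$max_affine == 0)
  }

  # tissue slab footprint (world frame)
  mx <- spec$tissue_margin_frac * spec$width_um
  my <- spec$tissue_margin_frac * spec$height_um
  t_x <- c(mx, spec$width_um - mx); t_y <- c(my, spec$height_um - my)
  area_mm2 <- diff(t_x) * diff(t_y) / 1e6

  # nuclei uniform in the 3D slab (z padded by a radius so boundary planes
  # see complete caps)
  pad <- spec$nucleus_diameter_range_um[2] / 2
  depth <- n * Tk
  n_nuc <- stats::rpois(1, spec$nucleus_density_mm2 * area_mm2 * (depth + 2 * pad) / Tk)
  inset <- 3
  nuc <- data.frame(
    id = seq_len(n_nuc),
    x = stats::runif(n_nuc, t_x[1] + inset, t_x[2] - inset),
    y = stats::runif(n_nuc, t_y[1] + inset, t_y[2] - inset),
    z = stats::runif(n_nuc, -pad, depth + pad),
    diameter = pmin(pmax(stats::rnorm(n_nuc, spec$nucleus_diameter_mean_um,
                                      spec$nucleus_diameter_sd_um),
                         spec$nucleus_diameter_range_um[1]),
                    spec$nucleus_diameter_range_um[2]))
  nuc$split <- ifelse(stats::runif(n_nuc) < spec$reference_fraction,
                      "reference", "registration")

  tex_shared <- smooth_field(H, W, sp, spec$texture_scale_um,
                             spec$texture_amplitude_shared)
  col_bg <- spec$colors$background; col_ti <- spec$colors$tissue
  col_nu <- spec$colors$nucleus; col_ve <- spec$colors$vessel

  tis_rows <- max(1L, floor(t_y[1] / sp + 1)):min(H, ceiling(t_y[2] / sp + 1))
  tis_cols <- max(1L, floor(t_x[1] / sp + 1)):min(W, ceiling(t_x[2] / sp + 1))

  vessel_xy <- function(v, z) {
    a <- v$angle_deg * pi / 180; ph <- v$azimuth_deg * pi / 180
    v$p0_um + z * tan(a) * c(cos(ph), sin(ph))
  }

  stack <- vector("list", n)
  vess_cent <- lapply(spec$vessels, function(v) matrix(NA_real_, n, 2))
  for (k in seq_len(n)) {
    z0 <- (k - 1) * Tk; z1 <- k * Tk; zmid <- (z0 + z1) / 2
    ch <- lapply(1:3, function(i) matrix(col_bg[i], H, W))
    tex <- tex_shared + smooth_field(H, W, sp, spec$texture_scale_um,
                                     spec$texture_amplitude_section)
    for (i in 1:3)
      ch[[i]][tis_rows, tis_cols] <- col_ti[i] + tex[tis_rows, tis_cols]
    # vessels: white lumen + brown annular wall at the slab mid-plane
    for (vi in seq_along(spec$vessels)) {
      v <- spec$vessels[[vi]]
      p <- vessel_xy(v, zmid)
      outer_idx <- disk_idx(H, W, p[1], p[2], v$lumen_radius_um + v$wall_um, sp)
      inner_idx <- disk_idx(H, W, p[1], p[2], v$lumen_radius_um, sp)
      wall <- setdiff(outer_idx, inner_idx)
      for (i in 1:3) { ch[[i]][inner_idx] <- col_bg[i]; ch[[i]][wall] <- col_ve[i] }
    }
    # nuclei: disk of the sphere-slab intersection's largest circle
    r <- nuc$diameter / 2
    d_out <- pmax(z0 - nuc$z, nuc$z - z1, 0)      # distance to slab if outside
    vis <- which(d_out < r)
    rad <- sqrt(r[vis]^2 - d_out[vis]^2)
    for (j in seq_along(vis)) {
      idx <- disk_idx(H, W, nuc$x[vis[j]], nuc$y[vis[j]], rad[j], sp)
      for (i in 1:3) ch[[i]][idx] <- col_nu[i]
    }
    img <- array(0, c(H, W, 3))
    for (i in 1:3) img[, , i] <- ch[[i]]
    si <- section_image(img, spacing = sp, index = k, thickness = Tk)
    if (max(abs(G[[k]]$matrix - diag(2))) > 0 || any(G[[k]]$translation != 0))
      si <- resample_image(si, at_invert(G[[k]]))
    noisy <- si$pixels + array(stats::rnorm(H * W * 3, 0, spec$noise_sd), c(H, W, 3))
    si$pixels <- round(pmin(pmax(noisy, 0), 255))
    stack[[k]] <- si
    for (vi in seq_along(spec$vessels))
      vess_cent[[vi]][k, ] <- at_apply(at_invert(G[[k]]),
                                       vessel_xy(spec$vessels[[vi]], zmid))[1, ]
  }

  # homologous bisected-nucleus pairs per interior cutting plane
  pairs <- if (n > 1) lapply(seq_len(n - 1L), function(j) {
    zc <- j * Tk
    sel <- which(abs(nuc$z - zc) < nuc$diameter / 2)
    if (length(sel) == 0)
      return(data.frame(id = integer(), x_fixed_um = numeric(),
                        y_fixed_um = numeric(), x_moving_um = numeric(),
                        y_moving_um = numeric(), split = character()))
    w <- cbind(nuc$x[sel], nuc$y[sel])
    f <- at_apply(at_invert(G[[j]]), w)
    m <- at_apply(at_invert(G[[j + 1]]), w)
    data.frame(id = nuc$id[sel], x_fixed_um = f[, 1], y_fixed_um = f[, 2],
               x_moving_um = m[, 1], y_moving_um = m[, 2],
               split = nuc$split[sel])
  }) else list()

  pairwise <- if (n > 1) lapply(seq_len(n - 1L), function(k)
    compose(at_invert(G[[k]]), G[[k + 1]])) else list()

  structure(list(
    stack = stack,
    truth = list(pairwise = pairwise, cumulative = G, nuclei = nuc,
                 pairs = pairs, vessel_centroids = vess_cent, spec = spec)),
    class = "phantom")
}

#' Extract a landmark split as a reference landmark set
#'
#' Returns the homologous bisected-nucleus centroid pairs of the requested
#' split, expressed in the perturbed (rendered) local frames of each
#' adjacent section pair. The two splits are disjoint and together cover all
#' bisected nuclei; the reference split is withheld from registration.
#'
#' @param truth the `truth` element of a [generate_phantom()] result (or the
#'   `phantom` itself).
#' @param split "reference" or "registration".
#' @return [reference_landmarks()].
#' @export
ground_truth_pairs <- function(truth, split = c("reference", "registration")) {
  split <- match.arg(split)
  if (inherits(truth, "phantom")) truth <- truth$truth
  reference_landmarks(lapply(truth$pairs, function(p) {
    out <- p[p$split == split, , drop = FALSE]
    rownames(out) <- NULL
    out
  }))
}

#' Recovered vessel axis inclination
#'
#' Maps per-section vessel cross-section centroids through a reconstruction
#' chain, places them at `z = (section - 1) * thickness`, fits a 3D line
#' through the mapped points by total least squares (principal component),
#' and returns the line's angle to the z axis in degrees. A pairwise
#' registration that snaps vessel cross-sections onto each other drives this
#' angle to 0 regardless of the true inclination — the
#' "banana-into-cylinder" failure this package's landmark method avoids.
#'
#' @param centroids n x 2 matrix of section-local vessel centroids (um), one
#'   row per section (e.g. `truth$vessel_centroids[[1]]`), `NA` rows
#'   allowed.
#' @param chain [transform_chain()] mapping each section into the section-1
#'   frame.
#' @param thickness section thickness, micrometres.
#' @return Angle to the z axis, degrees.
#' @export
vessel_axis_angle <- function(centroids, chain, thickness = 5) {
  centroids <- as.matrix(centroids)
  ok <- which(stats::complete.cases(centroids))
  if (length(ok) < 3)
    stop("vessel_axis_angle: vessel must be visible on >= 3 sections")
  pts <- t(vapply(ok, function(k)
    c(at_apply(chain$cumulative[[k]], centroids[k, , drop = FALSE])[1, ],
      (k - 1) * thickness), numeric(3)))
  dir <- stats::prcomp(pts, center = TRUE)$rotation[, 1]
  acos(abs(dir[3]) / sqrt(sum(dir^2))) * 180 / pi
}
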