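#' Pipeline configuration defaults
#'
#' All tunable parameters of the reconstruction pipeline, in physical units
#' so behaviour is independent of scan resolution. Color fractions are
#' relative to the 8-bit maximum of 255.
#'
#' @return Named list of defaults: nucleus color threshold (green < 80%),
#'   nucleus area range (6-160 um^2), debris ring (5 um dilation, background
#'   mean > 95% and SD < 4%), block-matching neighborhood (250 um side,
#'   window/level 14/235), candidate gate (T = 100 um), best-k selection
#'   (k = 100), intensity-branch downsampling (4 um/px) and coarse extents
#'   (172 x 264 px).
#' @export
default_config <- function() {
  list(
    downsample_spacing_um = 4,
    coarse_extents_px = c(172, 264),
    green_threshold_frac = 0.80,
    area_min_um2 = 6,
    area_max_um2 = 160,
    dilation_radius_um = 5,
    bg_mean_frac = 0.95,
    bg_sd_frac = 0.04,
    neighborhood_side_um = 250,
    window = 14,
    level = 235,
    gate_T_um = 100,
    top_k = 100,
    mutual_best = FALSE
  )
}

# 8-connected labeling: EBImage::bwlabel (4-connected) plus a union-find merge
# of diagonally adjacent labels.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]     # down-right neighbours
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]     # down-left neighbours
  s1 <- a1 > 0L & b1 > 0L & a1 != b1
  s2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

#' Segment nucleus landmarks
#'
#' Detects hematoxylin-stained nuclei by combined color and size criteria:
#' pixels whose green channel is below 80% of 255 form the foreground; its
#' 8-connected components with area within 6-160 um^2 (96-2560 px at 0.25
#' um/px) become landmarks at their centroids, in section-local micrometre
#' coordinates. Both criteria must be met; an empty result is allowed.
#'
#' @param section `section_image` with spacing set.
#' @param green_threshold_frac color threshold as a fraction of 255.
#' @param area_min_um2,area_max_um2 component area range, um^2.
#' @return data.frame with columns `section_index`, `x_um`, `y_um`,
#'   `area_um2`, `label`; the label raster and spacing are attached as
#'   attributes `labels` and `spacing` for reuse by [filter_debris()].
#' @export
segment_nuclei <- function(section, green_threshold_frac = 0.80,
                           area_min_um2 = 6, area_max_um2 = 160) {
  stopifnot(inherits(section, "section_image"))
  sp <- section$spacing
  green <- section$pixels[, , 2]
  lab <- label_components(green < green_threshold_frac * 255)
  empty <- data.frame(section_index = integer(), x_um = numeric(),
                      y_um = numeric(), area_um2 = numeric(), label = integer())
  n <- max(lab)
  if (n == 0) {
    attr(empty, "labels") <- lab; attr(empty, "spacing") <- sp
    return(empty)
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area_px <- tabulate(l, nbins = n)
  sum_r <- rowsum(as.numeric(rows), l)[, 1]
  sum_c <- rowsum(as.numeric(cols), l)[, 1]
  labs_present <- as.integer(rownames(rowsum(as.numeric(rows), l)))
  area_um2 <- area_px[labs_present] * sp^2
  keep <- area_um2 >= area_min_um2 & area_um2 <= area_max_um2
  out <- data.frame(
    section_index = rep(section$index, sum(keep)),
    x_um = (sum_c[keep] / area_px[labs_present][keep] - 1) * sp,
    y_um = (sum_r[keep] / area_px[labs_present][keep] - 1) * sp,
    area_um2 = area_um2[keep],
    label = labs_present[keep])
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  attr(out, "spacing") <- sp
  out
}

#' Reject slide debris among segmented nuclei
#'
#' Debris on the bare glass outside the tissue can satisfy the nucleus color
#' and size criteria. For each landmark, its component is dilated by a 5 um
#' radius disk and the green channel statistics of the surrounding ring
#' (dilation minus component, clipped to the image) are examined: the
#' landmark is discarded iff the ring's mean green exceeds 95% of 255 AND its
#' standard deviation is below 4% of 255, i.e. the surroundings look like
#' clean slide background.
#'
#' @param landmarks output of [segment_nuclei()] for the same section.
#' @param section the `section_image` the landmarks came from.
#' @param dilation_radius_um disk radius, micrometres.
#' @param bg_mean_frac,bg_sd_frac background criteria as fractions of 255.
#' @return Filtered landmark data.frame (attributes preserved).
#' @export
filter_debris <- function(landmarks, section, dilation_radius_um = 5,
                          bg_mean_frac = 0.95, bg_sd_frac = 0.04) {
  if (nrow(landmarks) == 0) return(landmarks)
  lab <- attr(landmarks, "labels")
  sp <- section$spacing
  if (is.null(lab))
    lab <- attr(segment_nuclei(section), "labels")
  green <- section$pixels[, , 2]
  r_px <- max(1L, ceiling(dilation_radius_um / sp))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  H <- nrow(lab); W <- ncol(lab)
  keep <- vapply(seq_len(nrow(landmarks)), function(i) {
    l <- landmarks$label[i]
    idx <- which(lab == l)
    rows <- (idx - 1L) %% H + 1L
    cols <- (idx - 1L) %/% H + 1L
    r0 <- max(1L, min(rows) - r_px); r1 <- min(H, max(rows) + r_px)
    c0 <- max(1L, min(cols) - r_px); c1 <- min(W, max(cols) + r_px)
    comp <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    comp[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    dil <- EBImage::dilate(comp, brush) > 0
    ring <- dil & !comp
    if (!any(ring)) return(TRUE)
    g <- green[r0:r1, c0:c1][ring]
    s <- if (length(g) > 1) stats::sd(g) else 0
    !(mean(g) > bg_mean_frac * 255 && s < bg_sd_frac * 255)
  }, logical(1))
  out <- landmarks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  attr(out, "spacing") <- sp
  out
}

#' Extract a square block-matching neighborhood
#'
#' Axis-aligned square patch of the green channel centred on a point
#' (pixel-aligned to the nearest pixel centre), contrast-mapped with
#' [window_level()] (default window 14 / level 235). Regions outside the
#' image are padded with slide-background white before the mapping. At the
#' default side of 250 um and 0.25 um/px this is a 1000 x 1000 raster.
#'
#' @param section `section_image`.
#' @param center length-2 physical (x, y) centre, micrometres.
#' @param side patch side length, micrometres.
#' @param window,level contrast mapping parameters.
#' @return n x n numeric matrix, `n = round(side / spacing)`.
#' @export
extract_neighborhood <- function(section, center, side = 250,
                                 window = 14, level = 235) {
  stopifnot(side > 0)
  sp <- section$spacing
  green <- section$pixels[, , 2]
  n <- max(1L, round(side / sp))
  off <- seq_len(n) - 1L - (n %/% 2L)
  rc <- round(center[2] / sp) + 1L + off
  cc <- round(center[1] / sp) + 1L + off
  out <- matrix(255, n, n)
  vr <- which(rc >= 1L & rc <= nrow(green))
  vc <- which(cc >= 1L & cc <= ncol(green))
  if (length(vr) && length(vc))
    out[vr, vc] <- green[rc[vr], cc[vc]]
  window_level(out, window, level)
}

#' Correspond bisected nuclei across adjacent sections by block matching
#'
#' For each nucleus landmark p on section I, candidate partners are the
#' landmarks q on section J whose centroid, mapped through the coarse
#' initialization transform into section I's frame, lies within the gating
#' distance T (default 100 um) of p. The correspondence chosen for p is the
#' candidate minimizing the MSE between the window/leveled green-channel
#' neighborhoods centred on p and on q (each in its own section's frame);
#' landmarks with no candidate yield no pair. Many-to-one matches are allowed
#' unless `mutual_best = TRUE`, which additionally requires p to be q's best
#' reverse match.
#'
#' @param landmarks_I,landmarks_J landmark data.frames from
#'   [segment_nuclei()] / [filter_debris()].
#' @param section_I,section_J the corresponding `section_image`s.
#' @param init `affine2d` mapping section-J coordinates into section I's
#'   frame (the coarse initialization).
#' @param gate_T_um candidate gating radius T, micrometres.
#' @param neighborhood_side_um,window,level see [extract_neighborhood()].
#' @param mutual_best logical; apply the optional mutual-best filter.
#' @return A `correspondence_set` data.frame with one row per matched p:
#'   indices, section-local coordinates of p and q, q mapped through `init`,
#'   gating distance and the neighborhood-MSE score. The initialization and T
#'   are attached as attributes.
#' @export
match_nuclei <- function(landmarks_I, landmarks_J, section_I, section_J,
                         init = at_identity(), gate_T_um = 100,
                         neighborhood_side_um = 250, window = 14, level = 235,
                         mutual_best = FALSE) {
  res <- match_one_way(landmarks_I, landmarks_J, section_I, section_J, init,
                       gate_T_um, neighborhood_side_um, window, level)
  if (mutual_best && nrow(res) > 0) {
    rev <- match_one_way(landmarks_J, landmarks_I, section_J, section_I,
                         at_invert(init), gate_T_um, neighborhood_side_um,
                         window, level)
    ok <- vapply(seq_len(nrow(res)), function(i) {
      r <- rev[rev$idx_I == res$idx_J[i], ]
      nrow(r) == 1 && r$idx_J == res$idx_I[i]
    }, logical(1))
    res <- res[ok, , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "init") <- init
  attr(res, "gate_T_um") <- gate_T_um
  class(res) <- c("correspondence_set", "data.frame")
  res
}

match_one_way <- function(landmarks_I, landmarks_J, section_I, section_J,
                          init, gate_T_um, side, window, level) {
  empty <- data.frame(idx_I = integer(), idx_J = integer(),
                      xI_um = numeric(), yI_um = numeric(),
                      xJ_um = numeric(), yJ_um = numeric(),
                      xJ_mapped_um = numeric(), yJ_mapped_um = numeric(),
                      dist_um = numeric(), score = numeric())
  if (nrow(landmarks_I) == 0 || nrow(landmarks_J) == 0) return(empty)
  mapped <- at_apply(init, cbind(landmarks_J$x_um, landmarks_J$y_um))
  patchesJ <- vector("list", nrow(landmarks_J))
  getJ <- function(j) {
    if (is.null(patchesJ[[j]]))
      patchesJ[[j]] <<- extract_neighborhood(
        section_J, c(landmarks_J$x_um[j], landmarks_J$y_um[j]), side, window, level)
    patchesJ[[j]]
  }
  rows <- vector("list", nrow(landmarks_I))
  for (i in seq_len(nrow(landmarks_I))) {
    dx <- mapped[, 1] - landmarks_I$x_um[i]
    dy <- mapped[, 2] - landmarks_I$y_um[i]
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d <= gate_T_um)
    if (length(cand) == 0) next
    pI <- extract_neighborhood(section_I,
                               c(landmarks_I$x_um[i], landmarks_I$y_um[i]),
                               side, window, level)
    scores <- vapply(cand, function(j) mean((pI - getJ(j))^2), numeric(1))
    j <- cand[which.min(scores)]
    rows[[i]] <- data.frame(
      idx_I = i, idx_J = j,
      xI_um = landmarks_I$x_um[i], yI_um = landmarks_I$y_um[i],
      xJ_um = landmarks_J$x_um[j], yJ_um = landmarks_J$y_um[j],
      xJ_mapped_um = mapped[j, 1], yJ_mapped_um = mapped[j, 2],
      dist_um = d[j], score = min(scores))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Retain the best-scoring correspondences
#'
#' Keeps the `min(k, n)` pairs with the smallest neighborhood-MSE scores
#' (default k = 100). Not every nucleus is bisected by the blade, so many
#' putative matches are spurious; retaining only the best-scoring pairs keeps
#' the fit dominated by true bisected-nucleus pairs. Ties at the cutoff are
#' broken deterministically by (score, section-local y of p, then x).
#'
#' @param set `correspondence_set` from [match_nuclei()].
#' @param k number of pairs to retain.
#' @return The filtered `correspondence_set` (attributes preserved).
#' @export
select_best_correspondences <- function(set, k = 100) {
  if (nrow(set) < 2)
    stop("select_best_correspondences: fewer than 2 correspondences; section pair unregistrable")
  ord <- order(set$score, set$yI_um, set$xI_um)
  out <- set[ord[seq_len(min(k, nrow(set)))], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "init") <- attr(set, "init")
  attr(out, "gate_T_um") <- attr(set, "gate_T_um")
  class(out) <- class(set)
  out
}

#' Landmark-based transform estimation from nucleus correspondences
#'
#' Fits a rigid or affine transform minimizing the summed squared residual
#' between the matched nucleus centroids: the section-J points are first
#' mapped through the initialization transform, the fit is computed on
#' (mapped q -> p), and the result is composed with the initialization so the
#' returned transform maps raw section-J coordinates into section I's frame.
#'
#' @param pairs `correspondence_set` (after [select_best_correspondences()]).
#' @param model "rigid" or "affine".
#' @param init initialization transform; defaults to the one recorded on
#'   `pairs`.
#' @return `affine2d` mapping section J into section I.
#' @export
register_landmarks <- function(pairs, model = c("rigid", "affine"), init = NULL) {
  model <- match.arg(model)
  if (is.null(init)) init <- attr(pairs, "init")
  if (is.null(init)) init <- at_identity()
  need <- if (model == "rigid") 2L else 3L
  if (nrow(pairs) < need)
    stop(sprintf("register_landmarks: %d correspondences, need >= %d for %s model; section pair unregistrable",
                 nrow(pairs), need, model))
  src <- cbind(pairs$xJ_mapped_um, pairs$yJ_mapped_um)
  dst <- cbind(pairs$xI_um, pairs$yI_um)
  fit <- if (model == "rigid") fit_rigid(src, dst) else fit_affine(src, dst)
  compose(fit, init)
}

#' Write landmarks or correspondences to CSV
#' @param x landmark data.frame or `correspondence_set`.
#' @param path output CSV path.
#' @export
write_landmarks_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
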