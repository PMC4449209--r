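#' Reconstruct a serial-section stack
#'
#' Runs the full cascade: coarse low-resolution rigid intensity
#' initialization of every adjacent pair, followed by the selected
#' refinement branch, followed by composition into cumulative transforms
#' anchored at section 1.
#'
#' Branches:
#' \describe{
#'   \item{intensity_rigid / intensity_affine}{MSE-driven regular-step
#'     gradient descent on grayscale images downsampled to
#'     `config$downsample_spacing_um` (default 4 um/px); the affine stage is
#'     initialized with the rigid result and run with the high-resolution
#'     step sizes.}
#'   \item{nucleus_rigid / nucleus_affine}{segment nuclei, reject debris,
#'     block-match bisected nuclei within the gating radius, keep the best-k
#'     scored correspondences, and fit the landmark transform (the affine
#'     fit reuses the correspondences selected for the rigid fit).}
#' }
#' Both branches consume the identical coarse initialization. Deterministic
#' given the configuration.
#'
#' @param stack list of [section_image()] (>= 2, consistent spacing,
#'   contiguous indices from 1).
#' @param method one of "intensity_rigid", "intensity_affine",
#'   "nucleus_rigid", "nucleus_affine".
#' @param config parameter list, see [default_config()].
#' @param verbose print per-pair progress.
#' @return Object of class `reconstruction_result`: `chain`
#'   ([transform_chain()]), `method`, `coarse_init` (list of rigid
#'   transforms), `volume_geometry` (in-plane spacing, thickness), and
#'   per-pair `diagnostics` (landmark and correspondence counts).
#' @export
reconstruct <- function(stack, method = c("nucleus_affine", "nucleus_rigid",
                                          "intensity_rigid", "intensity_affine"),
                        config = default_config(), verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(length(stack) >= 2)
  sp <- vapply(stack, function(s) s$spacing, numeric(1))
  stopifnot(all(sp == sp[1]))
  idx <- vapply(stack, function(s) s$index, integer(1))
  if (!identical(idx, seq_along(stack)))
    stop("reconstruct: section indices must be contiguous from 1")
  cfg <- utils::modifyList(default_config(), config)

  coarse <- coarse_initialize(stack, coarse_extents = cfg$coarse_extents_px)
  branch <- if (startsWith(method, "nucleus")) "nucleus" else "intensity"
  model <- if (endsWith(method, "affine")) "affine" else "rigid"

  seg_cache <- vector("list", length(stack))
  get_landmarks <- function(k) {
    if (is.null(seg_cache[[k]])) {
      lm <- segment_nuclei(stack[[k]], cfg$green_threshold_frac,
                           cfg$area_min_um2, cfg$area_max_um2)
      seg_cache[[k]] <<- filter_debris(lm, stack[[k]], cfg$dilation_radius_um,
                                       cfg$bg_mean_frac, cfg$bg_sd_frac)
    }
    seg_cache[[k]]
  }
  gray_cache <- vector("list", length(stack))
  get_gray <- function(k) {
    if (is.null(gray_cache[[k]])) {
      target <- max(cfg$downsample_spacing_um, stack[[k]]$spacing)
      gray_cache[[k]] <<- to_grayscale(downsample(stack[[k]], target))
    }
    gray_cache[[k]]
  }

  pairwise <- vector("list", length(stack) - 1L)
  diagnostics <- vector("list", length(stack) - 1L)
  for (k in seq_len(length(stack) - 1L)) {
    t0 <- Sys.time()
    init <- coarse[[k]]
    if (branch == "intensity") {
      spacing <- max(cfg$downsample_spacing_um, stack[[k]]$spacing)
      fx <- get_gray(k); mv <- get_gray(k + 1)
      t_rig <- register_rigid_mse(fx, mv, settings = high_res_settings(3),
                                  init = init, spacing = spacing)
      t_out <- if (model == "affine")
        register_affine_mse(fx, mv, settings = high_res_settings(6),
                            init = t_rig, spacing = spacing)
      else t_rig
      diagnostics[[k]] <- list(pair = k, n_landmarks_fixed = NA_integer_,
                               n_landmarks_moving = NA_integer_,
                               n_pairs = NA_integer_,
                               seconds = as.numeric(Sys.time() - t0, units = "secs"))
    } else {
      lmI <- get_landmarks(k); lmJ <- get_landmarks(k + 1)
      cs <- match_nuclei(lmI, lmJ, stack[[k]], stack[[k + 1]], init = init,
                         gate_T_um = cfg$gate_T_um,
                         neighborhood_side_um = cfg$neighborhood_side_um,
                         window = cfg$window, level = cfg$level,
                         mutual_best = cfg$mutual_best)
      if (nrow(cs) < 2)
        stop(sprintf("reconstruct: section pair (%d, %d) unregistrable (%d correspondences)",
                     k, k + 1, nrow(cs)))
      best <- select_best_correspondences(cs, cfg$top_k)
      t_out <- register_landmarks(best, model = model, init = init)
      diagnostics[[k]] <- list(pair = k, n_landmarks_fixed = nrow(lmI),
                               n_landmarks_moving = nrow(lmJ),
                               n_pairs = nrow(best),
                               seconds = as.numeric(Sys.time() - t0, units = "secs"))
    }
    pairwise[[k]] <- t_out
    if (verbose)
      message(sprintf("pair %d -> %d: %s [%.1f s]", k + 1, k, method,
                      diagnostics[[k]]$seconds))
  }
  structure(list(chain = transform_chain(pairwise), method = method,
                 coarse_init = coarse,
                 volume_geometry = list(spacing = stack[[1]]$spacing,
                                        thickness = stack[[1]]$thickness),
                 diagnostics = diagnostics),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("<reconstruction: %s, %d sections>\n", x$method,
              length(x$chain$cumulative)))
  invisible(x)
}

#' Render the reconstructed 3D volume
#'
#' Resamples each full-resolution RGB section by its cumulative transform
#' into the section-1 frame on a common bounding grid (the union of the
#' transformed section footprints, so no tissue is cropped; the grid origin
#' is snapped to a multiple of the pixel spacing so section 1 stays
#' pixel-aligned), stacked along z with slice spacing equal to the section
#' thickness. Background is slide white.
#'
#' @param stack list of [section_image()].
#' @param result `reconstruction_result` (or a bare [transform_chain()]).
#' @return List of class `histology_volume`: `slices` (list of H x W x 3
#'   arrays), `spacing` (in-plane um), `thickness` (slice spacing um),
#'   `origin` (physical x, y of the grid origin in the section-1 frame).
#' @export
render_volume <- function(stack, result) {
  chain <- if (inherits(result, "transform_chain")) result else result$chain
  stopifnot(length(chain$cumulative) == length(stack))
  sp <- stack[[1]]$spacing
  corners_all <- do.call(rbind, lapply(seq_along(stack), function(k) {
    d <- dim(stack[[k]]$pixels)
    corners <- cbind(c(0, (d[2] - 1) * sp, 0, (d[2] - 1) * sp),
                     c(0, 0, (d[1] - 1) * sp, (d[1] - 1) * sp))
    at_apply(chain$cumulative[[k]], corners)
  }))
  origin <- floor(apply(corners_all, 2, min) / sp) * sp
  upper <- apply(corners_all, 2, max)
  geom <- output_geometry(sp,
                          height = ceiling((upper[2] - origin[2]) / sp) + 1L,
                          width = ceiling((upper[1] - origin[1]) / sp) + 1L,
                          origin = origin)
  slices <- lapply(seq_along(stack), function(k)
    resample_image(stack[[k]], chain$cumulative[[k]], geom)$pixels)
  structure(list(slices = slices, spacing = sp,
                 thickness = stack[[1]]$thickness, origin = origin),
            class = "histology_volume")
}

#' Write a rendered volume to disk
#'
#' Writes a multipage 8-bit RGB TIFF (one page per section) plus a JSON
#' sidecar recording the voxel spacing in micrometres (in-plane, in-plane,
#' thickness; default 0.25 x 0.25 x 5 um at full scan resolution).
#'
#' @param volume `histology_volume` from [render_volume()].
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "histology_volume"))
  ok <- try(tiff::writeTIFF(lapply(volume$slices,
                                   function(s) pmin(pmax(s / 255, 0), 1)),
                            path, bits.per.sample = 8L), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("write_volume: cannot write '", path, "'")
  jsonlite::write_json(
    list(voxel_spacing_um = c(volume$spacing, volume$spacing, volume$thickness),
         n_sections = length(volume$slices),
         origin_um = volume$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a written volume
#' @param path TIFF path written by [write_volume()].
#' @return `histology_volume`.
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(list(slices = lapply(pages, function(p) p * 255),
                 spacing = meta$voxel_spacing_um[1],
                 thickness = meta$voxel_spacing_um[3],
                 origin = meta$origin_um),
            class = "histology_volume")
}

#' Segment the stained vessel wall
#'
#' Color mask of the DAB-brown immunostained smooth-muscle wall: brown pixels
#' have red clearly above blue and a sub-background green level, which
#' separates them from the near-white tissue, the blue nuclei and the slide.
#'
#' @param section `section_image`.
#' @return Logical H x W matrix.
#' @export
segment_vessel_mask <- function(section) {
  px <- section$pixels
  px[, , 1] > px[, , 3] + 30 & px[, , 2] < 0.8 * 255
}

#' Naive pairwise vessel-centroid baseline
#'
#' A deliberately naive reconstruction that translates each section so the
#' centroid of its vessel-wall mask lands on the centroid of the previous
#' section's mask. Pairwise alignment of a salient multi-section structure
#' like a vessel cross-section straightens obliquely oriented vessels into
#' section-orthogonal cylinders (the "banana-into-cylinder" artifact); this
#' baseline exists to demonstrate that failure mode against the
#' nucleus-landmark method.
#'
#' @param stack list of [section_image()].
#' @return [transform_chain()] of pure translations.
#' @export
naive_vessel_baseline <- function(stack) {
  sp <- stack[[1]]$spacing
  cent <- lapply(stack, function(s) {
    m <- segment_vessel_mask(s)
    idx <- which(m)
    if (length(idx) == 0)
      stop("naive_vessel_baseline: no vessel pixels on section ", s$index)
    rows <- (idx - 1L) %% nrow(m) + 1L
    cols <- (idx - 1L) %/% nrow(m) + 1L
    c((mean(cols) - 1) * sp, (mean(rows) - 1) * sp)
  })
  transform_chain(lapply(seq_len(length(stack) - 1L), function(k)
    at_translation(cent[[k]][1] - cent[[k + 1]][1],
                   cent[[k]][2] - cent[[k + 1]][2])))
}
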