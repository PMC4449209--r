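#' Section image
#'
#' An RGB raster of one physical histology section together with its physical
#' geometry. Pixel intensities are stored as numeric 0-255 per channel; the
#' physical position of pixel (row r, col c), 1-based, is
#' `x = (c - 1) * spacing`, `y = (r - 1) * spacing` micrometres, i.e. the
#' origin sits at the centre of pixel (1, 1), x runs along columns and y along
#' rows.
#'
#' @param pixels H x W x 3 numeric array (0-255), or H x W matrix (replicated
#'   to 3 channels).
#' @param spacing isotropic pixel spacing, micrometres per pixel.
#' @param index 1-based section number within its stack.
#' @param thickness physical section thickness, micrometres.
#' @return Object of class `section_image`.
#' @export
section_image <- function(pixels, spacing, index = 1L, thickness = 5) {
  if (length(dim(pixels)) == 2)
    pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            spacing > 0, thickness > 0, index >= 1)
  structure(list(pixels = pixels, spacing = spacing,
                 index = as.integer(index), thickness = thickness),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<section %d: %d x %d px RGB, %.4g um/px, %.4g um thick>\n",
              x$index, d[1], d[2], x$spacing, x$thickness))
  invisible(x)
}

#' Read an ordered series of section images
#'
#' Reads TIFF or PNG files into a contiguous 1-based section series. 8-bit RGB
#' is enforced: grayscale inputs are replicated to 3 channels and inputs with
#' a deeper sample format are rescaled to 0-255 by per-file max-value
#' normalization.
#'
#' @param paths character vector of file paths, in section order.
#' @param spacing pixel spacing, micrometres per pixel.
#' @param thickness section thickness, micrometres.
#' @return List of [section_image()] objects numbered 1..N.
#' @export
read_section_series <- function(paths, spacing, thickness = 5) {
  if (length(paths) == 0)
    stop("read_section_series: empty path list")
  lapply(seq_along(paths), function(i) {
    p <- paths[i]
    if (!file.exists(p))
      stop("read_section_series: cannot read '", p, "'")
    raw <- if (grepl("\\.png$", p, ignore.case = TRUE)) {
      png::readPNG(p) * 255
    } else {
      info <- tiff::readTIFF(p, payload = FALSE)
      v <- tiff::readTIFF(p)               # normalized 0-1
      bits <- info$bits.per.sample
      if (!is.null(bits) && max(bits) > 8 && max(v) > 0)
        v / max(v) * 255                   # deep inputs: max-value normalization
      else
        v * 255
    }
    if (length(raw) == 0 || min(dim(raw)[1:2]) == 0)
      stop("read_section_series: zero-size image '", p, "'")
    if (length(dim(raw)) == 3 && dim(raw)[3] > 3) raw <- raw[, , 1:3]  # drop alpha
    section_image(raw, spacing = spacing, index = i, thickness = thickness)
  })
}

#' Write a section image as 8-bit TIFF
#' @param image `section_image`.
#' @param path output file path.
#' @export
write_section <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image$pixels / 255, 0), 1), path,
                  bits.per.sample = 8L)
  invisible(path)
}

# Vectorized bilinear sampling of a matrix at fractional (row, col) positions.
# Positions outside [1, H] x [1, W] return `fill`.
bilinear_sample <- function(m, row, col, fill = 255) {
  H <- nrow(m); W <- ncol(m)
  out <- rep(fill, length(row))
  ok <- row >= 1 & row <= H & col >= 1 & col <= W
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  if (H == 1) r0 <- rep(1, length(r))
  if (W == 1) c0 <- rep(1, length(c))
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  v <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
       m[cbind(r0, c1)] * (1 - fr) * fc +
       m[cbind(r1, c0)] * fr * (1 - fc) +
       m[cbind(r1, c1)] * fr * fc
  out[ok] <- v
  out
}

#' Downsample a section image
#'
#' Resamples to a coarser isotropic spacing by bilinear interpolation. The
#' output raster has `ceil(original physical extent / target_spacing)` pixels
#' per axis (e.g. a 17135 x 26398 raster at 0.25 um/px becomes 1071 x 1650 at
#' 4 um/px). Upsampling is refused.
#'
#' @param image `section_image`.
#' @param target_spacing output spacing, micrometres per pixel; must be >=
#'   the input spacing.
#' @return `section_image` at the target spacing.
#' @export
downsample <- function(image, target_spacing) {
  stopifnot(inherits(image, "section_image"))
  if (target_spacing < image$spacing)
    stop("downsample: target_spacing below source spacing (no upsampling path)")
  if (target_spacing == image$spacing) return(image)
  d <- dim(image$pixels)
  outH <- ceiling(d[1] * image$spacing / target_spacing)
  outW <- ceiling(d[2] * image$spacing / target_spacing)
  # output pixel centres in input pixel units
  rr <- ((seq_len(outH) - 1) * target_spacing) / image$spacing + 1
  cc <- ((seq_len(outW) - 1) * target_spacing) / image$spacing + 1
  R <- rep(rr, times = outW); C <- rep(cc, each = outH)
  out <- array(0, c(outH, outW, 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample(image$pixels[, , ch], R, C), outH, outW)
  section_image(out, spacing = target_spacing, index = image$index,
                thickness = image$thickness)
}

#' Convert to grayscale by unweighted RGB mean
#' @param image `section_image`.
#' @return H x W numeric matrix (0-255).
#' @export
to_grayscale <- function(image) {
  stopifnot(inherits(image, "section_image"))
  (image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3]) / 3
}

#' Window/level contrast mapping
#'
#' Linear intensity ramp mapping `[level - window/2, level + window/2]` onto
#' `[0, 255]`, clamped outside (radiology convention: window = full ramp
#' width, level = ramp centre). Output is rounded half-up to the nearest
#' integer level. Applied to the green channel at window 14 / level 235 this
#' strongly enhances tissue-background contrast for near-white slide
#' backgrounds.
#'
#' @param channel numeric matrix or vector of intensities (0-255).
#' @param window ramp width, intensity units, > 0.
#' @param level ramp centre, intensity units.
#' @return Mapped raster, same shape, values in 0-255.
#' @export
window_level <- function(channel, window, level) {
  stopifnot(window > 0)
  v <- (channel - (level - window / 2)) / window * 255
  v <- pmin(pmax(v, 0), 255)
  out <- floor(v + 0.5)                      # round half up
  if (is.matrix(channel)) out <- matrix(out, nrow(channel), ncol(channel))
  out
}

#' Mean squared error between rasters
#'
#' Mean over overlapping (or masked) pixels of the squared intensity
#' difference; the ideal value is zero.
#'
#' @param a,b numeric matrices of equal dimension.
#' @param overlap_mask optional logical matrix selecting the pixels entering
#'   the mean; must select at least one pixel.
#' @return Non-negative scalar.
#' @export
mse_metric <- function(a, b, overlap_mask = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  d2 <- (a - b)^2
  if (is.null(overlap_mask)) return(mean(d2))
  if (!any(overlap_mask))
    stop("mse_metric: empty overlap, no comparable region")
  mean(d2[overlap_mask])
}

#' Output geometry for resampling
#'
#' @param spacing pixel spacing, micrometres.
#' @param height,width raster extents in pixels.
#' @param origin physical (x, y) of the centre of pixel (1, 1), micrometres.
#' @return List describing the output grid.
#' @export
output_geometry <- function(spacing, height, width, origin = c(0, 0)) {
  stopifnot(spacing > 0, height >= 1, width >= 1)
  list(spacing = spacing, height = as.integer(height),
       width = as.integer(width), origin = as.numeric(origin))
}

# physical coordinates of every output pixel of a geometry, as x/y vectors
geometry_grid <- function(geom) {
  x <- geom$origin[1] + (seq_len(geom$width) - 1) * geom$spacing
  y <- geom$origin[2] + (seq_len(geom$height) - 1) * geom$spacing
  list(x = rep(x, each = geom$height), y = rep(y, times = geom$width))
}

#' Resample a section image through a transform
#'
#' Backward (pull) warping: the output pixel at physical location `x` takes
#' the bilinearly interpolated input value at `t^{-1}(x)`. Locations falling
#' outside the input domain are filled with slide-background white
#' (255, 255, 255).
#'
#' @param image `section_image` (input / moving image).
#' @param t `affine2d` mapping input physical coordinates to output physical
#'   coordinates.
#' @param geometry [output_geometry()]; defaults to the input geometry.
#' @return `section_image` on the output grid.
#' @export
resample_image <- function(image, t, geometry = NULL) {
  stopifnot(inherits(image, "section_image"))
  d <- dim(image$pixels)
  if (is.null(geometry))
    geometry <- output_geometry(image$spacing, d[1], d[2])
  g <- geometry_grid(geometry)
  src <- at_apply(at_invert(t), cbind(g$x, g$y))
  col <- src[, 1] / image$spacing + 1
  row <- src[, 2] / image$spacing + 1
  out <- array(0, c(geometry$height, geometry$width, 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(bilinear_sample(image$pixels[, , ch], row, col, fill = 255),
                          geometry$height, geometry$width)
  section_image(out, spacing = geometry$spacing, index = image$index,
                thickness = image$thickness)
}

# Warp a grayscale raster (matrix, with its spacing) through t onto the fixed
# raster's grid; returns the warped values and the in-bounds overlap mask.
# Used by the intensity metric, which averages over the overlap only.
warp_gray <- function(moving, moving_spacing, t, fixed_dim, fixed_spacing) {
  x <- rep((seq_len(fixed_dim[2]) - 1) * fixed_spacing, each = fixed_dim[1])
  y <- rep((seq_len(fixed_dim[1]) - 1) * fixed_spacing, times = fixed_dim[2])
  src <- at_apply(at_invert(t), cbind(x, y))
  col <- src[, 1] / moving_spacing + 1
  row <- src[, 2] / moving_spacing + 1
  inb <- row >= 1 & row <= nrow(moving) & col >= 1 & col <= ncol(moving)
  vals <- bilinear_sample(moving, row, col, fill = 255)
  list(values = matrix(vals, fixed_dim[1], fixed_dim[2]),
       mask = matrix(inb, fixed_dim[1], fixed_dim[2]))
}
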