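#' Regular-step gradient descent settings
#'
#' Settings for the MSE-driven registration optimizer. Parameter scales weight
#' the parameter space so that components with very different sensitivities
#' (radians vs micrometres) become comparable: the gradient is divided
#' component-wise by the scales and steps are taken along the normalized
#' scaled gradient. Defaults follow the low-resolution rigid convention:
#' scales 10^2 for rotational / matrix components and 10^-2 for translations,
#' maximum (initial) step 4 and minimum (convergence) step 0.1; the
#' high-resolution refinement uses steps 0.01 and 0.001.
#'
#' @param scales positive per-parameter weights.
#' @param max_step initial step length (scaled-gradient units).
#' @param min_step convergence step length; iteration stops once the relaxed
#'   step falls below it.
#' @param max_iterations iteration cap.
#' @param relaxation step-shrink factor in (0, 1) applied when the gradient
#'   direction reverses or a step fails to decrease the metric.
#' @return Object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(scales = NULL, max_step = 4, min_step = 0.1,
                               max_iterations = 200, relaxation = 0.5) {
  stopifnot(min_step < max_step, max_iterations >= 1,
            relaxation > 0, relaxation < 1)
  if (!is.null(scales)) stopifnot(all(scales > 0))
  structure(list(scales = scales, max_step = max_step, min_step = min_step,
                 max_iterations = as.integer(max_iterations),
                 relaxation = relaxation),
            class = "optimizer_settings")
}

#' Low- and high-resolution default optimizer settings
#' @name default_settings
#' @param n_params 3 (rigid) or 6 (affine); fills the scale vector with 10^2
#'   for rotation/matrix components and 10^-2 for translations.
NULL

default_scales <- function(n_params) {
  if (n_params == 3) c(1e2, 1e-2, 1e-2) else c(rep(1e2, 4), 1e-2, 1e-2)
}

#' @rdname default_settings
#' @export
low_res_settings <- function(n_params = 3)
  optimizer_settings(default_scales(n_params), max_step = 4, min_step = 0.1)

#' @rdname default_settings
#' @export
high_res_settings <- function(n_params = 6)
  optimizer_settings(default_scales(n_params), max_step = 0.01, min_step = 0.001)

# -- internal machinery -------------------------------------------------------

# Parameterization: the optimizer works on the fixed->moving map P about the
# fixed-image centre c (rotation about the centre decouples rotation from
# translation):
#   rigid : x_m = R(theta) (x_f - c) + c + t        params (theta, tx, ty)
#   affine: x_m = M (x_f - c) + c + t               params (m11, m21, m12, m22, tx, ty)
# The registration transform returned to callers is invert(P): moving->fixed.
params_to_transform <- function(p, center, model) {
  if (model == "rigid") {
    Tc <- at_rotation(p[1], center)
    affine2d(Tc$matrix, Tc$translation + p[2:3], rigid = TRUE)
  } else {
    M <- matrix(p[1:4], 2, 2)
    affine2d(M, as.numeric(center) - as.vector(M %*% as.numeric(center)) + p[5:6])
  }
}

transform_to_params <- function(t, center, model) {
  shift <- at_apply(t, center)[1, ] - as.numeric(center)
  if (model == "rigid") c(atan2(t$matrix[2, 1], t$matrix[1, 1]), shift)
  else c(as.vector(t$matrix), shift)
}

# MSE of fixed vs moving warped by the fixed->moving map P, averaged over the
# overlap (out-of-bounds moving samples excluded from the mean).
make_metric <- function(fixed, moving, spacing) {
  d <- dim(fixed)
  gx <- rep((seq_len(d[2]) - 1) * spacing, each = d[1])
  gy <- rep((seq_len(d[1]) - 1) * spacing, times = d[2])
  fvals <- as.vector(fixed)
  H <- nrow(moving); W <- ncol(moving)
  function(P) {
    src <- at_apply(P, cbind(gx, gy))
    col <- src[, 1] / spacing + 1
    row <- src[, 2] / spacing + 1
    inb <- row >= 1 & row <= H & col >= 1 & col <= W
    if (!any(inb)) return(Inf)
    mv <- bilinear_sample(moving, row[inb], col[inb], fill = 255)
    mean((fvals[inb] - mv)^2)
  }
}

# ITK-style regular-step descent with an explicit acceptance check so the
# accepted metric trace is non-increasing. Deterministic.
regular_step_descent <- function(metric_fn, p0, settings, fd_delta) {
  scales <- settings$scales
  p <- p0
  f <- metric_fn(p)
  step <- settings$max_step
  prev_dir <- NULL
  trace <- list()
  for (iter in seq_len(settings$max_iterations)) {
    if (!is.finite(f))
      stop(sprintf("intensity registration: non-finite metric at iteration %d (params: %s)",
                   iter, paste(signif(p, 6), collapse = ", ")))
    # anneal the finite-difference perturbation with the step length: wide
    # early (averages pixel-scale interpolation/noise ripple), finer near
    # convergence, floored at 5% of the base width
    fd <- fd_delta * max(step / settings$max_step, 0.05)
    g <- vapply(seq_along(p), function(i) {
      e <- numeric(length(p)); e[i] <- fd[i]
      (metric_fn(p + e) - metric_fn(p - e)) / (2 * fd[i])
    }, numeric(1))
    gs <- g / scales
    gn <- sqrt(sum(gs^2))
    if (gn < 1e-12) break
    dir <- gs / gn
    if (!is.null(prev_dir) && sum(dir * prev_dir) < 0)
      step <- step * settings$relaxation
    if (step < settings$min_step) break
    cand <- p - step * dir
    fc <- metric_fn(cand)
    if (is.finite(fc) && fc <= f) {
      p <- cand; f <- fc; prev_dir <- dir
      trace[[length(trace) + 1L]] <- c(iteration = iter, step = step, mse = f, p)
    } else {
      step <- step * settings$relaxation
    }
    if (step < settings$min_step) break
  }
  list(params = p, value = f,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

register_mse <- function(fixed, moving, settings, init, spacing, model) {
  n_par <- if (model == "rigid") 3L else 6L
  if (is.null(settings$scales)) settings$scales <- default_scales(n_par)
  stopifnot(length(settings$scales) == n_par)
  d <- dim(fixed)
  center <- c((d[2] - 1) / 2 * spacing, (d[1] - 1) / 2 * spacing)
  P0 <- at_invert(init)
  p0 <- transform_to_params(P0, center, model)
  metric_P <- make_metric(fixed, moving, spacing)
  metric_fn <- function(p) metric_P(params_to_transform(p, center, model))
  # finite-difference perturbations of about one pixel: averages over the
  # pixel-scale interpolation/noise ripple of the bilinear MSE landscape so
  # the gradient reflects the basin slope
  half_diag <- sqrt(sum((c(d[1], d[2]) * spacing / 2)^2))
  dt <- 1.0 * spacing
  fd_delta <- if (model == "rigid") c(dt / half_diag, dt, dt)
              else c(rep(dt / half_diag, 4), dt, dt)
  res <- regular_step_descent(metric_fn, p0, settings, fd_delta)
  out <- at_invert(params_to_transform(res$params, center, model))
  out$rigid <- (model == "rigid")
  attr(out, "mse") <- res$value
  attr(out, "trace") <- res$trace
  out
}

#' Rigid registration by MSE minimization
#'
#' Searches the space of 2D rigid transforms (rotation about the fixed-image
#' centre + translation) minimizing the mean squared intensity difference
#' over the overlap, using regular-step gradient descent: steps are taken
#' along the scaled negative gradient with the current step length; when the
#' gradient direction reverses (or a step fails to decrease the metric) the
#' step is multiplied by the relaxation factor; iteration stops once the step
#' falls below `min_step` or the iteration cap is reached. Deterministic for
#' fixed inputs and settings. The gradient is computed by central finite
#' differences.
#'
#' @param fixed,moving grayscale rasters (numeric matrices, 0-255) sharing
#'   `spacing`.
#' @param settings [optimizer_settings()].
#' @param init `affine2d` initialization mapping moving coordinates into the
#'   fixed frame (identity by default).
#' @param spacing pixel spacing of both rasters, micrometres.
#' @return Rigid `affine2d` mapping moving into fixed coordinates, with the
#'   final metric value in `attr(, "mse")` and the accepted-step trace
#'   (iteration, step, mse, parameters) in `attr(, "trace")`.
#' @export
register_rigid_mse <- function(fixed, moving, settings = low_res_settings(3),
                               init = at_identity(), spacing = 1) {
  register_mse(fixed, moving, settings, init, spacing, "rigid")
}

#' Affine registration by MSE minimization
#'
#' As [register_rigid_mse()] over the 6-parameter affine space (linear part
#' about the fixed-image centre + translation), typically initialized with
#' the rigid result and run with the high-resolution step sizes (0.01 /
#' 0.001) to refine convergence.
#'
#' @inheritParams register_rigid_mse
#' @return `affine2d` mapping moving into fixed coordinates.
#' @export
register_affine_mse <- function(fixed, moving, settings = high_res_settings(6),
                                init = at_identity(), spacing = 1) {
  register_mse(fixed, moving, settings, init, spacing, "affine")
}

#' Coarse rigid initialization of a section stack
#'
#' For each adjacent pair, both sections are downsampled to low-resolution
#' rasters (default target extents about 172 x 264 pixels), converted to
#' grayscale by channel averaging, and registered rigidly from the identity
#' with the low-resolution optimizer settings (max/min steps 4 / 0.1, scales
#' 10^2 rotation and 10^-2 translation). This coarse alignment initializes
#' both the intensity-based and the nucleus landmark-based branches.
#'
#' @param stack list of [section_image()] (>= 2 sections).
#' @param coarse_extents target low-resolution extents c(rows, cols) in
#'   pixels.
#' @param settings [optimizer_settings()] for the low-resolution pass.
#' @return List of `N - 1` rigid `affine2d`, entry k mapping section k + 1
#'   into section k's frame (micrometre coordinates).
#' @export
coarse_initialize <- function(stack, coarse_extents = c(172, 264),
                              settings = low_res_settings(3)) {
  stopifnot(length(stack) >= 2)
  d <- dim(stack[[1]]$pixels)
  sp <- stack[[1]]$spacing
  target <- max(d[1] * sp / coarse_extents[1], d[2] * sp / coarse_extents[2])
  target <- max(target, sp)
  coarse <- lapply(stack, function(s) to_grayscale(downsample(s, target)))
  lapply(seq_len(length(stack) - 1L), function(k) {
    register_rigid_mse(coarse[[k]], coarse[[k + 1]], settings = settings,
                       init = at_identity(), spacing = target)
  })
}
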