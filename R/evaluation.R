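#' Reference landmark set
#'
#' Verified homologous nucleus centroid pairs per adjacent section pair, used
#' to build the reference (surrogate ideal) reconstruction and to measure
#' registration error. These landmarks must be disjoint from the landmarks
#' that drive the automatic registration.
#'
#' @param pairs list of length N - 1; element k a data.frame with columns
#'   `x_fixed_um`, `y_fixed_um` (point on section k) and `x_moving_um`,
#'   `y_moving_um` (homologous point on section k + 1).
#' @return Object of class `reference_landmarks`.
#' @export
reference_landmarks <- function(pairs) {
  stopifnot(is.list(pairs))
  for (p in pairs)
    stopifnot(all(c("x_fixed_um", "y_fixed_um", "x_moving_um", "y_moving_um")
                  %in% names(p)))
  structure(list(pairs = pairs), class = "reference_landmarks")
}

#' Read reference landmark pairs from CSV
#'
#' Expects columns `section_index` (the fixed section k of the (k, k+1)
#' pair), `x_fixed_um`, `y_fixed_um`, `x_moving_um`, `y_moving_um`.
#'
#' @param path CSV path.
#' @param n_sections total sections N (defaults to max section_index + 1).
#' @return `reference_landmarks`.
#' @export
read_reference_csv <- function(path, n_sections = NULL) {
  df <- utils::read.csv(path)
  if (is.null(n_sections)) n_sections <- max(df$section_index) + 1L
  reference_landmarks(lapply(seq_len(n_sections - 1L), function(k)
    df[df$section_index == k, , drop = FALSE]))
}

#' Write reference landmark pairs to CSV
#' @param refs `reference_landmarks`.
#' @param path output CSV path.
#' @export
write_reference_csv <- function(refs, path) {
  df <- do.call(rbind, lapply(seq_along(refs$pairs), function(k) {
    p <- refs$pairs[[k]]
    if (nrow(p) == 0) return(NULL)
    data.frame(section_index = k, x_fixed_um = p$x_fixed_um,
               y_fixed_um = p$y_fixed_um, x_moving_um = p$x_moving_um,
               y_moving_um = p$y_moving_um, verified = TRUE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Build the reference reconstruction
#'
#' Fits a transform per adjacent pair from the verified landmark pairs
#' (moving section k + 1 onto fixed section k) and composes them into a
#' chain: the surrogate for an ideal reconstruction that preserves both
#' topology and geometry. The affine model is the default, matching the
#' reference errors reported for affine registration of verified landmarks.
#'
#' @param refs `reference_landmarks`.
#' @param model "affine" (default) or "rigid".
#' @return [transform_chain()].
#' @export
build_reference_reconstruction <- function(refs, model = c("affine", "rigid")) {
  model <- match.arg(model)
  transform_chain(lapply(seq_along(refs$pairs), function(k) {
    p <- refs$pairs[[k]]
    need <- if (model == "rigid") 2L else 3L
    if (nrow(p) < need)
      stop(sprintf("build_reference_reconstruction: pair (%d, %d) has %d landmarks, need >= %d",
                   k, k + 1, nrow(p), need))
    src <- cbind(p$x_moving_um, p$y_moving_um)
    dst <- cbind(p$x_fixed_um, p$y_fixed_um)
    tryCatch(if (model == "rigid") fit_rigid(src, dst) else fit_affine(src, dst),
             error = function(e)
               stop(sprintf("build_reference_reconstruction: pair (%d, %d): %s",
                            k, k + 1, conditionMessage(e))))
  }))
}

#' Pairwise registration error
#'
#' Post-registration Euclidean distance between homologous point pairs on
#' adjacent sections: `||p_I - T(p_J)||` per pair. When the pairs are
#' withheld reference landmarks this is the target registration error (TRE);
#' when they are the landmarks that defined the transform it is the fiducial
#' registration error (FRE). The ideal value is zero.
#'
#' @param transform `affine2d` mapping section-J coordinates into the
#'   section-I frame.
#' @param pairs data.frame with `x_fixed_um`, `y_fixed_um`, `x_moving_um`,
#'   `y_moving_um`.
#' @return Numeric vector of distances, micrometres.
#' @export
pairwise_error <- function(transform, pairs) {
  if (nrow(pairs) == 0) return(numeric())
  mapped <- at_apply(transform, cbind(pairs$x_moving_um, pairs$y_moving_um))
  sqrt((pairs$x_fixed_um - mapped[, 1])^2 + (pairs$y_fixed_um - mapped[, 2])^2)
}

#' Accumulated registration error
#'
#' Maps each reference landmark into the section-1 frame through both the
#' algorithm's and the reference cumulative transforms and measures the
#' Euclidean distance between the two mapped positions, capturing the
#' propagation of pairwise error through the stack. Section 1 is the
#' untransformed base, so its errors are zero by construction. Landmark k of
#' pair (k, k+1) contributes its moving-side (section k + 1) position.
#'
#' @param algo_chain,ref_chain [transform_chain()] over the same sections.
#' @param refs `reference_landmarks`.
#' @return data.frame with columns `section` and `error_um` (section-1 rows
#'   are the zero errors of the base section).
#' @export
accumulated_error <- function(algo_chain, ref_chain, refs) {
  if (length(algo_chain$cumulative) != length(ref_chain$cumulative))
    stop("accumulated_error: chains cover different section counts")
  if (length(refs$pairs) != length(algo_chain$pairwise))
    stop("accumulated_error: landmark pair list does not match chain length")
  base <- data.frame(section = 1L,
                     error_um = rep(0, nrow(refs$pairs[[1]])))
  rest <- do.call(rbind, lapply(seq_along(refs$pairs), function(k) {
    p <- refs$pairs[[k]]
    if (nrow(p) == 0) return(NULL)
    pts <- cbind(p$x_moving_um, p$y_moving_um)
    a <- at_apply(algo_chain$cumulative[[k + 1]], pts)
    r <- at_apply(ref_chain$cumulative[[k + 1]], pts)
    data.frame(section = k + 1L,
               error_um = sqrt(rowSums((a - r)^2)))
  }))
  rbind(base, rest)
}

#' Leave-one-out cross-validated registration error
#'
#' For each landmark pair i, the transform is refit on the remaining n - 1
#' pairs and the pairwise error of pair i under that fit is recorded,
#' yielding n distances. Because the fit is blinded to only one pair at a
#' time, the mean LOOCV error is an optimistic estimate of the TRE but less
#' optimistic than the FRE. Folds whose leave-one-out configuration is
#' degenerate are reported as `NA`, not fabricated.
#'
#' @param pairs data.frame with `x_fixed_um`, `y_fixed_um`, `x_moving_um`,
#'   `y_moving_um`.
#' @param model "rigid" or "affine".
#' @return Numeric vector of n distances (micrometres), `NA` for degenerate
#'   folds.
#' @export
loocv_tre <- function(pairs, model = c("affine", "rigid")) {
  model <- match.arg(model)
  need <- if (model == "rigid") 2L else 3L
  n <- nrow(pairs)
  if (n < need + 1L)
    stop("loocv_tre: need at least ", need + 1L, " pairs")
  vapply(seq_len(n), function(i) {
    rest <- pairs[-i, , drop = FALSE]
    src <- cbind(rest$x_moving_um, rest$y_moving_um)
    dst <- cbind(rest$x_fixed_um, rest$y_fixed_um)
    t <- tryCatch(if (model == "rigid") fit_rigid(src, dst) else fit_affine(src, dst),
                  error = function(e) NULL)
    if (is.null(t)) return(NA_real_)
    pairwise_error(t, pairs[i, , drop = FALSE])
  }, numeric(1))
}

#' Summarize a registration error distribution
#'
#' Pooled median, interquartile range, and rank-based 95% confidence
#' interval on the median: the CI bounds are the sorted values at ranks
#' `n/2 - 1.96 sqrt(n)/2` and `n/2 + 1.96 sqrt(n)/2`, rounded to the nearest
#' integer rank and clamped to `[1, n]` (e.g. ranks 40 and 60 for n = 100).
#' With per-section grouping, also reports each section's maximum error and
#' the mean and SD of those maxima across sections.
#'
#' @param errors non-empty numeric vector, micrometres.
#' @param sections optional per-value section labels.
#' @return Object of class `error_report`: `n`, `median`, `iqr`,
#'   `ci95` (length 2), and, when grouped, `per_section_max` plus its
#'   `max_mean` and `max_sd`.
#' @export
summarize_errors <- function(errors, sections = NULL) {
  errors <- errors[!is.na(errors)]
  if (length(errors) == 0) stop("summarize_errors: empty input")
  n <- length(errors)
  s <- sort(errors)
  lo <- min(max(round(n / 2 - 1.96 * sqrt(n) / 2), 1), n)
  hi <- min(max(round(n / 2 + 1.96 * sqrt(n) / 2), 1), n)
  rep <- list(n = n, median = stats::median(errors),
              iqr = stats::IQR(errors), ci95 = c(s[lo], s[hi]))
  if (!is.null(sections)) {
    mx <- c(tapply(errors, sections, max))   # drop the 1-d array dim
    rep$per_section_max <- mx
    rep$max_mean <- mean(mx)
    rep$max_sd <- if (length(mx) > 1) stats::sd(mx) else 0
  }
  structure(rep, class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error report: n = %d, median %.3g um, IQR %.3g, 95%% CI [%.3g, %.3g]>\n",
              x$n, x$median, x$iqr, x$ci95[1], x$ci95[2]))
  if (!is.null(x$per_section_max))
    cat(sprintf("  per-section max: mean %.3g +- %.3g um over %d sections\n",
                x$max_mean, x$max_sd, length(x$per_section_max)))
  invisible(x)
}

#' Compare two paired error distributions
#'
#' Screens each sample for normality (Kolmogorov-Smirnov test against a
#' normal with the sample's moments) and then runs a paired Wilcoxon
#' signed-rank test of equal medians on the landmark-aligned differences
#' (zero differences are discarded, the standard signed-rank convention).
#' The normality result is reported, not used to switch tests: registration
#' errors are generally non-normal, so the non-parametric comparison is
#' always the one made.
#'
#' @param errors_a,errors_b equal-length numeric vectors paired by landmark.
#' @return List: `normality_p` (length 2), `wilcoxon_p`, `statistic`,
#'   `median_a`, `median_b`, `direction` ("a < b", "b < a" or "none").
#' @export
compare_methods <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("compare_methods: samples must be paired (equal length)")
  ksp <- function(x) {
    if (stats::sd(x) == 0) return(0)
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  w <- suppressWarnings(stats::wilcox.test(errors_a, errors_b, paired = TRUE,
                                           exact = FALSE))
  ma <- stats::median(errors_a); mb <- stats::median(errors_b)
  list(normality_p = c(a = ksp(errors_a), b = ksp(errors_b)),
       wilcoxon_p = if (is.na(w$p.value)) 1 else w$p.value,
       statistic = unname(w$statistic),
       median_a = ma, median_b = mb,
       direction = if (is.na(w$p.value) || w$p.value >= 0.05) "none"
                   else if (ma < mb) "a < b" else "b < a")
}

#' MSE landscape sweep around a registration optimum
#'
#' Evaluates the grayscale MSE of the moving section warped by the given
#' transform composed with pure translations along one axis, over a
#' symmetric range (default +-20 um in 0.5 um increments: 81 samples), and
#' reports the displacement of the MSE minimum from the centre transform. A
#' displacement of 0 means the intensity-metric optimum coincides with the
#' (landmark-based) centre transform.
#'
#' @param fixed,moving `section_image`s.
#' @param center `affine2d` mapping moving into the fixed frame (typically a
#'   nucleus-landmark registration).
#' @param axis "x" or "y".
#' @param range_um sweep half-range, micrometres.
#' @param step_um sweep increment, micrometres.
#' @return List: `displacements` (um), `mse` (one value per displacement),
#'   `optimum_um` (displacement of the minimum).
#' @export
mse_landscape_sweep <- function(fixed, moving, center = at_identity(),
                                axis = c("x", "y"), range_um = 20,
                                step_um = 0.5) {
  axis <- match.arg(axis)
  fg <- to_grayscale(fixed)
  mg <- to_grayscale(moving)
  sp <- fixed$spacing
  disp <- seq(-range_um, range_um, by = step_um)
  mse <- vapply(disp, function(d) {
    off <- if (axis == "x") at_translation(d, 0) else at_translation(0, d)
    w <- warp_gray(mg, moving$spacing, compose(off, center), dim(fg), sp)
    mse_metric(fg, w$values, w$mask)
  }, numeric(1))
  list(displacements = disp, mse = mse, optimum_um = disp[which.min(mse)])
}

#' Non-parametric upper prediction bound
#'
#' For a sample of N values, the maximum observed value is the upper bound
#' of the `P` percent prediction interval with `P = 100 (N - 1) / (N + 1)`
#' (e.g. N = 39 gives a 95% interval).
#'
#' @param values non-empty numeric vector (N >= 2).
#' @return List: `upper` (max of the sample) and `P_percent`.
#' @export
prediction_interval_upper <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("prediction_interval_upper: need N >= 2 values")
  list(upper = max(values), P_percent = 100 * (n - 1) / (n + 1))
}
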