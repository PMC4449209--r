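#' 2D affine transform in physical coordinates
#'
#' Constructs a 2D affine map `x -> matrix %*% x + translation` operating in
#' physical micrometre coordinates. Rigid transforms (rotation + translation
#' only) are the constrained case flagged by `rigid = TRUE`; their linear part
#' must be a proper rotation (orthogonal, determinant +1).
#'
#' All registration transforms in this package map *moving*-section
#' coordinates into the *fixed*-section frame, and all thresholds stated in
#' micrometres are therefore resolution-independent.
#'
#' @param matrix 2x2 numeric linear part (dimensionless).
#' @param translation length-2 numeric translation, micrometres.
#' @param rigid logical; if `TRUE` the linear part is checked to be a proper
#'   rotation.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(matrix = diag(2), translation = c(0, 0), rigid = FALSE) {
  matrix <- base::matrix(as.numeric(matrix), 2, 2)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 2, all(is.finite(matrix)), all(is.finite(translation)))
  if (abs(det(matrix)) <= 1e-12)
    stop("affine2d: linear part is singular (|det| <= 1e-12)")
  if (rigid) {
    if (max(abs(crossprod(matrix) - diag(2))) > 1e-8 || det(matrix) < 0)
      stop("affine2d: rigid = TRUE but linear part is not a proper rotation")
  }
  structure(list(matrix = matrix, translation = translation, rigid = isTRUE(rigid)),
            class = "affine2d")
}

#' Identity transform
#' @return Rigid identity `affine2d`.
#' @export
at_identity <- function() affine2d(diag(2), c(0, 0), rigid = TRUE)

#' Pure translation transform
#' @param tx,ty translation components, micrometres.
#' @return Rigid `affine2d`.
#' @export
at_translation <- function(tx, ty) affine2d(diag(2), c(tx, ty), rigid = TRUE)

#' Rotation about a centre point
#'
#' @param theta rotation angle, radians (counter-clockwise in (x, y)).
#' @param center length-2 centre of rotation, micrometres.
#' @return Rigid `affine2d` mapping `x -> R (x - c) + c`.
#' @export
at_rotation <- function(theta, center = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  affine2d(R, as.numeric(center) - R %*% as.numeric(center), rigid = TRUE)
}

#' @export
print.affine2d <- function(x, ...) {
  cat(if (x$rigid) "<rigid 2D transform>" else "<affine 2D transform>", "\n")
  cat(sprintf("  matrix: [%.6g %.6g; %.6g %.6g]\n",
              x$matrix[1, 1], x$matrix[1, 2], x$matrix[2, 1], x$matrix[2, 2]))
  cat(sprintf("  translation (um): (%.6g, %.6g)\n", x$translation[1], x$translation[2]))
  invisible(x)
}

is_affine2d <- function(x) inherits(x, "affine2d")

#' Compose two transforms
#'
#' Returns the transform `x -> outer(inner(x))`. The result is flagged rigid
#' iff both inputs are rigid.
#'
#' @param outer,inner `affine2d` objects.
#' @return `affine2d`.
#' @export
compose <- function(outer, inner) {
  stopifnot(is_affine2d(outer), is_affine2d(inner))
  affine2d(outer$matrix %*% inner$matrix,
           as.vector(outer$matrix %*% inner$translation) + outer$translation,
           rigid = outer$rigid && inner$rigid)
}

#' Apply a transform to points
#'
#' @param t `affine2d`.
#' @param points numeric n x 2 matrix (or length-2 vector) of micrometre
#'   coordinates, columns x then y.
#' @return n x 2 matrix of transformed points.
#' @export
at_apply <- function(t, points) {
  stopifnot(is_affine2d(t))
  p <- if (is.null(dim(points))) matrix(as.numeric(points), ncol = 2) else
    as.matrix(points)
  stopifnot(ncol(p) == 2, all(is.finite(p)))
  out <- p %*% t(t$matrix)
  out[, 1] <- out[, 1] + t$translation[1]
  out[, 2] <- out[, 2] + t$translation[2]
  dimnames(out) <- NULL
  out
}

#' Invert a transform
#'
#' `compose(t, at_invert(t))` is the identity to numerical precision.
#'
#' @param t `affine2d` with invertible linear part.
#' @return `affine2d`.
#' @export
at_invert <- function(t) {
  stopifnot(is_affine2d(t))
  Minv <- solve(t$matrix)
  affine2d(Minv, -as.vector(Minv %*% t$translation), rigid = t$rigid)
}

#' Least-squares rigid (Procrustes) fit
#'
#' Finds the rotation + translation minimizing the summed squared residual
#' `sum ||T(src_i) - dst_i||^2` in closed form via the SVD of the centred
#' cross-covariance, with the reflection case guarded (determinant forced to
#' +1). Deterministic.
#'
#' @param src,dst n x 2 matrices of corresponding points, micrometres.
#' @return Rigid `affine2d` mapping `src` onto `dst`.
#' @export
fit_rigid <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  if (nrow(src) < 2)
    stop("fit_rigid: at least 2 point pairs required")
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  if (max(abs(A)) < 1e-12)
    stop("fit_rigid: degenerate input (all source points coincident)")
  H <- crossprod(A, B)                      # 2x2 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  affine2d(R, cd - as.vector(R %*% cs), rigid = TRUE)
}

#' Least-squares affine fit
#'
#' Ordinary least-squares affine transform minimizing
#' `sum ||T(src_i) - dst_i||^2`; with exactly 3 non-collinear pairs the fit
#' interpolates exactly.
#'
#' @param src,dst n x 2 matrices of corresponding points, micrometres.
#' @return `affine2d` mapping `src` onto `dst`.
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst))
  if (nrow(src) < 3)
    stop("fit_affine: at least 3 point pairs required")
  X <- cbind(src, 1)
  q <- qr(X)
  if (q$rank < 3)
    stop("fit_affine: degenerate (collinear) source configuration")
  coef <- qr.coef(q, dst)                   # 3 x 2: rows x, y, intercept
  affine2d(t(coef[1:2, , drop = FALSE]), coef[3, ], rigid = FALSE)
}

#' Serialize a transform to JSON
#'
#' Writes the 3x3 homogeneous matrix (row-major) with units recorded as "um".
#'
#' @param t `affine2d`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
transform_to_json <- function(t, path = NULL) {
  stopifnot(is_affine2d(t))
  H <- rbind(cbind(t$matrix, t$translation), c(0, 0, 1))
  obj <- list(homogeneous_matrix = as.vector(t(H)), order = "row-major",
              rigid = t$rigid, units = "um")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a transform from JSON
#' @param x JSON string or file path produced by [transform_to_json()].
#' @return `affine2d`.
#' @export
transform_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  H <- matrix(obj$homogeneous_matrix, 3, 3, byrow = TRUE)
  affine2d(H[1:2, 1:2], H[1:2, 3], rigid = isTRUE(obj$rigid))
}

#' Transform chain for a section series
#'
#' Holds the `N - 1` pairwise transforms of an `N`-section reconstruction
#' (entry `k` maps section `k + 1` coordinates into section `k`'s frame) and
#' the derived cumulative transforms mapping each section into the frame of
#' section 1 (the untransformed base): `cumulative[[k]]` is
#' `pairwise[[1]] o ... o pairwise[[k - 1]]` with the innermost (first
#' applied) factor being `pairwise[[k - 1]]`.
#'
#' @param pairwise list of `affine2d`, entry `k` mapping section `k + 1` into
#'   section `k`.
#' @return Object of class `transform_chain` with elements `pairwise` and
#'   `cumulative` (length `N`, `cumulative[[1]]` the identity).
#' @export
transform_chain <- function(pairwise) {
  stopifnot(is.list(pairwise), all(vapply(pairwise, is_affine2d, logical(1))))
  cumulative <- vector("list", length(pairwise) + 1L)
  cumulative[[1L]] <- at_identity()
  for (k in seq_along(pairwise))
    cumulative[[k + 1L]] <- compose(cumulative[[k]], pairwise[[k]])
  structure(list(pairwise = pairwise, cumulative = cumulative),
            class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform chain: %d sections, %d pairwise transforms>\n",
              length(x$cumulative), length(x$pairwise)))
  invisible(x)
}

#' Serialize a transform chain to JSON
#' @param chain `transform_chain`.
#' @param path optional output file.
#' @return JSON string (invisibly if written).
#' @export
chain_to_json <- function(chain, path = NULL) {
  stopifnot(inherits(chain, "transform_chain"))
  ser <- function(t) list(homogeneous_matrix =
                            as.vector(t(rbind(cbind(t$matrix, t$translation), c(0, 0, 1)))),
                          order = "row-major", rigid = t$rigid, units = "um")
  js <- jsonlite::toJSON(list(pairwise = lapply(chain$pairwise, ser)),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a transform chain from JSON
#' @param x JSON string or path written by [chain_to_json()].
#' @return `transform_chain`.
#' @export
chain_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  transform_chain(lapply(obj$pairwise, function(e) {
    H <- matrix(e$homogeneous_matrix, 3, 3, byrow = TRUE)
    affine2d(H[1:2, 1:2], H[1:2, 3], rigid = isTRUE(e$rigid))
  }))
}
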