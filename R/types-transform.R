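#' En-face affine transform
#'
#' A 2x3 affine matrix mapping moving en-face positions to fixed en-face
#' positions, both in micrometres: `(x', y')' = A %*% c(x, y, 1)`. Working in
#' metric units makes the transform independent of each image's pixel pitch.
#'
#' @param matrix numeric 2x3 matrix; the 2x2 linear part must be non-singular.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(matrix) {
  m <- base::matrix(as.numeric(matrix), 2, 3)
  assert_that(all(is.finite(m)), "affine matrix must be finite")
  assert_that(abs(det(m[, 1:2])) > 1e-12, "linear part of affine is singular")
  structure(list(matrix = m), class = "affine2d")
}

#' @rdname affine2d
#' @export
affine2d_identity <- function() affine2d(cbind(diag(2), c(0, 0)))

#' Build an affine from geometric parameters
#'
#' Composition order: scale/shear, then rotation, then translation, about the
#' origin of the metric frame.
#'
#' @param rotation_deg rotation angle, degrees (counter-clockwise).
#' @param scale isotropic scale factor.
#' @param shear shear coefficient applied to x as a function of y.
#' @param translation numeric `c(tx, ty)` in micrometres.
#' @export
affine2d_from_params <- function(rotation_deg = 0, scale = 1, shear = 0,
                                 translation = c(0, 0)) {
  th <- rotation_deg * pi / 180
  R <- base::matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- base::matrix(c(scale, 0, shear * scale, scale), 2, 2)
  affine2d(cbind(R %*% S, as.numeric(translation)))
}

#' Apply an affine transform to points
#'
#' @param t an `affine2d`.
#' @param xy n x 2 matrix of `(x, y)` positions in micrometres.
#' @return n x 2 matrix of transformed positions.
#' @export
affine_apply <- function(t, xy) {
  xy <- base::matrix(as.numeric(xy), ncol = 2)
  out <- cbind(xy, 1) %*% t(t$matrix)
  colnames(out) <- c("x", "y")
  out
}

#' Invert an affine transform
#' @param t an `affine2d`.
#' @export
affine_invert <- function(t) {
  A <- t$matrix[, 1:2]
  b <- t$matrix[, 3]
  Ai <- solve(A)
  affine2d(cbind(Ai, -Ai %*% b))
}

#' Compose affine transforms (`a` after `b`)
#' @param a,b `affine2d` objects; the result maps `p -> a(b(p))`.
#' @export
affine_compose <- function(a, b) {
  A <- a$matrix[, 1:2]; B <- b$matrix[, 1:2]
  affine2d(cbind(A %*% B, A %*% b$matrix[, 3] + a$matrix[, 3]))
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> moving (um) -> fixed (um)\n")
  print(x$matrix)
  invisible(x)
}

#' Per-A-scan axial displacement field
#'
#' `delta[b, a]` is the axial displacement (in axial pixels) that aligns the
#' moving column at en-face cell `(b, a)` with the fixed one; see
#' [column_shift_field()].
#'
#' @param delta numeric matrix `(n_bscans x n_ascans)`.
#' @param valid logical matrix of the same shape; defaults to finite cells.
#' @return An object of class `zshift_field`.
#' @export
zshift_field <- function(delta, valid = NULL) {
  assert_that(is.matrix(delta), "delta must be a matrix")
  if (is.null(valid)) valid <- is.finite(delta)
  assert_that(identical(dim(valid), dim(delta)) && is.logical(valid),
              "valid mask shape mismatch")
  assert_that(all(is.finite(delta[valid])), "delta must be finite where valid")
  structure(list(delta = delta, valid = valid), class = "zshift_field")
}

#' @export
print.zshift_field <- function(x, ...) {
  cat(sprintf("<zshift_field> %d x %d, %.1f%% valid\n",
              nrow(x$delta), ncol(x$delta), 100 * mean(x$valid)))
  invisible(x)
}

#' Per-B-scan transform list
#'
#' One 2D transform in the `(a, z)` plane (metric units) per B-scan of the
#' fixed grid, as produced by layer point matching. A `NULL` entry marks a
#' per-B-scan registration failure.
#'
#' @param transforms list of 2x3 matrices (or `NULL` failure markers), one per
#'   B-scan.
#' @param model_kind `"rigid"` or `"similarity"`.
#' @export
bscan_transforms <- function(transforms, model_kind = c("rigid", "similarity")) {
  model_kind <- match.arg(model_kind)
  assert_that(is.list(transforms) && length(transforms) >= 1,
              "transforms must be a non-empty list")
  for (tr in transforms) {
    if (!is.null(tr)) {
      assert_that(is.matrix(tr) && all(dim(tr) == c(2, 3)) && all(is.finite(tr)),
                  "each transform must be a finite 2x3 matrix or NULL")
    }
  }
  structure(list(transforms = transforms, model_kind = model_kind),
            class = "bscan_transforms")
}

#' @export
length.bscan_transforms <- function(x) length(x$transforms)

#' @export
print.bscan_transforms <- function(x, ...) {
  nf <- sum(vapply(x$transforms, is.null, logical(1)))
  cat(sprintf("<bscan_transforms> %s, %d B-scans (%d failed)\n",
              x$model_kind, length(x$transforms), nf))
  invisible(x)
}

# --- closed-form 2-point / least-squares fits used by RANSAC ----------------

# Umeyama alignment of paired 2D point sets P -> Q (rows are points).
# Returns a 2x3 matrix. model: "rigid" (rotation+translation) or
# "similarity" (adds isotropic scale).
fit_point_transform <- function(P, Q, model = c("rigid", "similarity")) {
  model <- match.arg(model)
  P <- base::matrix(P, ncol = 2); Q <- base::matrix(Q, ncol = 2)
  n <- nrow(P)
  mp <- colMeans(P); mq <- colMeans(Q)
  Pc <- sweep(P, 2, mp); Qc <- sweep(Q, 2, mq)
  S <- crossprod(Qc, Pc) / n           # 2x2 covariance
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  s <- if (model == "similarity") {
    varP <- mean(rowSums(Pc^2))
    if (varP <= 0) 1 else sum(diag(D) * sv$d) / varP
  } else 1
  tvec <- mq - s * R %*% mp
  cbind(s * R, tvec)
}

apply_mat23 <- function(m, xy) {
  xy <- base::matrix(as.numeric(xy), ncol = 2)
  cbind(xy, 1) %*% t(m)
}
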