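# RANSAC estimation of the en-face affine from matched keypoints.
#
# Keypoint coordinates are converted from pixels to micrometres with each
# image's own pixel pitch before estimation, so the recovered transform is
# independent of either image's resolution. A deliberately high iteration
# budget limits RANSAC's inherent randomness; the final model is refit by
# least squares on its inlier set.

#' RANSAC parameters for the en-face affine
#'
#' @param n_iter fixed iteration budget (default 10000).
#' @param inlier_tol_um inlier residual tolerance in micrometres (default 25).
#' @param seed integer seed (deterministic result).
#' @export
ransac_params <- function(n_iter = 10000L, inlier_tol_um = 25, seed = 0L) {
  list(n_iter = as.integer(n_iter), inlier_tol_um = inlier_tol_um,
       seed = as.integer(seed))
}

#' A registration-failure marker
#'
#' Returned where an estimation stage cannot produce a transform (for the
#' affine stage: consensus below the 3-inlier minimum). Distinguishable from
#' a transform via `inherits(x, "registration_failure")`.
#'
#' @param reason human-readable reason.
#' @export
registration_failure <- function(reason) {
  structure(list(reason = reason), class = "registration_failure")
}

#' @export
print.registration_failure <- function(x, ...) {
  cat("<registration_failure>", x$reason, "\n")
  invisible(x)
}

# Exact affine through 3 point pairs; NULL when degenerate.
affine_from_3 <- function(P, Q) {
  M <- cbind(P, 1)
  if (abs(det(M)) < 1e-9) return(NULL)
  t(solve(M, Q))  # 2x3
}

affine_lstsq <- function(P, Q) {
  P1 <- cbind(P, 1)
  t(solve(crossprod(P1), crossprod(P1, Q)))
}

#' Estimate the en-face affine with RANSAC
#'
#' Affine estimation (minimum sample 3) over matched keypoints, in metric
#' units. Matches are canonicalized by index order first, so the result is
#' invariant to the ordering of the input match list under the same seed.
#'
#' @param matches a `match_set` from [match_descriptors()].
#' @param fixed_kp,moving_kp the [keypoint_set()]s the matches index into.
#' @param params a [ransac_params()].
#' @return An [affine2d()] (moving micrometres to fixed micrometres) with
#'   attributes `inliers` (logical per match) and `n_inliers`, or a
#'   [registration_failure()] when the best consensus has fewer than 3
#'   inliers. Fewer than 3 matches is an error.
#' @export
estimate_affine_ransac <- function(matches, fixed_kp, moving_kp,
                                   params = ransac_params()) {
  assert_that(nrow(matches) >= 3, "affine RANSAC needs at least 3 matches")
  ord <- order(matches$index_fixed, matches$index_moving)
  matches <- matches[ord, ]
  # pixels -> micrometres (x * dx, y * dy), each image's own pitch
  Q <- cbind(fixed_kp$xy[matches$index_fixed, 1] * fixed_kp$spacing[2],
             fixed_kp$xy[matches$index_fixed, 2] * fixed_kp$spacing[1])
  P <- cbind(moving_kp$xy[matches$index_moving, 1] * moving_kp$spacing[2],
             moving_kp$xy[matches$index_moving, 2] * moving_kp$spacing[1])
  n <- nrow(P)
  P1 <- cbind(P, 1)
  tol2 <- params$inlier_tol_um^2
  best_count <- -1L; best_inliers <- NULL
  with_seed(params$seed, {
    for (it in seq_len(params$n_iter)) {
      s <- sample.int(n, 3L)
      A <- affine_from_3(P[s, , drop = FALSE], Q[s, , drop = FALSE])
      if (is.null(A)) next
      res <- P1 %*% t(A) - Q
      inl <- (res[, 1]^2 + res[, 2]^2) <= tol2
      cnt <- sum(inl)
      if (cnt > best_count) {
        best_count <- cnt
        best_inliers <- inl
      }
    }
  })
  if (is.null(best_inliers) || best_count < 3) {
    return(registration_failure(sprintf(
      "affine consensus too small (%d inliers of %d matches)",
      max(best_count, 0), n)))
  }
  A <- affine_lstsq(P[best_inliers, , drop = FALSE],
                    Q[best_inliers, , drop = FALSE])
  # one consensus re-expansion after the least-squares refit
  res <- P1 %*% t(A) - Q
  inl <- (res[, 1]^2 + res[, 2]^2) <= tol2
  if (sum(inl) >= 3) {
    A <- affine_lstsq(P[inl, , drop = FALSE], Q[inl, , drop = FALSE])
  } else {
    inl <- best_inliers
  }
  out <- affine2d(A)
  # report inliers in the caller's original match order
  inv <- integer(n); inv[ord] <- seq_len(n)
  attr(out, "inliers") <- inl[inv]
  attr(out, "n_inliers") <- sum(inl)
  out
}
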