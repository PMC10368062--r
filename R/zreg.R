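# Axial (Z-axis) registration guided by the ILM surface.
#
# Two alternatives:
#   Column Shifting — each A-scan column is moved axially by the per-column
#     ILM difference; this matches the ILM exactly at every valid column but
#     is sensitive to single-cell segmentation errors.
#   Layer Point Matching (LPM) — per B-scan, a rigid or similarity transform
#     in the (a, z) plane is estimated by RANSAC over the pre-paired ILM
#     points, which tolerates corrupted ILM cells but cannot match the ILM
#     exactly everywhere.
# LPM point coordinates are metric (a in um via da, z in um via dz) so that
# rotations are geometrically meaningful under anisotropic spacing.

#' Per-A-scan axial shift field from ILM surfaces
#'
#' `delta[b, a] = ILM_fixed[b, a] - ILM_moving_warped[b, a]` where both are
#' valid; invalid elsewhere. Both height grids must be in the same axial
#' pixel scale (rescale by `dz_moving / dz_fixed` first if the devices
#' differ).
#'
#' @param fixed_ilm,moving_ilm_warped [surface_set()]s containing `ILM`, or
#'   plain height matrices (then assumed all-valid at finite cells), on the
#'   same `(b, a)` grid.
#' @return A [zshift_field()].
#' @export
column_shift_field <- function(fixed_ilm, moving_ilm_warped) {
  get <- function(x) {
    if (inherits(x, "surface_set")) {
      assert_that("ILM" %in% names(x$heights), "surface set lacks ILM")
      list(h = x$heights$ILM, v = x$valid$ILM)
    } else {
      list(h = x, v = is.finite(x))
    }
  }
  f <- get(fixed_ilm); m <- get(moving_ilm_warped)
  assert_that(identical(dim(f$h), dim(m$h)), "ILM grids differ in shape")
  both <- f$v & m$v
  assert_that(any(both), "no jointly valid ILM cell")
  delta <- matrix(NA_real_, nrow(f$h), ncol(f$h))
  delta[both] <- f$h[both] - m$h[both]
  zshift_field(delta, both)
}

#' Apply a column shift field to a volume
#'
#' `registered[b, z, a] = volume[b, z - delta[b, a], a]` with linear
#' interpolation along z; out-of-range samples take the fill value. Columns
#' with an invalid shift pass through unchanged and are flagged in the
#' attached `shifted` attribute. After this operation the moving ILM
#' coincides with the fixed ILM at every valid column.
#'
#' @param volume [oct_volume()] already on the fixed en-face grid.
#' @param delta a [zshift_field()] on the same `(b, a)` grid.
#' @param fill fill value for samples shifted in from outside the axial
#'   range.
#' @return An [oct_volume()]; attribute `shifted` is the validity mask used.
#' @export
apply_column_shift <- function(volume, delta, fill = 0) {
  d <- dim(volume)
  assert_that(identical(dim(delta$delta), d[c(1, 3)]),
              "shift field grid does not match the volume's (b, a) grid")
  nz <- d[2]
  out <- volume$intensity
  z0 <- 0:(nz - 1)
  for (b in seq_len(d[1])) {
    cols <- which(delta$valid[b, ])
    if (!length(cols)) next
    slice <- volume$intensity[b, , ]          # z x a
    for (a in cols) {
      zq <- z0 - delta$delta[b, a]
      out[b, , a] <- linear_sample_1d(slice[, a], zq, fill = fill)
    }
  }
  res <- oct_volume(pmax(out, 0), volume$spacing, volume$device_tag)
  attr(res, "shifted") <- delta$valid
  res
}

#' Shift surface heights by a column shift field
#'
#' Surfaces move with their columns: `height + delta` where both are valid.
#'
#' @param surfaces a [surface_set()].
#' @param delta a [zshift_field()] on the same grid.
#' @export
shift_surfaces <- function(surfaces, delta) {
  heights <- list(); vmask <- list()
  for (nm in names(surfaces$heights)) {
    h <- surfaces$heights[[nm]] + delta$delta
    v <- surfaces$valid[[nm]] & delta$valid
    h[!v] <- NA_real_
    heights[[nm]] <- h
    vmask[[nm]] <- v
  }
  surface_set(heights, vmask)
}

#' LPM parameters
#'
#' @param n_iter RANSAC iteration budget per B-scan.
#' @param tol_px inlier tolerance: residuals are measured in micrometres,
#'   converted to pixel units via `(da, dz)`, and compared to this value.
#' @param seed integer seed.
#' @param da_um,dz_um pixel pitches used to place ILM points in metric
#'   coordinates.
#' @export
lpm_params <- function(n_iter = 2000L, tol_px = 3, seed = 0L, da_um = 1,
                       dz_um = 1) {
  list(n_iter = as.integer(n_iter), tol_px = tol_px, seed = as.integer(seed),
       da_um = da_um, dz_um = dz_um)
}

#' Register one B-scan by layer point matching
#'
#' RANSAC over the pre-paired ILM point sets `{(a, ILM_fixed(a))}` and
#' `{(a, ILM_moving(a))}` of one B-scan, fitting a rigid or similarity
#' transform in the metric `(a, z)` plane (minimal sample 2). The returned
#' 2x3 matrix maps moving `(a_um, z_um)` to fixed `(a_um, z_um)`.
#'
#' @param fixed_row,moving_row ILM heights over the A-scan axis (axial
#'   pixels; `NA` = invalid).
#' @param model `"rigid"`, `"similarity"` or `"affine"` (affine needs 3
#'   points and is kept out of the defaults).
#' @param params an [lpm_params()].
#' @return 2x3 matrix with attributes `inliers`, `n_inliers`, or a
#'   [registration_failure()] when fewer than 2 (3 for affine) jointly valid
#'   points exist or consensus stays below the minimum.
#' @export
lpm_register_bscan <- function(fixed_row, moving_row,
                               model = c("rigid", "similarity", "affine"),
                               params = lpm_params()) {
  model <- match.arg(model)
  min_n <- if (model == "affine") 3L else 2L
  ok <- is.finite(fixed_row) & is.finite(moving_row)
  if (sum(ok) < min_n) {
    return(registration_failure(sprintf("only %d valid ILM pairs", sum(ok))))
  }
  a_idx <- which(ok) - 1
  Q <- cbind(a_idx * params$da_um, fixed_row[ok] * params$dz_um)
  P <- cbind(a_idx * params$da_um, moving_row[ok] * params$dz_um)
  n <- nrow(P)
  # residuals compared in pixel units to honour the anisotropic spacing
  scale_px <- c(params$da_um, params$dz_um)
  tol2 <- params$tol_px^2
  fit_fn <- function(Ps, Qs) {
    if (model == "affine") {
      A <- affine_from_3(Ps, Qs)
      if (is.null(A)) return(NULL)
      A
    } else {
      fit_point_transform(Ps, Qs, model)
    }
  }
  best_count <- -1L; best_inliers <- NULL
  P1 <- cbind(P, 1)
  with_seed(params$seed, {
    for (it in seq_len(params$n_iter)) {
      s <- sample.int(n, min_n)
      A <- fit_fn(P[s, , drop = FALSE], Q[s, , drop = FALSE])
      if (is.null(A) || any(!is.finite(A))) next
      res <- P1 %*% t(A) - Q
      r2 <- (res[, 1] / scale_px[1])^2 + (res[, 2] / scale_px[2])^2
      inl <- r2 <= tol2
      cnt <- sum(inl)
      if (cnt > best_count) {
        best_count <- cnt
        best_inliers <- inl
      }
    }
  })
  if (is.null(best_inliers) || best_count < min_n) {
    return(registration_failure("LPM consensus below the minimal sample"))
  }
  A <- fit_fn(P[best_inliers, , drop = FALSE], Q[best_inliers, , drop = FALSE])
  res <- P1 %*% t(A) - Q
  r2 <- (res[, 1] / scale_px[1])^2 + (res[, 2] / scale_px[2])^2
  inl <- r2 <= tol2
  if (sum(inl) >= min_n) {
    A <- fit_fn(P[inl, , drop = FALSE], Q[inl, , drop = FALSE])
  } else {
    inl <- best_inliers
  }
  structure(A, inliers = inl, n_inliers = sum(inl), valid_a = a_idx)
}

#' Register every B-scan by layer point matching
#'
#' Applies [lpm_register_bscan()] per B-scan. B-scans that fail fall back to
#' the nearest successfully registered B-scan's transform and are flagged.
#'
#' @param fixed_surfaces,moving_surfaces_warped [surface_set()]s on the same
#'   grid (moving already on the fixed en-face grid).
#' @param model transform model.
#' @param params an [lpm_params()]; the per-B-scan seed is derived from it.
#' @return A [bscan_transforms()]; attribute `fallback` flags B-scans that
#'   borrowed a neighbour's transform (`NULL` entries remain only when no
#'   B-scan registered at all).
#' @export
lpm_register_volume <- function(fixed_surfaces, moving_surfaces_warped,
                                model = c("rigid", "similarity", "affine"),
                                params = lpm_params()) {
  model <- match.arg(model)
  fh <- fixed_surfaces$heights$ILM; fv <- fixed_surfaces$valid$ILM
  mh <- moving_surfaces_warped$heights$ILM; mv <- moving_surfaces_warped$valid$ILM
  assert_that(!is.null(fh) && !is.null(mh), "both surface sets need ILM")
  nb <- nrow(fh)
  trs <- vector("list", nb)
  okflag <- logical(nb)
  for (b in seq_len(nb)) {
    fr <- fh[b, ]; fr[!fv[b, ]] <- NA_real_
    mr <- mh[b, ]; mr[!mv[b, ]] <- NA_real_
    pb <- params; pb$seed <- derive_seed(params$seed, paste0("bscan", b))
    r <- lpm_register_bscan(fr, mr, model, pb)
    if (!inherits(r, "registration_failure")) {
      trs[[b]] <- matrix(as.numeric(r), 2, 3)
      okflag[b] <- TRUE
    }
  }
  fallback <- logical(nb)
  if (any(okflag) && !all(okflag)) {
    good <- which(okflag)
    for (b in which(!okflag)) {
      nb_good <- good[which.min(abs(good - b))]
      trs[[b]] <- trs[[nb_good]]
      fallback[b] <- TRUE
    }
  }
  out <- bscan_transforms(trs, if (model == "affine") "rigid" else model)
  out$model_kind <- model
  attr(out, "fallback") <- fallback
  out
}

#' Apply per-B-scan transforms to a volume
#'
#' Each B-scan is resampled under the inverse of its transform (bilinear in
#' the metric `(a, z)` plane). B-scans with a `NULL` failure marker pass
#' through unchanged and are flagged.
#'
#' @param volume [oct_volume()] on the fixed en-face grid.
#' @param transforms a [bscan_transforms()] of matching length.
#' @param fill fill value for out-of-range samples.
#' @return An [oct_volume()]; attribute `registered` flags transformed
#'   B-scans.
#' @export
apply_bscan_transforms <- function(volume, transforms, fill = 0) {
  d <- dim(volume)
  assert_that(length(transforms) == d[1],
              "need one transform per B-scan (%d vs %d)",
              length(transforms), d[1])
  da <- volume$spacing[3]; dz <- volume$spacing[2]
  nz <- d[2]; na_ <- d[3]
  # output pixel grid of one B-scan in metric coordinates
  gx <- rep(0:(na_ - 1), each = nz) * da    # a
  gy <- rep(0:(nz - 1), times = na_) * dz   # z
  out <- volume$intensity
  flags <- logical(d[1])
  for (b in seq_len(d[1])) {
    A <- transforms$transforms[[b]]
    if (is.null(A)) next
    Ai <- affine_invert(affine2d(A))
    pre <- affine_apply(Ai, cbind(gx, gy))
    px_a <- pre[, 1] / da; px_z <- pre[, 2] / dz
    slice <- volume$intensity[b, , ]          # z x a
    out[b, , ] <- matrix(bilinear_sample(slice, px_a, px_z, fill = fill),
                         nz, na_)
    flags[b] <- TRUE
  }
  res <- oct_volume(pmax(out, 0), volume$spacing, volume$device_tag)
  attr(res, "registered") <- flags
  res
}
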