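# Applying the en-face affine to a full volume and its surfaces.

#' En-face grid geometry of a volume
#' @param volume an [oct_volume()].
#' @return List with `dim` `(n_bscans, n_ascans)` and `spacing` `(db, da)`.
#' @export
enface_grid <- function(volume) {
  d <- dim(volume)
  list(dim = c(d[1], d[3]), spacing = c(volume$spacing[1], volume$spacing[3]))
}

#' Resample a moving volume and its surfaces onto the fixed en-face grid
#'
#' Every axial slice and every surface height grid is resampled with the same
#' 2D transform onto the fixed `(b, a)` grid: intensities and surface heights
#' bilinearly, validity by nearest neighbour. Out-of-field voxels take the
#' fill value and are masked invalid. The axial axis is untouched (heights
#' remain in the moving volume's axial pixels).
#'
#' @param volume moving [oct_volume()].
#' @param surfaces moving [surface_set()] (may be `NULL`).
#' @param transform an [affine2d()] mapping moving micrometres to fixed
#'   micrometres.
#' @param fixed_grid target geometry from [enface_grid()].
#' @param fill fill value for out-of-field voxels.
#' @return List `volume` (on the fixed grid, moving axial sampling),
#'   `surfaces`, and `valid` (per-`(b, a)` in-field mask).
#' @export
apply_enface_transform <- function(volume, surfaces, transform, fixed_grid,
                                   fill = 0) {
  assert_that(inherits(transform, "affine2d"), "transform must be an affine2d")
  d <- dim(volume)
  nb_f <- fixed_grid$dim[1]; na_f <- fixed_grid$dim[2]
  db_f <- fixed_grid$spacing[1]; da_f <- fixed_grid$spacing[2]
  Ti <- affine_invert(transform)
  # fixed grid pixel centres in micrometres -> pre-image in moving pixels
  ax <- rep(0:(na_f - 1), each = nb_f) * da_f
  by <- rep(0:(nb_f - 1), times = na_f) * db_f
  pre <- affine_apply(Ti, cbind(ax, by))
  mx <- pre[, 1] / volume$spacing[3]   # moving a (x) in pixels
  my <- pre[, 2] / volume$spacing[1]   # moving b (y) in pixels
  infield <- mx >= 0 & mx <= d[3] - 1 & my >= 0 & my <= d[1] - 1
  valid <- matrix(infield, nb_f, na_f)

  out <- array(fill, dim = c(nb_f, d[2], na_f))
  for (z in seq_len(d[2])) {
    slice <- volume$intensity[, z, ]          # (b, a) = (rows, cols)
    out[, z, ] <- matrix(bilinear_sample(slice, mx, my, fill = fill),
                         nb_f, na_f)
  }
  vol_out <- oct_volume(pmax(out, 0),
                        c(db_f, volume$spacing[2], da_f),
                        device_tag = volume$device_tag)

  surf_out <- NULL
  if (!is.null(surfaces)) {
    heights <- list(); vmasks <- list()
    for (nm in names(surfaces$heights)) {
      h <- surfaces$heights[[nm]]
      hv <- surfaces$valid[[nm]]
      h_fill <- h; h_fill[!hv] <- NA_real_
      hw <- matrix(bilinear_sample(h_fill, mx, my, fill = NA_real_), nb_f, na_f)
      vw <- matrix(nearest_sample(hv * 1, mx, my, fill = 0) > 0.5, nb_f, na_f)
      v <- vw & valid & is.finite(hw)
      hw[!v] <- NA_real_
      heights[[nm]] <- hw
      vmasks[[nm]] <- v
    }
    surf_out <- surface_set(heights, vmasks)
  }
  list(volume = vol_out, surfaces = surf_out, valid = valid)
}
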