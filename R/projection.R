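# Layer-bounded en-face projections of an OCT volume.
#
# Four modes, each averaging intensities over a per-column axial interval
# [z_top, z_bottom):
#   outer       — ILM .. RPE_outer + margin fraction of the axial extent
#   inner       — fixed offset below the image top (default 30 um) .. RPE_outer
#   hybrid      — inner's upper bound .. outer's lower bound
#   layer_based — IS_OSJ .. RPE_outer
# Interval endpoints are rounded half-up to integer rows before averaging
# (the projection averages whole pixel rows; fractional-endpoint weighting is
# deliberately not applied). The lower bound is clamped to the axial extent.

#' Projection specification
#'
#' @param mode one of `"outer"`, `"inner"`, `"hybrid"`, `"layer_based"`.
#' @param inner_top_offset_um upper bound of the inner/hybrid projection,
#'   micrometres below the top of the axial axis (default 30).
#' @param outer_margin_fraction fraction of the axial extent added below
#'   RPE_outer for the outer/hybrid projection (default 0.20).
#' @param log_compress average `log1p` intensities instead of raw ones
#'   (default `FALSE`: raw intensities are averaged).
#' @export
projection_spec <- function(mode = c("hybrid", "outer", "inner", "layer_based"),
                            inner_top_offset_um = 30,
                            outer_margin_fraction = 0.20,
                            log_compress = FALSE) {
  mode <- match.arg(mode)
  assert_that(inner_top_offset_um >= 0, "inner_top_offset_um must be >= 0")
  assert_that(outer_margin_fraction >= 0 && outer_margin_fraction <= 1,
              "outer_margin_fraction must be in [0, 1]")
  structure(list(mode = mode, inner_top_offset_um = inner_top_offset_um,
                 outer_margin_fraction = outer_margin_fraction,
                 log_compress = isTRUE(log_compress)),
            class = "projection_spec")
}

#' Layer-bounded en-face projection
#'
#' Averages volume intensities per `(b, a)` column over the axial interval
#' selected by `spec`, producing an en-face image on the `(db, da)` grid.
#' Columns whose required surfaces are
#' invalid, or whose interval is empty after clamping, are set to the fill
#' value and marked invalid in the result's mask.
#'
#' @param volume an [oct_volume()].
#' @param surfaces a [surface_set()] on the volume's `(b, a)` grid.
#' @param spec a [projection_spec()].
#' @param fill value for invalid columns (default 0).
#' @param normalize min-max normalize valid pixels to `[0, 1]` (the form the
#'   keypoint network consumes). Default `FALSE`: raw interval means.
#' @return An [enface_image()] with modality `"oct_projection"` and a validity
#'   mask.
#' @export
project_enface <- function(volume, surfaces, spec = projection_spec(),
                           fill = 0, normalize = FALSE) {
  d <- dim(volume)
  assert_that(identical(surfaces$grid_dim, d[c(1, 3)]),
              "surfaces grid does not match the volume's (b, a) grid")
  nz <- d[2]
  need <- switch(spec$mode,
    outer = c("ILM", "RPE_outer"),
    inner = "RPE_outer",
    hybrid = "RPE_outer",
    layer_based = c("IS_OSJ", "RPE_outer"))
  missing <- setdiff(need, names(surfaces$heights))
  assert_that(length(missing) == 0, "projection mode %s requires surface(s): %s",
              spec$mode, paste(missing, collapse = ", "))

  dz <- volume$spacing[2]
  top_offset_px <- round_half_up(spec$inner_top_offset_um / dz)
  margin_px <- spec$outer_margin_fraction * nz

  get_h <- function(nm) surfaces$heights[[nm]]
  get_v <- function(nm) surfaces$valid[[nm]]
  z_top <- switch(spec$mode,
    outer = get_h("ILM"),
    inner = matrix(top_offset_px, d[1], d[3]),
    hybrid = matrix(top_offset_px, d[1], d[3]),
    layer_based = get_h("IS_OSJ"))
  z_bottom <- switch(spec$mode,
    outer = get_h("RPE_outer") + margin_px,
    inner = get_h("RPE_outer"),
    hybrid = get_h("RPE_outer") + margin_px,
    layer_based = get_h("RPE_outer"))
  valid <- switch(spec$mode,
    outer = get_v("ILM") & get_v("RPE_outer"),
    inner = get_v("RPE_outer"),
    hybrid = get_v("RPE_outer"),
    layer_based = get_v("IS_OSJ") & get_v("RPE_outer"))

  zt <- round_half_up(z_top)
  zb <- pmin(round_half_up(z_bottom), nz)
  zt <- pmax(zt, 0)
  valid <- valid & is.finite(zt) & is.finite(zb) & (zt < zb)

  # cumulative sums along z make every column average O(1)
  intens <- volume$intensity
  if (spec$log_compress) intens <- log1p(intens)
  # cum[b, z + 1, a] = sum of rows 0..z-1 (0-based); cum[, 1, ] = 0
  cum <- array(0, dim = c(d[1], nz + 1, d[3]))
  cum[, 2:(nz + 1), ] <- aperm(apply(intens, c(1, 3), cumsum), c(2, 1, 3))

  out <- matrix(fill, d[1], d[3])
  idx <- which(valid)
  if (length(idx)) {
    bi <- ((idx - 1) %% d[1]) + 1
    ai <- ((idx - 1) %/% d[1]) + 1
    lo <- zt[idx]; hi <- zb[idx]
    s <- cum[cbind(bi, hi + 1, ai)] - cum[cbind(bi, lo + 1, ai)]
    out[idx] <- s / (hi - lo)
  }
  img <- out
  if (normalize && any(valid)) {
    r <- range(img[valid])
    img[valid] <- if (r[2] - r[1] > 0) (img[valid] - r[1]) / (r[2] - r[1]) else 0
    img[!valid] <- fill
  }
  enface_image(img, c(volume$spacing[1], volume$spacing[3]),
               modality = "oct_projection", valid = valid)
}
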