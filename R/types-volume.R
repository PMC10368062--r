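#' OCT volume
#'
#' A 3D OCT intensity grid with anisotropic physical spacing. The array is
#' indexed `[b, z, a]`: `b` is the B-scan (slow scan) axis, `z` the axial
#' (depth) axis and `a` the A-scan (fast) axis. En-face pixel `(y, x)`
#' corresponds to `(b, a)`.
#'
#' @param intensity 3D numeric array of non-negative, finite intensities,
#'   dimension `(n_bscans, n_axial, n_ascans)`.
#' @param spacing named numeric vector `c(db, dz, da)` in micrometres:
#'   distance between B-scans, axial sample pitch, and distance between
#'   A-scans. All must be positive.
#' @param device_tag free-text device label.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, spacing, device_tag = "") {
  assert_that(is.array(intensity) && length(dim(intensity)) == 3,
              "intensity must be a 3D array (b, z, a)")
  assert_that(all(is.finite(intensity)), "intensities must be finite")
  assert_that(min(intensity) >= 0, "intensities must be non-negative")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3 && all(is.finite(spacing)) && all(spacing > 0),
              "spacing must be 3 positive values (db, dz, da) in micrometres")
  structure(list(
    intensity = intensity,
    spacing = c(db = spacing[1], dz = spacing[2], da = spacing[3]),
    device_tag = device_tag
  ), class = "oct_volume")
}

#' @export
dim.oct_volume <- function(x) dim(x$intensity)

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<oct_volume> %d B-scans x %d axial x %d A-scans | spacing %.2f/%.2f/%.2f um | %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (nzchar(x$device_tag)) x$device_tag else "untagged"))
  invisible(x)
}

SURFACE_NAMES <- c("ILM", "IS_OSJ", "RPE_outer")

#' Retinal surface set
#'
#' Named retinal surfaces stored as real-valued (sub-pixel) axial heights per
#' `(b, a)` grid cell, with a per-cell validity mask. Heights are in axial
#' pixels (0-based coordinates, `[0, n_axial)`); conversion to micrometres is
#' explicit via the volume's `dz`. Surface names come from
#' `{ILM, IS_OSJ, RPE_outer}` and must respect the anatomical ordering
#' ILM <= IS_OSJ <= RPE_outer wherever jointly valid.
#'
#' @param heights named list of numeric matrices `(n_bscans x n_ascans)`.
#' @param valid named list of logical matrices, same shapes; defaults to
#'   finite cells of `heights`.
#' @param n_axial optional axial extent used to check `0 <= z < n_axial`.
#' @return An object of class `surface_set`.
#' @export
surface_set <- function(heights, valid = NULL, n_axial = NULL) {
  assert_that(is.list(heights) && length(heights) > 0 && !is.null(names(heights)),
              "heights must be a named list of matrices")
  bad <- setdiff(names(heights), SURFACE_NAMES)
  assert_that(length(bad) == 0, "unknown surface name(s): %s", paste(bad, collapse = ", "))
  d <- dim(heights[[1]])
  for (nm in names(heights)) {
    assert_that(is.matrix(heights[[nm]]) && identical(dim(heights[[nm]]), d),
                "all surface grids must be matrices of identical shape")
  }
  if (is.null(valid)) {
    valid <- lapply(heights, function(h) is.finite(h))
  }
  assert_that(identical(names(valid), names(heights)) ||
                setequal(names(valid), names(heights)),
              "valid masks must match surface names")
  valid <- valid[names(heights)]
  for (nm in names(heights)) {
    v <- valid[[nm]]
    assert_that(is.matrix(v) && identical(dim(v), d) && is.logical(v),
                "valid masks must be logical matrices of the grid shape")
    assert_that(all(is.finite(heights[[nm]][v])),
                "surface %s has non-finite heights marked valid", nm)
    if (!is.null(n_axial)) {
      h <- heights[[nm]][v]
      assert_that(all(h >= 0 & h < n_axial),
                  "surface %s has heights outside [0, n_axial)", nm)
    }
  }
  ss <- structure(list(heights = heights, valid = valid, grid_dim = d),
                  class = "surface_set")
  check_surface_ordering(ss)
  ss
}

# ILM <= IS_OSJ <= RPE_outer wherever jointly valid.
check_surface_ordering <- function(ss, tol = 1e-9) {
  pairs <- list(c("ILM", "IS_OSJ"), c("IS_OSJ", "RPE_outer"), c("ILM", "RPE_outer"))
  for (p in pairs) {
    if (all(p %in% names(ss$heights))) {
      both <- ss$valid[[p[1]]] & ss$valid[[p[2]]]
      if (any(both)) {
        assert_that(all(ss$heights[[p[1]]][both] <= ss$heights[[p[2]]][both] + tol),
                    "surface ordering violated: %s above %s somewhere", p[2], p[1])
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> %s on %d x %d grid\n",
              paste(names(x$heights), collapse = ", "),
              x$grid_dim[1], x$grid_dim[2]))
  invisible(x)
}

#' En-face 2D image
#'
#' A frontal-view image: either a scanning laser ophthalmoscopy (SLO) capture
#' or an axial projection of an OCT volume. Indexed `(y, x)` with physical
#' pixel spacing in micrometres.
#'
#' @param image numeric matrix.
#' @param spacing numeric `c(dy, dx)` in micrometres, both positive.
#' @param modality `"slo"` or `"oct_projection"`.
#' @param valid optional logical matrix marking pixels with defined content.
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(image, spacing, modality = c("oct_projection", "slo"),
                         valid = NULL) {
  modality <- match.arg(modality)
  assert_that(is.matrix(image) && all(is.finite(image)),
              "image must be a finite numeric matrix")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 2 && all(spacing > 0),
              "spacing must be 2 positive values (dy, dx) in micrometres")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(image), ncol(image))
  assert_that(identical(dim(valid), dim(image)), "valid mask shape mismatch")
  structure(list(image = image, spacing = c(dy = spacing[1], dx = spacing[2]),
                 modality = modality, valid = valid),
            class = "enface_image")
}

#' @export
dim.enface_image <- function(x) dim(x$image)

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px | %.2f x %.2f um/px | %s\n",
              nrow(x$image), ncol(x$image), x$spacing[1], x$spacing[2], x$modality))
  invisible(x)
}

# Min-max normalization to [0, 1]; constant images map to 0.
normalize01 <- function(m) {
  r <- range(m)
  if (r[2] - r[1] <= 0) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

#' Resample an en-face image to an isotropic pixel pitch
#'
#' Bilinear resampling onto square pixels of pitch `pitch_um`, preserving the
#' physical footprint. Keypoints are detected on images brought to a common
#' pitch so that descriptor patches cover comparable retinal areas in both
#' images of a pair.
#'
#' @param img an [enface_image()].
#' @param pitch_um target pixel pitch in micrometres.
#' @export
resample_enface <- function(img, pitch_um) {
  ext_y <- (nrow(img$image) - 1) * img$spacing[1]
  ext_x <- (ncol(img$image) - 1) * img$spacing[2]
  nr <- max(2, round(ext_y / pitch_um) + 1)
  nc <- max(2, round(ext_x / pitch_um) + 1)
  # endpoint-aligned resize keeps the footprint; the pitch is re-derived
  out <- resize_bilinear(img$image, nr, nc)
  vout <- resize_bilinear(img$valid * 1, nr, nc) > 0.5
  enface_image(out, c(ext_y / (nr - 1), ext_x / (nc - 1)), img$modality, vout)
}

#' Fill missing surface cells by linear interpolation along the A-scan axis
#'
#' Optional utility, never applied implicitly: missing cells normally
#' propagate as invalid, since silently in-filled segmentation errors would
#' corrupt the axial registration downstream. When used, each B-scan row is
#' interpolated linearly across its invalid cells (no extrapolation beyond
#' the first/last valid cell).
#'
#' @param ss a [surface_set()].
#' @return A [surface_set()] with interpolated cells marked valid; attribute
#'   `filled` lists the per-surface count of filled cells.
#' @export
fill_surface_gaps <- function(ss) {
  heights <- ss$heights; valid <- ss$valid
  filled <- integer(0)
  for (nm in names(heights)) {
    n_filled <- 0L
    for (b in seq_len(nrow(heights[[nm]]))) {
      v <- valid[[nm]][b, ]
      if (sum(v) >= 2 && any(!v)) {
        x <- which(v)
        gaps <- which(!v)
        gaps <- gaps[gaps > min(x) & gaps < max(x)]
        if (length(gaps)) {
          heights[[nm]][b, gaps] <- stats::approx(x, heights[[nm]][b, x],
                                                  xout = gaps)$y
          valid[[nm]][b, gaps] <- TRUE
          n_filled <- n_filled + length(gaps)
        }
      }
    }
    filled[nm] <- n_filled
  }
  out <- surface_set(heights, valid)
  attr(out, "filled") <- filled
  out
}
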