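# Readers/writers for volumes, surfaces, en-face images and transforms.
#
# Volumes: multi-page TIFF (one page per B-scan, page = z x a matrix) or
# NIfTI-1. Spacing is never assumed: it must come from a sidecar YAML
# `{db_um, dz_um, da_um}` next to the file (`<file>.spacing.yaml`) or be
# passed explicitly. Surfaces: long-form CSV `surface,b,a,z` (0-based b/a,
# axial-pixel z). Transforms: JSON.

sidecar_path <- function(path) paste0(path, ".spacing.yaml")

read_spacing_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  y <- yaml::read_yaml(sp)
  if (!all(c("db_um", "dz_um", "da_um") %in% names(y))) return(NULL)
  c(y$db_um, y$dz_um, y$da_um)
}

write_spacing_sidecar <- function(path, spacing) {
  yaml::write_yaml(list(db_um = as.numeric(spacing[1]),
                        dz_um = as.numeric(spacing[2]),
                        da_um = as.numeric(spacing[3])),
                   sidecar_path(path))
}

#' Read an OCT volume
#'
#' @param path file path to a multi-page TIFF (`.tif`/`.tiff`; one page per
#'   B-scan, rows = axial samples, columns = A-scans) or a NIfTI-1 file.
#' @param format `"tiff_stack"` or `"nifti"`; guessed from the extension by
#'   default.
#' @param spacing optional `c(db, dz, da)` in micrometres; if missing, the
#'   sidecar `<path>.spacing.yaml` is required. Missing spacing is an error —
#'   it is never silently assumed.
#' @param axis_map for NIfTI: character permutation describing which volume
#'   axis each NIfTI array axis holds, e.g. `c("z", "a", "b")`. Default
#'   assumes the array is already `(b, z, a)`.
#' @param device_tag device label attached to the volume.
#' @return An [oct_volume()].
#' @export
read_oct_volume <- function(path, format = c("auto", "tiff_stack", "nifti"),
                            spacing = NULL, axis_map = c("b", "z", "a"),
                            device_tag = "") {
  format <- match.arg(format)
  assert_that(file.exists(path), "no such file: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tiff_stack"
  }
  if (is.null(spacing)) spacing <- read_spacing_sidecar(path)
  assert_that(!is.null(spacing),
              "spacing for %s not supplied and no sidecar %s found; refusing to assume 1 um",
              path, sidecar_path(path))
  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nb <- length(pages)
    d <- dim(pages[[1]])
    arr <- array(0, dim = c(nb, d[1], d[2]))
    for (i in seq_len(nb)) arr[i, , ] <- pages[[i]]
    arr <- arr / 65535  # stored as 16-bit integers
  } else {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    assert_that(length(dim(arr)) == 3, "NIfTI volume must be 3D")
    assert_that(setequal(axis_map, c("b", "z", "a")),
                "axis_map must be a permutation of b, z, a")
    perm <- match(c("b", "z", "a"), axis_map)
    arr <- aperm(arr, perm)
  }
  oct_volume(arr, spacing, device_tag = device_tag)
}

#' Write an OCT volume
#'
#' Writes a multi-page 16-bit TIFF (intensities clipped to `[0, 1]`) or a
#' NIfTI-1 file, plus the spacing sidecar YAML.
#'
#' @param vol an [oct_volume()].
#' @param path output path.
#' @param format `"tiff_stack"` or `"nifti"` (guessed from extension).
#' @export
write_oct_volume <- function(vol, path, format = c("auto", "tiff_stack", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "tiff_stack"
  }
  d <- dim(vol)
  if (format == "tiff_stack") {
    pages <- lapply(seq_len(d[1]), function(b) clamp(vol$intensity[b, , ], 0, 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    RNifti::writeNifti(RNifti::asNifti(vol$intensity), path)
  }
  write_spacing_sidecar(path, vol$spacing)
  invisible(path)
}

#' Read a surface set from long-form CSV
#'
#' Expects a header `surface,b,a,z` with 0-based integer `b`, `a` and
#' real-valued axial-pixel `z`. Cells absent from the table are marked
#' invalid.
#'
#' @param path CSV path.
#' @param grid_dim optional `c(n_bscans, n_ascans)`; inferred from the data
#'   maxima when omitted.
#' @param n_axial optional axial extent; rows with `z` outside `[0, n_axial)`
#'   raise an error.
#' @return A [surface_set()].
#' @export
read_surfaces <- function(path, grid_dim = NULL, n_axial = NULL) {
  assert_that(file.exists(path), "no such file: %s", path)
  df <- utils::read.csv(path)
  assert_that(all(c("surface", "b", "a", "z") %in% names(df)),
              "surfaces CSV must have columns surface,b,a,z")
  if (is.null(grid_dim)) grid_dim <- c(max(df$b) + 1L, max(df$a) + 1L)
  if (!is.null(n_axial)) {
    assert_that(all(df$z >= 0 & df$z < n_axial),
                "surface heights outside [0, n_axial)")
  }
  heights <- list(); valid <- list()
  for (nm in intersect(SURFACE_NAMES, unique(df$surface))) {
    h <- matrix(NA_real_, grid_dim[1], grid_dim[2])
    sub <- df[df$surface == nm, ]
    assert_that(all(sub$b >= 0 & sub$b < grid_dim[1] & sub$a >= 0 & sub$a < grid_dim[2]),
                "surface %s has (b, a) outside the grid", nm)
    h[cbind(sub$b + 1L, sub$a + 1L)] <- sub$z
    heights[[nm]] <- h
    valid[[nm]] <- is.finite(h)
  }
  surface_set(heights, valid, n_axial = n_axial)
}

#' Write a surface set to long-form CSV
#' @param ss a [surface_set()].
#' @param path CSV path.
#' @export
write_surfaces <- function(ss, path) {
  rows <- list()
  for (nm in names(ss$heights)) {
    v <- which(ss$valid[[nm]], arr.ind = TRUE)
    if (nrow(v) == 0) next
    rows[[nm]] <- data.frame(surface = nm, b = v[, 1] - 1L, a = v[, 2] - 1L,
                             z = ss$heights[[nm]][v])
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a transform to JSON
#'
#' Serializes an [affine2d()], [zshift_field()] or [bscan_transforms()] with
#' full double precision; [read_transform()] restores it exactly (round-trip
#' error below 1e-12). Invalid `zshift_field` cells are stored as `null` and
#' restored as invalid.
#'
#' @param t the transform object.
#' @param path output JSON path.
#' @export
write_transform <- function(t, path) {
  obj <- if (inherits(t, "affine2d")) {
    list(type = "affine2d", matrix = t$matrix)
  } else if (inherits(t, "zshift_field")) {
    d <- t$delta; d[!t$valid] <- NA_real_
    list(type = "zshift_field", dim = dim(d), delta = as.vector(d))
  } else if (inherits(t, "bscan_transforms")) {
    list(type = "bscan_transforms", model_kind = t$model_kind,
         n_bscans = length(t$transforms),
         transforms = lapply(t$transforms, function(m) if (is.null(m)) NULL else m))
  } else stop_oct("unsupported transform class")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a transform from JSON
#' @param path JSON path written by [write_transform()].
#' @param n_bscans optional expected B-scan count for `bscan_transforms`; a
#'   mismatch is an error.
#' @export
read_transform <- function(path, n_bscans = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    affine2d = affine2d(matrix(obj$matrix, 2, 3)),
    zshift_field = {
      d <- matrix(unlist(ifelse(vapply(obj$delta, is.null, logical(1)),
                                NA_real_, obj$delta)),
                  obj$dim[1], obj$dim[2])
      zshift_field(d)
    },
    bscan_transforms = {
      trs <- lapply(obj$transforms, function(m) {
        if (is.null(m) || length(m) == 0) NULL else matrix(unlist(m), 2, 3)
      })
      if (!is.null(n_bscans)) {
        assert_that(length(trs) == n_bscans,
                    "transform list has %d B-scans, expected %d",
                    length(trs), n_bscans)
      }
      bscan_transforms(trs, obj$model_kind)
    },
    stop_oct("unknown transform type in %s", path)
  )
}

#' Write an en-face image plus spacing sidecar
#'
#' `.tif`/`.tiff` paths are written as 16-bit TIFF (the lossless route);
#' `.png` writes an 8-bit preview. Intensities are clipped to `[0, 1]`.
#'
#' @param img an [enface_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_enface <- function(img, path) {
  m <- clamp(img$image, 0, 1)
  if (grepl("\\.png$", path)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  }
  yaml::write_yaml(list(dy_um = as.numeric(img$spacing[1]),
                        dx_um = as.numeric(img$spacing[2]),
                        modality = img$modality),
                   paste0(path, ".spacing.yaml"))
  invisible(path)
}

#' Read an en-face image written by [write_enface()]
#' @param path image path; the sidecar `<path>.spacing.yaml` must exist.
#' @export
read_enface <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  y <- yaml::read_yaml(paste0(path, ".spacing.yaml"))
  m <- if (grepl("\\.png$", path)) png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  enface_image(m, c(y$dy_um, y$dx_um), modality = y$modality)
}

#' Read a landmark set from CSV (`label,x,y` in native 0-based pixels)
#' @param path CSV path.
#' @param spacing `c(dy, dx)` micrometre pixel spacing of the image the
#'   landmarks live in.
#' @export
read_landmarks <- function(path, spacing) {
  df <- utils::read.csv(path)
  assert_that(all(c("label", "x", "y") %in% names(df)),
              "landmarks CSV must have columns label,x,y")
  landmark_set(df$label, cbind(df$x, df$y), spacing)
}
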