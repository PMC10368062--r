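# Interpolation and resampling primitives.
#
# Coordinate convention (used by every module): continuous image coordinates
# are 0-based, with (0, 0) at the centre of the first pixel, so a coordinate
# u maps to R array index u + 1. En-face pixel (y, x) = (b, a): y runs along
# the slow scan axis (B-scan index), x along the fast axis (A-scan index).
# Physical position in micrometres is coordinate * spacing.

# Bilinear sampling of matrix `img` at 0-based coordinates (x, y), where x
# indexes columns and y rows. Out-of-bounds samples return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp the 4 corners; validity decided on the un-clamped footprint
  inside <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  cx0 <- clamp(x0, 0, nc - 1); cx1 <- clamp(x0 + 1, 0, nc - 1)
  cy0 <- clamp(y0, 0, nr - 1); cy1 <- clamp(y0 + 1, 0, nr - 1)
  idx <- function(r, c) r + 1 + c * nr  # linear index for 0-based (row, col)
  v00 <- img[idx(cy0, cx0)]
  v01 <- img[idx(cy0, cx1)]
  v10 <- img[idx(cy1, cx0)]
  v11 <- img[idx(cy1, cx1)]
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  out[!inside] <- fill
  out
}

# As bilinear_sample but also returns the validity mask.
bilinear_sample_masked <- function(img, x, y, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  inside <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  val <- bilinear_sample(img, x, y, fill = fill)
  list(value = val, valid = inside)
}

# Nearest-neighbour sampling (used for validity masks).
nearest_sample <- function(img, x, y, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  xr <- round_half_up(x); yr <- round_half_up(y)
  inside <- xr >= 0 & xr <= nc - 1 & yr >= 0 & yr <= nr - 1
  xr <- clamp(xr, 0, nc - 1); yr <- clamp(yr, 0, nr - 1)
  out <- img[yr + 1 + xr * nr]
  out[!inside] <- fill
  out
}

# Bilinear resize of a matrix to (new_nr, new_nc). Pixel centres are mapped so
# the image footprint is preserved: output coordinate i maps to input
# coordinate i * (n_in - 1) / (n_out - 1) (endpoints align).
resize_bilinear <- function(img, new_nr, new_nc) {
  nr <- nrow(img); nc <- ncol(img)
  if (new_nr == nr && new_nc == nc) return(img)
  ys <- if (new_nr == 1) 0 else (0:(new_nr - 1)) * (nr - 1) / (new_nr - 1)
  xs <- if (new_nc == 1) 0 else (0:(new_nc - 1)) * (nc - 1) / (new_nc - 1)
  gx <- rep(xs, each = new_nr)
  gy <- rep(ys, times = new_nc)
  matrix(bilinear_sample(img, gx, gy), new_nr, new_nc)
}

# Linear interpolation along the axial (z) axis of a single A-scan column.
# `col` holds samples at 0-based coordinates 0..n-1; `z` are query
# coordinates. Out-of-range queries -> fill.
linear_sample_1d <- function(col, z, fill = 0) {
  n <- length(col)
  z0 <- floor(z)
  fz <- z - z0
  inside <- z >= 0 & z <= n - 1
  c0 <- clamp(z0, 0, n - 1); c1 <- clamp(z0 + 1, 0, n - 1)
  out <- (1 - fz) * col[c0 + 1] + fz * col[c1 + 1]
  out[!inside] <- fill
  out
}

# Separable 2D Gaussian blur with reflected borders (small sigma use only).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  pad_reflect <- function(v, r) c(v[pmin(r:1 + 1, length(v))], v, v[pmax(length(v) - (1:r), 1)])
  conv_rows <- function(m) {
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    mp <- rbind(m[pmin(r:1 + 1, nr), , drop = FALSE], m,
                m[pmax(nr - (1:r), 1), , drop = FALSE])
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nr - 1), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(img))))
}
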