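# Synthetic layered-retina phantom: paired OCT volumes + surfaces + SLO with
# known ground-truth en-face affine and per-A-scan axial displacement.
#
# The phantom emulates the paired-device setting the pipeline targets: a
# "fixed" commercial-style volume (fewer B-scans, square FoV, accompanied by
# a higher-resolution SLO) and a "moving" research-style volume (denser
# B-scans, wider slow-axis FoV). Both image the same anatomy: smooth ILM/RPE
# surfaces, a branching vessel tree casting en-face shadows, multiplicative
# speckle, and a modality-dependent contrast remap between renderings.

#' Phantom configuration
#'
#' Defaults mirror the two-device asymmetry of the target setting at reduced
#' grid size: the fixed volume has 48 B-scans over a 6 x 6 mm field of view,
#' the moving volume 124 B-scans over 8 x 6 mm, both with 96 A-scans and a
#' 3.5 um axial pitch (160 samples, 560 um depth).
#'
#' @param fixed_shape,moving_shape integer `(n_bscans, n_axial, n_ascans)`.
#' @param fixed_spacing,moving_spacing `(db, dz, da)` in micrometres.
#' @param vessel_count number of primary vessels in the en-face tree.
#' @param vessel_width_range_um vessel diameter range, micrometres.
#' @param surface_wavelength_um smallest undulation wavelength of the
#'   generated retinal surfaces (controls smoothness).
#' @param speckle_contrast multiplicative speckle contrast in `[0, 1)`; 0
#'   disables speckle (noise-free rendering).
#' @param gt_rotation_deg,gt_scale,gt_shear,gt_translation_um parameters of
#'   the ground-truth en-face affine (moving -> fixed, micrometres).
#'   Rotation is limited to 30 degrees and scale to `[0.8, 1.2]` so the pair
#'   keeps overlapping.
#' @param gt_axial `"smooth_field"` or `"constant"` ground-truth axial
#'   displacement model.
#' @param gt_axial_px amplitude (smooth field) or value (constant), axial px.
#' @param slo_spacing_um SLO pixel pitch (square pixels).
#' @param seed integer seed; the same config + seed is bit-reproducible.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(fixed_shape = c(48, 160, 96),
                           moving_shape = c(124, 160, 96),
                           fixed_spacing = c(6000 / 48, 3.5, 6000 / 96),
                           moving_spacing = c(8000 / 124, 3.5, 6000 / 96),
                           vessel_count = 7,
                           vessel_width_range_um = c(40, 120),
                           surface_wavelength_um = 1500,
                           speckle_contrast = 0.25,
                           gt_rotation_deg = 2,
                           gt_scale = 1.0,
                           gt_shear = 0,
                           gt_translation_um = c(120, -80),
                           gt_axial = c("smooth_field", "constant"),
                           gt_axial_px = 6,
                           slo_spacing_um = 31.25,
                           seed = 1L) {
  gt_axial <- match.arg(gt_axial)
  assert_that(all(fixed_shape >= c(4, 32, 32)) && all(moving_shape >= c(4, 32, 32)),
              "phantom shapes must be at least (4, 32, 32)")
  assert_that(abs(gt_rotation_deg) <= 30, "|rotation| must be <= 30 degrees")
  assert_that(gt_scale >= 0.8 && gt_scale <= 1.2, "scale must be in [0.8, 1.2]")
  assert_that(speckle_contrast >= 0 && speckle_contrast < 1,
              "speckle_contrast must be in [0, 1)")
  structure(list(
    fixed_shape = as.integer(fixed_shape),
    moving_shape = as.integer(moving_shape),
    fixed_spacing = as.numeric(fixed_spacing),
    moving_spacing = as.numeric(moving_spacing),
    vessel_count = as.integer(vessel_count),
    vessel_width_range_um = as.numeric(vessel_width_range_um),
    surface_wavelength_um = as.numeric(surface_wavelength_um),
    speckle_contrast = as.numeric(speckle_contrast),
    gt_rotation_deg = as.numeric(gt_rotation_deg),
    gt_scale = as.numeric(gt_scale),
    gt_shear = as.numeric(gt_shear),
    gt_translation_um = as.numeric(gt_translation_um),
    gt_axial = gt_axial,
    gt_axial_px = as.numeric(gt_axial_px),
    slo_spacing_um = as.numeric(slo_spacing_um),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Smooth seeded random field: sum of low-frequency cosines over metric (x, y).
# Returns a vectorized function of micrometre coordinates.
smooth_field_fn <- function(seed, amplitude, min_wavelength_um, n_terms = 6,
                            offset = 0) {
  with_seed(seed, {
    wl <- stats::runif(n_terms, min_wavelength_um, 4 * min_wavelength_um)
    th <- stats::runif(n_terms, 0, 2 * pi)
    ph <- stats::runif(n_terms, 0, 2 * pi)
    amp <- stats::runif(n_terms, 0.3, 1)
  })
  amp <- amp / sum(amp) * amplitude
  function(x, y) {
    out <- rep(offset, length(x))
    for (k in seq_along(wl)) {
      f <- 2 * pi / wl[k]
      out <- out + amp[k] * cos(f * (cos(th[k]) * x + sin(th[k]) * y) + ph[k])
    }
    out
  }
}

# Rasterize a seeded branching vessel tree onto a canvas of `dim_px`
# (rows = y, cols = x) with pixel pitch `spacing_um` and metric origin
# `origin_um = c(x0, y0)`. Returns list(image, mask).
render_vessel_canvas <- function(dim_px, spacing_um, origin_um, config, seed) {
  h <- dim_px[1]; w <- dim_px[2]
  M <- matrix(0, h, w)
  wr_px <- config$vessel_width_range_um / spacing_um
  trace_one <- function(x, y, dir, width, depth, max_len) {
    pts <- list()
    step <- 2
    n_steps <- ceiling(max_len / step)
    for (i in seq_len(n_steps)) {
      dir <- dir + stats::rnorm(1, 0, 0.09)
      x <- x + step * cos(dir); y <- y + step * sin(dir)
      if (x < -5 || x > w + 4 || y < -5 || y > h + 4) break
      width <- width * 0.9995
      pts[[length(pts) + 1]] <- c(x, y, width)
      if (depth < 2 && stats::runif(1) < 0.012) {
        side <- sample(c(-1, 1), 1)
        pts <- c(pts, trace_one(x, y, dir + side * stats::runif(1, 0.35, 0.9),
                                width * 0.7, depth + 1, max_len * 0.6))
      }
    }
    pts
  }
  pts <- with_seed(seed, {
    all_pts <- list()
    for (v in seq_len(config$vessel_count)) {
      edge <- sample(4, 1)
      t0 <- stats::runif(1)
      start <- switch(edge,
        c(t0 * w, 1), c(t0 * w, h - 1), c(1, t0 * h), c(w - 1, t0 * h))
      centre_dir <- atan2(h / 2 - start[2], w / 2 - start[1])
      dir <- centre_dir + stats::rnorm(1, 0, 0.35)
      width <- stats::runif(1, wr_px[1], wr_px[2])
      all_pts <- c(all_pts, trace_one(start[1], start[2], dir, width, 0,
                                      1.6 * max(h, w)))
    }
    all_pts
  })
  for (p in pts) {
    r <- max(1L, ceiling(p[3]))  # stamp radius ~ diameter: soft profile
    xs <- floor(p[1] - r):ceiling(p[1] + r)
    ys <- floor(p[2] - r):ceiling(p[2] + r)
    xs <- xs[xs >= 0 & xs < w]; ys <- ys[ys >= 0 & ys < h]
    if (!length(xs) || !length(ys)) next
    dx <- outer(ys - p[2], xs - p[1], function(yy, xx) xx^2 + yy^2)
    prof <- exp(-dx / (2 * (p[3] / 2)^2))
    sub <- M[ys + 1, xs + 1, drop = FALSE]
    M[ys + 1, xs + 1] <- pmax(sub, prof)
  }
  # textured background: low-frequency shading + fine grain
  bgf <- smooth_field_fn(derive_seed(seed, "bg"), 0.10, 1200, offset = 0.55)
  gx <- rep((0:(w - 1)) * spacing_um + origin_um[1], each = h)
  gy <- rep((0:(h - 1)) * spacing_um + origin_um[2], times = w)
  bg <- matrix(bgf(gx, gy), h, w)
  grain <- with_seed(derive_seed(seed, "grain"),
                     matrix(stats::rnorm(h * w, 0, 0.02), h, w))
  img <- clamp(bg * (1 - 0.65 * M) + grain, 0, 1)
  list(image = img, mask = M > 0.3)
}

#' Generate a seeded en-face vessel map
#'
#' Produces a synthetic en-face image: dark branching curvilinear vessels
#' with Gaussian cross-profile over a textured background. The binary vessel
#' mask is attached as attribute `"vessel_mask"`.
#'
#' @param width,height canvas size in pixels (at least 32).
#' @param config a [phantom_config()] (vessel count and widths are used).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param spacing_um pixel pitch of the canvas.
#' @return An [enface_image()] with values in `[0, 1]`.
#' @export
generate_vessel_map <- function(width, height, config = phantom_config(),
                                seed = config$seed, spacing_um = 25) {
  assert_that(width >= 32 && height >= 32, "canvas must be at least 32 x 32")
  cv <- render_vessel_canvas(c(height, width), spacing_um, c(0, 0), config, seed)
  out <- enface_image(cv$image, c(spacing_um, spacing_um),
                      modality = "oct_projection")
  attr(out, "vessel_mask") <- cv$mask
  out
}

# Smooth axial intensity profile of one rendered column. All arguments in
# axial pixels; `v` is the vessel-shadow strength in [0, 1].
axial_profile <- function(z, ilm, isosj, rpe, v) {
  sig <- function(t) stats::plogis(t / 1.2)
  inner_end <- ilm + 8
  i <- 0.06 +
    (0.55 - 0.06) * sig(z - ilm) +
    (0.30 - 0.55) * sig(z - inner_end) +
    (0.68 - 0.30) * sig(z - isosj) +
    (0.12 - 0.68) * sig(z - rpe)
  i * (1 - 0.55 * v * sig(z - (ilm + 2)))
}

# Render a volume on a (b, a) grid given surface grids in axial px and a
# vessel-shadow grid; adds multiplicative gamma speckle unless contrast == 0.
render_volume_grid <- function(shape, ilm_px, isosj_px, rpe_px, vshadow,
                               contrast, gamma_remap, seed) {
  nb <- shape[1]; nz <- shape[2]; na_ <- shape[3]
  arr <- array(0, dim = c(nb, nz, na_))
  for (z in seq_len(nz)) {
    slice <- axial_profile(z - 1, ilm_px, isosj_px, rpe_px, vshadow)
    arr[, z, ] <- slice
  }
  if (gamma_remap != 1) arr <- arr^gamma_remap
  if (contrast > 0) {
    L <- 1 / contrast^2
    noise <- with_seed(seed, stats::rgamma(length(arr), shape = L, rate = L))
    arr <- arr * array(noise, dim = dim(arr))
  }
  arr
}

#' Generate a paired synthetic OCT phantom
#'
#' Builds a fixed volume + surfaces + SLO and a moving volume + surfaces
#' imaging the same anatomy, related by a known en-face affine `gt_T2D`
#' (moving -> fixed, micrometres) and a known per-A-scan axial displacement
#' `gt_delta` (on the fixed grid, axial pixels, with
#' `moving ILM warped onto the fixed grid = fixed ILM - gt_delta`).
#' Also returns four labelled landmarks and a set of dense oracle
#' correspondences (metric coordinates in each frame) for network-free
#' geometry testing.
#'
#' @param config a [phantom_config()].
#' @return A `phantom_pair` list with elements `fixed` (volume, surfaces,
#'   slo), `moving` (volume, surfaces), `gt_T2D`, `gt_delta`, `landmarks`,
#'   `oracle`.
#' @export
generate_phantom_pair <- function(config = phantom_config()) {
  seed <- config$seed
  T2D <- affine2d_from_params(config$gt_rotation_deg, config$gt_scale,
                              config$gt_shear, config$gt_translation_um)
  fs <- config$fixed_shape; ms <- config$moving_shape
  fsp <- config$fixed_spacing; msp <- config$moving_spacing

  # fixed field of view (micrometres), pixel centres
  fov_fixed <- c((fs[3] - 1) * fsp[3], (fs[1] - 1) * fsp[1])  # (x, y)
  fov_moving <- c((ms[3] - 1) * msp[3], (ms[1] - 1) * msp[1])

  # overlap check: fraction of fixed pixel centres whose pre-image lies
  # inside the moving field of view
  Ti <- affine_invert(T2D)
  gx <- seq(0, fov_fixed[1], length.out = 24)
  gy <- seq(0, fov_fixed[2], length.out = 24)
  gpts <- cbind(rep(gx, each = 24), rep(gy, times = 24))
  pre <- affine_apply(Ti, gpts)
  frac <- mean(pre[, 1] >= 0 & pre[, 1] <= fov_moving[1] &
               pre[, 2] >= 0 & pre[, 2] <= fov_moving[2])
  assert_that(frac >= 0.25,
              "ground-truth affine leaves under 25%% of the fixed FoV covered")

  # anatomy (fixed metric frame): smooth surfaces in micrometres
  ilm_fn <- smooth_field_fn(derive_seed(seed, "ilm"), 40,
                            config$surface_wavelength_um, offset = 150)
  thick_fn <- smooth_field_fn(derive_seed(seed, "thick"), 25,
                              config$surface_wavelength_um, offset = 310)
  delta_fn <- if (config$gt_axial == "constant") {
    function(x, y) rep(config$gt_axial_px, length(x))
  } else {
    smooth_field_fn(derive_seed(seed, "delta"), config$gt_axial_px,
                    1.3 * config$surface_wavelength_um, offset = 0)
  }

  # vessel canvas covering fixed FoV plus the warped moving footprint
  mv_corners <- rbind(c(0, 0), c(fov_moving[1], 0), c(0, fov_moving[2]),
                      fov_moving)
  warped <- affine_apply(T2D, mv_corners)
  pad <- 200
  x0 <- min(0, warped[, 1]) - pad; x1 <- max(fov_fixed[1], warped[, 1]) + pad
  y0 <- min(0, warped[, 2]) - pad; y1 <- max(fov_fixed[2], warped[, 2]) + pad
  cpx <- 25
  cw <- ceiling((x1 - x0) / cpx) + 1; ch <- ceiling((y1 - y0) / cpx) + 1
  canvas <- render_vessel_canvas(c(ch, cw), cpx, c(x0, y0), config,
                                 derive_seed(seed, "vessels"))
  # soft vessel-shadow strength field
  vmask_soft <- gaussian_blur(canvas$mask * 1, 1)
  sample_canvas <- function(m, x, y) {
    bilinear_sample(m, (x - x0) / cpx, (y - y0) / cpx, fill = 0)
  }

  grid_um <- function(shape, sp) {
    a <- rep(0:(shape[3] - 1), each = shape[1]) * sp[3]
    b <- rep(0:(shape[1] - 1), times = shape[3]) * sp[1]
    cbind(x = a, y = b)  # column-major over (b, a) matrices
  }

  # ---- fixed side ----
  gf <- grid_um(fs, fsp)
  ilm_f_um <- matrix(ilm_fn(gf[, 1], gf[, 2]), fs[1], fs[3])
  thick_f <- matrix(thick_fn(gf[, 1], gf[, 2]), fs[1], fs[3])
  ilm_f <- ilm_f_um / fsp[2]
  rpe_f <- (ilm_f_um + thick_f) / fsp[2]
  isosj_f <- rpe_f - 60 / fsp[2]
  vsh_f <- matrix(sample_canvas(vmask_soft, gf[, 1], gf[, 2]), fs[1], fs[3])
  vol_f <- render_volume_grid(fs, ilm_f, isosj_f, rpe_f, vsh_f,
                              config$speckle_contrast, 1,
                              derive_seed(seed, "speckle_fixed"))
  surf_f <- surface_set(list(ILM = ilm_f, IS_OSJ = isosj_f, RPE_outer = rpe_f),
                        n_axial = fs[2])

  # ---- moving side: anatomy seen through the ground-truth affine ----
  gm <- grid_um(ms, msp)
  gm_fixed <- affine_apply(T2D, gm)   # where each moving pixel sits in the
                                      # fixed anatomical frame
  ilm_m_um <- ilm_fn(gm_fixed[, 1], gm_fixed[, 2])
  thick_m <- thick_fn(gm_fixed[, 1], gm_fixed[, 2])
  dz_m <- msp[2]
  delta_m <- delta_fn(gm_fixed[, 1], gm_fixed[, 2])
  ilm_m <- matrix(ilm_m_um / dz_m - delta_m, ms[1], ms[3])
  rpe_m <- matrix((ilm_m_um + thick_m) / dz_m - delta_m, ms[1], ms[3])
  isosj_m <- rpe_m - 60 / dz_m
  vsh_m <- matrix(sample_canvas(vmask_soft, gm_fixed[, 1], gm_fixed[, 2]),
                  ms[1], ms[3])
  vol_m <- render_volume_grid(ms, ilm_m, isosj_m, rpe_m, vsh_m,
                              config$speckle_contrast, 0.85,
                              derive_seed(seed, "speckle_moving"))
  surf_m <- surface_set(list(ILM = ilm_m, IS_OSJ = isosj_m, RPE_outer = rpe_m),
                        n_axial = ms[2])

  # ---- SLO: higher-resolution, contrast-remapped rendering of the fixed
  # vessel canvas (monotone remap + extra blur = simulated modality gap) ----
  ssp <- config$slo_spacing_um
  sw <- floor(fov_fixed[1] / ssp) + 1; sh <- floor(fov_fixed[2] / ssp) + 1
  gs_x <- rep((0:(sw - 1)) * ssp, each = sh)
  gs_y <- rep((0:(sh - 1)) * ssp, times = sw)
  slo_raw <- matrix(sample_canvas(canvas$image, gs_x, gs_y), sh, sw)
  slo_img <- gaussian_blur(clamp(0.1 + 0.85 * slo_raw^0.7, 0, 1), 0.8)
  slo_noise <- with_seed(derive_seed(seed, "slo"),
                         matrix(stats::rnorm(sh * sw, 0, 0.015), sh, sw))
  slo <- enface_image(clamp(slo_img + slo_noise, 0, 1), c(ssp, ssp),
                      modality = "slo")

  # ---- ground-truth axial field on the fixed grid ----
  delta_f <- matrix(delta_fn(gf[, 1], gf[, 2]), fs[1], fs[3])
  gt_delta <- zshift_field(delta_f)

  # ---- landmarks and oracle correspondences inside the overlap ----
  pick_overlap_points <- function(n, seed) {
    with_seed(seed, {
      got <- matrix(0, 0, 2)
      while (nrow(got) < n) {
        cand <- cbind(stats::runif(4 * n, 0.08, 0.92) * fov_fixed[1],
                      stats::runif(4 * n, 0.08, 0.92) * fov_fixed[2])
        pre <- affine_apply(Ti, cand)
        ok <- pre[, 1] >= 0.05 * fov_moving[1] & pre[, 1] <= 0.95 * fov_moving[1] &
              pre[, 2] >= 0.05 * fov_moving[2] & pre[, 2] <= 0.95 * fov_moving[2]
        got <- rbind(got, cand[ok, , drop = FALSE])
      }
      got[seq_len(n), , drop = FALSE]
    })
  }
  lm_fixed_um <- pick_overlap_points(4, derive_seed(seed, "landmarks"))
  lm_moving_um <- affine_apply(Ti, lm_fixed_um)
  orc_fixed_um <- pick_overlap_points(40, derive_seed(seed, "oracle"))
  orc_moving_um <- affine_apply(Ti, orc_fixed_um)

  labels <- paste0("L", seq_len(nrow(lm_fixed_um)))
  landmarks <- list(
    fixed = landmark_set(labels, sweep(lm_fixed_um, 2, c(ssp, ssp), "/"),
                         c(ssp, ssp)),
    moving = landmark_set(labels,
                          sweep(lm_moving_um, 2, c(msp[3], msp[1]), "/"),
                          c(msp[1], msp[3]))
  )

  structure(list(
    fixed = list(volume = oct_volume(vol_f, fsp, "fixed-device"),
                 surfaces = surf_f, slo = slo),
    moving = list(volume = oct_volume(vol_m, msp, "moving-device"),
                  surfaces = surf_m),
    gt_T2D = T2D,
    gt_delta = gt_delta,
    landmarks = landmarks,
    oracle = list(fixed_um = orc_fixed_um, moving_um = orc_moving_um),
    config = config
  ), class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("<phantom_pair>\n  fixed:  "); print(x$fixed$volume)
  cat("  moving: "); print(x$moving$volume)
  cat("  gt affine translation (um):",
      sprintf("%.1f, %.1f", x$gt_T2D$matrix[1, 3], x$gt_T2D$matrix[2, 3]), "\n")
  invisible(x)
}
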