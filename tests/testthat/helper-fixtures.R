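# Shared fixtures, built once per test run. Phantom configurations are kept
# small so the whole suite stays fast; geometry ratios still mirror the
# two-device asymmetry (denser moving B-scans over a wider slow-axis FoV).

# small paired phantom: fixed 16 x 64 x 48 over 3 x 3 mm, moving 40 x 64 x 48
# over 4 x 3 mm, shared 3.5 um axial pitch
small_phantom_config <- function(seed = 1L, ...) {
  args <- list(
    fixed_shape = c(16, 160, 48),
    moving_shape = c(40, 160, 48),
    fixed_spacing = c(3000 / 16, 3.5, 3000 / 48),
    moving_spacing = c(4000 / 40, 3.5, 3000 / 48),
    surface_wavelength_um = 900,
    gt_rotation_deg = 2,
    gt_translation_um = c(80, -60),
    gt_axial_px = 4,
    slo_spacing_um = 31.25,
    seed = seed
  )
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

# memoized default small pair used by read-only tests
.cache <- new.env(parent = emptyenv())
small_pair <- function() {
  if (is.null(.cache$pair)) .cache$pair <- generate_phantom_pair(small_phantom_config(seed = 11))
  .cache$pair
}

# a tiny volume with a closed-form intensity pattern, for projection oracles
ramp_volume <- function(nb = 3, nz = 100, na_ = 4, dz = 3) {
  arr <- array(0, dim = c(nb, nz, na_))
  for (z in seq_len(nz)) arr[, z, ] <- z - 1   # intensity(z) = z, 0-based
  oct_volume(arr, c(100, dz, 50))
}

const_surfaces <- function(nb, na_, ilm = 10, isosj = 40, rpe = 50) {
  surface_set(list(ILM = matrix(ilm, nb, na_),
                   IS_OSJ = matrix(isosj, nb, na_),
                   RPE_outer = matrix(rpe, nb, na_)))
}

# random unit descriptors
runit <- function(n, d = 128) {
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_lte(max(abs(object - expected)), tol)
}

# crafted single-query AP scenario with exactly known AP = 1/2:
# one valid query, true match at distance 0.4, one nearer negative at 0.2,
# two far negatives
rank2_scenario <- function() {
  H <- 8; D <- 16
  dist_vec <- function(dd, axis) {
    th <- 2 * asin(dd / 2)
    v <- numeric(D); v[1] <- cos(th); v[axis] <- sin(th)
    v
  }
  X <- array(0, dim = c(H, H, D))
  for (y in 1:H) for (x in 1:H) X[y, x, 1] <- 1
  Xp <- array(0, dim = c(H, H, D))
  put <- function(arr, y0, x0, v) { arr[y0 + 1, x0 + 1, ] <- v; arr }
  Xp <- put(Xp, 2, 2, dist_vec(0.4, 2))
  Xp <- put(Xp, 2, 6, dist_vec(0.2, 3))
  Xp <- put(Xp, 6, 2, c(0, 0, 0, 1, rep(0, D - 4)))
  Xp <- put(Xp, 6, 6, c(0, 0, 0, 0, 1, rep(0, D - 5)))
  U <- flow_identity(H, H)
  U$valid[] <- FALSE
  U$valid[3, 3] <- TRUE
  list(X = X, Xp = Xp, U = U,
       cfg = loss_config(N = 8, k = 0.5, ap_bins = 100, neg_stride = 4))
}

# keypoint/match simulation for affine RANSAC tests
make_kp <- function(xy_px, spacing, d = NULL) {
  n <- nrow(xy_px)
  if (is.null(d)) d <- diag(n)
  keypoint_set(xy_px, rep(1, n), rep(1, n), rep(1, n), d, spacing)
}

simulate_matches <- function(n_inliers, n_outliers, A_true, noise_px = 0,
                             seed = 1, spacing = c(10, 10)) {
  oct3dreg:::with_seed(seed, {
    P <- cbind(runif(n_inliers + n_outliers, 0, 200),
               runif(n_inliers + n_outliers, 0, 200))
    Q_um <- affine_apply(A_true, cbind(P[, 1] * spacing[2],
                                       P[, 2] * spacing[1]))
    Q <- cbind(Q_um[, 1] / spacing[2], Q_um[, 2] / spacing[1])
    if (n_outliers > 0) {
      o <- (n_inliers + 1):(n_inliers + n_outliers)
      Q[o, ] <- cbind(runif(n_outliers, 0, 200), runif(n_outliers, 0, 200))
    }
    if (noise_px > 0) {
      Q[1:n_inliers, ] <- Q[1:n_inliers, ] +
        matrix(rnorm(2 * n_inliers, 0, noise_px), n_inliers, 2)
    }
    m <- data.frame(index_fixed = seq_len(nrow(P)),
                    index_moving = seq_len(nrow(P)),
                    distance = 0)
    class(m) <- c("match_set", "data.frame")
    list(matches = m, fixed = make_kp(Q, spacing), moving = make_kp(P, spacing))
  })
}
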