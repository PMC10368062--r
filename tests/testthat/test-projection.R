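# Layer-bounded en-face projections.

test_that("constant volumes project to their constant", {
  arr <- array(5, dim = c(2, 100, 3))
  vol <- oct_volume(arr, c(100, 3, 50))
  ss <- const_surfaces(2, 3, ilm = 10, rpe = 50)
  pr <- project_enface(vol, ss, projection_spec("outer"))
  expect_true(all(pr$valid))
  expect_close(pr$image, 5, 1e-12)
})

test_that("outer projection of an axial ramp matches the closed-form mean", {
  vol <- ramp_volume(nb = 3, nz = 100, na_ = 4)
  ss <- const_surfaces(3, 4, ilm = 10, rpe = 50)
  # interval [10, 50 + 0.2 * 100) = [10, 70): mean of 10..69 is 39.5
  pr <- project_enface(vol, ss, projection_spec("outer"))
  expect_close(pr$image, 39.5, 1e-12)
})

test_that("layer-based projection reads only between IS/OSJ and RPE", {
  arr <- array(9, dim = c(2, 100, 3))
  arr[, 41:50, ] <- 2   # rows 41..50 are 0-based z 40..49 = [40, 50)
  vol <- oct_volume(arr, c(100, 3, 50))
  ss <- const_surfaces(2, 3, ilm = 10, isosj = 40, rpe = 50)
  pr <- project_enface(vol, ss, projection_spec("layer_based"))
  expect_close(pr$image, 2, 1e-12)
})

test_that("inner and hybrid bounds follow the 30-um top offset", {
  vol <- ramp_volume(nb = 2, nz = 100, na_ = 2, dz = 3)
  ss <- const_surfaces(2, 2, ilm = 10, rpe = 50)
  # top offset = round(30 / 3) = 10 px; inner interval [10, 50): mean 29.5
  pr_in <- project_enface(vol, ss, projection_spec("inner"))
  expect_close(pr_in$image, mean(10:49), 1e-12)
  # hybrid interval [10, 70): same as outer here
  pr_hy <- project_enface(vol, ss, projection_spec("hybrid"))
  expect_close(pr_hy$image, mean(10:69), 1e-12)
})

test_that("per-column means equal an explicit loop over random volumes", {
  withr::local_seed(4)
  nb <- 3; nz <- 40; na_ <- 5
  arr <- array(runif(nb * nz * na_), dim = c(nb, nz, na_))
  vol <- oct_volume(arr, c(100, 3, 50))
  ilm <- matrix(runif(nb * na_, 2, 8), nb, na_)
  rpe <- matrix(runif(nb * na_, 20, 30), nb, na_)
  ss <- surface_set(list(ILM = ilm, RPE_outer = rpe))
  for (mode in c("outer", "inner", "hybrid", "layer_based")) {
    spec <- projection_spec(mode)
    if (mode == "layer_based") {
      ss2 <- surface_set(list(ILM = ilm, IS_OSJ = rpe - 6, RPE_outer = rpe))
    } else ss2 <- ss
    pr <- project_enface(vol, ss2, spec)
    for (b in 1:nb) for (a in 1:na_) {
      zt <- switch(mode, outer = floor(ilm[b, a] + 0.5),
                   layer_based = floor(rpe[b, a] - 6 + 0.5),
                   floor(30 / 3 + 0.5))
      zb <- switch(mode, inner = floor(rpe[b, a] + 0.5),
                   layer_based = floor(rpe[b, a] + 0.5),
                   min(floor(rpe[b, a] + 0.2 * nz + 0.5), nz))
      ref <- mean(arr[b, (zt + 1):zb, a])
      expect_close(pr$image[b, a], ref, 1e-12)
      # mean-value bounds
      expect_gte(pr$image[b, a], min(arr[b, (zt + 1):zb, a]) - 1e-12)
      expect_lte(pr$image[b, a], max(arr[b, (zt + 1):zb, a]) + 1e-12)
    }
  }
})

test_that("degenerate columns are masked invalid rather than erroring", {
  vol <- ramp_volume(nb = 2, nz = 100, na_ = 2)
  # inner mode: z_top = 10 px. Column (2,1): RPE above z_top -> empty
  # interval; column (2,2): RPE invalid.
  rpe <- matrix(c(50, 5, 50, NA), 2, 2)
  ss <- surface_set(list(RPE_outer = rpe),
                    valid = list(RPE_outer = matrix(c(TRUE, TRUE, TRUE, FALSE),
                                                    2, 2)))
  pr <- project_enface(vol, ss, projection_spec("inner"), fill = -1)
  expect_false(pr$valid[2, 1])     # empty interval after clamping
  expect_false(pr$valid[2, 2])     # invalid surface cell
  expect_equal(pr$image[2, 1], -1)
  expect_equal(pr$image[2, 2], -1)
  expect_true(pr$valid[1, 1] && pr$valid[1, 2])
  # a missing required surface is an error
  expect_error(project_enface(vol, ss, projection_spec("outer")), "ILM")
})

test_that("outer interval contains the layer-based interval", {
  pp <- small_pair()
  sp_out <- projection_spec("outer")
  sp_lb <- projection_spec("layer_based")
  vol <- pp$fixed$volume; ss <- pp$fixed$surfaces
  nz <- dim(vol)[2]
  zt_out <- floor(ss$heights$ILM + 0.5)
  zb_out <- pmin(floor(ss$heights$RPE_outer + 0.2 * nz + 0.5), nz)
  zt_lb <- floor(ss$heights$IS_OSJ + 0.5)
  zb_lb <- pmin(floor(ss$heights$RPE_outer + 0.5), nz)
  expect_true(all(zt_out <= zt_lb))
  expect_true(all(zb_out >= zb_lb))
})
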