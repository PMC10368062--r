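# Domain types and file round-trips.

test_that("volume round-trips through TIFF and NIfTI losslessly", {
  arr <- array(round(runif(4 * 8 * 6), 4), dim = c(4, 8, 6))
  vol <- oct_volume(arr, c(120, 3, 60), device_tag = "dev-a")

  tf <- withr::local_tempfile(fileext = ".tif")
  write_oct_volume(vol, tf)
  back <- read_oct_volume(tf)
  # 16-bit TIFF quantizes to 1/65535 steps; values here are multiples of 1e-4
  expect_lt(max(abs(back$intensity - vol$intensity)), 1 / 65535)
  expect_equal(unname(back$spacing), c(120, 3, 60))

  nf <- withr::local_tempfile(fileext = ".nii.gz")
  write_oct_volume(vol, nf)
  back2 <- read_oct_volume(nf)
  expect_equal(back2$intensity, vol$intensity, tolerance = 1e-7)
})

test_that("NIfTI volumes with permuted axes are reordered to (b, z, a)", {
  arr <- array(runif(4 * 8 * 6), dim = c(4, 8, 6))
  # store as (z, a, b)
  perm <- aperm(arr, c(2, 3, 1))
  nf <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(perm), nf)
  vol <- read_oct_volume(nf, spacing = c(100, 3, 50),
                         axis_map = c("z", "a", "b"))
  expect_equal(vol$intensity, arr, tolerance = 1e-7)
})

test_that("missing spacing is an explicit error, never assumed", {
  arr <- array(runif(4 * 8 * 6), dim = c(4, 8, 6))
  nf <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), nf)
  expect_error(read_oct_volume(nf), "spacing")
})

test_that("surface CSV reading assembles grids and flags absent cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- expand.grid(b = 0:1, a = 0:2)
  writeLines(c("surface,b,a,z",
               sprintf("ILM,%d,%d,10", df$b, df$a),
               # RPE_outer missing at (b=1, a=2)
               sprintf("RPE_outer,%d,%d,40",
                       df$b[-6], df$a[-6])), f)
  ss <- read_surfaces(f, grid_dim = c(2, 3))
  expect_true(all(ss$heights$ILM == 10))
  expect_true(all(ss$valid$ILM))
  expect_false(ss$valid$RPE_outer[2, 3])
  expect_true(all(ss$valid$RPE_outer[-6]))
})

test_that("surface ordering violations and out-of-range heights error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("surface,b,a,z", "ILM,0,0,50", "RPE_outer,0,0,40"), f)
  expect_error(read_surfaces(f, grid_dim = c(1, 1)), "ordering")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("surface,b,a,z", "ILM,0,0,120"), f2)
  expect_error(read_surfaces(f2, grid_dim = c(1, 1), n_axial = 100),
               "outside")
  # surfaces round-trip through write_surfaces
  ss <- const_surfaces(2, 3)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_surfaces(ss, f3)
  back <- read_surfaces(f3, grid_dim = c(2, 3))
  expect_equal(back$heights$ILM, ss$heights$ILM)
  expect_equal(back$heights$RPE_outer, ss$heights$RPE_outer)
})

test_that("transforms round-trip through JSON at full precision", {
  t1 <- affine2d(matrix(c(1.0000001, 0.2, -0.2, 0.99, 123.456789012345,
                          -0.000012345), 2, 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(t1, f)
  expect_close(read_transform(f)$matrix, t1$matrix, 1e-12)

  d <- matrix(rnorm(12), 3, 4)
  d[2, 2] <- NA_real_
  zf <- zshift_field(d)
  write_transform(zf, f)
  back <- read_transform(f)
  expect_identical(back$valid, zf$valid)
  expect_close(back$delta[zf$valid], zf$delta[zf$valid], 1e-12)

  bt <- bscan_transforms(list(cbind(diag(2), c(1.5, -2.5)), NULL,
                              cbind(diag(2) * 1.01, c(0, 0))), "rigid")
  write_transform(bt, f)
  back2 <- read_transform(f, n_bscans = 3)
  expect_null(back2$transforms[[2]])
  expect_close(back2$transforms[[1]], bt$transforms[[1]], 1e-12)
  expect_error(read_transform(f, n_bscans = 5), "expected 5")
})

test_that("type invariants are enforced", {
  expect_error(oct_volume(array(1, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(oct_volume(matrix(1, 2, 2), c(1, 1, 1)), "3D")
  expect_error(affine2d(matrix(c(1, 2, 2, 4, 0, 0), 2, 3)), "singular")
  expect_error(surface_set(list(ILM = matrix(5, 2, 2),
                                RPE_outer = matrix(3, 2, 2))), "ordering")
  expect_error(surface_set(list(FOO = matrix(1, 2, 2))), "unknown surface")
  expect_error(enface_image(matrix(Inf, 2, 2), c(1, 1)), "finite")
})

test_that("en-face images round-trip with spacing sidecars", {
  img <- enface_image(matrix(round(runif(12), 3), 3, 4), c(30, 25), "slo")
  f <- withr::local_tempfile(fileext = ".tif")
  write_enface(img, f)
  back <- read_enface(f)
  expect_lt(max(abs(back$image - img$image)), 1 / 65535)  # 16-bit TIFF
  expect_equal(unname(back$spacing), c(30, 25))
  expect_equal(back$modality, "slo")
  # PNG is an 8-bit preview
  f2 <- withr::local_tempfile(fileext = ".png")
  write_enface(img, f2)
  expect_lt(max(abs(read_enface(f2)$image - img$image)), 1 / 255)
})

test_that("surface gap filling is linear, bounded, and opt-in", {
  h <- matrix(10, 2, 6)
  h[1, 3] <- NA; h[1, 6] <- NA   # interior gap and an edge gap
  h[2, ] <- c(10, 12, NA, NA, 18, 20)
  ss <- surface_set(list(ILM = h))
  expect_false(ss$valid$ILM[1, 3])   # never filled implicitly
  f <- fill_surface_gaps(ss)
  expect_true(f$valid$ILM[1, 3])
  expect_equal(f$heights$ILM[1, 3], 10)
  expect_false(f$valid$ILM[1, 6])    # no extrapolation past the last valid
  expect_equal(f$heights$ILM[2, 3:4], c(14, 16))  # linear across the gap
})
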