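# Axial registration: column shifting and layer point matching.

test_that("the shift field is the ILM difference, cell by cell", {
  f <- matrix(c(20, 21, 22, 23, 24, 25), 2, 3)
  m <- f - 7
  d <- column_shift_field(f, m)
  expect_close(d$delta, 7, 1e-12)
  expect_true(all(d$valid))
  # identical surfaces -> zero field
  d0 <- column_shift_field(f, f)
  expect_close(d0$delta, 0, 1e-12)
  # one invalid moving cell invalidates exactly that cell
  m2 <- m; m2[1, 2] <- NA
  d2 <- column_shift_field(f, m2)
  expect_false(d2$valid[1, 2])
  expect_equal(sum(!d2$valid), 1)
  expect_close(d2$delta[d2$valid], 7, 1e-12)
  expect_error(column_shift_field(f, f * NA), "jointly valid")
})

test_that("applying shifts moves columns with exact linear interpolation", {
  nb <- 2; nz <- 120; na_ <- 3
  arr <- array(0, dim = c(nb, nz, na_))
  arr[1, 94, 1] <- 1                       # one-hot at 0-based z = 93
  for (z in 1:nz) arr[2, z, ] <- z - 1     # linear ramp column
  vol <- oct_volume(arr, c(100, 3, 50))

  d0 <- zshift_field(matrix(0, nb, na_))
  expect_close(apply_column_shift(vol, d0)$intensity, vol$intensity, 1e-12)

  d7 <- zshift_field(matrix(7, nb, na_))
  out <- apply_column_shift(vol, d7)
  expect_equal(out$intensity[1, 101, 1], 1)       # 93 + 7 -> 0-based 100
  expect_equal(sum(out$intensity[1, , 1]), 1)

  # fractional shift on a linear ramp: linear interpolation is exact
  d25 <- zshift_field(matrix(2.5, nb, na_))
  out2 <- apply_column_shift(vol, d25)
  z0 <- 0:(nz - 1)
  expected <- z0 - 2.5
  inside <- expected >= 0
  expect_close(out2$intensity[2, inside, 2], expected[inside], 1e-12)
})

test_that("column shifting matches the ILM exactly on phantom pairs", {
  pp <- small_pair()
  w <- apply_enface_transform(pp$moving$volume, pp$moving$surfaces,
                              pp$gt_T2D, enface_grid(pp$fixed$volume))
  delta <- column_shift_field(pp$fixed$surfaces, w$surfaces)
  sreg <- shift_surfaces(w$surfaces, delta)
  ok <- sreg$valid$ILM
  expect_gt(sum(ok), 0)
  expect_close(sreg$heights$ILM[ok], pp$fixed$surfaces$heights$ILM[ok], 1e-9)
})

test_that("LPM recovers per-B-scan offsets through heavy ILM corruption", {
  withr::local_seed(31)
  na_ <- 100
  a <- 0:(na_ - 1)
  fixed_row <- 40 + 6 * sin(a / 15)
  offset <- 9.25
  for (seed in 1:10) {
    moving_row <- fixed_row - offset
    corrupt <- oct3dreg:::with_seed(seed, sample(na_, 30))
    moving_row[corrupt] <- moving_row[corrupt] +
      oct3dreg:::with_seed(seed + 100, sample(c(-50, 50), 30, replace = TRUE))
    r <- lpm_register_bscan(fixed_row, moving_row, "rigid",
                            lpm_params(n_iter = 500, tol_px = 3, seed = seed,
                                       da_um = 60, dz_um = 3.5))
    expect_false(inherits(r, "registration_failure"))
    # the transform must move the clean points onto the fixed row
    clean <- setdiff(seq_len(na_), corrupt)
    P <- cbind((clean - 1) * 60, moving_row[clean] * 3.5)
    res <- oct3dreg:::apply_mat23(matrix(as.numeric(r), 2, 3), P)
    err_px <- abs(res[, 2] / 3.5 - fixed_row[clean])
    expect_lt(max(err_px), 0.1)
  }
})

test_that("the similarity estimator recovers exact 2D similarity pairs", {
  withr::local_seed(30)
  P <- cbind(runif(40, 0, 300), runif(40, 0, 300))
  th <- 4 * pi / 180
  S <- 1.02 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Q <- t(S %*% t(P)) + matrix(c(12, -7), 40, 2, byrow = TRUE)
  A <- oct3dreg:::fit_point_transform(P, Q, "similarity")
  expect_close(sqrt(det(A[, 1:2])), 1.02, 1e-9)
  expect_close(oct3dreg:::apply_mat23(A, P), Q, 1e-9)
  # rigid has no scale freedom
  Ar <- oct3dreg:::fit_point_transform(P, Q, "rigid")
  expect_close(det(Ar[, 1:2]), 1, 1e-9)
})

test_that("the similarity model absorbs an axial scale that rigid cannot", {
  # Pre-paired points share their lateral coordinate, so a pure axial
  # magnification is only expressible through the similarity scale in
  # proportion to the axial share of the point variance: the row is given
  # steep relief and fine lateral pitch so that share dominates.
  na_ <- 100
  a <- 0:(na_ - 1)
  fixed_row <- 60 + 45 * sin(a / 10)
  ctr <- mean(fixed_row)
  moving_row <- (fixed_row - ctr) / 1.02 + ctr - 4
  pars <- lpm_params(n_iter = 400, tol_px = 3, seed = 2, da_um = 2,
                     dz_um = 3.5)
  r_sim <- lpm_register_bscan(fixed_row, moving_row, "similarity", pars)
  s <- sqrt(det(matrix(as.numeric(r_sim), 2, 3)[, 1:2]))
  expect_lt(abs(s - 1.02), 0.005)
  r_rig <- lpm_register_bscan(fixed_row, moving_row, "rigid", pars)
  P <- cbind(a * 2, moving_row * 3.5)
  res_rig <- oct3dreg:::apply_mat23(matrix(as.numeric(r_rig), 2, 3), P)
  res_sim <- oct3dreg:::apply_mat23(matrix(as.numeric(r_sim), 2, 3), P)
  rig_err <- max(abs(res_rig[, 2] / 3.5 - fixed_row))
  sim_err <- max(abs(res_sim[, 2] / 3.5 - fixed_row))
  expect_lt(sim_err, rig_err / 3)   # rigid leaves a systematic residual
})

test_that("single-cell ILM corruption: column shifting is local, LPM is robust", {
  withr::local_seed(32)
  nb <- 4; na_ <- 80
  f <- matrix(45, nb, na_) + matrix(sin(outer(1:nb, 1:na_) / 40), nb, na_)
  m <- f - 5
  m_bad <- m; m_bad[2, 17] <- m_bad[2, 17] + 30

  # column shifting: exactly one column of the output changes
  d_clean <- column_shift_field(f, m)
  d_bad <- column_shift_field(f, m_bad)
  changed <- which(abs(d_clean$delta - d_bad$delta) > 1e-12, arr.ind = TRUE)
  expect_equal(nrow(changed), 1)
  expect_equal(unname(changed[1, ]), c(2, 17))

  # LPM-rigid: the corrupted point is rejected; the B-scan transform moves
  # every clean column by <= 0.5 px of its clean-fit position
  pars <- lpm_params(n_iter = 400, tol_px = 3, seed = 3, da_um = 60,
                     dz_um = 3.5)
  r_clean <- lpm_register_bscan(f[2, ], m[2, ], "rigid", pars)
  r_bad <- lpm_register_bscan(f[2, ], m_bad[2, ], "rigid", pars)
  P <- cbind((0:(na_ - 1)) * 60, m[2, ] * 3.5)
  z_clean <- oct3dreg:::apply_mat23(matrix(as.numeric(r_clean), 2, 3), P)[, 2]
  z_bad <- oct3dreg:::apply_mat23(matrix(as.numeric(r_bad), 2, 3), P)[, 2]
  expect_lt(max(abs(z_clean - z_bad)) / 3.5, 0.5)
})

test_that("per-B-scan transforms apply independently with failure fallback", {
  pp <- small_pair()
  vol <- pp$fixed$volume
  d <- dim(vol)
  ident <- cbind(diag(2), c(0, 0))
  # all identities -> unchanged
  bt <- bscan_transforms(rep(list(ident), d[1]), "rigid")
  out <- apply_bscan_transforms(vol, bt)
  expect_close(out$intensity, vol$intensity, 1e-9)
  # single B-scan z-translation: only that B-scan moves
  shift <- cbind(diag(2), c(0, 2 * vol$spacing[2]))
  trs <- rep(list(ident), d[1]); trs[[3]] <- shift
  out2 <- apply_bscan_transforms(vol, bscan_transforms(trs, "rigid"))
  expect_close(out2$intensity[-3, , ], vol$intensity[-3, , ], 1e-9)
  expect_close(out2$intensity[3, 3:d[2], ], vol$intensity[3, 1:(d[2] - 2), ],
               1e-9)
  # failed B-scans borrow the nearest registered transform
  fh <- pp$fixed$surfaces
  mh <- fh
  mh$heights$ILM <- mh$heights$ILM - 3
  mh$heights$IS_OSJ <- mh$heights$IS_OSJ - 3
  mh$heights$RPE_outer <- mh$heights$RPE_outer - 3
  mh$valid$ILM[2, ] <- FALSE   # B-scan 2 has no valid ILM pairs
  res <- lpm_register_volume(fh, mh, "rigid",
                             lpm_params(n_iter = 200, seed = 4,
                                        da_um = vol$spacing[3],
                                        dz_um = vol$spacing[2]))
  expect_true(attr(res, "fallback")[2])
  expect_false(any(attr(res, "fallback")[-2]))
  expect_false(is.null(res$transforms[[2]]))
})
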