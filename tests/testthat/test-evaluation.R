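# Landmark metrics, failure rule, overlap masking, RPE statistics, Dice.

test_that("landmark error is the mean metric distance over matched labels", {
  lab <- c("A", "B", "C", "D")
  f <- landmark_set(lab, cbind(c(10, 20, 30, 40), c(10, 20, 30, 40)), c(10, 10))
  expect_equal(landmark_error(f, f, NULL), 0)
  # every point offset by (3, 4) px at 10 um/px -> 5 px * 10 um = 50 um
  m <- landmark_set(lab, f$xy + matrix(c(3, 4), 4, 2, byrow = TRUE), c(10, 10))
  expect_equal(landmark_error(f, m, NULL), 50)
  # invariant to label order
  m_shuf <- landmark_set(lab[c(3, 1, 4, 2)], m$xy[c(3, 1, 4, 2), ], c(10, 10))
  expect_equal(landmark_error(f, m_shuf, NULL), 50)
  expect_error(landmark_error(f, landmark_set(c("A", "B", "X", "D"), m$xy,
                                              c(10, 10))), "labels")
})

test_that("the failure rule uses a strict inequality", {
  lab <- c("A", "B", "C", "D")
  f <- landmark_set(lab, cbind(1:4, 1:4) * 10, c(10, 10))
  # identity on identical sets: after == before -> not a failure
  expect_false(detect_failure(f, f, affine2d_identity()))
  # a transform that doubles a pure offset -> failure
  m <- landmark_set(lab, f$xy + 5, c(10, 10))
  worse <- affine2d(cbind(diag(2), c(50, 50)))
  expect_true(detect_failure(f, m, worse))
  # an estimation failure marker is always a failure
  expect_true(detect_failure(f, m, registration_failure("x")))
})

test_that("2D aggregates follow the reporting protocol", {
  r <- aggregate_2d(c(10, 20, 30))
  expect_equal(r$mean, 20); expect_equal(r$median, 20)
  expect_equal(r$n_failures, 0)
  r2 <- aggregate_2d(c(10, 1000, 30), c(FALSE, TRUE, FALSE))
  expect_equal(r2$n_failures, 1)
  expect_equal(r2$mean_excluding_failures, 20)
  r3 <- aggregate_2d(42)
  expect_equal(r3$mean, 42); expect_equal(r3$median, 42)
  expect_true(is.na(aggregate_2d(5, TRUE)$mean_excluding_failures))
})

test_that("overlap masks intersect fields of view and validity", {
  g <- list(dim = c(20, 30), spacing = c(10, 10))
  full <- overlap_mask(g, g, affine2d_identity())
  expect_true(all(full))
  # translate the moving FoV by half its width: the left half of the fixed
  # grid has no pre-image
  half <- overlap_mask(g, g, affine2d(cbind(diag(2), c(150, 0))))
  expect_true(all(!half[, 1:15]))
  expect_true(all(half[, 16:30]))
  # disjoint fields of view
  far <- overlap_mask(g, g, affine2d(cbind(diag(2), c(10000, 0))))
  expect_true(all(!far))
  # validity masks propagate
  fv <- matrix(TRUE, 20, 30); fv[3, ] <- FALSE
  expect_true(all(!overlap_mask(g, g, affine2d_identity(),
                                fixed_valid = fv)[3, ]))
})

test_that("the five RPE statistics match a hand-enumerated grid", {
  f <- matrix(0, 2, 3)
  m <- matrix(c(1, 4, 2, 5, 3, 6), 2, 3)   # |diffs| = {1,2,3; 4,5,6} px
  mask <- matrix(TRUE, 2, 3)
  r <- rpe_error_metrics(f, m, mask, dz_um = 1)
  expect_equal(r$mean, 3.5)
  expect_equal(r$median, 3.5)
  expect_equal(r$max_mean_per_bscan, 5)    # row means 2 and 5
  expect_equal(r$max_mean_per_ascan, 4.5)  # column means 2.5, 3.5, 4.5
  expect_equal(r$max, 6)
  # dz scales every statistic; identical surfaces give zeros
  r3 <- rpe_error_metrics(f, f + 2, mask, dz_um = 3)
  expect_true(all(unlist(r3) == 6))
  r0 <- rpe_error_metrics(f, f, mask, 3)
  expect_true(all(unlist(r0) == 0))
  # empty mask -> undefined markers
  expect_true(all(is.na(unlist(rpe_error_metrics(f, m, mask & FALSE, 1)))))
})

test_that("retinal-band Dice follows interval arithmetic", {
  mk <- function(ilm, rpe, nb = 2, na_ = 3) {
    surface_set(list(ILM = matrix(ilm, nb, na_),
                     RPE_outer = matrix(rpe, nb, na_)))
  }
  mask <- matrix(TRUE, 2, 3)
  expect_equal(retina_dice(mk(10, 50), mk(10, 50), mask), 1)
  expect_equal(retina_dice(mk(10, 50), mk(55, 90), mask), 0)
  # bands [10, 50) and [30, 70): 2 * 20 / (40 + 40) = 0.5
  expect_equal(retina_dice(mk(10, 50), mk(30, 70), mask), 0.5)
  # symmetry and monotonicity in the intersection
  expect_equal(retina_dice(mk(30, 70), mk(10, 50), mask), 0.5)
  expect_gt(retina_dice(mk(10, 50), mk(20, 60), mask),
            retina_dice(mk(10, 50), mk(30, 70), mask))
  # per-B-scan variant agrees on homogeneous grids
  expect_close(retina_dice(mk(10, 50), mk(30, 70), mask, per_bscan = TRUE),
               c(0.5, 0.5), 1e-12)
})

test_that("repeat-evaluation selects the run with the median key", {
  fn <- function(seed) list(n_failures = (seed %% 5), median_error = seed %% 7,
                            seed = seed)
  r <- evaluate_repeats(fn, repeats = 3, select = "median_failures", seed = 1)
  runs <- attr(r, "runs")
  keys <- vapply(runs, `[[`, numeric(1), "n_failures")
  expect_equal(r$n_failures, sort(keys)[2])
  r2 <- evaluate_repeats(fn, repeats = 3, select = "median_error", seed = 1)
  keys2 <- vapply(attr(r2, "runs"), `[[`, numeric(1), "median_error")
  expect_equal(r2$median_error, sort(keys2)[2])
})
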