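# Training objective: cosine-similarity, peakiness, AP and reliability terms.

test_that("cosine-similarity loss identities", {
  withr::local_seed(1)
  S <- matrix(runif(32 * 32), 32, 32)
  U <- flow_identity(32, 32)
  expect_close(cosim_loss(S, S, U, 16), 0, 1e-10)
  # constant heatmaps are collinear regardless of level
  expect_close(cosim_loss(matrix(0.3, 32, 32), matrix(0.8, 32, 32), U, 16),
               0, 1e-10)
  # orthogonal one-hot windows
  a <- matrix(0, 16, 16); a[5, 7] <- 1
  b <- matrix(0, 16, 16); b[9, 3] <- 1
  expect_close(cosim_loss(a, b, flow_identity(16, 16), 16), 1, 1e-12)
})

test_that("peakiness loss identities and bounds", {
  expect_close(peakiness_loss(matrix(0.5, 20, 20), 16), 1, 1e-12)
  one_hot <- matrix(0, 16, 16); one_hot[4, 11] <- 1
  expect_close(peakiness_loss(one_hot, 16), 1 / 256, 1e-12)
  withr::local_seed(2)
  for (i in 1:5) {
    S <- matrix(runif(24 * 24), 24, 24)
    v <- peakiness_loss(S, 8)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  # peaking a window strictly decreases the loss relative to a constant
  expect_lt(peakiness_loss(one_hot, 16), peakiness_loss(matrix(1, 16, 16), 16))
})

test_that("repeatability loss composes its terms and is symmetric", {
  U <- flow_identity(16, 16)
  S <- matrix(0.4, 16, 16)
  expect_close(repeatability_loss(S, S, U, 16), 1, 1e-12)  # 0 + (1+1)/2
  one_hot <- matrix(0, 16, 16); one_hot[4, 11] <- 1
  expect_close(repeatability_loss(one_hot, one_hot, U, 16), 1 / 256, 1e-9)
  # swapping S, S' under the (identity-)inverted flow leaves the value
  withr::local_seed(3)
  A <- matrix(runif(256), 16, 16); B <- matrix(runif(256), 16, 16)
  expect_close(repeatability_loss(A, B, U, 16),
               repeatability_loss(B, A, U, 16), 1e-10)
})

test_that("exact average precision on ranked lists", {
  q <- c(1, 0, 0)
  expect_equal(exact_ap(q, c(1, 0, 0), rbind(c(0, 1, 0), c(0, 0, 1))), 1)
  # positive ranked last of n = 3
  expect_equal(exact_ap(c(1, 0, 0), c(0, 1, 0),
                        rbind(c(1, 0.01, 0), c(1, 0, 0.02))), 1 / 3)
  expect_equal(exact_ap(q, c(0, 1, 0), NULL), 1)
  # tie distances broken by index: positive (index 0) wins
  expect_equal(exact_ap(c(1, 0), c(0, 1), rbind(c(0, 1))), 1)
})

test_that("quantized AP converges to the exact oracle", {
  withr::local_seed(4)
  for (i in 1:50) {
    m <- sample(2:20, 1)
    repeat {
      D <- runit(m, 16)
      q <- as.vector(runit(1, 16))
      d <- sqrt(rowSums(sweep(D, 2, q)^2))
      if (min(abs(d[-1] - d[1])) > 3 * (max(d) - min(d)) / 999) break
    }
    sa <- oct3dreg:::soft_ap_vg(d, 1L, 1000L)
    expect_close(sa$value, exact_ap(q, D[1, ], D[-1, , drop = FALSE]), 1e-3)
  }
  # all-identical candidates: expected AP of a random single-positive ranking
  d <- rep(0.7, 6)
  expect_close(oct3dreg:::soft_ap_vg(d, 2L, 100L)$value, sum(1 / (1:6)) / 6,
               1e-12)
})

test_that("descriptor AP loss scores the crafted ranking exactly", {
  sc <- rank2_scenario()
  expect_close(ap_loss(sc$X, sc$Xp, sc$U, sc$cfg), 0.5, 1e-9)
  # perfect correspondences: orthogonal identical descriptor fields
  withr::local_seed(5)
  H <- 8
  Xs <- array(0, dim = c(H, H, 64))
  Xs[, , ] <- array(runit(H * H, 64), dim = c(H, H, 64))
  expect_lt(ap_loss(Xs, Xs, flow_identity(H, H),
                    loss_config(N = 8, neg_stride = 4)), 1e-6)
})

test_that("reliability per-pixel value at AP = k is 1 - k for any R", {
  sc <- rank2_scenario()   # AP = 0.5 = k
  for (r in c(0, 0.3, 1)) {
    R <- matrix(r, 8, 8)
    expect_close(reliability_loss(sc$X, sc$Xp, R, sc$U, sc$cfg), 0.5, 1e-9)
  }
  # AP = 1, R = 1 -> 0;  AP = 1, R = 0 -> 1 - k
  withr::local_seed(6)
  H <- 8
  Xs <- array(runit(H * H, 64), dim = c(H, H, 64))
  cfg <- loss_config(N = 8, k = 0.5, neg_stride = 4)
  expect_close(reliability_loss(Xs, Xs, matrix(1, H, H),
                                flow_identity(H, H), cfg), 0, 1e-6)
  expect_close(reliability_loss(Xs, Xs, matrix(0, H, H),
                                flow_identity(H, H), cfg), 0.5, 1e-6)
})

test_that("total loss is the sum of its two terms", {
  withr::local_seed(7)
  H <- 16
  mk <- function() {
    list(descriptors = array(runit(H * H, 32), dim = c(H, H, 32)),
         repeatability = matrix(runif(H * H), H, H),
         reliability = matrix(runif(H * H), H, H), H = H, W = H)
  }
  o1 <- mk(); o2 <- mk()
  U <- flow_identity(H, H)
  cfg <- loss_config(N = 8, neg_stride = 8)
  tot <- total_loss(o1, o2, U, cfg)
  lrep <- repeatability_loss(o1$repeatability, o2$repeatability, U, cfg$N)
  lrel <- reliability_loss(o1$descriptors, o2$descriptors, o1$reliability,
                           U, cfg)
  expect_close(as.numeric(tot), lrep + lrel, 1e-12)
  expect_close(attr(tot, "repeatability"), lrep, 1e-12)
  expect_close(attr(tot, "reliability"), lrel, 1e-12)
})

test_that("analytic loss gradients match finite differences", {
  withr::local_seed(8)
  S <- matrix(runif(144), 12, 12); Sp <- matrix(runif(144), 12, 12)
  U <- flow_identity(12, 12)
  U$x <- U$x + matrix(runif(144, -0.4, 0.4), 12, 12)
  U$y <- U$y + matrix(runif(144, -0.4, 0.4), 12, 12)
  U$valid <- matrix(runif(144) > 0.1, 12, 12)
  num_grad <- function(f, x, eps = 1e-6) {
    g <- x * 0
    for (i in seq_along(x)) {
      x1 <- x; x2 <- x
      x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
      g[i] <- (f(x1) - f(x2)) / (2 * eps)
    }
    g
  }
  cv <- oct3dreg:::cosim_vg(S, Sp, U, 4)
  expect_close(num_grad(function(x) oct3dreg:::cosim_vg(x, Sp, U, 4)$value, S),
               cv$dS, 1e-6)
  expect_close(num_grad(function(x) oct3dreg:::cosim_vg(S, x, U, 4)$value, Sp),
               cv$dSp, 1e-6)
  pv <- oct3dreg:::peakiness_vg(S, 4)
  expect_close(num_grad(function(x) oct3dreg:::peakiness_vg(x, 4)$value, S),
               pv$dS, 1e-6)
  d <- runif(10, 0.1, 1.9)
  sa <- oct3dreg:::soft_ap_vg(d, 3L, 25L)
  expect_close(num_grad(function(x) oct3dreg:::soft_ap_vg(x, 3L, 25L)$value, d,
                        eps = 1e-7),
               sa$dd, 1e-5)
})
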