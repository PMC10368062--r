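# Detector/descriptor network contract.

test_that("outputs keep the input size and descriptor norms are unit", {
  net <- keypoint_net("desk", seed = 1)
  img <- matrix(runif(40 * 52), 40, 52)
  o <- net_forward(net, img)
  expect_equal(dim(o$descriptors), c(40, 52, 128))
  expect_equal(dim(o$repeatability), c(40, 52))
  expect_equal(dim(o$reliability), c(40, 52))
  nrm <- sqrt(apply(o$descriptors^2, c(1, 2), sum))
  expect_close(nrm, 1, 1e-5)
  expect_true(all(o$repeatability >= 0 & o$repeatability <= 1))
  expect_true(all(o$reliability >= 0 & o$reliability <= 1))
})

test_that("a constant input yields spatially constant outputs away from borders", {
  net <- keypoint_net("desk", seed = 2)
  img <- matrix(0, 48, 48)
  o <- net_forward(net, img)
  rf <- receptive_field(net)
  interior <- o$repeatability[(rf + 1):(48 - rf), (rf + 1):(48 - rf)]
  expect_lt(diff(range(interior)), 1e-12)
})

test_that("shifting the input shifts the repeatability map (equivariance)", {
  net <- keypoint_net("desk", seed = 3)
  img <- generate_vessel_map(48, 40, phantom_config(vessel_count = 4),
                             seed = 2, spacing_um = 60)$image
  sh <- 8
  img2 <- matrix(0, nrow(img), ncol(img))
  img2[, (sh + 1):ncol(img)] <- img[, 1:(ncol(img) - sh)]
  o1 <- net_forward(net, img)
  o2 <- net_forward(net, img2)
  rf <- receptive_field(net)
  a <- o1$repeatability[(rf + 1):(nrow(img) - rf), (rf + 1):(ncol(img) - rf - sh)]
  b <- o2$repeatability[(rf + 1):(nrow(img) - rf), (rf + 1 + sh):(ncol(img) - rf)]
  expect_lt(max(abs(a - b)), 1e-4)
})

test_that("images below the receptive field are rejected", {
  net <- keypoint_net("desk", seed = 4)
  rf <- receptive_field(net)
  expect_error(net_forward(net, matrix(0, rf - 1, 64)), "receptive field")
})

test_that("initialization is seeded and weights round-trip through JSON", {
  n1 <- keypoint_net("desk", seed = 5)
  n2 <- keypoint_net("desk", seed = 5)
  expect_identical(n1$params, n2$params)
  f <- withr::local_tempfile(fileext = ".json")
  save_weights(n1, f)
  n3 <- load_weights(f)
  for (nm in names(n1$params)) {
    expect_close(n3$params[[nm]]$w, n1$params[[nm]]$w, 1e-12)
    expect_close(n3$params[[nm]]$b, n1$params[[nm]]$b, 1e-12)
  }
  img <- matrix(runif(30 * 30), 30, 30)
  expect_close(net_forward(n3, img)$repeatability,
               net_forward(n1, img)$repeatability, 1e-12)
})

test_that("backpropagation matches finite differences through the total loss", {
  net <- keypoint_net("desk", seed = 6)
  img <- generate_vessel_map(32, 32, phantom_config(vessel_count = 3),
                             seed = 5, spacing_um = 80)$image
  pair <- make_training_pair(img, augmentation_config(
    scale_range = NULL, rotation_deg = 8, perspective = 1e-4,
    scale_jitter = 0.05, translation_px = 2, noise_sd = 0), seed = 3)
  cfg <- loss_config(N = 8, ap_bins = 25, neg_stride = 8)
  lossfn <- function(net) {
    as.numeric(total_loss(net_forward(net, pair$I),
                          net_forward(net, pair$I_prime), pair$U, cfg))
  }
  o1 <- net_forward(net, pair$I, with_cache = TRUE)
  o2 <- net_forward(net, pair$I_prime, with_cache = TRUE)
  vg <- oct3dreg:::total_loss_vg(o1, o2, pair$U, cfg)
  g <- oct3dreg:::add_grads(
    oct3dreg:::net_backward(net, o1$cache,
                            list(d_desc = vg$dX, d_rep = as.vector(vg$dS),
                                 d_rel = as.vector(vg$dR))),
    oct3dreg:::net_backward(net, o2$cache,
                            list(d_desc = vg$dXp, d_rep = as.vector(vg$dSp),
                                 d_rel = NULL)))
  withr::local_seed(9)
  eps <- 1e-5
  for (nm in c("conv2", "conv4", "desc", "rep", "rel")) {
    for (i in sample(length(net$params[[nm]]$w), 2)) {
      n1 <- net; n1$params[[nm]]$w[i] <- n1$params[[nm]]$w[i] + eps
      n2 <- net; n2$params[[nm]]$w[i] <- n2$params[[nm]]$w[i] - eps
      num <- (lossfn(n1) - lossfn(n2)) / (2 * eps)
      expect_lt(abs(g[[nm]]$w[i] - num), 1e-4 + 1e-3 * abs(num))
    }
  }
})
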