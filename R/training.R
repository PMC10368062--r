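# Self-supervised training: each step builds a synthetic pair (I, I') from a
# single image via a random homography ("tilting") plus pixel noise, with the
# exact pixel correspondence as flow, then descends the total loss.

#' Augmentation configuration for training pairs
#'
#' @param scale_range target range (pixels) for the shorter image side; the
#'   image is rescaled to a random size inside it. `NULL` keeps the native
#'   size.
#' @param rotation_deg maximum absolute in-plane rotation.
#' @param perspective maximum absolute perspective coefficient of the
#'   homography.
#' @param scale_jitter maximum relative isotropic scale change.
#' @param translation_px maximum absolute translation.
#' @param noise_sd additive Gaussian pixel-noise level on `[0, 1]` images.
#' @export
augmentation_config <- function(scale_range = c(256, 768), rotation_deg = 25,
                                perspective = 5e-4, scale_jitter = 0.1,
                                translation_px = 4, noise_sd = 0.02) {
  list(scale_range = scale_range, rotation_deg = rotation_deg,
       perspective = perspective, scale_jitter = scale_jitter,
       translation_px = translation_px, noise_sd = noise_sd)
}

#' Identity augmentation (for tests and sanity checks)
#' @export
augmentation_identity <- function() {
  augmentation_config(scale_range = NULL, rotation_deg = 0, perspective = 0,
                      scale_jitter = 0, translation_px = 0, noise_sd = 0)
}

# Apply 3x3 homography to 0-based (x, y) points. Rows of `xy` are points.
homography_apply <- function(Hm, xy) {
  p <- cbind(xy, 1) %*% t(Hm)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

sample_homography <- function(H, W, aug) {
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  for (attempt in 1:20) {
    th <- stats::runif(1, -aug$rotation_deg, aug$rotation_deg) * pi / 180
    sc <- 1 + stats::runif(1, -aug$scale_jitter, aug$scale_jitter)
    tx <- stats::runif(1, -aug$translation_px, aug$translation_px)
    ty <- stats::runif(1, -aug$translation_px, aug$translation_px)
    p1 <- stats::runif(1, -aug$perspective, aug$perspective)
    p2 <- stats::runif(1, -aug$perspective, aug$perspective)
    A <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    # centre the rotation/scale, then translate; perspective row last
    t_ <- c(cx + tx, cy + ty) - A %*% c(cx, cy)
    Hm <- rbind(cbind(A, t_), c(p1, p2, 1))
    if (abs(det(Hm)) > 1e-6) return(Hm)
  }
  stop_oct("could not sample a non-degenerate homography")
}

#' Build one training pair
#'
#' Rescales the source image (optional), warps it by a random homography,
#' adds pixel noise, and returns the exact flow of the warp. With
#' [augmentation_identity()] the pair is `(I, I)` under the identity flow.
#'
#' @param image numeric matrix or [enface_image()] with values in `[0, 1]`.
#' @param aug an [augmentation_config()].
#' @param seed integer seed (deterministic output).
#' @return List `I`, `I_prime` (matrices) and `U` (flow with `x`, `y`,
#'   `valid`).
#' @export
make_training_pair <- function(image, aug = augmentation_config(), seed = 0L) {
  if (inherits(image, "enface_image")) image <- image$image
  with_seed(derive_seed(seed, "pair"), {
    if (!is.null(aug$scale_range)) {
      target <- stats::runif(1, aug$scale_range[1], aug$scale_range[2])
      short <- min(dim(image))
      f <- target / short
      image <- resize_bilinear(image, max(2, round(nrow(image) * f)),
                               max(2, round(ncol(image) * f)))
    }
    H <- nrow(image); W <- ncol(image)
    Hm <- sample_homography(H, W, aug)
    # I'(q) = I(Hm^-1 q); flow U(p) = Hm p
    Hi <- solve(Hm)
    gx <- rep(0:(W - 1), each = H); gy <- rep(0:(H - 1), times = W)
    src <- homography_apply(Hi, cbind(gx, gy))
    Ip <- matrix(bilinear_sample(image, src[, 1], src[, 2], fill = 0), H, W)
    if (aug$noise_sd > 0) {
      Ip <- clamp(Ip + matrix(stats::rnorm(H * W, 0, aug$noise_sd), H, W), 0, 1)
    }
    tgt <- homography_apply(Hm, cbind(gx, gy))
    U <- list(x = matrix(tgt[, 1], H, W), y = matrix(tgt[, 2], H, W),
              valid = matrix(tgt[, 1] >= 0 & tgt[, 1] <= W - 1 &
                             tgt[, 2] >= 0 & tgt[, 2] <= H - 1, H, W))
    list(I = image, I_prime = Ip, U = U, homography = Hm)
  })
}

#' Training configuration
#'
#' The `"paper"` preset is the full-scale regime customary for this family
#' of detector/descriptor models (Adam, learning rate 1e-4, weight decay
#' 5e-4, batch size 8, 2500 epochs, scales 256-768, `N = 16`, `k = 0.5`);
#' the `"desk"` preset is a CPU-scale variant (small
#' network, small images, few epochs) used throughout the test suite.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param epochs,batch_size,lr,weight_decay optimizer settings.
#' @param loss a [loss_config()].
#' @param aug an [augmentation_config()].
#' @param seed master seed fanned out to all samplers.
#' @export
training_config <- function(preset = c("desk", "paper"), epochs = NULL,
                            batch_size = NULL, lr = NULL, weight_decay = 5e-4,
                            loss = NULL, aug = NULL, seed = 0L) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    list(preset = preset, epochs = epochs %||% 2500L,
         batch_size = batch_size %||% 8L, lr = lr %||% 1e-4,
         weight_decay = weight_decay,
         loss = loss %||% loss_config(N = 16L),
         aug = aug %||% augmentation_config(scale_range = c(256, 768)),
         seed = as.integer(seed))
  } else {
    list(preset = preset, epochs = epochs %||% 12L,
         batch_size = batch_size %||% 4L, lr = lr %||% 1e-3,
         weight_decay = weight_decay,
         loss = loss %||% loss_config(N = 8L, ap_bins = 25L),
         aug = aug %||% augmentation_config(scale_range = NULL,
                                            rotation_deg = 15,
                                            perspective = 2e-4,
                                            scale_jitter = 0.08,
                                            translation_px = 3,
                                            noise_sd = 0.02),
         seed = as.integer(seed))
  }
}

#' Train the keypoint network
#'
#' Stochastic gradient training of the joint detector/descriptor on a
#' collection of en-face images, with in-pair homography augmentation. Fully
#' deterministic given the seed.
#'
#' @param images list of matrices or [enface_image()]s in `[0, 1]`.
#' @param config a [training_config()].
#' @param net optional pre-built [keypoint_net()] (defaults to the preset's).
#' @param verbose print per-epoch losses.
#' @return List `net` (trained), `history` (per-epoch mean total loss) and
#'   `terms` (per-epoch repeatability/reliability means).
#' @export
train_keypoint_net <- function(images, config = training_config(), net = NULL,
                               verbose = FALSE) {
  assert_that(length(images) >= 1, "need at least one training image")
  images <- lapply(images, function(im) {
    m <- if (inherits(im, "enface_image")) im$image else im
    normalize01(m)
  })
  if (is.null(net)) {
    net <- keypoint_net(preset = config$preset,
                        seed = derive_seed(config$seed, "init"))
  }
  state <- adam_init(net$params)
  history <- numeric(config$epochs)
  terms <- matrix(0, config$epochs, 2,
                  dimnames = list(NULL, c("repeatability", "reliability")))
  n_img <- length(images)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("shuffle", ep)),
                     sample(n_img))
    ep_losses <- c(); ep_rep <- c(); ep_rel <- c()
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bi in seq_along(batches)) {
      acc <- NULL; bs <- 0
      for (ii in batches[[bi]]) {
        pair <- make_training_pair(images[[ii]], config$aug,
                                   seed = derive_seed(config$seed,
                                                      paste0("aug", ep, "_", ii)))
        o1 <- net_forward(net, pair$I, with_cache = TRUE)
        o2 <- net_forward(net, pair$I_prime, with_cache = TRUE)
        vg <- total_loss_vg(o1, o2, pair$U, config$loss)
        if (!is.finite(vg$value)) {
          stop_oct("non-finite loss at epoch %d (image %d): rep=%.4g rel=%.4g",
                   ep, ii, vg$repeatability, vg$reliability)
        }
        g1 <- net_backward(net, o1$cache,
                           list(d_desc = vg$dX, d_rep = as.vector(vg$dS),
                                d_rel = as.vector(vg$dR)))
        g2 <- net_backward(net, o2$cache,
                           list(d_desc = vg$dXp, d_rep = as.vector(vg$dSp),
                                d_rel = NULL))
        gsum <- add_grads(g1, g2)
        acc <- if (is.null(acc)) gsum else add_grads(acc, gsum)
        bs <- bs + 1
        ep_losses <- c(ep_losses, vg$value)
        ep_rep <- c(ep_rep, vg$repeatability); ep_rel <- c(ep_rel, vg$reliability)
      }
      acc <- scale_grads(acc, 1 / bs)
      upd <- adam_step(net$params, acc, state, lr = config$lr,
                       weight_decay = config$weight_decay)
      net$params <- upd$params; state <- upd$state
    }
    history[ep] <- mean(ep_losses)
    terms[ep, ] <- c(mean(ep_rep), mean(ep_rel))
    if (verbose) {
      message(sprintf("epoch %3d  total %.4f  rep %.4f  rel %.4f",
                      ep, history[ep], terms[ep, 1], terms[ep, 2]))
    }
  }
  list(net = net, history = history, terms = terms)
}

add_grads <- function(a, b) {
  for (nm in names(a)) for (f in names(a[[nm]])) {
    a[[nm]][[f]] <- a[[nm]][[f]] + b[[nm]][[f]]
  }
  a
}

scale_grads <- function(a, s) {
  for (nm in names(a)) for (f in names(a[[nm]])) {
    a[[nm]][[f]] <- a[[nm]][[f]] * s
  }
  a
}
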