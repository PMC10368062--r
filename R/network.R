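# Compact fully-convolutional keypoint detector/descriptor network.
#
# An L2-Net-style backbone in which stride is replaced by dilation, so every
# output has the same spatial size as the input. Three heads share the
# backbone features:
#   descriptors  — 1x1 conv to `desc_dim` channels, L2-normalized per pixel
#   repeatability S — 1x1 conv + sigmoid, in [0, 1]
#   reliability  R — 1x1 conv + sigmoid, in [0, 1]
# Forward and backward passes are written directly in vectorised R
# (im2col + BLAS matrix products); the parameter set is small enough that a
# CPU desk-scale training run takes minutes.
#
# Feature maps are stored as (H*W) x C matrices in column-major pixel order
# (pixel (y, x), 0-based, maps to row y + 1 + x * H).

# Zero-padded shift of a (H*W) x C feature matrix by (dy, dx) pixels:
# out(y, x) = X(y + dy, x + dx).
shift_feat <- function(X, H, W, dy, dx) {
  out <- matrix(0, nrow(X), ncol(X))
  ys <- max(0, -dy):min(H - 1, H - 1 - dy)
  xs <- max(0, -dx):min(W - 1, W - 1 - dx)
  if (length(ys) <= 0 || length(xs) <= 0) return(out)
  rows_out <- as.vector(outer(ys + 1, xs * H, `+`))
  rows_src <- as.vector(outer(ys + dy + 1, (xs + dx) * H, `+`))
  out[rows_out, ] <- X[rows_src, , drop = FALSE]
  out
}

conv_offsets <- function(dilation) {
  od <- expand.grid(dy = c(-dilation, 0, dilation), dx = c(-dilation, 0, dilation))
  od[order(od$dx, od$dy), ]  # fixed, documented order
}

im2col <- function(X, H, W, dilation) {
  off <- conv_offsets(dilation)
  blocks <- vector("list", nrow(off))
  for (i in seq_len(nrow(off))) {
    blocks[[i]] <- shift_feat(X, H, W, off$dy[i], off$dx[i])
  }
  do.call(cbind, blocks)
}

col2im <- function(dCols, H, W, dilation, cin) {
  off <- conv_offsets(dilation)
  dX <- matrix(0, H * W, cin)
  for (i in seq_len(nrow(off))) {
    blk <- dCols[, ((i - 1) * cin + 1):(i * cin), drop = FALSE]
    dX <- dX + shift_feat(blk, H, W, -off$dy[i], -off$dx[i])
  }
  dX
}

#' Create a keypoint detector/descriptor network
#'
#' @param preset `"desk"` (small channels, for CPU-scale experiments) or
#'   `"paper"` (wider backbone).
#' @param desc_dim descriptor dimensionality (default 128).
#' @param seed seed for weight initialization (He-normal).
#' @return An object of class `keypoint_net`.
#' @export
keypoint_net <- function(preset = c("desk", "paper"), desc_dim = 128L,
                         seed = 0L) {
  preset <- match.arg(preset)
  channels <- switch(preset, desk = c(8, 8, 16, 16), paper = c(32, 32, 64, 64))
  dilations <- c(1L, 1L, 2L, 4L)
  cin <- c(1L, channels[-length(channels)])
  params <- list()
  init_w <- function(n_in, n_out, seed) {
    with_seed(seed, matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)),
                           n_in, n_out))
  }
  for (l in seq_along(channels)) {
    params[[paste0("conv", l)]] <- list(
      w = init_w(9L * cin[l], channels[l], derive_seed(seed, paste0("w", l))),
      b = numeric(channels[l]))
  }
  cl <- channels[length(channels)]
  params$desc <- list(w = init_w(cl, desc_dim, derive_seed(seed, "wdesc")),
                      b = numeric(desc_dim))
  params$rep <- list(w = init_w(cl, 1L, derive_seed(seed, "wrep")), b = 0)
  params$rel <- list(w = init_w(cl, 1L, derive_seed(seed, "wrel")), b = 0)
  structure(list(params = params, dilations = dilations, channels = channels,
                 desc_dim = as.integer(desc_dim), preset = preset,
                 receptive_field = 1L + 2L * sum(3L %/% 3L * dilations) * 1L),
            class = "keypoint_net")
}

#' Receptive field (patch size M) of the network
#' @param net a [keypoint_net()].
#' @export
receptive_field <- function(net) 1L + 2L * sum(net$dilations)

#' @export
print.keypoint_net <- function(x, ...) {
  np <- sum(vapply(unlist(x$params, recursive = FALSE), length, numeric(1)))
  cat(sprintf("<keypoint_net> preset %s, channels %s, %d-d descriptors, RF %d px, %d parameters\n",
              x$preset, paste(x$channels, collapse = "-"), x$desc_dim,
              receptive_field(x), np))
  invisible(x)
}

#' Run the network on an en-face image
#'
#' Fully convolutional: any input at least as large as the receptive field.
#'
#' @param net a [keypoint_net()].
#' @param image numeric matrix in `[0, 1]` (or an [enface_image()]).
#' @param with_cache keep intermediates for backpropagation.
#' @return A `network_outputs` list: `descriptors` (H x W x desc_dim,
#'   unit-norm per pixel), `repeatability` and `reliability` (H x W in
#'   `[0, 1]`), plus `H`, `W`.
#' @export
net_forward <- function(net, image, with_cache = FALSE) {
  if (inherits(image, "enface_image")) image <- image$image
  H <- nrow(image); W <- ncol(image)
  rf <- receptive_field(net)
  assert_that(H >= rf && W >= rf,
              "image (%d x %d) smaller than the receptive field (%d)", H, W, rf)
  X <- matrix(as.numeric(image), H * W, 1)
  cache <- list(H = H, W = W)
  nl <- length(net$channels)
  for (l in seq_len(nl)) {
    d <- net$dilations[l]
    cols <- im2col(X, H, W, d)
    pre <- sweep(cols %*% net$params[[paste0("conv", l)]]$w, 2,
                 net$params[[paste0("conv", l)]]$b, `+`)
    act <- pmax(pre, 0)
    if (with_cache) {
      cache[[paste0("cols", l)]] <- cols
      cache[[paste0("pre", l)]] <- pre
    }
    X <- act
  }
  if (with_cache) cache$feat <- X
  # descriptor head + L2 normalization
  desc_raw <- sweep(X %*% net$params$desc$w, 2, net$params$desc$b, `+`)
  nrm <- sqrt(rowSums(desc_raw^2)) + 1e-8
  desc <- desc_raw / nrm
  # heatmap heads
  rep_pre <- as.vector(X %*% net$params$rep$w) + net$params$rep$b
  rel_pre <- as.vector(X %*% net$params$rel$w) + net$params$rel$b
  S <- stats::plogis(rep_pre)
  R <- stats::plogis(rel_pre)
  out <- list(
    descriptors = array(desc, dim = c(H, W, net$desc_dim)),
    repeatability = matrix(S, H, W),
    reliability = matrix(R, H, W),
    H = H, W = W)
  if (with_cache) {
    cache$desc_raw <- desc_raw; cache$nrm <- nrm; cache$desc <- desc
    cache$S <- S; cache$R <- R
    out$cache <- cache
  }
  class(out) <- "network_outputs"
  out
}

# Backward pass. `grads`: d_desc ((H*W) x desc_dim, w.r.t. the *normalized*
# descriptors), d_rep, d_rel (length H*W vectors, w.r.t. S and R).
# Returns parameter gradients with the same structure as net$params.
net_backward <- function(net, cache, grads) {
  H <- cache$H; W <- cache$W
  g <- list()
  feat <- cache$feat
  dfeat <- matrix(0, H * W, ncol(feat))

  # descriptor head (through L2 normalization)
  if (!is.null(grads$d_desc)) {
    dn <- grads$d_desc
    desc <- cache$desc
    dot <- rowSums(dn * desc)
    draw <- (dn - desc * dot) / cache$nrm
    g$desc <- list(w = crossprod(feat, draw), b = colSums(draw))
    dfeat <- dfeat + draw %*% t(net$params$desc$w)
  } else {
    g$desc <- list(w = 0 * net$params$desc$w, b = 0 * net$params$desc$b)
  }
  # heatmap heads (through sigmoid)
  for (head in c("rep", "rel")) {
    gh <- grads[[paste0("d_", head)]]
    if (!is.null(gh)) {
      s <- if (head == "rep") cache$S else cache$R
      dpre <- as.vector(gh) * s * (1 - s)
      g[[head]] <- list(w = crossprod(feat, dpre), b = sum(dpre))
      dfeat <- dfeat + matrix(dpre, ncol = 1) %*% t(net$params[[head]]$w)
    } else {
      g[[head]] <- list(w = 0 * net$params[[head]]$w, b = 0 * net$params[[head]]$b)
    }
  }
  # backbone
  nl <- length(net$channels)
  dact <- dfeat
  for (l in rev(seq_len(nl))) {
    pre <- cache[[paste0("pre", l)]]
    dpre <- dact * (pre > 0)
    cols <- cache[[paste0("cols", l)]]
    g[[paste0("conv", l)]] <- list(w = crossprod(cols, dpre), b = colSums(dpre))
    if (l > 1) {
      dCols <- dpre %*% t(net$params[[paste0("conv", l)]]$w)
      dact <- col2im(dCols, H, W, net$dilations[l], net$channels[l - 1])
    }
  }
  g[names(net$params)]
}

# --- Adam optimizer over the nested parameter list -------------------------

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 5e-4) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    for (f in names(params[[nm]])) {
      gr <- grads[[nm]][[f]] + weight_decay * params[[nm]][[f]]
      state$m[[nm]][[f]] <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * gr
      state$v[[nm]][[f]] <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * gr^2
      mhat <- state$m[[nm]][[f]] / (1 - beta1^state$t)
      vhat <- state$v[[nm]][[f]] / (1 - beta2^state$t)
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Save / load network weights
#'
#' Weights are stored as JSON (text checkpoint) with full double precision.
#' @param net a [keypoint_net()].
#' @param path checkpoint path.
#' @export
save_weights <- function(net, path) {
  obj <- list(preset = net$preset, desc_dim = net$desc_dim,
              channels = net$channels, dilations = net$dilations,
              params = lapply(net$params, function(p)
                list(w = list(dim = dim(as.matrix(p$w)), data = as.vector(p$w)),
                     b = as.vector(p$b))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- keypoint_net(preset = obj$preset, desc_dim = obj$desc_dim, seed = 0L)
  for (nm in names(obj$params)) {
    p <- obj$params[[nm]]
    net$params[[nm]]$w <- matrix(p$w$data, p$w$dim[1], p$w$dim[2])
    net$params[[nm]]$b <- if (length(p$b) == 1) p$b else as.numeric(p$b)
  }
  net
}
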