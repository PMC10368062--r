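# Multi-scale keypoint extraction and descriptor matching.

#' Keypoint set
#'
#' @param xy n x 2 matrix of `(x, y)` positions in native image pixels
#'   (0-based).
#' @param scale detection scale factor per point (1 = native resolution).
#' @param repeatability,reliability per-point scores in `[0, 1]`.
#' @param descriptors n x D matrix of unit-norm descriptors.
#' @param spacing `(dy, dx)` micrometre pixel pitch of the source image.
#' @export
keypoint_set <- function(xy, scale, repeatability, reliability, descriptors,
                         spacing) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  n <- nrow(xy)
  assert_that(length(scale) == n && length(repeatability) == n &&
                length(reliability) == n && NROW(descriptors) == n,
              "keypoint fields must have one entry per point")
  if (n > 0) {
    assert_that(all(repeatability >= 0 & repeatability <= 1) &&
                  all(reliability >= 0 & reliability <= 1),
                "scores must lie in [0, 1]")
  }
  structure(list(xy = xy, scale = as.numeric(scale),
                 repeatability = as.numeric(repeatability),
                 reliability = as.numeric(reliability),
                 descriptors = as.matrix(descriptors),
                 spacing = as.numeric(spacing)),
            class = "keypoint_set")
}

#' @export
length.keypoint_set <- function(x) nrow(x$xy)

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d points, %d-d descriptors\n",
              nrow(x$xy), ncol(x$descriptors)))
  invisible(x)
}

#' Keypoint extraction parameters
#'
#' @param scales explicit vector of scale factors (<= 1), or `NULL` to build
#'   a pyramid from full size down to `min_size` by factors of `2^(1/4)`.
#' @param min_size smallest allowed shorter side of a pyramid level.
#' @param top_k keep at most this many points overall (by repeatability).
#' @param rep_thresh,rel_thresh absolute score thresholds applied to the
#'   repeatability / reliability heatmaps.
#' @param rep_quantile,rel_quantile when set (in `[0, 1)`), the threshold
#'   for that heatmap is taken as this quantile of the candidate maxima's
#'   own scores instead of the absolute value. Absolute thresholds assume a
#'   stable operating point of the sigmoid heads; quantile thresholds stay
#'   meaningful across training lengths and datasets.
#' @export
keypoint_params <- function(scales = NULL, min_size = 256, top_k = 5000,
                            rep_thresh = 0.7, rel_thresh = 0.7,
                            rep_quantile = NULL, rel_quantile = NULL) {
  list(scales = scales, min_size = min_size, top_k = top_k,
       rep_thresh = rep_thresh, rel_thresh = rel_thresh,
       rep_quantile = rep_quantile, rel_quantile = rel_quantile)
}

# Keypoint selection from one scale level's heatmaps: strict local maxima
# of S, filtered by the repeatability then the reliability threshold
# (absolute, or a quantile of the candidates' own scores).
# Returns a list of 0-based (y, x) positions and their linear rows.
select_keypoints_from_maps <- function(S, R, rep_thresh, rel_thresh,
                                       rep_quantile = NULL,
                                       rel_quantile = NULL) {
  pk <- nms_strict(S)
  if (nrow(pk) == 0) return(NULL)
  rows <- pk[, "y"] + 1 + pk[, "x"] * nrow(S)
  if (!is.null(rep_quantile)) {
    rep_thresh <- stats::quantile(S[rows], rep_quantile, names = FALSE)
  }
  if (!is.null(rel_quantile)) {
    rel_thresh <- stats::quantile(R[rows], rel_quantile, names = FALSE)
  }
  keep <- S[rows] >= rep_thresh & R[rows] >= rel_thresh
  if (!any(keep)) return(NULL)
  list(yx = pk[keep, , drop = FALSE], rows = rows[keep])
}

# Strict 3x3 local maxima (plateaus yield no keypoint). Returns 0-based
# (y, x) positions.
nms_strict <- function(S) {
  H <- nrow(S); W <- ncol(S)
  if (H < 3 || W < 3) return(matrix(0, 0, 2))
  P <- matrix(-Inf, H + 2, W + 2)
  P[2:(H + 1), 2:(W + 1)] <- S
  is_max <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- P[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
    is_max <- is_max & (S > nb)
  }
  w <- which(is_max, arr.ind = TRUE)
  cbind(y = w[, 1] - 1, x = w[, 2] - 1)
}

#' Extract multi-scale keypoints
#'
#' Runs the network over an image pyramid; at each level, strict local
#' maxima of the repeatability heatmap are kept, filtered by the
#' repeatability then the reliability threshold, and reported at native
#' resolution. The global `top_k` by repeatability survive. An image with no
#' surviving maxima yields an empty set (not an error).
#'
#' @param image an [enface_image()] or matrix (min-max normalized
#'   internally).
#' @param net a trained [keypoint_net()].
#' @param params a [keypoint_params()].
#' @return A [keypoint_set()].
#' @export
extract_keypoints <- function(image, net, params = keypoint_params()) {
  spacing <- if (inherits(image, "enface_image")) image$spacing else c(1, 1)
  img <- normalize01(if (inherits(image, "enface_image")) image$image else image)
  H <- nrow(img); W <- ncol(img)
  scales <- params$scales
  if (is.null(scales)) {
    scales <- 1
    f <- 2^(-1 / 4)
    while (min(H, W) * scales[length(scales)] * f >= params$min_size) {
      scales <- c(scales, scales[length(scales)] * f)
    }
  }
  rf <- receptive_field(net)
  out <- list()
  for (s in scales) {
    hs <- max(2, round(H * s)); ws <- max(2, round(W * s))
    if (min(hs, ws) < rf) next
    level <- if (s == 1) img else resize_bilinear(img, hs, ws)
    o <- net_forward(net, level)
    sel <- select_keypoints_from_maps(o$repeatability, o$reliability,
                                      params$rep_thresh, params$rel_thresh,
                                      params$rep_quantile, params$rel_quantile)
    if (is.null(sel)) next
    pk <- sel$yx
    rows <- sel$rows
    # scale bookkeeping: level coordinate u maps to native
    # u * (n_native - 1) / (n_level - 1) per axis (endpoint-aligned resize)
    fy <- if (nrow(level) > 1) (H - 1) / (nrow(level) - 1) else 1
    fx <- if (ncol(level) > 1) (W - 1) / (ncol(level) - 1) else 1
    D <- matrix(o$descriptors, nrow(level) * ncol(level), net$desc_dim)
    out[[length(out) + 1]] <- list(
      xy = cbind(pk[, "x"] * fx, pk[, "y"] * fy),
      scale = rep(s, nrow(pk)),
      repeatability = o$repeatability[rows],
      reliability = o$reliability[rows],
      descriptors = D[rows, , drop = FALSE])
  }
  if (!length(out)) {
    return(keypoint_set(matrix(0, 0, 2), numeric(0), numeric(0), numeric(0),
                        matrix(0, 0, net$desc_dim), spacing))
  }
  xy <- do.call(rbind, lapply(out, `[[`, "xy"))
  sc <- unlist(lapply(out, `[[`, "scale"))
  rp <- unlist(lapply(out, `[[`, "repeatability"))
  rl <- unlist(lapply(out, `[[`, "reliability"))
  de <- do.call(rbind, lapply(out, `[[`, "descriptors"))
  ord <- order(rp, decreasing = TRUE)
  if (length(ord) > params$top_k) ord <- ord[seq_len(params$top_k)]
  keypoint_set(xy[ord, , drop = FALSE], sc[ord], rp[ord], rl[ord],
               de[ord, , drop = FALSE], spacing)
}

#' Match descriptors by mutual nearest neighbour
#'
#' Euclidean-distance matching with the minimal symmetric pruning: a pair is
#' kept only when each point is the other's nearest neighbour. Swapping the
#' inputs transposes the pairs.
#'
#' @param fixed,moving [keypoint_set()]s.
#' @return A `match_set` data.frame with columns `index_fixed`,
#'   `index_moving`, `distance`.
#' @export
match_descriptors <- function(fixed, moving) {
  empty <- data.frame(index_fixed = integer(0), index_moving = integer(0),
                      distance = numeric(0))
  class(empty) <- c("match_set", "data.frame")
  if (length(fixed) == 0 || length(moving) == 0) return(empty)
  A <- fixed$descriptors; B <- moving$descriptors
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2 <- pmax(d2, 0)
  nn_ab <- max.col(-d2, ties.method = "first")
  nn_ba <- max.col(-t(d2), ties.method = "first")
  i <- which(nn_ba[nn_ab] == seq_len(nrow(A)))
  m <- data.frame(index_fixed = i, index_moving = nn_ab[i],
                  distance = sqrt(d2[cbind(i, nn_ab[i])]))
  class(m) <- c("match_set", "data.frame")
  m
}
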