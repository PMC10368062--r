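# Training objective of the joint detector/descriptor network.
#
# Total loss = repeatability loss + reliability loss.
#   repeatability = cosine-similarity term (corresponding N x N windows of
#                   the two heatmaps should match under the known flow)
#                 + peakiness term (each window should hold a single peak)
#   reliability   = per-query 1 - AP * R - k (1 - R), with AP a quantized,
#                   differentiable average precision over descriptor
#                   distances (the exact AP is the oracle it approximates).
#
# Every loss has a value-only exported form and an internal *_vg form that
# also returns analytic gradients (checked against finite differences in the
# test suite).

#' Loss configuration
#'
#' @param N window size for the repeatability/peakiness terms (default 16).
#' @param k reliability AP threshold in `[0, 1]` (default 0.5).
#' @param ap_bins number of quantization bins of the differentiable AP
#'   (default 25).
#' @param neg_stride stride of the negative-sampling grid for the AP loss;
#'   defaults to `N`.
#' @param exclude_radius pixels around the true match excluded from the
#'   negative set (default 3).
#' @export
loss_config <- function(N = 16L, k = 0.5, ap_bins = 25L, neg_stride = NULL,
                        exclude_radius = 3) {
  assert_that(N >= 2, "N must be >= 2")
  assert_that(k >= 0 && k <= 1, "k must be in [0, 1]")
  list(N = as.integer(N), k = k, ap_bins = as.integer(ap_bins),
       neg_stride = as.integer(neg_stride %||% N),
       exclude_radius = exclude_radius)
}

#' Identity flow field
#' @param H,W image size.
#' @export
flow_identity <- function(H, W) {
  list(x = matrix(rep(0:(W - 1), each = H), H, W),
       y = matrix(rep(0:(H - 1), times = W), H, W),
       valid = matrix(TRUE, H, W))
}

# ---- cosine similarity over corresponding windows -------------------------

cosim_vg <- function(S, S_prime, U, N) {
  H <- nrow(S); W <- ncol(S)
  stopifnot(identical(dim(S), dim(S_prime)))
  # resample S' at the flow targets (bilinear), invalid flow -> excluded
  xs <- as.vector(U$x); ys <- as.vector(U$y)
  samp <- bilinear_sample_masked(S_prime, xs, ys, fill = 0)
  Sp_w <- matrix(samp$value, H, W)
  ok <- matrix(samp$valid & as.vector(U$valid), H, W)

  nby <- H %/% N; nbx <- W %/% N
  assert_that(nby >= 1 && nbx >= 1, "image smaller than one %d x %d window", N, N)
  total <- 0; n_used <- 0
  dS <- matrix(0, H, W); dSp_w <- matrix(0, H, W)
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    ry <- ((by - 1) * N + 1):(by * N); rx <- ((bx - 1) * N + 1):(bx * N)
    m <- ok[ry, rx]
    if (!any(m)) next
    a <- S[ry, rx][m]; b <- Sp_w[ry, rx][m]
    na <- sqrt(sum(a^2)) + 1e-12; nb <- sqrt(sum(b^2)) + 1e-12
    cs <- sum(a * b) / (na * nb)
    total <- total + cs; n_used <- n_used + 1
    da <- (b / (na * nb) - cs * a / na^2)
    db <- (a / (na * nb) - cs * b / nb^2)
    ga <- matrix(0, N, N); gb <- matrix(0, N, N)
    ga[m] <- da; gb[m] <- db
    dS[ry, rx] <- dS[ry, rx] + ga
    dSp_w[ry, rx] <- dSp_w[ry, rx] + gb
  }
  if (n_used == 0) return(list(value = 0, dS = dS, dSp = matrix(0, H, W)))
  value <- 1 - total / n_used
  dS <- -dS / n_used
  dSp_w <- -dSp_w / n_used
  # scatter the resampled gradient back through the bilinear weights
  dSp <- scatter_bilinear(dSp_w, xs, ys, nrow(S_prime), ncol(S_prime),
                          as.vector(ok))
  list(value = value, dS = dS, dSp = dSp)
}

scatter_bilinear <- function(dvals, x, y, H, W, active) {
  v <- as.vector(dvals)[active]
  x <- x[active]; y <- y[active]
  if (!length(v)) return(matrix(0, H, W))
  x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
  cx0 <- clamp(x0, 0, W - 1); cx1 <- clamp(x0 + 1, 0, W - 1)
  cy0 <- clamp(y0, 0, H - 1); cy1 <- clamp(y0 + 1, 0, H - 1)
  idx <- c(cy0 + 1 + cx0 * H, cy0 + 1 + cx1 * H,
           cy1 + 1 + cx0 * H, cy1 + 1 + cx1 * H)
  w <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
  acc <- rowsum(w * rep(v, 4), idx)
  out <- numeric(H * W)
  out[as.integer(rownames(acc))] <- acc
  matrix(out, H, W)
}

#' Cosine-similarity loss between corresponding heatmap windows
#'
#' `1 - mean` over non-overlapping `N x N` windows of the cosine similarity
#' between the flattened fixed-image window and the flow-resampled moving
#' window. Windows with no valid flow are excluded from the mean.
#'
#' @param S,S_prime repeatability heatmaps (matrices of equal size).
#' @param U flow field from `S` coordinates to `S_prime` coordinates (see
#'   [flow_identity()]).
#' @param N window size.
#' @return Scalar in `[0, 2]`.
#' @export
cosim_loss <- function(S, S_prime, U, N = 16L) cosim_vg(S, S_prime, U, N)$value

# ---- peakiness over all overlapping windows -------------------------------

# Box-filter sums over all N x N windows anchored at top-left (i, j),
# i in 0..H-N, j in 0..W-N, via 2D cumulative sums.
window_sums <- function(S, N) {
  H <- nrow(S); W <- ncol(S)
  C <- matrix(0, H + 1, W + 1)
  C[2:(H + 1), 2:(W + 1)] <- t(apply(apply(S, 2, cumsum), 1, cumsum))
  i <- 1:(H - N + 1); j <- 1:(W - N + 1)
  C[i + N, j + N, drop = FALSE] - C[i, j + N, drop = FALSE] -
    C[i + N, j, drop = FALSE] + C[i, j, drop = FALSE]
}

window_max <- function(S, N) {
  # running max along rows then columns (window anchored at top-left)
  H <- nrow(S); W <- ncol(S)
  M <- S
  for (k in 1:(N - 1)) {
    M[1:(H - k), ] <- pmax(M[1:(H - k), , drop = FALSE],
                           S[(1 + k):H, , drop = FALSE])
  }
  M <- M[1:(H - N + 1), , drop = FALSE]
  out <- M
  for (k in 1:(N - 1)) {
    out[, 1:(W - k)] <- pmax(out[, 1:(W - k), drop = FALSE],
                             M[, (1 + k):W, drop = FALSE])
  }
  out[, 1:(W - N + 1), drop = FALSE]
}

peakiness_vg <- function(S, N) {
  H <- nrow(S); W <- ncol(S)
  assert_that(H >= N && W >= N, "heatmap smaller than the window")
  mx <- window_max(S, N)
  sm <- window_sums(S, N)
  nw <- (H - N + 1) * (W - N + 1)
  value <- 1 - (sum(mx) - sum(sm) / N^2) / nw

  # gradient: for each window, +1 split among its maximizers, -1/N^2 for
  # every member; loss = 1 - mean so signs flip
  ties <- matrix(0, H - N + 1, W - N + 1)
  for (u in 0:(N - 1)) for (v in 0:(N - 1)) {
    blk <- S[(1 + u):(H - N + 1 + u), (1 + v):(W - N + 1 + v), drop = FALSE]
    ties <- ties + (blk >= mx - 1e-12)
  }
  dS <- matrix(0, H, W)
  inv_ties <- 1 / ties
  for (u in 0:(N - 1)) for (v in 0:(N - 1)) {
    blk <- S[(1 + u):(H - N + 1 + u), (1 + v):(W - N + 1 + v), drop = FALSE]
    hit <- (blk >= mx - 1e-12) * inv_ties
    dS[(1 + u):(H - N + 1 + u), (1 + v):(W - N + 1 + v)] <-
      dS[(1 + u):(H - N + 1 + u), (1 + v):(W - N + 1 + v)] + hit - 1 / N^2
  }
  list(value = value, dS = -dS / nw)
}

#' Peakiness loss
#'
#' `1 - mean` over all overlapping `N x N` windows of `max - mean` of the
#' window. Constant heatmaps score 1 (no peaks); a single peak per window
#' drives the loss toward `1 - (1 - 1/N^2)`.
#'
#' @param S heatmap matrix with values in `[0, 1]`.
#' @param N window size.
#' @return Scalar in `[0, 1]`.
#' @export
peakiness_loss <- function(S, N = 16L) peakiness_vg(S, N)$value

#' Repeatability loss
#'
#' `cosim_loss(S, S', U) + (peakiness_loss(S) + peakiness_loss(S')) / 2`.
#'
#' @inheritParams cosim_loss
#' @export
repeatability_loss <- function(S, S_prime, U, N = 16L) {
  cosim_loss(S, S_prime, U, N) +
    0.5 * (peakiness_loss(S, N) + peakiness_loss(S_prime, N))
}

# ---- average precision ----------------------------------------------------

#' Exact average precision of a single-positive ranked list
#'
#' The brute-force oracle for the differentiable AP: candidates are ranked by
#' ascending Euclidean distance to the query; with one relevant item at rank
#' r, AP = 1/r. Distance ties are broken by candidate index (the positive
#' counts as index 0, negatives follow in order).
#'
#' @param query_descriptor numeric vector.
#' @param true_match numeric vector (the positive).
#' @param negatives matrix with one negative per row (may have zero rows).
#' @return AP in `(0, 1]`.
#' @export
exact_ap <- function(query_descriptor, true_match, negatives = NULL) {
  d_pos <- sqrt(sum((query_descriptor - true_match)^2))
  if (is.null(negatives) || NROW(negatives) == 0) return(1)
  negatives <- matrix(negatives, ncol = length(query_descriptor))
  d_neg <- sqrt(rowSums(sweep(negatives, 2, query_descriptor)^2))
  rank <- 1 + sum(d_neg < d_pos)  # ties: positive has the smaller index
  1 / rank
}

# Quantized (differentiable) AP for one query. `d` distances to all
# candidates, `pos` index of the (single) positive.
#
# Triangular-kernel soft histogram over the observed distance range (bins
# spanning [min d, max d]; descriptor distances concentrate in a narrow
# band, so a fixed-range histogram could not resolve ranks). With a single
# relevant item the AP is the expected precision at the positive's rank;
# per bin t, with c_t the negative mass strictly below the bin and s_t the
# negative mass sharing it, the positive's contribution is the expected
# reciprocal rank under a uniform tie-break,
#   g(c, s) = (digamma(2 + c + s) - digamma(1 + c)) / (1 + s),
# which is 1 / (1 + c) for an isolated positive (s = 0) and the mean of
# 1/(1+c+k), k = 0..s, at integer ties. Hence the quantized AP converges to
# exact_ap as bins grow, and an all-tied candidate set scores the expected
# AP of a random ranking. Returns the value and the gradient w.r.t. every
# distance, including the dependence of the bin edges on min(d) and max(d).
soft_ap_vg <- function(d, pos, bins) {
  nb <- bins
  m <- length(d)
  lo <- min(d); hi <- max(d)
  if (hi - lo < 1e-12 || nb < 2) {
    # complete tie: expected AP of a random ranking with one positive
    return(list(value = sum(1 / (1:m)) / m, dd = numeric(m)))
  }
  delta <- (hi - lo) / (nb - 1)
  centers <- lo + (0:(nb - 1)) * delta
  # h[j, t] = triangular assignment of distance j to bin t
  diff <- abs(outer(d, centers, `-`)) / delta
  h <- pmax(1 - diff, 0)
  pos_t <- h[pos, ]
  neg_t <- colSums(h) - pos_t
  below <- cumsum(neg_t) - neg_t
  g <- (digamma(2 + below + neg_t) - digamma(1 + below)) / (1 + neg_t)
  ap <- sum(pos_t * g)

  # gradients w.r.t. histogram masses
  dg_dc <- (trigamma(2 + below + neg_t) - trigamma(1 + below)) / (1 + neg_t)
  dg_ds <- trigamma(2 + below + neg_t) / (1 + neg_t) - g / (1 + neg_t)
  A <- pos_t * dg_dc
  # neg mass in bin t' feeds c_t for t > t' and s_t at t' = t
  dneg <- rev(cumsum(rev(A))) - A + pos_t * dg_ds
  dh <- matrix(rep(dneg, each = m), m, nb)
  dh[pos, ] <- g
  # chain through the triangular kernel: dh/dd = -sign(d - c)/delta inside
  sgn <- sign(outer(d, centers, `-`))
  inside <- (diff < 1) & (diff > 0)
  dd <- rowSums(dh * (-sgn / delta) * inside)
  # the bin layout itself depends on lo = min(d) and hi = max(d):
  # c_t = lo (1 - t/(nb-1)) + hi t/(nb-1), delta = (hi - lo)/(nb-1)
  u <- sgn * diff
  alpha <- 1 - (0:(nb - 1)) / (nb - 1)
  beta <- (0:(nb - 1)) / (nb - 1)
  dh_dlo <- sgn * sweep(-u / (nb - 1), 2, alpha, `+`) / delta
  dh_dhi <- sgn * sweep(u / (nb - 1), 2, beta, `+`) / delta
  dd[which.min(d)] <- dd[which.min(d)] + sum(dh * dh_dlo * inside)
  dd[which.max(d)] <- dd[which.max(d)] + sum(dh * dh_dhi * inside)
  list(value = ap, dd = dd)
}

# Sample query pixels / negative grid and compute the AP of each query.
# X, Xp: (H*W) x D matrices of unit descriptors; U flow; cfg loss_config.
# Returns per-query APs plus everything needed to push gradients back.
ap_machinery <- function(X, Xp, U, H, W, Hp, Wp, cfg) {
  stride <- cfg$neg_stride
  qy <- seq(stride %/% 2, H - 1, by = stride)
  qx <- seq(stride %/% 2, W - 1, by = stride)
  qpix <- as.matrix(expand.grid(y = qy, x = qx))
  ux <- U$x[qpix[, "y"] + 1 + qpix[, "x"] * H]
  uy <- U$y[qpix[, "y"] + 1 + qpix[, "x"] * H]
  uv <- U$valid[qpix[, "y"] + 1 + qpix[, "x"] * H]
  tx <- round_half_up(ux); ty <- round_half_up(uy)
  ok <- uv & tx >= 0 & tx <= Wp - 1 & ty >= 0 & ty <= Hp - 1
  assert_that(any(ok), "no valid correspondences for the AP loss")
  qpix <- qpix[ok, , drop = FALSE]; tx <- tx[ok]; ty <- ty[ok]
  q_rows <- qpix[, "y"] + 1 + qpix[, "x"] * H
  t_rows <- ty + 1 + tx * Hp

  ny <- seq(stride %/% 2, Hp - 1, by = stride)
  nx <- seq(stride %/% 2, Wp - 1, by = stride)
  ngrid <- as.matrix(expand.grid(y = ny, x = nx))
  n_rows <- ngrid[, "y"] + 1 + ngrid[, "x"] * Hp

  nq <- nrow(qpix)
  aps <- numeric(nq)
  per_query <- vector("list", nq)
  for (qi in seq_len(nq)) {
    keep <- abs(ngrid[, "y"] - ty[qi]) > cfg$exclude_radius |
            abs(ngrid[, "x"] - tx[qi]) > cfg$exclude_radius
    cand_rows <- c(t_rows[qi], n_rows[keep])
    q <- X[q_rows[qi], ]
    C <- Xp[cand_rows, , drop = FALSE]
    diffs <- sweep(C, 2, q)
    dists <- sqrt(rowSums(diffs^2))
    sa <- soft_ap_vg(dists, 1L, cfg$ap_bins)
    aps[qi] <- sa$value
    per_query[[qi]] <- list(q_row = q_rows[qi], cand_rows = cand_rows,
                            diffs = diffs, dists = dists, dd = sa$dd)
  }
  list(aps = aps, per_query = per_query, q_rows = q_rows)
}

# Push d(loss)/d(AP_q) through the distance computations into dX, dXp.
ap_backward <- function(mach, dap, D, nX, nXp) {
  dX <- matrix(0, nX, D); dXp <- matrix(0, nXp, D)
  for (qi in seq_along(mach$per_query)) {
    pq <- mach$per_query[[qi]]
    w <- dap[qi] * pq$dd / pmax(pq$dists, 1e-8)   # d dist/d diff = diff/dist
    gc_ <- pq$diffs * w
    dXp[pq$cand_rows, ] <- dXp[pq$cand_rows, ] + gc_
    dX[pq$q_row, ] <- dX[pq$q_row, ] - colSums(gc_)
  }
  list(dX = dX, dXp = dXp)
}

as_desc_matrix <- function(X) {
  if (is.array(X) && length(dim(X)) == 3) {
    d <- dim(X)
    list(m = matrix(X, d[1] * d[2], d[3]), H = d[1], W = d[2])
  } else stop_oct("descriptors must be an H x W x D array")
}

#' Descriptor (average precision) loss
#'
#' Mean over sampled query pixels of `1 - AP`, where AP is the quantized
#' differentiable average precision of the query's descriptor against its
#' true correspondence (under the flow) and a stride-grid of negatives from
#' the second image. Converges to [exact_ap()] as `ap_bins` grows.
#'
#' @param X,X_prime descriptor arrays `H x W x D` (unit-norm per pixel).
#' @param U flow field from image 1 to image 2.
#' @param config a [loss_config()].
#' @export
ap_loss <- function(X, X_prime, U, config = loss_config()) {
  a <- as_desc_matrix(X); b <- as_desc_matrix(X_prime)
  mach <- ap_machinery(a$m, b$m, U, a$H, a$W, b$H, b$W, config)
  mean(1 - mach$aps)
}

#' Reliability loss
#'
#' Mean over sampled query pixels of `1 - AP * R - k (1 - R)`: reliable
#' pixels (AP above `k`) are pushed toward `R = 1`, unreliable ones toward
#' `R = 0`; at `AP = k` the value is `1 - k` regardless of `R`.
#'
#' @inheritParams ap_loss
#' @param R reliability heatmap of the first image (`H x W` in `[0, 1]`).
#' @export
reliability_loss <- function(X, X_prime, R, U, config = loss_config()) {
  a <- as_desc_matrix(X); b <- as_desc_matrix(X_prime)
  mach <- ap_machinery(a$m, b$m, U, a$H, a$W, b$H, b$W, config)
  rq <- as.vector(R)[mach$q_rows]
  mean(1 - mach$aps * rq - config$k * (1 - rq))
}

#' Total training loss
#'
#' `repeatability_loss + reliability_loss`, the full objective of the
#' detector/descriptor network.
#'
#' @param outputs,outputs_prime `network_outputs` for the two images of a
#'   training pair (see [net_forward()]).
#' @param U flow field from image 1 to image 2.
#' @param config a [loss_config()].
#' @return Scalar; attributes `repeatability` and `reliability` carry the two
#'   terms.
#' @export
total_loss <- function(outputs, outputs_prime, U, config = loss_config()) {
  lrep <- repeatability_loss(outputs$repeatability, outputs_prime$repeatability,
                             U, config$N)
  lrel <- reliability_loss(outputs$descriptors, outputs_prime$descriptors,
                           outputs$reliability, U, config)
  structure(lrep + lrel, repeatability = lrep, reliability = lrel)
}

# Full objective with gradients w.r.t. S, S', R, X, X' — used by training.
total_loss_vg <- function(outputs, outputs_prime, U, config = loss_config()) {
  S <- outputs$repeatability; Sp <- outputs_prime$repeatability
  cv <- cosim_vg(S, Sp, U, config$N)
  p1 <- peakiness_vg(S, config$N)
  p2 <- peakiness_vg(Sp, config$N)
  lrep <- cv$value + 0.5 * (p1$value + p2$value)

  a <- as_desc_matrix(outputs$descriptors)
  b <- as_desc_matrix(outputs_prime$descriptors)
  mach <- ap_machinery(a$m, b$m, U, a$H, a$W, b$H, b$W, config)
  rq <- as.vector(outputs$reliability)[mach$q_rows]
  nq <- length(mach$aps)
  lrel <- mean(1 - mach$aps * rq - config$k * (1 - rq))
  # d lrel / d AP_q = -rq / nq ; d lrel / d R_q = (-AP_q + k) / nq
  dap <- -rq / nq
  gr <- ap_backward(mach, dap, ncol(a$m), nrow(a$m), nrow(b$m))
  dR <- matrix(0, a$H, a$W)
  dR[mach$q_rows] <- dR[mach$q_rows] + (-mach$aps + config$k) / nq

  list(value = lrep + lrel, repeatability = lrep, reliability = lrel,
       dS = cv$dS + 0.5 * p1$dS,
       dSp = cv$dSp + 0.5 * p2$dS,
       dR = dR,
       dX = gr$dX, dXp = gr$dXp,
       mean_ap = mean(mach$aps))
}
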