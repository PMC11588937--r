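#' Optical-flow propagation parameters
#'
#' Parameters of the sparse-to-dense Lucas-Kanade mask propagation.
#'
#' @param of_sigma Flow smoothness regularization added to the normal
#'   equations of the Lucas-Kanade solve (default 0.04).
#' @param fgs_lambda Regularization strength of the edge-aware sparse-to-dense
#'   interpolation; the spatial kernel scale is `sqrt(fgs_lambda)/24` px
#'   (default 5000).
#' @param fgs_sigma Intensity sigma of the edge-aware interpolation, on the
#'   8-bit gray scale (default 3).
#' @param ref_stride Spacing of candidate reference frames: every
#'   `ref_stride`-th segmented frame (plus frame 0) may serve as reference
#'   (default 5).
#' @param smooth_kernel Gaussian kernel size in pixels for mask smoothing
#'   (odd, default 15; the Gaussian sigma is `smooth_kernel / 12`).
#' @param binarize_at Level at which smoothed masks are re-binarized
#'   (default 0.5).
#' @param lk_window Lucas-Kanade window size in pixels (odd).
#' @param lk_levels Number of pyramid levels.
#' @param lk_iters Maximum Lucas-Kanade iterations per level.
#' @param grid_spacing Spacing of the regular feature grid inside the mask
#'   bounding boxes, in pixels.
#' @param n_corners Number of additional strong corners tracked.
#' @param dense_stride Node spacing of the sparse-to-dense interpolation grid.
#' @return Object of class `of_params`.
#' @export
of_params <- function(of_sigma = 0.04, fgs_lambda = 5000, fgs_sigma = 3,
                      ref_stride = 5L, smooth_kernel = 15L, binarize_at = 0.5,
                      lk_window = 11L, lk_levels = 3L, lk_iters = 10L,
                      grid_spacing = 6L, n_corners = 80L, dense_stride = 4L) {
  if (any(c(of_sigma, fgs_lambda, fgs_sigma, ref_stride, smooth_kernel,
            binarize_at, lk_window, lk_levels, lk_iters, grid_spacing,
            dense_stride) <= 0))
    stop("of_params values must be strictly positive")
  if (smooth_kernel %% 2 == 0) stop("smooth_kernel must be odd")
  if (lk_window %% 2 == 0) stop("lk_window must be odd")
  structure(list(of_sigma = of_sigma, fgs_lambda = fgs_lambda,
                 fgs_sigma = fgs_sigma, ref_stride = as.integer(ref_stride),
                 smooth_kernel = as.integer(smooth_kernel),
                 binarize_at = binarize_at, lk_window = as.integer(lk_window),
                 lk_levels = as.integer(lk_levels),
                 lk_iters = as.integer(lk_iters),
                 grid_spacing = as.integer(grid_spacing),
                 n_corners = as.integer(n_corners),
                 dense_stride = as.integer(dense_stride)),
            class = "of_params")
}

grad_x <- function(img) {
  w <- ncol(img)
  (img[, c(2:w, w), drop = FALSE] - img[, c(1, 1:(w - 1)), drop = FALSE]) / 2
}

grad_y <- function(img) {
  h <- nrow(img)
  (img[c(2:h, h), , drop = FALSE] - img[c(1, 1:(h - 1)), , drop = FALSE]) / 2
}

# Shi-Tomasi corners: local maxima of the smaller structure-tensor eigenvalue,
# greedily thinned to a minimum mutual distance. Returns n x 2 matrix of
# 0-based (x, y) coordinates.
strong_corners <- function(img, n_max = 80L, min_dist = 6) {
  Ix <- grad_x(img); Iy <- grad_y(img)
  Sxx <- as.matrix(EBImage::gblur(Ix * Ix, sigma = 2))
  Syy <- as.matrix(EBImage::gblur(Iy * Iy, sigma = 2))
  Sxy <- as.matrix(EBImage::gblur(Ix * Iy, sigma = 2))
  resp <- 0.5 * ((Sxx + Syy) - sqrt((Sxx - Syy)^2 + 4 * Sxy^2))
  resp[c(1:3, (nrow(resp) - 2):nrow(resp)), ] <- 0
  resp[, c(1:3, (ncol(resp) - 2):ncol(resp))] <- 0
  ord <- order(resp, decreasing = TRUE)
  ord <- ord[resp[ord] > 1e-6][seq_len(min(2000L, sum(resp > 1e-6)))]
  if (!length(ord)) return(matrix(numeric(0), 0, 2))
  ys <- (ord - 1) %% nrow(img)
  xs <- (ord - 1) %/% nrow(img)
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (i in seq_along(ord)) {
    if (length(keep_x) >= n_max) break
    if (!length(keep_x) ||
        min((keep_x - xs[i])^2 + (keep_y - ys[i])^2) >= min_dist^2) {
      keep_x <- c(keep_x, xs[i]); keep_y <- c(keep_y, ys[i])
    }
  }
  cbind(x = keep_x, y = keep_y)
}

# Regular grid of feature points inside the (padded) bounding boxes of the
# mask labels; whole-image grid when no mask is supplied.
feature_grid <- function(dim_hw, mask = NULL, spacing = 6L, pad = 6L) {
  h <- dim_hw[1]; w <- dim_hw[2]
  boxes <- list()
  if (!is.null(mask) && any(mask > 0)) {
    for (lab in sort(unique(mask[mask > 0]))) {
      idx <- which(mask == lab)
      r <- (idx - 1) %% h; c <- (idx - 1) %/% h
      boxes[[length(boxes) + 1]] <- c(max(min(c) - pad, 2), min(max(c) + pad, w - 3),
                                      max(min(r) - pad, 2), min(max(r) + pad, h - 3))
    }
  } else {
    boxes[[1]] <- c(2, w - 3, 2, h - 3)
  }
  pts <- unique(do.call(rbind, lapply(boxes, function(b) {
    xs <- seq(b[1], b[2], by = spacing)
    ys <- seq(b[3], b[4], by = spacing)
    cbind(x = rep(xs, each = length(ys)), y = rep(ys, length(xs)))
  })))
  pts
}

# Pyramidal iterative Lucas-Kanade tracking of sparse points from `ref` to
# `cur`. pts: n x 2 matrix of 0-based (x, y) positions in the reference frame.
# Returns list(pts, disp = n x 2 displacements, valid = logical).
lk_track <- function(ref, cur, pts, params = of_params()) {
  n <- nrow(pts)
  if (n == 0) return(list(pts = pts, disp = matrix(0, 0, 2), valid = logical(0)))
  hw <- (params$lk_window - 1) / 2
  nw <- params$lk_window^2
  dxo <- rep(-hw:hw, times = params$lk_window)
  dyo <- rep(-hw:hw, each = params$lk_window)
  levels <- params$lk_levels
  while (levels > 1 && min(dim(ref)) / 2^(levels - 1) < (2 * hw + 4))
    levels <- levels - 1
  pyr_r <- list(ref); pyr_c <- list(cur)
  for (l in seq_len(levels - 1)) {
    pyr_r[[l + 1]] <- pyr_down(pyr_r[[l]])
    pyr_c[[l + 1]] <- pyr_down(pyr_c[[l]])
  }
  d <- matrix(0, n, 2)
  ok <- rep(TRUE, n)
  reg <- nw * params$of_sigma^2
  rms <- rep(Inf, n)
  for (l in levels:1) {
    R <- pyr_r[[l]]; C <- pyr_c[[l]]
    sc <- 2^-(l - 1)
    px <- pts[, 1] * sc; py <- pts[, 2] * sc
    X <- matrix(px, n, nw) + matrix(rep(dxo, each = n), n, nw)
    Y <- matrix(py, n, nw) + matrix(rep(dyo, each = n), n, nw)
    Tref <- matrix(bilinear_sample(R, X, Y), n, nw)
    Gx <- matrix(bilinear_sample(grad_x(R), X, Y), n, nw)
    Gy <- matrix(bilinear_sample(grad_y(R), X, Y), n, nw)
    gxx <- rowSums(Gx * Gx) + reg
    gyy <- rowSums(Gy * Gy) + reg
    gxy <- rowSums(Gx * Gy)
    det <- gxx * gyy - gxy^2
    ok <- ok & det > 1e-10 & (gxx + gyy) > (2.5 * reg)
    for (it in seq_len(params$lk_iters)) {
      Tcur <- matrix(bilinear_sample(C, X + d[, 1], Y + d[, 2]), n, nw)
      e <- Tref - Tcur
      bx <- rowSums(e * Gx); by <- rowSums(e * Gy)
      du <- (gyy * bx - gxy * by) / det
      dv <- (gxx * by - gxy * bx) / det
      du[!ok] <- 0; dv[!ok] <- 0
      d[, 1] <- d[, 1] + du; d[, 2] <- d[, 2] + dv
      if (max(abs(c(du, dv))) < 0.01) break
    }
    if (l == 1) {
      Tcur <- matrix(bilinear_sample(C, X + d[, 1], Y + d[, 2]), n, nw)
      rms <- sqrt(rowMeans((Tref - Tcur)^2))
    } else {
      d <- d * 2
    }
  }
  inb <- (pts[, 1] + d[, 1]) >= 0 & (pts[, 1] + d[, 1]) <= (ncol(ref) - 1) &
    (pts[, 2] + d[, 2]) >= 0 & (pts[, 2] + d[, 2]) <= (nrow(ref) - 1)
  valid <- ok & inb & is.finite(rms) & rms < 0.3 &
    abs(d[, 1]) < ncol(ref) / 2 & abs(d[, 2]) < nrow(ref) / 2
  list(pts = pts, disp = d, valid = valid)
}

# Bilinearly upsample a coarse node field (nodes every `stride` px, starting
# at pixel 0) to the full image resolution.
upsample_field <- function(nodes, stride, h, w) {
  xi <- (seq_len(w) - 1) / stride
  yi <- (seq_len(h) - 1) / stride
  matrix(bilinear_sample(nodes, rep(xi, each = h), rep(yi, w)), h, w)
}

#' Dense optical flow between two frames
#'
#' Sparse features (a regular grid inside the reference mask's bounding boxes
#' plus strong corners) are tracked from the reference frame to the current
#' frame by pyramidal iterative Lucas-Kanade, and the sparse motion vectors
#' are interpolated to a per-pixel field by an edge-aware weighting
#' (Gaussian in space, Gaussian in local mean intensity difference) governed
#' by `fgs_lambda` and `fgs_sigma`. The field maps reference coordinates to
#' current-frame coordinates. Featureless (near-constant) frame pairs yield a
#' zero field with a warning.
#'
#' @param ref,cur Grayscale frames (matrices of equal shape, values in `[0,1]`).
#' @param params An [of_params()].
#' @param ref_mask Optional label mask of the reference frame used to place
#'   the feature grid.
#' @return List with matrices `u` (horizontal) and `v` (vertical)
#'   displacement in pixels, and attribute `n_features` (valid tracks used).
#' @export
dense_flow <- function(ref, cur, params = of_params(), ref_mask = NULL) {
  if (!all(dim(ref) == dim(cur))) stop("frames must have the same shape")
  h <- nrow(ref); w <- ncol(ref)
  pts <- feature_grid(c(h, w), ref_mask, params$grid_spacing)
  crn <- strong_corners(ref, params$n_corners)
  if (nrow(crn)) pts <- unique(rbind(pts, crn))
  tr <- lk_track(ref, cur, pts, params)
  if (!any(tr$valid)) {
    warning("featureless frames: returning zero flow field")
    z <- matrix(0, h, w)
    return(structure(list(u = z, v = matrix(0, h, w)), n_features = 0L))
  }
  fx <- tr$pts[tr$valid, 1]; fy <- tr$pts[tr$valid, 2]
  fu <- tr$disp[tr$valid, 1]; fv <- tr$disp[tr$valid, 2]
  s <- params$dense_stride
  xs <- seq(0, w - 1, by = s); ys <- seq(0, h - 1, by = s)
  nx <- length(xs); ny <- length(ys)
  refb <- as.matrix(EBImage::gblur(ref, sigma = 2))
  node_int <- as.vector(refb[ys + 1, xs + 1])
  feat_int <- bilinear_sample(refb, fx, fy)
  NX <- rep(xs, each = ny); NY <- rep(ys, times = nx)
  sig_s <- sqrt(params$fgs_lambda) / 24
  sig_i <- 4 * params$fgs_sigma / 255
  wgt <- exp(-(outer(NX, fx, `-`)^2 + outer(NY, fy, `-`)^2) / (2 * sig_s^2) -
               outer(node_int, feat_int, `-`)^2 / (2 * sig_i^2))
  um <- stats::median(fu); vm <- stats::median(fv)
  eps <- 1e-6
  wsum <- rowSums(wgt) + eps
  un <- matrix((wgt %*% fu + eps * um) / wsum, ny, nx)
  vn <- matrix((wgt %*% fv + eps * vm) / wsum, ny, nx)
  structure(list(u = upsample_field(un, s, h, w),
                 v = upsample_field(vn, s, h, w)),
            n_features = sum(tr$valid))
}

#' Select the reference frame for propagation
#'
#' Among the already-segmented frames whose 0-based index is divisible by
#' `ref_stride` (frame 0 is always a candidate), returns the one whose pixel
#' intensities have the highest zero-normalized cross-correlation with the
#' current frame; ties are broken towards the most recent index. The selected
#' frame need not be the direct predecessor, which helps recover correct
#' muscle shapes after the transition from exercise back into rest.
#'
#' @param t Current 0-based frame index (>= 1).
#' @param segmented Integer vector of already-segmented 0-based frame indices.
#' @param video Numeric array `height x width x n_frames`.
#' @param ref_stride Candidate spacing in frames.
#' @return The selected 0-based reference frame index.
#' @export
select_reference_frame <- function(t, segmented, video, ref_stride = 5L) {
  if (t < 1) stop("t must be >= 1")
  cand <- sort(unique(segmented[(segmented %% ref_stride == 0 |
                                   segmented == 0) & segmented < t]))
  if (!length(cand)) stop("no reference candidates available")
  f <- as.vector(video[, , t + 1])
  sdf <- stats::sd(f)
  sc <- vapply(cand, function(i) {
    g <- as.vector(video[, , i + 1])
    if (sdf == 0 || stats::sd(g) == 0) return(0)
    stats::cor(f, g)
  }, numeric(1))
  cand[max(which(sc >= max(sc) - 1e-12))]
}

#' Warp a label mask along a dense flow field
#'
#' Backward warping: each label's indicator is sampled at the preimage of
#' every pixel under the flow (bilinear interpolation, out-of-frame samples
#' are background), smoothed with a Gaussian filter of size `smooth_kernel`,
#' and re-binarized at `binarize_at`; where several labels exceed the level,
#' the strongest wins, so labels remain in `{0, 1, 2, 3}`.
#'
#' @param mask Integer label mask.
#' @param flow A [dense_flow()] result aligned with the mask.
#' @param params An [of_params()].
#' @return Warped integer label mask.
#' @export
warp_mask <- function(mask, flow, params = of_params()) {
  if (!all(dim(mask) == dim(flow$u))) stop("mask and flow must have the same shape")
  h <- nrow(mask); w <- ncol(mask)
  sx <- as.vector(matrix(seq_len(w) - 1, h, w, byrow = TRUE) - flow$u)
  sy <- as.vector(matrix(seq_len(h) - 1, h, w) - flow$v)
  sigma <- params$smooth_kernel / 12
  best_val <- matrix(0, h, w)
  out <- matrix(0L, h, w)
  for (lab in muscle_labels()) {
    if (!any(mask == lab)) next
    ind <- matrix(bilinear_sample((mask == lab) * 1, sx, sy, outside = "zero"),
                  h, w)
    sm <- as.matrix(EBImage::gblur(ind, sigma = sigma, boundary = "replicate"))
    sel <- sm > params$binarize_at & sm > best_val
    out[sel] <- lab
    best_val <- pmax(best_val, sm)
  }
  out
}

#' Temporal post-processing of a propagated mask
#'
#' For each muscle label, keeps only the connected component maximizing
#' (area + overlap with the previous frame's component of that label) and
#' fills interior holes, assuming each muscle is a single uniform surface.
#' Pixels of other labels are never overwritten. Idempotent.
#'
#' @param mask Integer label mask to clean.
#' @param prev Label mask of the previous frame (same shape).
#' @return Cleaned integer label mask.
#' @export
postprocess_mask <- function(mask, prev) {
  if (!all(dim(mask) == dim(prev))) stop("masks must have the same shape")
  out <- mask
  for (lab in muscle_labels()) {
    bw <- out == lab
    if (!any(bw)) next
    cc <- as.matrix(EBImage::bwlabel(bw))
    K <- max(cc)
    if (K > 1) {
      areas <- tabulate(cc[cc > 0], nbins = K)
      ov <- tabulate(cc[prev == lab], nbins = K)
      keep <- which.max(areas + ov)
      out[bw & cc != keep] <- 0L
      bw <- cc == keep
    }
    filled <- as.matrix(EBImage::fillHull(bw * 1)) > 0
    out[filled & out == 0L] <- lab
  }
  out
}

#' Propagate an initial segmentation through a video
#'
#' Starting from the frame-0 label mask, every subsequent frame's mask is
#' obtained by selecting a reference frame ([select_reference_frame()]),
#' computing dense optical flow from the reference to the current frame
#' ([dense_flow()]), warping the reference's mask ([warp_mask()], which also
#' smooths and re-binarizes), and post-processing against the previous
#' frame's mask ([postprocess_mask()]). Deterministic given its inputs.
#'
#' @param video Numeric array `height x width x n_frames`, values in `[0,1]`.
#' @param initial_mask Integer label mask for frame 0.
#' @param params An [of_params()].
#' @return Integer array of propagated label masks, same shape as `video`.
#' @export
propagate <- function(video, initial_mask, params = of_params()) {
  d <- dim(video)
  if (length(d) != 3) stop("video must be a 3-D array")
  if (!all(dim(initial_mask) == d[1:2]))
    stop("initial_mask shape does not match the video frames")
  masks <- array(0L, dim = d)
  masks[, , 1] <- as.integer(initial_mask)
  segmented <- 0L
  for (t0 in seq_len(d[3] - 1L)) {
    ref0 <- select_reference_frame(t0, segmented, video, params$ref_stride)
    flow <- dense_flow(video[, , ref0 + 1L], video[, , t0 + 1L], params,
                       ref_mask = masks[, , ref0 + 1L])
    wm <- warp_mask(masks[, , ref0 + 1L], flow, params)
    masks[, , t0 + 1L] <- postprocess_mask(wm, masks[, , t0])
    segmented <- c(segmented, t0)
  }
  masks
}
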