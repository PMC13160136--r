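# Patchwise image registration: normalized cross-correlation template
# matching (FFT-accelerated), corner keypoint matching, robust affine fits,
# and single/multi-scale optic-flow fields.
#
# The matching metric throughout is normalized cross-correlation, which is
# robust to the brightness/contrast drift common over long SBEM runs.

# Normalized cross-correlation of `template` over every valid placement in
# `search`. Returns a matrix of size (dim(search) - dim(template) + 1);
# entries where the local window has (near-)zero variance are NA.
ncc_map <- function(search, template) {
  ns <- dim(search); nt <- dim(template)
  if (any(nt > ns)) stop("template larger than search image")
  n <- prod(nt)
  tmu <- mean(template); tsd <- sqrt(max(mean(template^2) - tmu^2, 0))
  py <- ns[1]; px <- ns[2]
  tp <- matrix(0, py, px)
  tp[seq_len(nt[1]), seq_len(nt[2])] <- template
  cross <- Re(stats::fft(stats::fft(search) * Conj(stats::fft(tp)),
                         inverse = TRUE)) / (py * px)
  vy <- ns[1] - nt[1] + 1; vx <- ns[2] - nt[2] + 1
  cross <- cross[seq_len(vy), seq_len(vx), drop = FALSE]
  s1 <- win_sum(search, nt)
  s2 <- win_sum(search^2, nt)
  smu <- s1 / n
  svar <- pmax(s2 / n - smu^2, 0)
  denom <- n * sqrt(svar) * tsd
  num <- cross - n * smu * tmu
  out <- num / denom
  out[denom < 1e-8 * n] <- NA_real_
  if (tsd < 1e-8) out[] <- NA_real_
  out
}

# Sliding-window sums over windows of size `wt` via 2-D cumulative sums.
win_sum <- function(m, wt) {
  cs <- apply(m, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  p <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  p[-1, -1] <- cs
  vy <- nrow(m) - wt[1] + 1; vx <- ncol(m) - wt[2] + 1
  iy <- seq_len(vy); ix <- seq_len(vx)
  p[iy + wt[1], ix + wt[2], drop = FALSE] -
    p[iy, ix + wt[2], drop = FALSE] -
    p[iy + wt[1], ix, drop = FALSE] +
    p[iy, ix, drop = FALSE]
}

# Quadratic sub-pixel refinement of a correlation peak: least-squares 2-D
# quadratic over the 3x3 neighborhood, falling back to separable 1-D
# parabolas when the fit is not a strict maximum. Returns fractional offsets
# in [-0.5, 0.5] per axis (0 at map borders).
subpixel_peak <- function(cmap, py, px) {
  refine_1d <- function(l, c, r) {
    if (is.na(l) || is.na(r)) return(0)
    den <- l + r - 2 * c
    if (den >= -1e-12) return(0)
    clamp((l - r) / (2 * den), -0.5, 0.5)
  }
  sep <- function() {
    fy <- 0; fx <- 0
    if (py > 1 && py < nrow(cmap)) {
      fy <- refine_1d(cmap[py - 1, px], cmap[py, px], cmap[py + 1, px])
    }
    if (px > 1 && px < ncol(cmap)) {
      fx <- refine_1d(cmap[py, px - 1], cmap[py, px], cmap[py, px + 1])
    }
    c(fy, fx)
  }
  if (py <= 1 || py >= nrow(cmap) || px <= 1 || px >= ncol(cmap)) {
    return(sep())
  }
  nb <- cmap[(py - 1):(py + 1), (px - 1):(px + 1)]
  if (any(is.na(nb))) return(sep())
  dyv <- rep(-1:1, times = 3); dxv <- rep(-1:1, each = 3)
  X <- cbind(1, dyv, dxv, dyv^2, dxv^2, dyv * dxv)
  b <- qr.solve(X, as.vector(nb))
  H <- matrix(c(2 * b[4], b[6], b[6], 2 * b[5]), 2, 2)
  detH <- H[1, 1] * H[2, 2] - H[1, 2]^2
  if (H[1, 1] >= -1e-12 || detH <= 1e-12) return(sep())
  sol <- -solve(H, b[2:3])
  if (any(abs(sol) > 0.75)) return(sep())
  clamp(sol, -0.5, 0.5)
}

# Peak location with deterministic tie-break: among equal maxima prefer the
# smallest displacement magnitude from `center`, then lexicographic order.
peak_location <- function(cmap, center) {
  mx <- max(cmap, na.rm = TRUE)
  cand <- which(!is.na(cmap) & cmap >= mx - 1e-12, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    d2 <- (cand[, 1] - center[1])^2 + (cand[, 2] - center[2])^2
    cand <- cand[order(d2, cand[, 1], cand[, 2]), , drop = FALSE]
  }
  cand[1, ]
}

# Ratio of the strongest secondary peak (outside an exclusion square around
# the primary) to the primary peak; 0 when no secondary exists.
secondary_peak_ratio <- function(cmap, py, px, exclude = 2L) {
  m <- cmap
  ys <- clamp((py - exclude):(py + exclude), 1, nrow(m))
  xs <- clamp((px - exclude):(px + exclude), 1, ncol(m))
  m[ys, xs] <- NA
  if (all(is.na(m))) return(0)
  s <- max(m, na.rm = TRUE)
  p <- cmap[py, px]
  if (p <= 0) return(1)
  max(0, s) / p
}

# Gradient-based (Lucas-Kanade) sub-pixel refinement around an integer
# placement: iteratively solves the linearized, intensity-normalized SSD
# between the template and the moving window sampled at a fractional
# offset. Exact (zero) for identical patches, unlike a parabola fit through
# an asymmetric correlation peak. `win` must contain the template placed at
# (py, px) (top-left, 1-based) with at least 1 px of margin on every side.
# Returns c(dy, dx) in [-1, 1], or c(0, 0) when the system is degenerate.
subpixel_lk <- function(win, template, py, px, iters = 3L) {
  nt <- dim(template)
  # large patches are subsampled: ~33 samples per axis suffice for a 2-dof
  # solve and keep the refinement cheap
  step <- max(1L, as.integer(ceiling(max(nt) / 33)))
  ys <- seq(1L, nt[1], by = step); xs <- seq(1L, nt[2], by = step)
  template <- template[ys, xs, drop = FALSE]
  nts <- dim(template)
  tz <- template - mean(template)
  tsd <- sqrt(sum(tz^2))
  if (tsd < 1e-9) return(c(0, 0))
  tz <- tz / tsd
  dy <- 0; dx <- 0
  base_y <- py - 1; base_x <- px - 1
  yy <- rep(ys, times = nts[2]); xx <- rep(xs, each = nts[1])
  samp <- function(oy, ox) {
    matrix(bilinear_sample(win, yy + base_y + oy, xx + base_x + ox),
           nts[1], nts[2])
  }
  for (it in seq_len(iters)) {
    m0 <- samp(dy, dx)
    mz <- m0 - mean(m0)
    msd <- sqrt(sum(mz^2))
    if (msd < 1e-9) return(c(0, 0))
    mz <- mz / msd
    gy <- (samp(dy + 0.5, dx) - samp(dy - 0.5, dx))
    gx <- (samp(dy, dx + 0.5) - samp(dy, dx - 0.5))
    gy <- gy / msd; gx <- gx / msd
    r <- tz - mz
    a11 <- sum(gy * gy); a12 <- sum(gy * gx); a22 <- sum(gx * gx)
    b1 <- sum(gy * r); b2 <- sum(gx * r)
    det <- a11 * a22 - a12^2
    if (det < 1e-12) return(c(0, 0))
    sy <- (a22 * b1 - a12 * b2) / det
    sx <- (a11 * b2 - a12 * b1) / det
    if (!is.finite(sy) || !is.finite(sx)) return(c(0, 0))
    dy <- clamp(dy + sy, -1, 1)
    dx <- clamp(dx + sx, -1, 1)
    if (abs(sy) < 1e-3 && abs(sx) < 1e-3) break
  }
  c(dy, dx)
}

# Sub-pixel refinement dispatcher: Lucas-Kanade against the actual image
# windows when the peak placement leaves a 1 px margin inside `search`,
# quadratic correlation-peak interpolation otherwise.
refine_peak <- function(search, template, pk, cmap) {
  nt <- dim(template)
  if (pk[1] > 1 && pk[2] > 1 &&
      pk[1] + nt[1] - 1 < nrow(search) && pk[2] + nt[2] - 1 < ncol(search)) {
    subpixel_lk(search, template, pk[1], pk[2])
  } else {
    subpixel_peak(cmap, pk[1], pk[2])
  }
}

# Locate `template` inside `search` by NCC; `nominal` is the expected
# (row, col) placement of the template's top-left corner. Returns the
# sub-pixel offset from nominal plus quality/validity.
match_template <- function(search, template, nominal, min_peak = 0.3) {
  if (stats::sd(template) < 1e-9) {
    return(list(dy = 0, dx = 0, quality = 0, valid = FALSE))
  }
  cmap <- ncc_map(search, template)
  if (all(is.na(cmap))) {
    return(list(dy = 0, dx = 0, quality = 0, valid = FALSE))
  }
  pk <- peak_location(cmap, nominal)
  q <- cmap[pk[1], pk[2]]
  frac <- refine_peak(search, template, pk, cmap)
  at_edge <- (pk[1] == 1 || pk[1] == nrow(cmap) ||
                pk[2] == 1 || pk[2] == ncol(cmap)) &&
    min(dim(cmap)) > 1
  list(dy = unname(pk[1] + frac[1] - nominal[1]),
       dx = unname(pk[2] + frac[2] - nominal[2]),
       quality = unname(q),
       valid = unname(is.finite(q) && q >= min_peak && !at_edge))
}

#' Estimate a rigid translation between two images
#'
#' Finds the displacement maximizing normalized cross-correlation over a
#' +-`search_radius` window: content at fixed position p appears at
#' p + offset in the moving image. Sub-pixel refined by quadratic peak
#' interpolation.
#'
#' @param fixed,moving numeric matrices of identical shape.
#' @param search_radius maximal displacement considered, pixels.
#' @param min_peak correlation floor below which the result is flagged
#'   invalid.
#' @return list with `dy`, `dx` (pixels), `peak_quality` (NCC at the
#'   optimum), `valid`.
#' @export
estimate_translation <- function(fixed, moving, search_radius = 20L,
                                 min_peak = 0.3) {
  r <- as.integer(search_radius)
  ny <- nrow(fixed); nx <- ncol(fixed)
  if (2 * r + 8 > min(ny, nx)) {
    stop("search_radius too large for image size")
  }
  tpl <- fixed[(r + 1):(ny - r), (r + 1):(nx - r), drop = FALSE]
  if (stats::sd(tpl) < 1e-9 || stats::sd(moving) < 1e-9) {
    return(list(dy = 0, dx = 0, peak_quality = 0, valid = FALSE))
  }
  cmap <- ncc_map(moving, tpl)
  if (all(is.na(cmap))) {
    return(list(dy = 0, dx = 0, peak_quality = 0, valid = FALSE))
  }
  ctr <- c(r + 1, r + 1)
  pk <- peak_location(cmap, ctr)
  frac <- refine_peak(moving, tpl, pk, cmap)
  q <- cmap[pk[1], pk[2]]
  list(dy = unname(pk[1] + frac[1] - ctr[1]),
       dx = unname(pk[2] + frac[2] - ctr[2]),
       peak_quality = unname(q),
       valid = unname(is.finite(q) && q >= min_peak))
}

# Harris corner response; returns data.frame(y, x, score) of up to `n` local
# maxima.
detect_corners <- function(img, n = 150L, sigma = 2, min_rel = 0.01,
                           border = 8L) {
  img <- img / 255
  gy <- (rbind(img[-1, , drop = FALSE], img[nrow(img), , drop = FALSE]) -
           rbind(img[1, , drop = FALSE], img[-nrow(img), , drop = FALSE])) / 2
  gx <- (cbind(img[, -1, drop = FALSE], img[, ncol(img), drop = FALSE]) -
           cbind(img[, 1, drop = FALSE], img[, -ncol(img), drop = FALSE])) / 2
  k <- gaussian_kernel_1d(sigma, 2 * ceiling(2 * sigma) + 1)
  sxx <- conv_separable(gx * gx, k)
  syy <- conv_separable(gy * gy, k)
  sxy <- conv_separable(gx * gy, k)
  resp <- (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
  # 5x5 local maxima
  mx <- resp
  for (dy in -2:2) for (dx in -2:2) {
    if (dy == 0 && dx == 0) next
    sh <- shift_matrix(resp, dy, dx, fill = -Inf)
    mx <- pmax(mx, sh)
  }
  is_max <- resp >= mx & resp > min_rel * max(resp)
  is_max[c(seq_len(border), nrow(resp) - seq_len(border) + 1), ] <- FALSE
  is_max[, c(seq_len(border), ncol(resp) - seq_len(border) + 1)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(y = numeric(), x = numeric(), score = numeric()))
  }
  sc <- resp[idx]
  ord <- order(-sc, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; sc <- sc[ord]
  keep <- seq_len(min(n, nrow(idx)))
  data.frame(y = idx[keep, 1], x = idx[keep, 2], score = sc[keep])
}

shift_matrix <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Match corner keypoints between two images
#'
#' Detects corner keypoints in the fixed image and localizes each in the
#' moving image by NCC template search in a window around its position.
#' A pair of images is judged overlapping when enough matches pass the
#' quality threshold.
#'
#' @param fixed,moving numeric matrices (may differ in shape).
#' @param max_keypoints corners to detect.
#' @param patch square descriptor patch side (odd).
#' @param search_radius search window half-size around the keypoint, pixels.
#' @param min_quality NCC threshold for a match to count.
#' @param min_matches matches required for an overlap verdict.
#' @param offset nominal (dy, dx) of moving relative to fixed, applied
#'   before the local search (use when placements differ).
#' @return list with `matches` (data.frame fixed_y, fixed_x, moving_y,
#'   moving_x, quality) and `overlap` (logical verdict).
#' @export
match_keypoints <- function(fixed, moving, max_keypoints = 150L,
                            patch = 13L, search_radius = 25L,
                            min_quality = 0.7, min_matches = 8L,
                            offset = c(0, 0)) {
  kp <- detect_corners(fixed, n = max_keypoints)
  h <- (patch - 1) / 2
  rows <- vector("list", nrow(kp))
  for (i in seq_len(nrow(kp))) {
    y <- kp$y[i]; x <- kp$x[i]
    if (y - h < 1 || y + h > nrow(fixed) || x - h < 1 || x + h > ncol(fixed)) next
    tpl <- fixed[(y - h):(y + h), (x - h):(x + h)]
    if (stats::sd(tpl) < 1e-9) next
    my <- y + offset[1]; mx <- x + offset[2]
    y0 <- round(clamp(my - h - search_radius, 1, nrow(moving)))
    y1 <- round(clamp(my + h + search_radius, 1, nrow(moving)))
    x0 <- round(clamp(mx - h - search_radius, 1, ncol(moving)))
    x1 <- round(clamp(mx + h + search_radius, 1, ncol(moving)))
    if (y1 - y0 < patch || x1 - x0 < patch) next
    win <- moving[y0:y1, x0:x1, drop = FALSE]
    cmap <- ncc_map(win, tpl)
    if (all(is.na(cmap))) next
    pk <- peak_location(cmap, c(my - h - y0 + 1, mx - h - x0 + 1))
    q <- cmap[pk[1], pk[2]]
    if (!is.finite(q)) next
    frac <- refine_peak(win, tpl, pk, cmap)
    rows[[i]] <- data.frame(
      fixed_y = y, fixed_x = x,
      moving_y = y0 + pk[1] + frac[1] - 1 + h,
      moving_x = x0 + pk[2] + frac[2] - 1 + h,
      quality = q)
  }
  matches <- do.call(rbind, rows)
  if (is.null(matches)) {
    matches <- data.frame(fixed_y = numeric(), fixed_x = numeric(),
                          moving_y = numeric(), moving_x = numeric(),
                          quality = numeric())
  }
  good <- matches[matches$quality >= min_quality, , drop = FALSE]
  list(matches = matches, good = good,
       overlap = nrow(good) >= min_matches)
}

#' Fit a 2-D affine transform to point correspondences
#'
#' Least-squares affine (fixed -> moving) with consensus-based outlier
#' rejection: exact fits on deterministic point triples vote for inlier
#' sets, and the final matrix is the least-squares fit over the best
#' consensus set.
#'
#' @param correspondences data.frame with columns fixed_y, fixed_x,
#'   moving_y, moving_x (e.g. `match_keypoints()$good`).
#' @param inlier_tol residual (pixels) below which a point supports a model.
#' @param max_trials consensus trials.
#' @return list with `matrix` (2 x 3, rows y then x: moving = A %*%
#'   c(fixed_y, fixed_x, 1)), `inliers` (logical), `residual_rms`.
#' @export
fit_affine <- function(correspondences, inlier_tol = 2, max_trials = 64L) {
  cc <- correspondences
  n <- nrow(cc)
  if (n < 3) stop("need at least 3 correspondences for an affine fit")
  X <- cbind(cc$fixed_y, cc$fixed_x, 1)
  Y <- cbind(cc$moving_y, cc$moving_x)
  lsq <- function(sel) {
    Xs <- X[sel, , drop = FALSE]
    if (qr(Xs)$rank < 3) return(NULL)
    t(qr.solve(Xs, Y[sel, , drop = FALSE]))
  }
  resid <- function(A) {
    P <- X %*% t(A)
    sqrt(rowSums((P - Y)^2))
  }
  best <- NULL; best_count <- -1L
  trials <- with_seed(777L, {
    lapply(seq_len(max_trials), function(i) sample.int(n, 3))
  })
  trials <- c(list(1:3), trials)
  for (tr in trials) {
    A <- tryCatch(lsq(seq_len(n) %in% tr), error = function(e) NULL)
    if (is.null(A) || any(!is.finite(A))) next
    inl <- resid(A) <= inlier_tol
    if (sum(inl) > best_count) { best <- inl; best_count <- sum(inl) }
  }
  if (is.null(best) || best_count < 3) {
    stop("affine fit failed: fewer than 3 inliers (points collinear?)")
  }
  A <- lsq(best)
  if (is.null(A)) stop("affine fit failed: inlier set is degenerate")
  # one re-fit over the refreshed inlier set
  inl <- resid(A) <= inlier_tol
  if (sum(inl) >= 3) {
    A2 <- lsq(inl)
    if (!is.null(A2)) { A <- A2 }
  } else {
    inl <- best
  }
  r <- resid(A)
  list(matrix = A, inliers = inl, residual_rms = rms(r[inl]))
}

#' Apply a 2-D affine transform to points
#'
#' @param A 2 x 3 matrix from [fit_affine()].
#' @param y,x coordinate vectors.
#' @return list of transformed `y`, `x`.
#' @export
apply_affine <- function(A, y, x) {
  list(y = A[1, 1] * y + A[1, 2] * x + A[1, 3],
       x = A[2, 1] * y + A[2, 2] * x + A[2, 3])
}

# Node center positions for a flow/mesh grid over an ny x nx image.
flow_node_positions <- function(ny, nx, patch_size, stride) {
  h <- floor(patch_size / 2)
  if (1 + h > ny - h || 1 + h > nx - h) {
    stop("patch larger than image")
  }
  ys <- seq(1 + h, ny - h, by = stride)
  xs <- seq(1 + h, nx - h, by = stride)
  list(ys = ys, xs = xs, h = h)
}

#' Estimate a patchwise optic-flow field
#'
#' At regular node intervals, the patch of the fixed image centered on the
#' node is localized in the moving image by NCC over a +-`search_radius`
#' window, with quadratic sub-pixel refinement. Nodes whose peak correlation
#' is below `min_peak`, whose secondary/primary peak ratio exceeds
#' `max_peak_ratio`, or whose patch is textureless are masked invalid.
#'
#' @param fixed,moving numeric matrices of identical shape.
#' @param patch_size patch side in pixels.
#' @param stride node spacing in pixels.
#' @param search_radius maximal displacement, pixels; default
#'   `patch_size / 2`.
#' @param min_peak validity floor on peak NCC.
#' @param max_peak_ratio validity ceiling on 2nd/1st peak ratio.
#' @return a `flow_field`: matrices `dy`, `dx`, `quality`, logical `valid`
#'   over the node grid, plus `node_y`, `node_x`, `patch_size`, `stride`.
#' @export
estimate_flow <- function(fixed, moving, patch_size = 160L, stride = 40L,
                          search_radius = NULL, min_peak = 0.3,
                          max_peak_ratio = 0.9,
                          border = c("strict", "shrink")) {
  if (!identical(dim(fixed), dim(moving))) stop("image shapes differ")
  border <- match.arg(border)
  if (is.null(search_radius)) search_radius <- floor(patch_size / 2)
  r <- as.integer(search_radius)
  h_min <- 12L
  np <- if (border == "shrink") {
    # nodes extend toward the image borders; their patches shrink (down to
    # h_min) so every template stays inside the image — border estimates
    # are noisier but unbiased
    flow_node_positions(nrow(fixed), ncol(fixed),
                        2L * h_min + 1L, stride)
  } else {
    # inset nodes so the whole search window fits: every node is fully
    # measurable
    flow_node_positions(nrow(fixed), ncol(fixed),
                        patch_size + 2L * r, stride)
  }
  h_full <- floor(patch_size / 2)
  nyn <- length(np$ys); nxn <- length(np$xs)
  dy <- matrix(0, nyn, nxn); dx <- matrix(0, nyn, nxn)
  qual <- matrix(0, nyn, nxn); valid <- matrix(FALSE, nyn, nxn)
  for (iy in seq_len(nyn)) {
    for (ix in seq_len(nxn)) {
      y <- np$ys[iy]; x <- np$xs[ix]
      if (border == "shrink") {
        h <- min(h_full, y - 1, nrow(fixed) - y, x - 1, ncol(fixed) - x)
        if (h < h_min) next
      } else {
        h <- h_full
      }
      # shrunken border patches only refine locally: a small patch given a
      # wide search range mostly finds spurious matches
      r_node <- if (h < h_full) min(r, 6L) else r
      tpl <- fixed[(y - h):(y + h), (x - h):(x + h), drop = FALSE]
      if (stats::sd(tpl) < 1e-9) next
      # patches dominated by fill (black) pixels carry no real signal:
      # warped inputs are zero-filled outside their source
      if (mean(tpl < 1) > 0.02) next
      y0 <- clamp(y - h - r_node, 1, nrow(moving))
      y1 <- clamp(y + h + r_node, 1, nrow(moving))
      x0 <- clamp(x - h - r_node, 1, ncol(moving))
      x1 <- clamp(x + h + r_node, 1, ncol(moving))
      clipped <- if (border == "shrink") FALSE else
        (y1 - y0) < 2 * (h + r_node) || (x1 - x0) < 2 * (h + r_node)
      win <- moving[y0:y1, x0:x1, drop = FALSE]
      if (any(dim(win) < dim(tpl))) next
      cmap <- ncc_map(win, tpl)
      if (all(is.na(cmap))) next
      nominal <- c(y - h - y0 + 1, x - h - x0 + 1)
      pk <- peak_location(cmap, nominal)
      q <- cmap[pk[1], pk[2]]
      if (!is.finite(q)) next
      frac <- refine_peak(win, tpl, pk, cmap)
      dy[iy, ix] <- pk[1] + frac[1] - nominal[1]
      dx[iy, ix] <- pk[2] + frac[2] - nominal[2]
      qual[iy, ix] <- q
      ratio <- secondary_peak_ratio(cmap, pk[1], pk[2],
                                    exclude = max(2L, h %/% 2L))
      # peaks on the correlation-map border (clipped window or displacement
      # at the search limit) cannot be localized reliably
      at_edge <- pk[1] == 1 || pk[1] == nrow(cmap) ||
        pk[2] == 1 || pk[2] == ncol(cmap)
      mwin <- moving[(y0 + pk[1] - 1):(y0 + pk[1] - 1 + 2 * h),
                     (x0 + pk[2] - 1):(x0 + pk[2] - 1 + 2 * h),
                     drop = FALSE]
      black_hit <- mean(mwin < 1) > 0.02
      valid[iy, ix] <- q >= min_peak && ratio <= max_peak_ratio &&
        !at_edge && !clipped && !black_hit
    }
  }
  structure(list(dy = dy, dx = dx, quality = qual, valid = valid,
                 node_y = np$ys, node_x = np$xs,
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride)),
            class = "flow_field")
}

#' Median-filter a flow field
#'
#' Replaces each valid node's displacement by the componentwise median over
#' the valid nodes of its (2r+1)^2 neighborhood. Standard outlier clean-up
#' before mesh regularization: isolated nodes that locked onto locally
#' moving content (or a wrong peak) are pulled back to the neighborhood
#' consensus.
#'
#' @param flow a `flow_field`.
#' @param r neighborhood radius in nodes.
#' @return the filtered `flow_field`.
#' @export
filter_flow <- function(flow, r = 1L, outlier_tol = 2) {
  ny <- nrow(flow$dy); nx <- ncol(flow$dy)
  dy <- flow$dy; dx <- flow$dx
  valid <- flow$valid
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!flow$valid[i, j]) next
    ys <- max(1, i - r):min(ny, i + r)
    xs <- max(1, j - r):min(nx, j + r)
    v <- flow$valid[ys, xs]
    if (!any(v)) next
    my <- stats::median(flow$dy[ys, xs][v])
    mx <- stats::median(flow$dx[ys, xs][v])
    # a node far from its neighborhood consensus is a matching failure,
    # not a measurement: drop it rather than smooth it
    if (sqrt((flow$dy[i, j] - my)^2 + (flow$dx[i, j] - mx)^2) >
        outlier_tol && sum(v) >= 3) {
      valid[i, j] <- FALSE
    }
    dy[i, j] <- my
    dx[i, j] <- mx
  }
  flow$dy <- dy; flow$dx <- dx; flow$valid <- valid
  flow
}

# Dense (ny x nx) displacement images from a flow field (invalid nodes are
# inpainted from valid neighbors by nearest-node fill before interpolation).
flow_dense <- function(flow, ny, nx) {
  dy <- fill_invalid(flow$dy, flow$valid)
  dx <- fill_invalid(flow$dx, flow$valid)
  oy <- flow$node_y[1]; ox <- flow$node_x[1]
  list(dy = upsample_field(dy, flow$stride, ny, nx, origin = c(oy, ox)),
       dx = upsample_field(dx, flow$stride, ny, nx, origin = c(oy, ox)))
}

# Replace invalid node values by the value of the nearest valid node
# (zero when no node is valid).
fill_invalid <- function(m, valid) {
  if (all(valid)) return(m)
  if (!any(valid)) return(matrix(0, nrow(m), ncol(m)))
  vi <- which(valid, arr.ind = TRUE)
  bad <- which(!valid, arr.ind = TRUE)
  for (i in seq_len(nrow(bad))) {
    d2 <- (vi[, 1] - bad[i, 1])^2 + (vi[, 2] - bad[i, 2])^2
    j <- which.min(d2)
    m[bad[i, 1], bad[i, 2]] <- m[vi[j, 1], vi[j, 2]]
  }
  m
}

#' Coarse-to-fine optic flow
#'
#' Runs [estimate_flow()] at each scale (given coarse to fine as integer
#' downsampling factors, e.g. `c(4, 1)`), using the accumulated field to
#' pre-warp the moving image before each refinement. Captures displacements
#' far larger than the patch size while preserving fine local accuracy; this
#' mirrors the practice of estimating global and local deformation from
#' downsampled and full-resolution data simultaneously.
#'
#' @inheritParams estimate_flow
#' @param scales integer vector of downsampling factors, coarse to fine;
#'   must end at 1.
#' @return a `flow_field` at full resolution whose displacements include all
#'   scales' contributions.
#' @export
multiscale_flow <- function(fixed, moving, scales = c(4L, 1L),
                            patch_size = 160L, stride = 40L,
                            search_radius = NULL, min_peak = 0.3,
                            max_peak_ratio = 0.9,
                            border = c("strict", "shrink")) {
  border <- match.arg(border)
  stopifnot(all(diff(scales) < 0) || length(scales) == 1,
            scales[length(scales)] == 1)
  ny <- nrow(fixed); nx <- ncol(fixed)
  Dy <- matrix(0, ny, nx); Dx <- matrix(0, ny, nx)
  last <- NULL
  for (s in scales) {
    fs <- if (s > 1) downsample_mean(fixed, s) else fixed
    if (any(Dy != 0) || any(Dx != 0)) {
      yy <- rep(seq_len(ny), times = nx); xx <- rep(seq_len(nx), each = ny)
      warped <- matrix(bilinear_sample(moving, yy + as.vector(Dy),
                                       xx + as.vector(Dx)), ny, nx)
    } else {
      warped <- moving
    }
    ws <- if (s > 1) downsample_mean(warped, s) else warped
    r_s <- if (is.null(search_radius)) patch_size %/% 2 else search_radius
    ps <- min(as.integer(patch_size), min(dim(fs)) - 2L * as.integer(r_s) - 2L)
    fl <- if (ps >= 9) {
      tryCatch(
        estimate_flow(fs, ws, patch_size = ps,
                      stride = max(4L, as.integer(stride)),
                      search_radius = search_radius,
                      min_peak = min_peak, max_peak_ratio = max_peak_ratio,
                      border = if (s == 1) border else "strict"),
        error = function(e) NULL)
    } else NULL
    if (is.null(fl)) {
      if (s == 1) stop("patch larger than image")
      next
    }
    dn <- flow_dense(fl, nrow(fs), ncol(fs))
    if (s > 1) {
      up_y <- s * resize_bilinear(dn$dy, ny, nx)
      up_x <- s * resize_bilinear(dn$dx, ny, nx)
    } else {
      up_y <- dn$dy; up_x <- dn$dx
    }
    Dy <- Dy + up_y; Dx <- Dx + up_x
    last <- fl
  }
  # express the accumulated dense field on the finest node grid
  idx <- as.matrix(expand.grid(y = clamp(last$node_y, 1, ny),
                               x = clamp(last$node_x, 1, nx)))
  structure(list(
    dy = matrix(Dy[idx], length(last$node_y), length(last$node_x)),
    dx = matrix(Dx[idx], length(last$node_y), length(last$node_x)),
    quality = last$quality, valid = last$valid,
    node_y = last$node_y, node_x = last$node_x,
    patch_size = last$patch_size, stride = last$stride),
    class = "flow_field")
}

# Bilinear resize of a dense matrix to ny x nx (used to upsample dense
# fields computed on downsampled images).
resize_bilinear <- function(m, ny, nx) {
  sy <- nrow(m) / ny; sx <- ncol(m) / nx
  ys <- (seq_len(ny) - 0.5) * sy + 0.5
  xs <- (seq_len(nx) - 0.5) * sx + 0.5
  yy <- rep(ys, times = nx); xx <- rep(xs, each = ny)
  y0 <- clamp(floor(yy), 1, nrow(m)); y1 <- clamp(y0 + 1, 1, nrow(m))
  x0 <- clamp(floor(xx), 1, ncol(m)); x1 <- clamp(x0 + 1, 1, ncol(m))
  fy <- clamp(yy - y0, 0, 1); fx <- clamp(xx - x0, 0, 1)
  v <- (1 - fy) * ((1 - fx) * m[cbind(y0, x0)] + fx * m[cbind(y0, x1)]) +
    fy * ((1 - fx) * m[cbind(y1, x0)] + fx * m[cbind(y1, x1)])
  matrix(v, ny, nx)
}
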