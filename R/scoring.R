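# Ground-truth recovery scoring for synthetic acquisitions.
#
# A landmark fixed in the phantom volume is pushed, per slice, through the
# ground-truth acquisition warp (phantom -> acquired tiles) and back through
# the recovered transforms (tiles -> stitched composite -> aligned frame).
# If alignment were perfect, every slice would map the landmark to the same
# aligned-frame position; the RMS spread across slices, relative to the
# root slice, is the recovery residual.

# Solve p + f(p) = target by fixed-point iteration (f smooth, |grad f| < 1).
invert_displacement <- function(f, target_y, target_x, iters = 30) {
  py <- target_y; px <- target_x
  for (i in seq_len(iters)) {
    d <- f(py, px)
    py <- target_y - d$dy
    px <- target_x - d$dx
  }
  list(y = py, x = px)
}

#' Score alignment recovery against synthetic ground truth
#'
#' @param manifest the manifest returned by [tile_and_deform()] (with its
#'   `warp`).
#' @param stitched list (per slice) of [stitch_tilemap()] results, or NULL
#'   entries for missing slices.
#' @param aligned the `aligned_stack` from [align_z()] over those slices.
#' @param landmarks optional n x 2 matrix of (y, x) phantom coordinates;
#'   defaults to a regular grid inset by one mesh cell plus the warp
#'   amplitude.
#' @param inset border (pixels) excluded when auto-generating landmarks.
#' @return list with `rms` (overall RMS residual in pixels), `per_slice`
#'   RMS vector, and the per-slice landmark positions.
#' @export
score_alignment_recovery <- function(manifest, stitched, aligned,
                                     landmarks = NULL, inset = 24) {
  warp <- manifest$warp
  ny <- manifest$slice_shape[1]; nx <- manifest$slice_shape[2]
  if (is.null(landmarks)) {
    gy <- seq(1 + inset, ny - inset, length.out = 6)
    gx <- seq(1 + inset, nx - inset, length.out = 6)
    landmarks <- as.matrix(expand.grid(y = gy, x = gx))
  }
  n_slices <- manifest$n_slices
  pos <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    if (is.null(stitched[[s]]) || aligned$status[s] %in% c("missing")) next
    p <- landmark_in_aligned_frame(manifest, stitched[[s]], aligned, s,
                                   landmarks)
    pos[[s]] <- p
  }
  root <- aligned$root
  if (is.null(pos[[root]])) stop("root slice has no landmark positions")
  per_slice <- rep(NA_real_, n_slices)
  sq <- c()
  for (s in seq_len(n_slices)) {
    if (is.null(pos[[s]]) || s == root) next
    ok <- stats::complete.cases(pos[[s]]) & stats::complete.cases(pos[[root]])
    d2 <- (pos[[s]][ok, 1] - pos[[root]][ok, 1])^2 +
      (pos[[s]][ok, 2] - pos[[root]][ok, 2])^2
    per_slice[s] <- sqrt(mean(d2))
    sq <- c(sq, d2)
  }
  list(rms = sqrt(mean(sq)), per_slice = per_slice, positions = pos)
}

# Landmark positions (phantom coords) mapped into the aligned frame of
# slice s. Returns a matrix with NA rows for landmarks outside coverage.
landmark_in_aligned_frame <- function(manifest, stitch, aligned, s,
                                      landmarks) {
  warp <- manifest$warp
  gy <- manifest$grid[1]; gx <- manifest$grid[2]
  tshape <- manifest$tile_shape
  out <- matrix(NA_real_, nrow(landmarks), 2)
  # 1. acquired ("jittered world") position: q + d_s(q) = L
  q <- invert_displacement(
    function(y, x) {
      if (is.null(warp)) return(list(dy = rep(0, length(y)),
                                     dx = rep(0, length(x))))
      warp_displacement(warp, s, y, x)
    },
    landmarks[, 1], landmarks[, 2])
  for (li in seq_len(nrow(landmarks))) {
    # 2. tile containing the landmark (prefer the most interior position)
    best <- NULL; best_margin <- -Inf
    for (r in seq_len(gy)) for (cc in seq_len(gx)) {
      jy <- 0; jx <- 0
      if (!is.null(warp)) {
        jy <- warp$jitter[s, r, cc, 1]; jx <- warp$jitter[s, r, cc, 2]
      }
      t_y <- q$y[li] - manifest$origins_y[r] - jy
      t_x <- q$x[li] - manifest$origins_x[cc] - jx
      margin <- min(t_y - 1, tshape[1] - t_y, t_x - 1, tshape[2] - t_x)
      if (margin > best_margin) {
        best_margin <- margin
        best <- list(i = (r - 1) * gx + cc, t_y = t_y, t_x = t_x)
      }
    }
    if (best_margin < 1) next
    # 3. composite position: t = (c - O_i) + mesh_i(c - O_i)
    O <- stitch$tile_origins[best$i, ]
    mesh_i <- stitch$meshes[[best$i]]
    loc <- invert_displacement(
      function(y, x) mesh_displacement(mesh_i, y, x),
      best$t_y, best$t_x)
    cpos <- c(loc$y + O[1], loc$x + O[2])
    # 4. aligned position: A.(p + m(p), 1) = c
    tf <- aligned$transforms[[s]]
    if (is.null(tf)) next
    A <- tf$affine
    lin <- matrix(c(A[1, 1], A[1, 2], A[2, 1], A[2, 2]), 2, 2, byrow = TRUE)
    rhs <- c(cpos[1] - A[1, 3], cpos[2] - A[2, 3])
    y0 <- solve(lin, rhs)
    if (is.null(tf$mesh)) {
      out[li, ] <- y0
    } else {
      p <- invert_displacement(
        function(y, x) mesh_displacement(tf$mesh, y, x), y0[1], y0[2])
      out[li, ] <- c(p$y, p$x)
    }
  }
  out
}
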