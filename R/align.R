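# Alignment pipeline orchestration: XY stitching of tile maps, fusion of
# overlapping tile maps, root-slice selection, Z alignment outward from the
# root, registration of high-resolution stacks into the reference frame,
# output rendering, and the resumability journal.

#' Alignment parameter defaults
#'
#' @param patch_size flow patch side in pixels; `NULL` picks
#'   `min(160, largest odd size <= min(dim)/3)` per image.
#' @param stride flow node spacing; `NULL` picks `max(8, patch_size/4)`.
#' @param search_radius flow search radius; `NULL` picks `patch_size/2`.
#' @param scales coarse-to-fine downsampling factors for Z alignment flow.
#' @param mesh_spacing elastic mesh node spacing; `NULL` picks the flow
#'   stride.
#' @param mesh_w data-term weight per constrained node.
#' @param coarse_search search radius (px) for rigid tile-offset estimation.
#' @param min_peak,max_peak_ratio flow validity thresholds.
#' @param min_overlap_px smallest declared tile overlap accepted.
#' @param feather_margin feather ramp width (px) for blending.
#' @param min_quality,min_matches keypoint-match acceptance parameters.
#' @param z_gap_growth growth factor of the search radius per missing slice
#'   bridged (radius x (1 + k/2) across k missing slices).
#' @return named list of parameters.
#' @export
align_params <- function(patch_size = NULL, stride = NULL,
                         search_radius = NULL, scales = c(4L, 1L),
                         mesh_spacing = NULL, mesh_w = 1, mesh_k = NULL,
                         coarse_search = 8L, min_peak = 0.3,
                         max_peak_ratio = 0.9, min_overlap_px = 10L,
                         feather_margin = 8L, min_quality = 0.7,
                         min_matches = 8L, z_gap_growth = 0.5, refine_iters = 2L) {
  list(patch_size = patch_size, stride = stride, mesh_k = mesh_k,
       search_radius = search_radius, scales = scales,
       mesh_spacing = mesh_spacing, mesh_w = mesh_w,
       coarse_search = coarse_search, min_peak = min_peak,
       max_peak_ratio = max_peak_ratio, min_overlap_px = min_overlap_px,
       feather_margin = feather_margin, min_quality = min_quality,
       min_matches = min_matches, z_gap_growth = z_gap_growth,
       refine_iters = refine_iters)
}

resolve_flow_params <- function(params, dims) {
  p <- params
  if (is.null(p$patch_size)) {
    p$patch_size <- max(9L, min(160L, 2L * (as.integer(min(dims)) %/% 6) + 1L))
  }
  if (is.null(p$stride)) p$stride <- max(8L, p$patch_size %/% 4)
  if (is.null(p$search_radius)) p$search_radius <- p$patch_size %/% 2
  if (is.null(p$mesh_spacing)) p$mesh_spacing <- p$stride
  p
}

#' Assemble a tile map from a discovered inventory
#'
#' Loads (and optionally preprocesses) all tiles of one slice.
#'
#' @param inv one inventory entry from [discover_project()].
#' @param slice slice index (as recorded in filenames).
#' @param overlap_fraction nominal overlap used for grid placement.
#' @param preprocess a [preprocess_params()] or NULL.
#' @param invert logical, histogram inversion before filtering.
#' @return a `tilemap`: list of images, grid, nominal origins, slice index.
#' @export
load_tilemap <- function(inv, slice, overlap_fraction = 0.15,
                         preprocess = NULL, invert = FALSE) {
  s <- inv$slices[[as.character(slice)]]
  if (is.null(s)) stop("slice ", slice, " not present in inventory")
  gy <- inv$grid_shape[1]; gx <- inv$grid_shape[2]
  images <- vector("list", gy * gx)
  for (i in seq_len(nrow(s))) {
    img <- read_image(file.path(inv$dir, s$file[i]))
    img <- preprocess_tile(img, preprocess, invert = invert)
    images[[s$row[i] * gx + s$col[i] + 1L]] <- img
  }
  shp <- dim(images[[which(!vapply(images, is.null, TRUE))[1]]])
  step_y <- round(shp[1] * (1 - overlap_fraction))
  step_x <- round(shp[2] * (1 - overlap_fraction))
  structure(list(images = images, grid = c(gy, gx), tile_shape = shp,
                 origins_y = (seq_len(gy) - 1) * step_y,
                 origins_x = (seq_len(gx) - 1) * step_x,
                 overlap_fraction = overlap_fraction,
                 slice_index = slice),
            class = "tilemap")
}

tm_image <- function(tm, r, c) tm$images[[(r - 1) * tm$grid[2] + c]]

# Feather weight for a (ty, tx) tile: distance to the nearest tile edge,
# capped at `margin`.
feather_weights <- function(ty, tx, margin) {
  wy <- pmin(seq_len(ty), ty + 1 - seq_len(ty), margin)
  wx <- pmin(seq_len(tx), tx + 1 - seq_len(tx), margin)
  outer(wy, wx, pmin)
}

#' Stitch one tile map into a single slice image
#'
#' Per-pair rigid offsets are estimated by normalized cross-correlation in
#' the nominal overlap bands and reconciled into per-tile translations by
#' least squares (first tile anchored). Residual deformation is corrected by
#' relaxing one elastic mesh per tile against optic-flow constraints in the
#' overlap bands, split antisymmetrically between the two tiles of each
#' pair. Tiles are rendered with linear feather blending.
#'
#' Pairs whose overlap correlation is invalid fall back to the nominal grid
#' placement (with a warning).
#'
#' @param tilemap a [load_tilemap()] result.
#' @param params [align_params()].
#' @return list: `image` (stitched composite), `tile_origins` (matrix,
#'   per-tile composite origin), `meshes` (per-tile `spring_mesh`),
#'   `quality` (per-pair offsets and correlations).
#' @export
stitch_tilemap <- function(tilemap, params = align_params()) {
  gy <- tilemap$grid[1]; gx <- tilemap$grid[2]
  ty <- tilemap$tile_shape[1]; tx <- tilemap$tile_shape[2]
  n <- gy * gx
  if (n == 1) {
    img <- tm_image(tilemap, 1, 1)
    mesh <- spring_mesh(c(ty, tx), max(8, min(ty, tx) / 4))
    return(list(image = img, tile_origins = matrix(0, 1, 2),
                meshes = list(mesh), quality = NULL))
  }
  ov_y <- ty - (tilemap$origins_y[2] - tilemap$origins_y[1])
  ov_x <- tx - (tilemap$origins_x[2] - tilemap$origins_x[1])
  if ((gy > 1 && ov_y < params$min_overlap_px) ||
      (gx > 1 && ov_x < params$min_overlap_px)) {
    stop("declared overlap below the supported minimum of ",
         params$min_overlap_px, " px")
  }
  # --- coarse: pairwise offsets in overlap bands ---
  # The template is anchored at B's leading edge (the side facing A) and
  # trimmed by the search pad, so the search window stays inside A while
  # allowing a +-pad offset in both axes.
  pairs <- list()
  add_pair <- function(a_r, a_c, b_r, b_c, axis) {
    A <- tm_image(tilemap, a_r, a_c); B <- tm_image(tilemap, b_r, b_c)
    if (is.null(A) || is.null(B)) return(NULL)
    ov <- if (axis == "x") ov_x else ov_y
    pad <- min(params$coarse_search, ov - 6L)
    est <- NULL
    if (pad >= 2) {
      if (axis == "x") {
        tpl <- B[(1 + pad):(ty - pad), seq_len(ov - pad), drop = FALSE]
        srch <- A[, (tx - ov - pad + 1):tx, drop = FALSE]
        nominal <- c(pad + 1, pad + 1)
      } else {
        tpl <- B[seq_len(ov - pad), (1 + pad):(tx - pad), drop = FALSE]
        srch <- A[(ty - ov - pad + 1):ty, , drop = FALSE]
        nominal <- c(pad + 1, pad + 1)
      }
      est <- tryCatch(match_template(srch, tpl, nominal),
                      error = function(e) NULL)
    }
    if (is.null(est)) est <- list(dy = 0, dx = 0, quality = 0, valid = FALSE)
    list(a = (a_r - 1) * gx + a_c, b = (b_r - 1) * gx + b_c,
         axis = axis, dy = est$dy, dx = est$dx,
         quality = est$quality, valid = est$valid)
  }
  for (r in seq_len(gy)) for (c in seq_len(gx)) {
    if (c < gx) pairs[[length(pairs) + 1]] <- add_pair(r, c, r, c + 1, "x")
    if (r < gy) pairs[[length(pairs) + 1]] <- add_pair(r, c, r + 1, c, "y")
  }
  pairs <- Filter(Negate(is.null), pairs)
  if (any(!vapply(pairs, `[[`, TRUE, "valid"))) {
    warning("some tile pairs had no valid overlap correlation; ",
            "falling back to nominal placement for those pairs")
  }
  # least-squares per-tile corrections (tile 1 anchored at 0)
  corr <- solve_tile_offsets(pairs, n)
  base_y <- rep(tilemap$origins_y, each = gx)
  base_x <- rep(tilemap$origins_x, times = gy)
  org <- cbind(base_y + corr[, 1], base_x + corr[, 2])
  org[, 1] <- org[, 1] - min(org[, 1])
  org[, 2] <- org[, 2] - min(org[, 2])
  # --- fine: per-tile meshes with antisymmetric flow constraints ---
  fp <- resolve_flow_params(params, c(min(ty, ov_y + 2 * params$coarse_search),
                                      min(tx, ov_x + 2 * params$coarse_search)))
  meshes <- lapply(seq_len(n), function(i) {
    spring_mesh(c(ty, tx), fp$mesh_spacing, k = fp$mesh_k, w = fp$mesh_w)
  })
  cons <- lapply(meshes, function(m) {
    list(ty = m$dy, tx = m$dx, w = matrix(0, nrow(m$dy), ncol(m$dy)),
         cnt = matrix(0, nrow(m$dy), ncol(m$dy)))
  })
  for (p in pairs) {
    if (!p$valid) next
    fc <- pair_flow_constraints(tilemap, org, p, fp)
    if (is.null(fc)) next
    for (side in c("a", "b")) {
      i <- p[[side]]
      sgn <- if (side == "a") -0.5 else 0.5
      sel <- fc[[side]]$idx
      lin <- (sel[, 2] - 1) * nrow(cons[[i]]$ty) + sel[, 1]
      sy <- rowsum(sgn * fc$dy, lin)
      sx <- rowsum(sgn * fc$dx, lin)
      cn <- rowsum(rep(1, length(lin)), lin)
      at <- as.integer(rownames(sy))
      cons[[i]]$ty[at] <- cons[[i]]$ty[at] + sy[, 1]
      cons[[i]]$tx[at] <- cons[[i]]$tx[at] + sx[, 1]
      cons[[i]]$cnt[at] <- cons[[i]]$cnt[at] + cn[, 1]
    }
  }
  for (i in seq_len(n)) {
    cnt <- pmax(cons[[i]]$cnt, 1)
    cons[[i]]$ty <- cons[[i]]$ty / cnt
    cons[[i]]$tx <- cons[[i]]$tx / cnt
    cons[[i]]$w <- matrix(fp$mesh_w * (cons[[i]]$cnt > 0),
                          nrow(cons[[i]]$cnt), ncol(cons[[i]]$cnt))
    if (is.null(tm_image(tilemap, (i - 1) %/% gx + 1, (i - 1) %% gx + 1))) next
    meshes[[i]] <- relax_mesh(meshes[[i]], cons[[i]])$mesh
  }
  img <- render_tiles(tilemap, org, meshes, params$feather_margin)
  list(image = img, tile_origins = org, meshes = meshes,
       quality = pairs)
}

# Solve per-tile translation corrections from pairwise measurements by
# weighted least squares, anchoring tile 1.
solve_tile_offsets <- function(pairs, n) {
  corr <- matrix(0, n, 2)
  valid_pairs <- Filter(function(p) p$valid, pairs)
  if (length(valid_pairs) == 0) return(corr)
  m <- length(valid_pairs)
  A <- matrix(0, m + 1, n)
  by <- numeric(m + 1); bx <- numeric(m + 1)
  wts <- numeric(m + 1)
  for (i in seq_len(m)) {
    p <- valid_pairs[[i]]
    A[i, p$a] <- -1; A[i, p$b] <- 1
    by[i] <- p$dy; bx[i] <- p$dx
    wts[i] <- max(p$quality, 0.01)
  }
  A[m + 1, 1] <- 1; wts[m + 1] <- 10  # anchor
  W <- sqrt(wts)
  Aw <- A * W
  corr[, 1] <- stats::coef(stats::lm.fit(Aw, by * W))
  corr[, 2] <- stats::coef(stats::lm.fit(Aw, bx * W))
  corr[is.na(corr)] <- 0
  corr
}

# Flow constraints for one overlapping tile pair: returns per-node target
# displacement (B relative to A in the composite frame) and, per side, the
# linear node indices of the mesh nodes concerned.
pair_flow_constraints <- function(tilemap, org, p, fp) {
  gy <- tilemap$grid[1]; gx <- tilemap$grid[2]
  ty <- tilemap$tile_shape[1]; tx <- tilemap$tile_shape[2]
  A <- tilemap$images[[p$a]]; B <- tilemap$images[[p$b]]
  oa <- org[p$a, ]; ob <- org[p$b, ]
  # overlap rectangle in composite coordinates
  y0 <- max(oa[1], ob[1]) + 1; y1 <- min(oa[1] + ty, ob[1] + ty)
  x0 <- max(oa[2], ob[2]) + 1; x1 <- min(oa[2] + tx, ob[2] + tx)
  if (y1 - y0 < 8 || x1 - x0 < 8) return(NULL)
  ys <- round(y0):round(y1 - 1); xs <- round(x0):round(x1 - 1)
  bandA <- matrix(bilinear_sample(A,
                                  rep(ys - oa[1], times = length(xs)),
                                  rep(xs - oa[2], each = length(ys))),
                  length(ys), length(xs))
  bandB <- matrix(bilinear_sample(B,
                                  rep(ys - ob[1], times = length(xs)),
                                  rep(xs - ob[2], each = length(ys))),
                  length(ys), length(xs))
  ps <- min(fp$patch_size, 2L * ((min(dim(bandA)) - 1L) %/% 2L) + 1L)
  if (ps < 7) return(NULL)
  fl <- tryCatch(
    estimate_flow(bandA, bandB, patch_size = ps,
                  stride = max(4L, min(fp$stride, ps)),
                  search_radius = max(3L, fp$search_radius %/% 4),
                  min_peak = fp$min_peak,
                  max_peak_ratio = fp$max_peak_ratio),
    error = function(e) NULL)
  if (is.null(fl) || !any(fl$valid)) return(NULL)
  vidx <- which(fl$valid)
  ny_n <- length(fl$node_y)
  comp_y <- ys[1] - 1 + fl$node_y[(vidx - 1) %% ny_n + 1]
  comp_x <- xs[1] - 1 + fl$node_x[(vidx - 1) %/% ny_n + 1]
  # flow: content of B at A's position q sits at q + f -> B must be pulled
  # by -f to match A; constraint applies at the nearest mesh node of each
  # tile
  near_nodes <- function(mesh, origin) {
    pos <- mesh_node_positions(mesh)
    iy <- clamp(round((comp_y - origin[1] - pos$y[1]) / mesh$spacing) + 1,
                1, length(pos$y))
    ix <- clamp(round((comp_x - origin[2] - pos$x[1]) / mesh$spacing) + 1,
                1, length(pos$x))
    cbind(iy, ix)
  }
  mesh_a <- spring_mesh(c(ty, tx), fp$mesh_spacing)
  list(dy = fl$dy[vidx], dx = fl$dx[vidx],
       a = list(idx = near_nodes(mesh_a, org[p$a, ])),
       b = list(idx = near_nodes(mesh_a, org[p$b, ])))
}

render_tiles <- function(tilemap, org, meshes, feather_margin) {
  gy <- tilemap$grid[1]; gx <- tilemap$grid[2]
  ty <- tilemap$tile_shape[1]; tx <- tilemap$tile_shape[2]
  ny <- ceiling(max(org[, 1]) + ty); nx <- ceiling(max(org[, 2]) + tx)
  num <- matrix(0, ny, nx); den <- matrix(0, ny, nx)
  fw <- feather_weights(ty, tx, feather_margin)
  for (i in seq_len(nrow(org))) {
    img <- tilemap$images[[i]]
    if (is.null(img)) next
    y0 <- floor(org[i, 1]); x0 <- floor(org[i, 2])
    ys <- (y0 + 1):min(y0 + ty + 1, ny)
    xs <- (x0 + 1):min(x0 + tx + 1, nx)
    yy <- rep(ys, times = length(xs)); xx <- rep(xs, each = length(ys))
    d <- mesh_displacement(meshes[[i]], yy - org[i, 1], xx - org[i, 2])
    sy <- yy - org[i, 1] + d$dy; sx <- xx - org[i, 2] + d$dx
    vals <- bilinear_sample(img, sy, sx, fill = 0)
    wts <- bilinear_sample(fw, sy, sx, fill = 0)
    idx <- cbind(yy, xx)
    num[idx] <- num[idx] + vals * wts
    den[idx] <- den[idx] + wts
  }
  out <- num / pmax(den, 1e-12)
  out[den <= 1e-12] <- 0
  as_uint8(round(out))
}

#' Fuse stitched tile maps that share a slice
#'
#' When several stitched images exist for one slice index, each pair is
#' tested for overlap by keypoint matching at its nominal placement.
#' Overlapping groups are coarse-aligned by a robust affine fit, elastically
#' refined, and feather-blended into one image; non-overlapping members are
#' returned unchanged at their nominal placements.
#'
#' @param members list of `list(image =, origin = c(y, x))` entries (origins
#'   are nominal placements in the slice frame).
#' @param params [align_params()].
#' @return list with `members`: a list of fused `list(image, origin)`
#'   groups, and `n_members`.
#' @export
fuse_overlapping_tilemaps <- function(members, params = align_params()) {
  n <- length(members)
  if (n == 1) return(list(members = members, n_members = 1L))
  # pairwise overlap verdicts
  adj <- matrix(FALSE, n, n)
  kp <- vector("list", n^2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    off <- members[[j]]$origin - members[[i]]$origin
    mk <- match_keypoints(members[[i]]$image, members[[j]]$image,
                          offset = -off,
                          min_quality = params$min_quality,
                          min_matches = params$min_matches)
    adj[i, j] <- adj[j, i] <- mk$overlap
    kp[[(i - 1) * n + j]] <- mk
  }
  groups <- graph_components_adj(adj)
  out <- list()
  for (g in groups) {
    if (length(g) == 1) {
      out[[length(out) + 1]] <- members[[g]]
      next
    }
    # merge members into the first one's frame
    base <- members[[g[1]]]
    for (j in g[-1]) {
      i <- g[1]
      mk <- kp[[(min(i, j) - 1) * n + max(i, j)]]
      if (is.null(mk) || !mk$overlap) {
        mk <- match_keypoints(base$image, members[[j]]$image,
                              offset = -(members[[j]]$origin - base$origin),
                              min_quality = params$min_quality,
                              min_matches = params$min_matches)
      }
      good <- mk$good
      if (nrow(good) < 3) {
        stop("overlap verdict true but affine fit impossible for members ",
             i, " and ", j)
      }
      # keypoints were matched in image-local coords; shift fixed coords to
      # base frame
      af <- fit_affine(good)
      base <- blend_pair(base, members[[j]], af, params)
    }
    out[[length(out) + 1]] <- base
  }
  list(members = out, n_members = length(out))
}

graph_components_adj <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  split(seq_len(n), comp)
}

# Warp member B into A's frame via the affine (A-local fixed -> B-local
# moving), refine elastically, feather-blend on a canvas covering both.
blend_pair <- function(A, B, af, params) {
  ny <- nrow(A$image); nx <- ncol(A$image)
  # B's footprint in A's frame: inverse-affine image of B's bounding box
  M <- af$matrix
  lin <- matrix(c(M[1, 1], M[1, 2], M[2, 1], M[2, 2]), 2, 2, byrow = TRUE)
  inv <- solve(lin)
  corners <- rbind(c(1, 1), c(nrow(B$image), 1),
                   c(1, ncol(B$image)), c(nrow(B$image), ncol(B$image)))
  pre <- t(inv %*% t(sweep(corners, 2, c(M[1, 3], M[2, 3]))))
  y0 <- floor(min(1, pre[, 1])); x0 <- floor(min(1, pre[, 2]))
  y1 <- ceiling(max(ny, pre[, 1])); x1 <- ceiling(max(nx, pre[, 2]))
  cny <- y1 - y0 + 1; cnx <- x1 - x0 + 1
  yy <- rep(seq_len(cny), times = cnx) + y0 - 1
  xx <- rep(seq_len(cnx), each = cny) + x0 - 1
  src <- apply_affine(M, yy, xx)
  Bw <- matrix(bilinear_sample(B$image, src$y, src$x, fill = 0), cny, cnx)
  Ac <- matrix(bilinear_sample(A$image, yy, xx, fill = 0), cny, cnx)
  fl <- tryCatch({
    fp <- resolve_flow_params(params, dim(A$image))
    estimate_flow(Ac, Bw, patch_size = fp$patch_size,
                  stride = fp$stride,
                  search_radius = max(4L, fp$search_radius %/% 4),
                  min_peak = fp$min_peak,
                  max_peak_ratio = fp$max_peak_ratio)
  }, error = function(e) NULL)
  if (!is.null(fl) && any(fl$valid)) {
    fp <- resolve_flow_params(params, dim(A$image))
    mesh <- spring_mesh(dim(Bw), fp$mesh_spacing, k = fp$mesh_k, w = fp$mesh_w)
    cons <- flow_constraints(fl, mesh)
    mesh <- relax_mesh(mesh, cons)$mesh
    Bw2 <- warp_image(Bw, mesh)
  } else {
    Bw2 <- Bw
  }
  wA <- 1 * (Ac > 0)
  wB <- 1 * (Bw2 > 0)
  both <- wA + wB
  fused <- (Ac * wA + Bw2 * wB) / pmax(both, 1)
  fused[both == 0] <- 0
  list(image = as_uint8(round(fused)),
       origin = A$origin + c(y0 - 1, x0 - 1))
}

#' Find the root slice of a project
#'
#' The root slice is the smallest slice index whose fusion result is a
#' single contiguous image; Z alignment propagates outward from it in both
#' directions.
#'
#' @param fusion_counts named integer vector: slice index -> number of
#'   disjoint members after fusion (NA for missing slices).
#' @return the root slice index.
#' @export
find_root_slice <- function(fusion_counts) {
  idx <- as.integer(names(fusion_counts))
  ord <- order(idx)
  for (i in ord) {
    if (!is.na(fusion_counts[i]) && fusion_counts[i] == 1L) {
      return(idx[i])
    }
  }
  stop("no contiguous slice found: every slice has multiple disjoint images")
}

# Warp an image by an affine map (output p -> source A.(p,1)).
warp_affine <- function(image, A, output_extent = dim(image)) {
  ny <- output_extent[1]; nx <- output_extent[2]
  yy <- rep(seq_len(ny), times = nx); xx <- rep(seq_len(nx), each = ny)
  src <- apply_affine(A, yy, xx)
  matrix(bilinear_sample(image, src$y, src$x, fill = 0), ny, nx)
}

identity_affine <- function() {
  matrix(c(1, 0, 0, 1, 0, 0), 2, 3)
}

# Align a single slice image to a reference image: coarse translation
# (falling back to a keypoint affine when translation matching fails, e.g.
# under rotation), then multiscale flow + mesh relaxation. Translation is
# preferred as the per-step coarse model: a full affine estimated between
# every neighbor pair accumulates spurious scale drift over long stacks,
# while residual non-rigid deformation is the mesh's job.
align_slice_pair <- function(ref, img, params, search_scale = 1) {
  fp <- resolve_flow_params(params, dim(ref))
  A <- identity_affine()
  coarse_ok <- FALSE
  sr <- min(round(20 * search_scale), (min(dim(ref)) - 9) %/% 2)
  et <- tryCatch(estimate_translation(ref, img, sr),
                 error = function(e) list(valid = FALSE))
  if (isTRUE(et$valid)) {
    A[1, 3] <- et$dy; A[2, 3] <- et$dx
    coarse_ok <- TRUE
  }
  if (!coarse_ok) {
    mk <- match_keypoints(ref, img, min_quality = params$min_quality,
                          min_matches = max(3L, params$min_matches %/% 2),
                          search_radius = round(25 * search_scale))
    if (nrow(mk$good) >= 3) {
      af <- tryCatch(fit_affine(mk$good), error = function(e) NULL)
      if (!is.null(af) && af$residual_rms < 5) {
        A <- af$matrix
        coarse_ok <- TRUE
      }
    }
  }
  if (!coarse_ok) return(NULL)
  warped1 <- warp_affine(img, A, dim(ref))
  # dual-scale constraints: large patches give accurate interior estimates,
  # smaller patches extend coverage toward the borders where a large patch
  # does not fit; small-patch nodes only fill mesh nodes the large-patch
  # hull misses
  small_patch <- max(25L, min(fp$patch_size, 2L * (fp$patch_size %/% 4L) + 1L))
  dual_constraints <- function(fixed, moving, sr_main, sr_border) {
    fl <- tryCatch(
      multiscale_flow(fixed, moving, scales = params$scales,
                      patch_size = fp$patch_size, stride = fp$stride,
                      search_radius = sr_main,
                      min_peak = fp$min_peak,
                      max_peak_ratio = fp$max_peak_ratio),
      error = function(e) NULL)
    flb <- tryCatch(
      estimate_flow(fixed, moving, patch_size = small_patch,
                    stride = fp$stride, search_radius = sr_border,
                    min_peak = fp$min_peak,
                    max_peak_ratio = fp$max_peak_ratio),
      error = function(e) NULL)
    cons <- NULL
    mesh0 <- spring_mesh(dim(fixed), fp$mesh_spacing, k = fp$mesh_k,
                         w = fp$mesh_w)
    if (!is.null(fl) && any(fl$valid)) {
      cons <- flow_constraints(filter_flow(fl), mesh0)
    }
    consb <- NULL
    if (!is.null(flb) && any(flb$valid)) {
      consb <- flow_constraints(filter_flow(flb), mesh0,
                                weight = 0.5 * fp$mesh_w)
    }
    if (is.null(cons)) return(consb)
    if (is.null(consb)) return(cons)
    combine_constraints(cons, consb)
  }
  mesh <- spring_mesh(dim(ref), fp$mesh_spacing, k = fp$mesh_k, w = fp$mesh_w)
  cons <- dual_constraints(ref, warped1, max(4L, fp$search_radius %/% 4), 6L)
  if (!is.null(cons)) {
    mesh <- relax_mesh(mesh, cons)$mesh
  }
  # refinement passes: re-measure residual flow on the rendered result and
  # compose the correction into the mesh; this cancels most of the
  # patch-averaging attenuation and sub-pixel bias of a single pass
  for (pass in seq_len(params$refine_iters)) {
    rendered <- warp_image(warped1, mesh, dim(ref))
    cons2 <- dual_constraints(ref, rendered, 4L, 4L)
    if (is.null(cons2)) break
    outer_mesh <- spring_mesh(dim(ref), fp$mesh_spacing, k = fp$mesh_k,
                              w = fp$mesh_w)
    outer_mesh <- relax_mesh(outer_mesh, cons2)$mesh
    if (max(abs(outer_mesh$dy), abs(outer_mesh$dx)) < 0.005) break
    mesh <- compose_meshes(outer_mesh, mesh)
  }
  rendered <- warp_image(warped1, mesh, dim(ref))
  resid <- if (!is.null(cons) && any(cons$w > 0)) {
    sel <- cons$w > 0
    stats::median(sqrt(cons$ty[sel]^2 + cons$tx[sel]^2))
  } else NA_real_
  list(affine = A, mesh = mesh, rendered = as_uint8(round(rendered)),
       flow_residual = resid,
       valid_fraction = if (is.null(cons)) 0 else mean(cons$w > 0))
}

#' Align fused slices along Z from the root slice
#'
#' Propagates outward from the root in both directions; each slice is
#' aligned (coarse affine from keypoints, elastic flow + mesh) to its last
#' processed neighbor. Slices in `skip_slices` are warped with their
#' neighbor's transform but never serve as reference; missing slices become
#' black slices and are bridged (the search range grows with the gap);
#' unalignable slices are recorded as failed and treated like skips.
#'
#' @param slices list of slice images, indexed 1..n (NULL = missing).
#' @param root root slice index (see [find_root_slice()]).
#' @param skip_slices indices never used as reference.
#' @param params [align_params()].
#' @param journal optional path to a journal file for resumability.
#' @param workdir optional directory where per-slice renders are cached
#'   (required when `journal` is used).
#' @return an `aligned_stack`: `images` (list, black for missing),
#'   `transforms` (per slice: affine + mesh or NULL), `status` character
#'   vector (root/done/skip/missing/failed), `root`.
#' @export
align_z <- function(slices, root, skip_slices = integer(),
                    params = align_params(), journal = NULL,
                    workdir = NULL) {
  n <- length(slices)
  if (root < 1 || root > n || is.null(slices[[root]])) {
    stop("invalid root slice")
  }
  dims <- dim(slices[[root]])
  black <- matrix(0L, dims[1], dims[2])
  images <- vector("list", n)
  transforms <- vector("list", n)
  status <- rep("pending", n)
  images[[root]] <- slices[[root]]
  transforms[[root]] <- list(affine = identity_affine(), mesh = NULL)
  status[root] <- "root"
  jrec <- function(slice, st, metrics = NULL) {
    if (!is.null(journal)) {
      journal_record(journal, step = "z", unit = slice, status = st,
                     metrics = metrics)
    }
  }
  jrec(root, "done")
  do_direction <- function(idxs) {
    ref <- slices[[root]]
    gap <- 0
    last_tf <- NULL
    for (i in idxs) {
      if (!is.null(journal) && !is.null(workdir) &&
          journal_is_done(journal, "z", i)) {
        f <- file.path(workdir, sprintf("z_S%04d.tif", i))
        tf <- file.path(workdir, sprintf("z_T%04d.json", i))
        if (file.exists(f)) {
          images[[i]] <<- read_image(f)
          if (file.exists(tf)) {
            transforms[[i]] <<- transform_from_json(tf)
            last_tf <- transforms[[i]]
          }
          status[i] <<- "done"
          if (!(i %in% skip_slices) && !is.null(images[[i]]) &&
              any(images[[i]] > 0)) {
            ref <- images[[i]]; gap <- 0
          }
          next
        }
      }
      if (is.null(slices[[i]])) {
        images[[i]] <<- black
        status[i] <<- "missing"
        gap <- gap + 1
        jrec(i, "missing")
        next
      }
      sc <- 1 + params$z_gap_growth * gap
      res <- align_slice_pair(ref, slices[[i]], params, search_scale = sc)
      if (is.null(res)) {
        # unalignable: warp with the neighbor's transform if available
        if (!is.null(last_tf)) {
          w1 <- warp_affine(slices[[i]], last_tf$affine, dims)
          images[[i]] <<- if (is.null(last_tf$mesh)) as_uint8(w1) else
            as_uint8(round(warp_image(w1, last_tf$mesh, dims)))
          transforms[[i]] <<- last_tf
        } else {
          images[[i]] <<- slices[[i]]
          transforms[[i]] <<- list(affine = identity_affine(), mesh = NULL)
        }
        status[i] <<- "failed"
        jrec(i, "failed")
        next
      }
      images[[i]] <<- res$rendered
      transforms[[i]] <<- list(affine = res$affine, mesh = res$mesh)
      last_tf <- transforms[[i]]
      if (i %in% skip_slices) {
        status[i] <<- "skip"
        jrec(i, "skip", list(flow_residual = res$flow_residual))
      } else {
        status[i] <<- "done"
        ref <- res$rendered
        gap <- 0
        jrec(i, "done", list(flow_residual = res$flow_residual,
                             valid_fraction = res$valid_fraction))
      }
      if (!is.null(workdir)) {
        dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
        write_image(images[[i]], file.path(workdir, sprintf("z_S%04d.tif", i)))
        transform_to_json(transforms[[i]],
                          file.path(workdir, sprintf("z_T%04d.json", i)))
      }
    }
  }
  if (root < n) do_direction((root + 1):n)
  if (root > 1) do_direction((root - 1):1)
  structure(list(images = images, transforms = transforms, status = status,
                 root = root, dims = dims),
            class = "aligned_stack")
}

transform_to_json <- function(tf, path) {
  l <- list(affine = as.vector(tf$affine),
            mesh = if (is.null(tf$mesh)) NULL else mesh_to_list(tf$mesh))
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

transform_from_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(affine = matrix(unlist(l$affine), 2, 3),
       mesh = if (is.null(l$mesh)) NULL else mesh_from_list(l$mesh))
}

#' Register a high-resolution stack into its reference frame
#'
#' Each high-resolution (synaptic class) slice is downsampled to the
#' reference (cellular class) scale, localized within the nearest available
#' non-black reference slice by whole-template NCC, and elastically refined.
#' The returned transform places the high-resolution stack in reference
#' world coordinates at its own pixel pitch; no intra-stack Z alignment is
#' performed.
#'
#' @param hr_slices list of high-resolution slice images (NULL = missing).
#' @param hr_slice_index integer vector: reference-frame z index of each
#'   high-resolution slice.
#' @param reference an `aligned_stack` (its black slices are skipped as
#'   references).
#' @param ratio pixel-size ratio reference/highres (e.g. 4 when the
#'   reference is 40 nm and the stack 10 nm); integer.
#' @param params [align_params()].
#' @param z_window furthest |delta z| allowed when substituting a missing
#'   reference slice.
#' @return a `highres_registration`: per-slice list with `offset` (y, x in
#'   reference pixels of the hr window origin, i.e. hr pixel (1,1) maps to
#'   reference position offset + (1,1)/ratio), `mesh` (reference-scale
#'   elastic refinement), `ref_slice`, `quality`, `status`.
#' @export
align_highres_to_reference <- function(hr_slices, hr_slice_index, reference,
                                       ratio, params = align_params(),
                                       z_window = 5L) {
  stopifnot(length(hr_slices) == length(hr_slice_index))
  ref_ok <- which(vapply(reference$images,
                         function(im) !is.null(im) && any(im > 0), TRUE))
  out <- vector("list", length(hr_slices))
  for (i in seq_along(hr_slices)) {
    hr <- hr_slices[[i]]
    if (is.null(hr)) {
      out[[i]] <- list(status = "missing")
      next
    }
    z <- hr_slice_index[i]
    if (length(ref_ok) == 0) {
      out[[i]] <- list(status = "failed")
      next
    }
    dz <- abs(ref_ok - z)
    cand <- ref_ok[order(dz, ref_ok)]
    rz <- cand[1]
    if (abs(rz - z) > z_window) {
      out[[i]] <- list(status = "failed")
      next
    }
    refimg <- reference$images[[rz]]
    hr_lr <- downsample_mean(hr, ratio)
    if (any(dim(hr_lr) > dim(refimg))) {
      out[[i]] <- list(status = "failed")
      next
    }
    cmap <- ncc_map(refimg, hr_lr)
    pk <- peak_location(cmap, c(1, 1))
    q <- cmap[pk[1], pk[2]]
    if (!is.finite(q) || q < params$min_peak) {
      out[[i]] <- list(status = "failed")
      next
    }
    frac <- subpixel_peak(cmap, pk[1], pk[2])
    off <- c(pk[1] + frac[1] - 1, pk[2] + frac[2] - 1)
    # elastic refinement at reference scale within the matched window
    wy <- round(off[1]); wx <- round(off[2])
    ys <- (wy + 1):min(wy + nrow(hr_lr), nrow(refimg))
    xs <- (wx + 1):min(wx + ncol(hr_lr), ncol(refimg))
    refwin <- refimg[ys, xs, drop = FALSE]
    hrwin <- hr_lr[seq_along(ys), seq_along(xs), drop = FALSE]
    fp <- resolve_flow_params(params, dim(hrwin))
    if (is.null(params$patch_size)) {
      # within the (small) matched window, larger patches than the generic
      # default stabilize the refinement flow
      fp$patch_size <- 2L * (min(dim(hrwin)) %/% 4L) + 1L
      fp$stride <- max(6L, fp$patch_size %/% 4L)
      fp$mesh_spacing <- fp$stride
    }
    mesh <- spring_mesh(dim(hr_lr), fp$mesh_spacing, k = fp$mesh_k, w = fp$mesh_w)
    fl <- tryCatch(
      estimate_flow(refwin, hrwin, patch_size = fp$patch_size,
                    stride = fp$stride,
                    search_radius = max(3L, fp$search_radius %/% 4),
                    min_peak = fp$min_peak,
                    max_peak_ratio = fp$max_peak_ratio),
      error = function(e) NULL)
    if (!is.null(fl) && any(fl$valid)) {
      cons <- flow_constraints(fl, mesh)
      # the flow measures hr content displaced relative to the reference
      # window; correcting the hr placement means subtracting it
      cons$ty <- -cons$ty; cons$tx <- -cons$tx
      mesh <- relax_mesh(mesh, cons)$mesh
    }
    out[[i]] <- list(offset = off, mesh = mesh, ref_slice = rz,
                     quality = q, status = "done")
  }
  structure(list(slices = out, ratio = ratio,
                 hr_slice_index = hr_slice_index),
            class = "highres_registration")
}

#' Map high-resolution voxel coordinates to reference-frame coordinates
#'
#' @param reg a `highres_registration`.
#' @param i high-resolution slice number (position in the registered list).
#' @param y,x high-resolution pixel coordinates.
#' @return list of reference-frame `y`, `x` (reference pixels) or NULL if
#'   the slice was not registered.
#' @export
highres_to_reference <- function(reg, i, y, x) {
  s <- reg$slices[[i]]
  if (is.null(s) || !identical(s$status, "done")) return(NULL)
  # pixel-center convention: high-res pixel v sits at position
  # (v - 0.5) / ratio + 0.5 of the downsampled window, whose pixel (1,1)
  # is matched at `offset` in the reference
  ly <- (y - 0.5) / reg$ratio + 0.5
  lx <- (x - 0.5) / reg$ratio + 0.5
  ry <- s$offset[1] + ly
  rx <- s$offset[2] + lx
  if (!is.null(s$mesh)) {
    d <- mesh_displacement(s$mesh, ly, lx)
    ry <- ry + d$dy; rx <- rx + d$dx
  }
  list(y = ry, x = rx)
}

#' Render aligned outputs to disk
#'
#' Writes the full-resolution aligned slices, an n-fold downsampled copy,
#' and the transform bundle (affines + meshes as JSON) sufficient for a
#' bit-identical re-render via [rerender_stack()].
#'
#' @param aligned an `aligned_stack`.
#' @param dir output directory.
#' @param downsample integer downsampling factor for the preview copy.
#' @return `dir`, invisibly.
#' @export
render_outputs <- function(aligned, dir, downsample = 4L) {
  dir.create(file.path(dir, "full"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "down"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "transforms"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_along(aligned$images)) {
    img <- aligned$images[[i]]
    if (is.null(img)) img <- matrix(0L, aligned$dims[1], aligned$dims[2])
    write_image(img, file.path(dir, "full", sprintf("S%04d.tif", i)))
    write_image(as_uint8(round(downsample_mean(img, downsample))),
                file.path(dir, "down", sprintf("S%04d.tif", i)))
    if (!is.null(aligned$transforms[[i]])) {
      transform_to_json(aligned$transforms[[i]],
                        file.path(dir, "transforms", sprintf("T%04d.json", i)))
    }
  }
  meta <- list(n = length(aligned$images), root = aligned$root,
               dims = aligned$dims, status = aligned$status,
               downsample = downsample)
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Re-render an aligned stack from saved transforms
#'
#' Applies the saved per-slice transforms to the supplied source slices;
#' the result is bit-identical to the original alignment run.
#'
#' @param slices the same source slice list given to [align_z()].
#' @param dir directory written by [render_outputs()].
#' @return list of re-rendered slice images.
#' @export
rerender_stack <- function(slices, dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  out <- vector("list", meta$n)
  for (i in seq_len(meta$n)) {
    st <- meta$status[i]
    if (st == "missing" || is.null(slices[[i]])) {
      out[[i]] <- matrix(0L, dims[1], dims[2])
      next
    }
    tfp <- file.path(dir, "transforms", sprintf("T%04d.json", i))
    if (!file.exists(tfp)) {
      out[[i]] <- slices[[i]]
      next
    }
    tf <- transform_from_json(tfp)
    if (st == "root") {
      out[[i]] <- slices[[i]]
      next
    }
    w1 <- warp_affine(slices[[i]], tf$affine, dims)
    out[[i]] <- if (is.null(tf$mesh)) as_uint8(round(w1)) else
      as_uint8(round(warp_image(w1, tf$mesh, dims)))
  }
  out
}

# ---- journal (JSON-lines, append-only) --------------------------------

#' Alignment journal
#'
#' Append-only JSON-lines store recording, per pipeline step and work unit,
#' the status and quality metrics of processing. A re-run skips units whose
#' latest record is `done`; [journal_wipe()] invalidates records for
#' arbitrary steps and unit ranges so they are recomputed.
#'
#' @param path journal file path.
#' @param step step name (e.g. "xy", "z").
#' @param unit work-unit identifier (e.g. slice index).
#' @param status one of "pending", "done", "skip", "missing", "failed",
#'   "wiped".
#' @param metrics optional named list of numeric quality metrics.
#' @return `journal_record` returns `path` invisibly; `journal_read` a
#'   data.frame; `journal_is_done` a logical.
#' @export
journal_record <- function(path, step, unit, status, metrics = NULL) {
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              step = step, unit = unit, status = status)
  if (!is.null(metrics)) rec$metrics <- metrics
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  invisible(path)
}

#' @rdname journal_record
#' @export
journal_read <- function(path) {
  if (!file.exists(path)) {
    return(data.frame(time = character(), step = character(),
                      unit = integer(), status = character()))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(time = vapply(recs, `[[`, "", "time"),
             step = vapply(recs, `[[`, "", "step"),
             unit = vapply(recs, function(r) as.integer(r$unit), 0L),
             status = vapply(recs, `[[`, "", "status"))
}

#' @rdname journal_record
#' @export
journal_is_done <- function(path, step, unit) {
  j <- journal_read(path)
  j <- j[j$step == step & j$unit == unit, , drop = FALSE]
  if (nrow(j) == 0) return(FALSE)
  utils::tail(j$status, 1) == "done"
}

#' @rdname journal_record
#' @param units integer vector of unit ids to wipe.
#' @export
journal_wipe <- function(path, step, units) {
  for (u in units) journal_record(path, step, u, "wiped")
  invisible(path)
}
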