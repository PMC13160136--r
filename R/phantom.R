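# Synthetic EM phantom generation.
#
# Every input consumed by the alignment, segmentation and connectivity
# modules can be produced here with known ground truth: label volumes of
# tube-like neurites, EM-style greyscale renderings, tiled + deformed
# acquisition trees, affinity volumes, synapse pair tables.

# Grey levels used by the renderer; membranes must stay clearly darker than
# interiors even after texture (+-TEXTURE_AMP) is applied.
GREY_MEMBRANE <- 40
GREY_INTERIOR <- 150
GREY_BACKGROUND <- 200
TEXTURE_AMP <- 25

#' Specification of a synthetic neural-tissue phantom
#'
#' Describes a small stained-tissue stand-in: a stack of slices containing
#' tube-like neurites (biased random walks along z) separated by dark
#' membranes, rendered as an 8-bit EM-like volume.
#'
#' @param volume_shape integer (z, y, x) in voxels; every dimension >= 8.
#' @param n_neurites number of neurite tubes (>= 1).
#' @param neurite_radius tube radius in voxels.
#' @param membrane_width membrane thickness in voxels (>= 1).
#' @param noise_sigma standard deviation of additive Gaussian grey noise.
#' @param seed integer seed; generation is deterministic per seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(16L, 96L, 96L), n_neurites = 20L,
                         neurite_radius = 5L, membrane_width = 1L,
                         noise_sigma = 3, seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 8)) {
    stop("volume_shape must be (z, y, x) with all dimensions >= 8")
  }
  if (n_neurites < 1) stop("n_neurites must be >= 1")
  if (neurite_radius < 1) stop("neurite_radius must be >= 1")
  if (membrane_width < 1) stop("membrane_width must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(volume_shape = volume_shape,
                 n_neurites = as.integer(n_neurites),
                 neurite_radius = as.integer(neurite_radius),
                 membrane_width = as.integer(membrane_width),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth 2-D random texture in [-1, 1]: coarse white noise upsampled
# bilinearly. Used for interior/background texture so flow patches always
# carry matchable structure.
smooth_noise_2d <- function(ny, nx, cell = 8) {
  gy <- max(2, ceiling(ny / cell) + 1)
  gx <- max(2, ceiling(nx / cell) + 1)
  g <- matrix(runif(gy * gx, -1, 1), gy, gx)
  upsample_field(g, cell, ny, nx)
}

#' Generate a phantom label volume and its EM rendering
#'
#' Neurites are grown as biased random walks along z and stamped as disks of
#' `neurite_radius`, so consecutive slices share most of their content (a
#' requirement of neighbor-based Z alignment). The EM rendering draws dark
#' membranes wherever labels change between 6-connected voxels, textured
#' mid-grey interiors, a lighter textured extracellular background, and
#' optional additive Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with `labels` (integer array z,y,x; 0 = background) and
#'   `em` (integer array z,y,x in 0..255).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$volume_shape[1]; ny <- spec$volume_shape[2]; nx <- spec$volume_shape[3]
  r <- spec$neurite_radius
  if (2 * (r + 1) > min(ny, nx)) {
    stop("volume cross-section too small to fit one neurite of this radius")
  }
  with_seed(spec$seed, {
    labels <- array(0L, dim = c(nz, ny, nx))
    # disk offsets for stamping
    dd <- expand.grid(dy = -r:r, dx = -r:r)
    dd <- dd[dd$dy^2 + dd$dx^2 <= r^2, ]
    for (i in seq_len(spec$n_neurites)) {
      cy0 <- runif(1, r + 1, ny - r)
      cx0 <- runif(1, r + 1, nx - r)
      # tube axis along z with mean-reverting lateral wiggle: neurites run
      # roughly straight (sub-pixel drift per 50 nm section) but wander
      # enough that consecutive slices are not identical
      py <- 0; px <- 0
      for (z in seq_len(nz)) {
        py <- 0.8 * py + rnorm(1, 0, 0.4)
        px <- 0.8 * px + rnorm(1, 0, 0.4)
        cy <- clamp(cy0 + py, r + 1, ny - r)
        cx <- clamp(cx0 + px, r + 1, nx - r)
        ys <- round(cy) + dd$dy; xs <- round(cx) + dd$dx
        ok <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
        idx <- cbind(z, ys[ok], xs[ok])
        free <- labels[idx] == 0L
        labels[idx[free, , drop = FALSE]] <- i
      }
    }
    # earlier tubes can cut later ones into pieces (stamping never
    # overwrites); relabel by connected components so every label is one
    # 6-connected object, as a segmentation ground truth must be
    labels <- label_components(labels)
    em <- render_em(labels, spec$membrane_width, spec$noise_sigma)
    list(labels = labels, em = em)
  })
}

# 6-connected boundary mask: voxel whose label differs from any face neighbor.
boundary_mask <- function(labels) {
  d <- dim(labels)
  m <- array(FALSE, d)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (nz > 1) {
    df <- labels[-1, , , drop = FALSE] != labels[-nz, , , drop = FALSE]
    m[-nz, , ] <- m[-nz, , , drop = FALSE] | df
    m[-1, , ] <- m[-1, , , drop = FALSE] | df
  }
  df <- labels[, -1, , drop = FALSE] != labels[, -ny, , drop = FALSE]
  m[, -ny, ] <- m[, -ny, , drop = FALSE] | df
  m[, -1, ] <- m[, -1, , drop = FALSE] | df
  df <- labels[, , -1, drop = FALSE] != labels[, , -nx, drop = FALSE]
  m[, , -nx] <- m[, , -nx, drop = FALSE] | df
  m[, , -1] <- m[, , -1, drop = FALSE] | df
  m
}

dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (nz > 1) {
    out[-nz, , ] <- out[-nz, , , drop = FALSE] | mask[-1, , , drop = FALSE]
    out[-1, , ] <- out[-1, , , drop = FALSE] | mask[-nz, , , drop = FALSE]
  }
  out[, -ny, ] <- out[, -ny, , drop = FALSE] | mask[, -1, , drop = FALSE]
  out[, -1, ] <- out[, -1, , drop = FALSE] | mask[, -ny, , drop = FALSE]
  out[, , -nx] <- out[, , -nx, drop = FALSE] | mask[, , -1, drop = FALSE]
  out[, , -1] <- out[, , -1, drop = FALSE] | mask[, , -nx, drop = FALSE]
  out
}

render_em <- function(labels, membrane_width, noise_sigma) {
  d <- dim(labels)
  em <- array(GREY_BACKGROUND, d)
  em[labels > 0L] <- GREY_INTERIOR
  memb <- boundary_mask(labels)
  if (membrane_width > 1) {
    for (i in seq_len(membrane_width - 1)) memb <- dilate6(memb)
  }
  # Coarse texture (organelle-scale) plus fine texture (vesicle-scale); the
  # fine component keeps correlation peaks sharp for block matching. Both
  # evolve as AR(1) processes along z, with persistence set by feature size
  # relative to the ~50 nm section: organelles (~0.5-1 um) span many
  # sections and decorrelate slowly, vesicle-scale texture much faster.
  p_coarse <- 0.9
  p_fine <- 0.5
  tc <- smooth_noise_2d(d[2], d[3], cell = 8)
  tf <- smooth_noise_2d(d[2], d[3], cell = 2)
  for (z in seq_len(d[1])) {
    if (z > 1) {
      tc <- p_coarse * tc +
        sqrt(1 - p_coarse^2) * smooth_noise_2d(d[2], d[3], cell = 8)
      tf <- p_fine * tf +
        sqrt(1 - p_fine^2) * smooth_noise_2d(d[2], d[3], cell = 2)
    }
    em[z, , ] <- em[z, , ] + TEXTURE_AMP * tc + 0.5 * TEXTURE_AMP * tf
  }
  em[memb] <- GREY_MEMBRANE
  if (noise_sigma > 0) em <- em + rnorm(length(em), 0, noise_sigma)
  array(as_uint8(round(em)), d)
}

#' Ground-truth deformation for a synthetic acquisition
#'
#' Builds the composed distortion applied when a phantom is "acquired": a
#' rigid translation per slice, a smooth elastic displacement field per slice
#' (a sum of at most five low-frequency sinusoidal components whose
#' amplitudes and phases drift slowly along z, emulating slowly varying
#' detector distortion), and an independent translation jitter per tile.
#'
#' @param n_slices number of slices.
#' @param slice_shape (ny, nx) of a full slice in pixels.
#' @param grid tile grid (gy, gx).
#' @param rigid_amplitude max |per-slice translation| per axis, pixels.
#' @param elastic_amplitude max total elastic displacement per axis, pixels.
#' @param n_components number of sinusoidal components (<= 5).
#' @param jitter_amplitude max |per-tile translation| per axis, pixels.
#' @param seed integer seed.
#' @return object of class `gt_warp`.
#' @export
ground_truth_warp <- function(n_slices, slice_shape, grid = c(1L, 1L),
                              rigid_amplitude = 3, elastic_amplitude = 4,
                              n_components = 3, jitter_amplitude = 2,
                              seed = 1L) {
  stopifnot(n_components <= 5, n_components >= 0)
  with_seed(seed, {
    rigid <- matrix(runif(2 * n_slices, -rigid_amplitude, rigid_amplitude),
                    n_slices, 2, dimnames = list(NULL, c("dy", "dx")))
    comps <- NULL
    if (n_components > 0 && elastic_amplitude > 0) {
      # A combined spatial wavelength of at least the field-of-view size
      # keeps the warp inside the low-frequency regime a patchwise flow
      # estimator can recover; direction and magnitude of the wave vector
      # are drawn separately so the bound holds jointly over both axes.
      mindim <- min(slice_shape)
      comps <- lapply(seq_len(n_components), function(i) {
        ang <- runif(1, 0, 2 * pi)
        mag <- runif(1, 0.25, 1) / mindim
        list(
          fy = mag * sin(ang),
          fx = mag * cos(ang),
          amp_y = runif(1, 0.3, 1) * elastic_amplitude / n_components,
          amp_x = runif(1, 0.3, 1) * elastic_amplitude / n_components,
          phase_y = runif(1, 0, 2 * pi),
          phase_x = runif(1, 0, 2 * pi),
          zfreq = runif(1, 0.2, 0.8) / n_slices,
          zphase = runif(1, 0, 2 * pi)
        )
      })
    }
    jitter <- array(runif(n_slices * grid[1] * grid[2] * 2,
                          -jitter_amplitude, jitter_amplitude),
                    dim = c(n_slices, grid[1], grid[2], 2))
    structure(list(n_slices = n_slices, slice_shape = slice_shape,
                   grid = as.integer(grid), rigid = rigid,
                   components = comps, jitter = jitter, seed = seed),
              class = "gt_warp")
  })
}

#' Evaluate a ground-truth warp's displacement at pixel positions
#'
#' Returns the slice-level (rigid + elastic) displacement, excluding
#' per-tile jitter, at given (y, x) positions of slice `slice`.
#'
#' @param warp a [ground_truth_warp()] object.
#' @param slice slice index (1-based).
#' @param y,x numeric vectors of equal length.
#' @return list with numeric vectors `dy`, `dx`.
#' @export
warp_displacement <- function(warp, slice, y, x) {
  dy <- rep(warp$rigid[slice, 1], length(y))
  dx <- rep(warp$rigid[slice, 2], length(x))
  for (cmp in warp$components) {
    zmod <- 0.5 + 0.5 * sin(2 * pi * cmp$zfreq * slice + cmp$zphase)
    ph <- 2 * pi * (cmp$fy * y + cmp$fx * x)
    dy <- dy + zmod * cmp$amp_y * sin(ph + cmp$phase_y)
    dx <- dx + zmod * cmp$amp_x * sin(ph + cmp$phase_x)
  }
  list(dy = dy, dx = dx)
}

# Tile origins (0-based offsets) for a grid over an extent, with uniform step
# round(tile * (1 - overlap)). Errors if tiles cannot cover the extent.
tile_origins <- function(extent, g, tile, overlap_fraction) {
  step <- round(tile * (1 - overlap_fraction))
  if (g > 1 && tile - step < 1) {
    stop("overlap too small: adjacent tiles would not share any pixels")
  }
  covered <- (g - 1) * step + tile
  if (covered < extent) {
    stop(sprintf(
      "overlap too small: %d tiles of %d px with step %d cover %d < %d px",
      g, tile, step, covered, extent))
  }
  (seq_len(g) - 1) * step
}

#' Write a synthetic tiled acquisition directory tree
#'
#' Cuts an EM phantom volume into per-slice tile grids with the stated
#' overlap, warps each tile by the composed ground-truth transform (slice
#' rigid + elastic + per-tile jitter), and writes them in the toolkit's
#' reference acquisition dialect: `Tile_r{row}c{col}_S{slice}.tif` plus a
#' `metadata_S{slice}.txt` file per slice containing `pixel_size_nm=<v>`.
#' Slices listed in `dropout_slices` are omitted entirely, emulating lost
#' sections.
#'
#' The acquisition model is backward: each acquired tile pixel samples the
#' phantom at its nominal position plus the ground-truth displacement, so the
#' alignment pipeline must recover (approximately) the inverse composed
#' transform.
#'
#' @param em integer array (z, y, x), the EM phantom.
#' @param grid (gy, gx) tile grid.
#' @param overlap_fraction nominal tile overlap as a fraction of tile shape
#'   in `[0, 1)`; default 0.15.
#' @param warp a [ground_truth_warp()] matching `grid` and slice count; NULL
#'   for an identity acquisition.
#' @param dropout_slices integer slice indices (1-based) to omit.
#' @param dir output directory (created).
#' @param pixel_size_nm pixel size written to per-slice metadata.
#' @param tile_shape optional (ty, tx); computed from grid and overlap to
#'   cover the slice when NULL.
#' @return invisibly, the ground-truth manifest (also written to
#'   `ground_truth.json` in `dir`): tile origins, shapes, grid, overlap,
#'   dropouts, pixel size, and the warp.
#' @export
tile_and_deform <- function(em, grid, overlap_fraction = 0.15, warp = NULL,
                            dropout_slices = integer(), dir,
                            pixel_size_nm = 40, tile_shape = NULL) {
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  d <- dim(em)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  gy <- grid[1]; gx <- grid[2]
  if (is.null(tile_shape)) {
    pick <- function(extent, g) {
      if (g == 1) return(extent)
      t0 <- ceiling(extent / (1 + (g - 1) * (1 - overlap_fraction)))
      while ((g - 1) * round(t0 * (1 - overlap_fraction)) + t0 < extent) {
        t0 <- t0 + 1
      }
      t0
    }
    tile_shape <- c(pick(ny, gy), pick(nx, gx))
  }
  oy <- tile_origins(ny, gy, tile_shape[1], overlap_fraction)
  ox <- tile_origins(nx, gx, tile_shape[2], overlap_fraction)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  py <- rep(seq_len(tile_shape[1]), times = tile_shape[2])
  px <- rep(seq_len(tile_shape[2]), each = tile_shape[1])
  for (z in seq_len(nz)) {
    if (z %in% dropout_slices) next
    slice <- em[z, , ]
    for (r in seq_len(gy)) {
      for (cc in seq_len(gx)) {
        jy <- 0; jx <- 0
        if (!is.null(warp)) {
          jy <- warp$jitter[z, r, cc, 1]
          jx <- warp$jitter[z, r, cc, 2]
        }
        wy <- py + oy[r] + jy
        wx <- px + ox[cc] + jx
        if (!is.null(warp)) {
          dsp <- warp_displacement(warp, z, wy, wx)
          wy <- wy + dsp$dy
          wx <- wx + dsp$dx
        }
        vals <- bilinear_sample(slice, wy, wx, fill = 0)
        tile <- matrix(vals, tile_shape[1], tile_shape[2])
        fn <- file.path(dir, sprintf("Tile_r%dc%d_S%d.tif", r - 1, cc - 1, z - 1))
        write_image(tile, fn)
      }
    }
    writeLines(sprintf("pixel_size_nm=%g", pixel_size_nm),
               file.path(dir, sprintf("metadata_S%d.txt", z - 1)))
  }
  manifest <- list(grid = c(gy, gx), tile_shape = tile_shape,
                   origins_y = oy, origins_x = ox,
                   overlap_fraction = overlap_fraction,
                   slice_shape = c(ny, nx), n_slices = nz,
                   dropout_slices = as.integer(dropout_slices),
                   pixel_size_nm = pixel_size_nm)
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$warp <- warp
  invisible(manifest)
}

#' Generate nearest-neighbor affinities from a label volume
#'
#' Affinity along each axis is 1 where both face-adjacent voxels share the
#' same nonzero label and 0 otherwise. With probability `hole_rate` per
#' touching label pair, a small patch of that pair's boundary is flipped to
#' affinity 1, emulating membrane holes that cause false merges. Optional
#' clipped additive Gaussian noise is applied last.
#'
#' @param labels integer array (z, y, x).
#' @param hole_rate probability in `[0, 1]` that a touching label pair gets a
#'   membrane hole.
#' @param noise_sigma sd of additive noise (clipped back to `[0, 1]`).
#' @param seed integer seed.
#' @return numeric array (3, z, y, x); channel 1/2/3 is the affinity between
#'   voxel v and its +z/+y/+x neighbor; entries whose partner lies outside
#'   the volume are 0.
#' @export
make_affinities <- function(labels, hole_rate = 0, noise_sigma = 0,
                            seed = 1L) {
  d <- dim(labels)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  aff <- array(0, dim = c(3, nz, ny, nx))
  same_pos <- function(a, b) as.numeric(a == b & a > 0L)
  if (nz > 1) {
    aff[1, -nz, , ] <- same_pos(labels[-nz, , , drop = FALSE],
                                labels[-1, , , drop = FALSE])
  }
  aff[2, , -ny, ] <- same_pos(labels[, -ny, , drop = FALSE],
                              labels[, -1, , drop = FALSE])
  aff[3, , , -nx] <- same_pos(labels[, , -nx, drop = FALSE],
                              labels[, , -1, drop = FALSE])
  with_seed(seed, {
    if (hole_rate > 0) {
      edges <- contact_edge_list(labels)
      if (nrow(edges) > 0) {
        pairs <- unique(edges[, c("la", "lb")])
        for (pi in seq_len(nrow(pairs))) {
          if (runif(1) > hole_rate) next
          sel <- edges$la == pairs$la[pi] & edges$lb == pairs$lb[pi]
          sub <- edges[sel, , drop = FALSE]
          ctr <- sub[sample.int(nrow(sub), 1), ]
          dist <- abs(sub$z - ctr$z) + abs(sub$y - ctr$y) + abs(sub$x - ctr$x)
          hole <- sub[dist <= 2, , drop = FALSE]
          aff[cbind(hole$axis, hole$z, hole$y, hole$x)] <- 1
        }
      }
    }
    if (noise_sigma > 0) {
      aff <- clamp(aff + rnorm(length(aff), 0, noise_sigma), 0, 1)
    }
  })
  aff
}

# All face-adjacent voxel pairs whose labels differ and are both nonzero.
# Returns the edge anchored at the lower voxel (channel convention), with the
# (unordered, la < lb) label pair.
contact_edge_list <- function(labels) {
  d <- dim(labels)
  res <- list()
  take <- function(axis, idx_a, idx_b) {
    la <- labels[idx_a]; lb <- labels[idx_b]
    keep <- la > 0L & lb > 0L & la != lb
    if (!any(keep)) return(NULL)
    data.frame(axis = axis,
               z = idx_a[keep, 1], y = idx_a[keep, 2], x = idx_a[keep, 3],
               la = pmin(la[keep], lb[keep]), lb = pmax(la[keep], lb[keep]))
  }
  grid_idx <- function(zs, ys, xs) {
    as.matrix(expand.grid(z = zs, y = ys, x = xs))
  }
  if (d[1] > 1) {
    ia <- grid_idx(seq_len(d[1] - 1), seq_len(d[2]), seq_len(d[3]))
    ib <- ia; ib[, 1] <- ib[, 1] + 1L
    res$z <- take(1L, ia, ib)
  }
  ia <- grid_idx(seq_len(d[1]), seq_len(d[2] - 1), seq_len(d[3]))
  ib <- ia; ib[, 2] <- ib[, 2] + 1L
  res$y <- take(2L, ia, ib)
  ia <- grid_idx(seq_len(d[1]), seq_len(d[2]), seq_len(d[3] - 1))
  ib <- ia; ib[, 3] <- ib[, 3] + 1L
  res$x <- take(3L, ia, ib)
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(axis = integer(), z = integer(), y = integer(),
                      x = integer(), la = integer(), lb = integer())
  }
  rownames(out) <- NULL
  out
}

#' Generate a synthetic synapse pair table
#'
#' Samples `n_pairs` pre/post voxel pairs inside labeled neurites. With
#' probability `autapse_rate` both sides are drawn from the same label
#' (a synthetic autapse artifact); otherwise the two sides come from two
#' distinct labels. Confidence scores are uniform in `[0, 1]`.
#'
#' @param labels integer array (z, y, x) with at least one positive label
#'   (at least two if `autapse_rate < 1`).
#' @param n_pairs number of pairs (>= 0).
#' @param autapse_rate probability a pair is an autapse.
#' @param seed integer seed.
#' @return data.frame with columns pre_z, pre_y, pre_x, post_z, post_y,
#'   post_x, score; the generating labels are attached as attribute `truth`
#'   (data.frame pre_label, post_label).
#' @export
make_synapses <- function(labels, n_pairs, autapse_rate = 0, seed = 1L) {
  if (n_pairs < 0) stop("n_pairs must be >= 0")
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) < 1) stop("label volume contains no positive labels")
  if (autapse_rate < 1 && length(present) < 2) {
    stop("need >= 2 labels when autapse_rate < 1")
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  colnames(idx) <- c("z", "y", "x")
  lab <- labels[idx]
  by_label <- split(seq_len(nrow(idx)), lab)
  with_seed(seed, {
    pre_i <- integer(n_pairs); post_i <- integer(n_pairs)
    for (i in seq_len(n_pairs)) {
      pre_i[i] <- sample.int(nrow(idx), 1)
      l <- lab[pre_i[i]]
      if (runif(1) < autapse_rate) {
        pool <- by_label[[as.character(l)]]
      } else {
        pool <- unlist(by_label[names(by_label) != as.character(l)],
                       use.names = FALSE)
      }
      post_i[i] <- pool[sample.int(length(pool), 1)]
    }
    out <- data.frame(
      pre_z = idx[pre_i, "z"], pre_y = idx[pre_i, "y"], pre_x = idx[pre_i, "x"],
      post_z = idx[post_i, "z"], post_y = idx[post_i, "y"],
      post_x = idx[post_i, "x"],
      score = runif(n_pairs))
    attr(out, "truth") <- data.frame(pre_label = lab[pre_i],
                                     post_label = lab[post_i])
    out
  })
}
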