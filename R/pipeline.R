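# End-to-end orchestration: synthetic project simulation and the full
# alignment run (plan -> xy -> fuse -> root -> z -> highres -> render).

#' Simulate a complete synthetic acquisition project
#'
#' Generates a phantom, a tiled + deformed cellular-resolution acquisition
#' tree, an optional high-resolution (synaptic class) sub-window stack,
#' affinities, a synapse table, and an acquisition inventory — everything
#' the pipeline consumes, with ground truth.
#'
#' @param dir output directory.
#' @param spec a [phantom_spec()].
#' @param grid cellular-resolution tile grid (gy, gx).
#' @param overlap_fraction tile overlap fraction.
#' @param rigid_amplitude,elastic_amplitude,jitter_amplitude ground-truth
#'   warp amplitudes in pixels (see [ground_truth_warp()]).
#' @param dropout_slices slices to omit (1-based).
#' @param highres_window NULL, or list(y, x, size, slices) describing a
#'   sub-window imaged at `highres_ratio` x finer pixel pitch.
#' @param highres_ratio integer pixel-size ratio cellular/synaptic.
#' @param pixel_size_nm cellular-resolution pixel size.
#' @param dwell_us dwell time recorded in the inventory.
#' @param n_synapses,autapse_rate synapse table parameters.
#' @param seed master seed; all sub-seeds derive from it.
#' @return invisibly, a list with the phantom, manifest (incl. warp), and
#'   file paths.
#' @export
simulate_project <- function(dir, spec = phantom_spec(),
                             grid = c(2L, 2L), overlap_fraction = 0.15,
                             rigid_amplitude = 3, elastic_amplitude = 4,
                             jitter_amplitude = 2,
                             dropout_slices = integer(),
                             highres_window = NULL, highres_ratio = 4L,
                             pixel_size_nm = 40, dwell_us = 2,
                             n_synapses = 200L, autapse_rate = 0.1,
                             seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec$seed <- as.integer(seed)
  ph <- make_phantom(spec)
  nz <- spec$volume_shape[1]
  ny <- spec$volume_shape[2]; nx <- spec$volume_shape[3]
  warp <- ground_truth_warp(nz, c(ny, nx), grid = grid,
                            rigid_amplitude = rigid_amplitude,
                            elastic_amplitude = elastic_amplitude,
                            jitter_amplitude = jitter_amplitude,
                            seed = seed + 1L)
  cell_dir <- file.path(dir, "cellular")
  manifest <- tile_and_deform(ph$em, grid, overlap_fraction, warp,
                              dropout_slices = dropout_slices,
                              dir = cell_dir,
                              pixel_size_nm = pixel_size_nm)
  hr_manifest <- NULL
  if (!is.null(highres_window)) {
    hw <- highres_window
    hr_dir <- file.path(dir, "synaptic")
    dir.create(hr_dir, showWarnings = FALSE)
    r <- highres_ratio
    for (s in hw$slices) {
      # sample the phantom at fine pitch inside the window (no extra warp:
      # the sub-stack is assumed internally stitched)
      fy <- hw$y + (seq_len(hw$size * r) - 0.5) / r - 0.5
      fx <- hw$x + (seq_len(hw$size * r) - 0.5) / r - 0.5
      img <- matrix(bilinear_sample(ph$em[s, , ],
                                    rep(fy, times = length(fx)),
                                    rep(fx, each = length(fy))),
                    length(fy), length(fx))
      write_image(img, file.path(hr_dir, sprintf("Tile_r0c0_S%d.tif", s - 1)))
      writeLines(sprintf("pixel_size_nm=%g", pixel_size_nm / r),
                 file.path(hr_dir, sprintf("metadata_S%d.txt", s - 1)))
    }
    hr_manifest <- list(window = hw, ratio = r,
                        pixel_size_nm = pixel_size_nm / r)
  }
  saveRDS(ph, file.path(dir, "phantom.rds"))
  aff <- make_affinities(ph$labels, seed = seed + 2L)
  syn <- make_synapses(ph$labels, n_synapses, autapse_rate = autapse_rate,
                       seed = seed + 3L)
  utils::write.csv(syn, file.path(dir, "synapses.csv"), row.names = FALSE)
  inv <- make_inventory(list(
    tileset_spec(resolution_class = "cellular",
                 gx = grid[2], gy = grid[1], nz = nz - length(dropout_slices),
                 nx = manifest$tile_shape[2], ny = manifest$tile_shape[1],
                 t_dwell_us = dwell_us, pixel_size_nm = pixel_size_nm,
                 overlap = overlap_fraction)))
  if (!is.null(highres_window)) {
    inv <- rbind(inv, make_inventory(list(
      tileset_spec(resolution_class = "synaptic", gx = 1, gy = 1,
                   nz = length(highres_window$slices),
                   nx = highres_window$size * highres_ratio,
                   ny = highres_window$size * highres_ratio,
                   t_dwell_us = dwell_us,
                   pixel_size_nm = pixel_size_nm / highres_ratio,
                   overlap = 0))))
  }
  utils::write.csv(inv, file.path(dir, "inventory.csv"), row.names = FALSE)
  out <- list(phantom = ph, manifest = manifest, warp = warp,
              affinities = aff, synapses = syn, inventory = inv,
              hr_manifest = hr_manifest,
              paths = list(dir = dir, cellular = cell_dir,
                           synapses = file.path(dir, "synapses.csv"),
                           inventory = file.path(dir, "inventory.csv")))
  invisible(out)
}

#' Run the alignment pipeline on an acquisition directory
#'
#' Convenience wrapper chaining discovery, planning, per-slice XY
#' stitching, fusion, root-slice selection and Z alignment, with journaled
#' resumability.
#'
#' @param acq_dir acquisition directory (reference dialect).
#' @param out_dir output directory (journal, renders).
#' @param overlap_fraction nominal tile overlap.
#' @param params [align_params()].
#' @param preprocess [preprocess_params()] or NULL for none.
#' @param invert histogram inversion decision for this directory.
#' @param skip_slices slice indices (1-based) excluded as references.
#' @param render logical; write full/downsampled outputs.
#' @return list with `stitched` (per-slice stitch results), `aligned`
#'   (`aligned_stack`), `root`, `config`, `out_dir`.
#' @export
run_alignment <- function(acq_dir, out_dir,
                          overlap_fraction = 0.15,
                          params = align_params(),
                          preprocess = NULL, invert = FALSE,
                          skip_slices = integer(), render = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inv <- discover_project(acq_dir)[[1]]
  decisions <- stats::setNames(list(invert), acq_dir)
  cfg <- plan_project(list(inv), decisions, output_dir = out_dir,
                      preprocess = if (is.null(preprocess))
                        preprocess_params(gaussian_sigma = 0,
                                          clahe_clip_limit = 0)
                      else preprocess)
  save_config(cfg, file.path(out_dir, "project.json"))
  journal <- file.path(out_dir, "journal.jsonl")
  present <- sort(as.integer(names(inv$slices)))
  lo <- min(present); hi <- max(present)
  all_idx <- lo:hi
  stitched <- vector("list", length(all_idx))
  slices <- vector("list", length(all_idx))
  xydir <- file.path(out_dir, "xy")
  dir.create(xydir, showWarnings = FALSE)
  for (k in seq_along(all_idx)) {
    s <- all_idx[k]
    if (!(s %in% present)) {
      journal_record(journal, "xy", s, "missing")
      next
    }
    cache <- file.path(xydir, sprintf("xy_S%04d.tif", s))
    meshf <- file.path(xydir, sprintf("xy_M%04d.json", s))
    if (journal_is_done(journal, "xy", s) && file.exists(cache) &&
        file.exists(meshf)) {
      slices[[k]] <- read_image(cache)
      stitched[[k]] <- stitch_from_json(meshf)
      stitched[[k]]$image <- slices[[k]]
      next
    }
    tm <- load_tilemap(inv, s, overlap_fraction,
                       preprocess = preprocess, invert = invert)
    st <- stitch_tilemap(tm, params)
    slices[[k]] <- st$image
    stitched[[k]] <- st
    write_image(st$image, cache)
    stitch_to_json(st, meshf)
    journal_record(journal, "xy", s, "done")
  }
  # fusion counts: the synthetic reference dialect yields one tile map per
  # slice, so every present slice is a single contiguous image
  counts <- stats::setNames(
    ifelse(vapply(slices, is.null, TRUE), NA_integer_, 1L),
    as.character(all_idx))
  root_idx <- find_root_slice(counts)
  root_k <- match(root_idx, all_idx)
  skip_k <- match(skip_slices, all_idx)
  skip_k <- skip_k[!is.na(skip_k)]
  aligned <- align_z(slices, root_k, skip_slices = skip_k, params = params,
                     journal = journal, workdir = file.path(out_dir, "z"))
  if (render) {
    render_outputs(aligned, file.path(out_dir, "aligned"))
  }
  list(stitched = stitched, aligned = aligned, root = root_idx,
       config = cfg, out_dir = out_dir, slice_index = all_idx,
       journal = journal)
}

stitch_to_json <- function(st, path) {
  l <- list(tile_origins = st$tile_origins,
            meshes = lapply(st$meshes, mesh_to_list))
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

stitch_from_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(image = NULL,
       tile_origins = do.call(rbind, lapply(l$tile_origins, unlist)),
       meshes = lapply(l$meshes, mesh_from_list),
       quality = NULL)
}
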