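# Acquisition representation: tiles, tile maps, project discovery, planning
# configuration, and tile preprocessing (invert -> Gaussian -> CLAHE).

#' Filename/metadata dialect for an acquisition directory
#'
#' Acquisition software encodes grid position and slice index in tile
#' filenames, and per-slice pixel size in a small text file. The dialect is a
#' declarative description of that encoding, so the loader can be adapted to
#' any vendor's output. The default is the toolkit's reference dialect, the
#' one written by [tile_and_deform()].
#'
#' @param tile_pattern regex with named-order capture groups row, col, slice.
#' @param metadata_pattern regex for per-slice metadata files with one
#'   capture group: the slice index.
#' @param pixel_size_key key (in `key=value` lines) holding nm/pixel.
#' @return a `tile_dialect` object.
#' @export
tile_dialect <- function(
    tile_pattern = "^Tile_r([0-9]+)c([0-9]+)_S([0-9]+)\\.tiff?$",
    metadata_pattern = "^metadata_S([0-9]+)\\.txt$",
    pixel_size_key = "pixel_size_nm") {
  structure(list(tile_pattern = tile_pattern,
                 metadata_pattern = metadata_pattern,
                 pixel_size_key = pixel_size_key),
            class = "tile_dialect")
}

parse_groups <- function(names, pattern) {
  m <- regmatches(names, regexec(pattern, names))
  m
}

#' Discover tile inventories in acquisition directories
#'
#' Scans each directory for tile images and per-slice metadata under the
#' active dialect, groups tiles by slice into tile maps, and records missing
#' slice indices as gaps. Image files that do not parse under the dialect
#' raise an error naming the file; non-image files are ignored.
#'
#' @param root_dirs character vector of directories.
#' @param dialect a [tile_dialect()].
#' @return list of per-directory inventories; each has `dir`, `slices`
#'   (named list: slice index -> data.frame of tiles with row, col, path),
#'   `grid_shape`, `tile_shape`, `pixel_size_nm` (named numeric per slice),
#'   `gaps` (missing slice indices within the observed range).
#' @export
discover_project <- function(root_dirs, dialect = tile_dialect()) {
  lapply(root_dirs, function(d) {
    if (!dir.exists(d)) stop("directory does not exist: ", d)
    files <- list.files(d)
    tifs <- files[grepl("\\.tiff?$", files, ignore.case = TRUE)]
    bad <- tifs[!grepl(dialect$tile_pattern, tifs)]
    if (length(bad) > 0) {
      stop("filename does not match the active dialect: ",
           file.path(d, bad[1]))
    }
    inv <- list(dir = d, slices = list(), grid_shape = c(0L, 0L),
                tile_shape = NULL, pixel_size_nm = numeric(), gaps = integer())
    if (length(tifs) == 0) return(inv)
    g <- parse_groups(tifs, dialect$tile_pattern)
    rec <- data.frame(
      file = tifs,
      row = as.integer(vapply(g, `[`, "", 2)),
      col = as.integer(vapply(g, `[`, "", 3)),
      slice = as.integer(vapply(g, `[`, "", 4)))
    shp <- NULL
    for (f in rec$file) {
      img_dim <- dim(read_image(file.path(d, f)))
      if (is.null(shp)) {
        shp <- img_dim
      } else if (!identical(shp, img_dim)) {
        stop("inconsistent tile shapes within directory ", d,
             " (", f, ")")
      }
    }
    # per-slice metadata
    meta <- files[grepl(dialect$metadata_pattern, files)]
    ps <- numeric()
    for (mf in meta) {
      sl <- as.integer(parse_groups(mf, dialect$metadata_pattern)[[1]][2])
      lines <- readLines(file.path(d, mf), warn = FALSE)
      kv <- lines[startsWith(lines, paste0(dialect$pixel_size_key, "="))]
      if (length(kv) >= 1) {
        ps[as.character(sl)] <- as.numeric(sub(".*=", "", kv[1]))
      }
    }
    slices <- split(rec, rec$slice)
    present <- sort(as.integer(names(slices)))
    gaps <- setdiff(seq(min(present), max(present)), present)
    inv$slices <- lapply(slices, function(s) s[order(s$row, s$col), ])
    inv$grid_shape <- c(max(rec$row) + 1L, max(rec$col) + 1L)
    inv$tile_shape <- shp
    inv$pixel_size_nm <- ps
    inv$gaps <- as.integer(gaps)
    inv
  })
}

#' Default preprocessing parameters
#'
#' Tiles are optionally histogram-inverted (to standard EM polarity:
#' electron-dense regions dark), denoised with a small Gaussian, and
#' contrast-adjusted with CLAHE, in that order.
#'
#' @param gaussian_sigma Gaussian sigma in pixels (0 disables).
#' @param gaussian_kernel odd (ky, kx) kernel size in pixels.
#' @param clahe_clip_limit CLAHE clip limit (0 disables CLAHE).
#' @param clahe_tile_grid CLAHE tile grid (ty, tx).
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(gaussian_sigma = 1,
                              gaussian_kernel = c(3L, 3L),
                              clahe_clip_limit = 2,
                              clahe_tile_grid = c(10L, 10L)) {
  structure(list(gaussian_sigma = gaussian_sigma,
                 gaussian_kernel = as.integer(gaussian_kernel),
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid)),
            class = "preprocess_params")
}

#' Preprocess one tile
#'
#' Applies, in order: optional 8-bit inversion (255 - v), Gaussian smoothing
#' with the configured sigma and kernel (replicate borders), and
#' contrast-limited adaptive histogram equalization. A constant image passes
#' through equalization unchanged (the conventional degenerate case). Output
#' has the same shape and 0..255 integer range as the input.
#'
#' @param img integer matrix in 0..255.
#' @param params a [preprocess_params()]; NULL disables all steps.
#' @param invert logical, invert the histogram first.
#' @return integer matrix, same shape.
#' @export
preprocess_tile <- function(img, params = preprocess_params(),
                            invert = FALSE) {
  out <- img
  if (isTRUE(invert)) out <- 255L - out
  if (is.null(params)) return(as_uint8(out))
  if (params$gaussian_sigma > 0) {
    ky <- gaussian_kernel_1d(params$gaussian_sigma, params$gaussian_kernel[1])
    kx <- gaussian_kernel_1d(params$gaussian_sigma, params$gaussian_kernel[2])
    out <- conv_separable(out, ky, kx)
  }
  if (params$clahe_clip_limit > 0) {
    rng <- range(out)
    if (rng[1] < rng[2]) {   # constant images are equalization fixed points
      # the equalizer needs dimensions divisible by its tile grid: pad by
      # edge replication, equalize, crop back
      gy <- params$clahe_tile_grid[1]; gx <- params$clahe_tile_grid[2]
      ny <- nrow(out); nx <- ncol(out)
      py <- (gy - ny %% gy) %% gy
      px <- (gx - nx %% gx) %% gx
      padded <- out[c(seq_len(ny), rep(ny, py)),
                    c(seq_len(nx), rep(nx, px)), drop = FALSE]
      eq <- EBImage::clahe(t(padded) / 255, nx = gx, ny = gy,
                           limit = params$clahe_clip_limit,
                           keep.range = TRUE)
      out <- t(eq)[seq_len(ny), seq_len(nx)] * 255
    }
  }
  as_uint8(round(out))
}

#' Plan an alignment project
#'
#' Converts discovered inventories plus the user's per-directory histogram
#' inversion decisions into a serializable project configuration: one block
#' per directory (paths, grid, inversion flag) and shared preprocessing and
#' alignment parameter defaults. The configuration round-trips losslessly
#' through JSON.
#'
#' @param inventories output of [discover_project()].
#' @param inversion_decisions named logical vector, one entry per directory
#'   (names = directory paths).
#' @param output_dir where aligned outputs should be written (recorded in
#'   the config).
#' @param preprocess a [preprocess_params()].
#' @param alignment named list of alignment parameter blocks; missing values
#'   are filled with [align_params()] defaults.
#' @param skip_slices integer slice indices to exclude as references during
#'   Z alignment.
#' @return a `project_config` list.
#' @export
plan_project <- function(inventories, inversion_decisions,
                         output_dir = "aligned",
                         preprocess = preprocess_params(),
                         alignment = list(), skip_slices = integer()) {
  dirs <- vapply(inventories, `[[`, "", "dir")
  missing <- setdiff(dirs, names(inversion_decisions))
  if (length(missing) > 0) {
    stop("missing inversion decision for: ", paste(missing, collapse = ", "))
  }
  ap <- utils::modifyList(align_params(), alignment)
  cfg <- list(
    directories = lapply(inventories, function(inv) {
      list(path = inv$dir,
           grid_shape = inv$grid_shape,
           tile_shape = inv$tile_shape,
           invert = isTRUE(inversion_decisions[[inv$dir]]),
           gaps = inv$gaps,
           pixel_size_nm = unname(inv$pixel_size_nm[1]))
    }),
    output_dir = output_dir,
    preprocess = unclass(preprocess),
    alignment = ap,
    skip_slices = as.integer(skip_slices))
  class(cfg) <- "project_config"
  cfg
}

#' Save / load a project configuration as JSON
#'
#' @param cfg a `project_config`.
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` the config.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$skip_slices <- as.integer(cfg$skip_slices)
  if (is.data.frame(cfg$directories)) {
    cfg$directories <- lapply(seq_len(nrow(cfg$directories)), function(i) {
      as.list(cfg$directories[i, ])
    })
  }
  class(cfg) <- "project_config"
  cfg
}
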