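# Acquisition time and data-size estimation for multi-resolution SBEM.
#
# For a tile map of g_x x g_y tiles of n_x x n_y pixels over n_z slices at
# dwell time t_dwell:
#
#   N_tile    = n_x n_y
#   N_tilemap = g_x g_y n_z N_tile
#   t_tilemap = N_tilemap t_dwell
#   t_total   = sum_i t_tilemap,i
#
# The tissue area covered by a tile map, accounting for the overlap o
# (fraction of tile shape) between neighbors:
#
#   x_tilemap = p (g_x n_x - n_x o (g_x - 1))     [first tile full width,
#   y_tilemap = p (g_y n_y - n_y o (g_y - 1))      then g-1 steps of
#   A_tilemap = x_tilemap y_tilemap                (1-o) tile width]
#
# The hypothetical all-synaptic-resolution scenario images the cellular
# tile maps' area at pixel area P_highres:
#
#   N_highres = sum_i A_tilemap,i / P_highres
#   t_highres = N_highres t_dwell
#
# This underestimates the hypothetical pixel count: overlap between the
# (more numerous) high-resolution tiles is ignored.

us_per_day <- 86400 * 1e6

#' Describe one acquired tile set
#'
#' @param resolution_class "cellular" or "synaptic".
#' @param gx,gy tiles per axis.
#' @param nz number of slices.
#' @param nx,ny pixels per tile per axis.
#' @param t_dwell_us dwell time, microseconds per pixel.
#' @param pixel_size_nm pixel size, nm (isotropic in XY).
#' @param overlap overlap fraction of tile shape in `[0, 1)`.
#' @return one-row data.frame.
#' @export
tileset_spec <- function(resolution_class, gx, gy, nz, nx, ny,
                         t_dwell_us, pixel_size_nm, overlap = 0.15) {
  resolution_class <- match.arg(resolution_class, c("cellular", "synaptic"))
  if (t_dwell_us <= 0) stop("dwell time must be positive")
  if (pixel_size_nm <= 0) stop("pixel size must be positive")
  if (any(c(gx, gy, nz, nx, ny) <= 0)) stop("geometry must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  data.frame(resolution_class = resolution_class, gx = gx, gy = gy,
             nz = nz, nx = nx, ny = ny, t_dwell_us = t_dwell_us,
             pixel_size_nm = pixel_size_nm, overlap = overlap)
}

#' Build an acquisition inventory
#'
#' @param specs list of [tileset_spec()] rows.
#' @return data.frame with one row per tile set.
#' @export
make_inventory <- function(specs) {
  do.call(rbind, specs)
}

#' Read / write an inventory as CSV
#'
#' @param path CSV file with the [tileset_spec()] columns.
#' @return data.frame inventory.
#' @export
read_inventory <- function(path) {
  inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("resolution_class", "gx", "gy", "nz", "nx", "ny",
              "t_dwell_us", "pixel_size_nm", "overlap")
  missing <- setdiff(needed, names(inv))
  if (length(missing) > 0) {
    stop("inventory misses columns: ", paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(inv))) {
    tileset_spec(inv$resolution_class[i], inv$gx[i], inv$gy[i], inv$nz[i],
                 inv$nx[i], inv$ny[i], inv$t_dwell_us[i],
                 inv$pixel_size_nm[i], inv$overlap[i])  # validation
  }
  inv[needed]
}

#' Pixel count and acquisition time of a tile map
#'
#' @param spec one inventory row.
#' @return list with `N_tile`, `N_tilemap` (pixels), `t_us`, `t_s`,
#'   `t_days`.
#' @export
tilemap_time <- function(spec) {
  # pixel counts overflow 32-bit integers for realistic stacks
  N_tile <- as.numeric(spec$nx) * as.numeric(spec$ny)
  N_tilemap <- as.numeric(spec$gx) * as.numeric(spec$gy) *
    as.numeric(spec$nz) * N_tile
  t_us <- N_tilemap * spec$t_dwell_us
  list(N_tile = N_tile, N_tilemap = N_tilemap,
       t_us = t_us, t_s = t_us / 1e6, t_days = t_us / us_per_day)
}

#' Tissue extent and area covered by a tile map
#'
#' The first tile contributes its full width and each further tile a step
#' of (1 - o) times the tile width: x = p (g n - n o (g - 1)).
#'
#' @param spec one inventory row.
#' @return list with `x_nm`, `y_nm` extents and `A_nm2` area.
#' @export
covered_area <- function(spec) {
  x_nm <- spec$pixel_size_nm *
    (spec$gx * spec$nx - spec$nx * spec$overlap * (spec$gx - 1))
  y_nm <- spec$pixel_size_nm *
    (spec$gy * spec$ny - spec$ny * spec$overlap * (spec$gy - 1))
  list(x_nm = x_nm, y_nm = y_nm, A_nm2 = x_nm * y_nm)
}

#' Hypothetical all-synaptic-resolution pixel count and time
#'
#' @param inventory inventory rows; must all be cellular class (the
#'   cellular tile maps cover the whole region of interest).
#' @param P_highres_nm2 pixel area of the hypothetical acquisition, nm^2.
#' @param t_dwell_us dwell time of the hypothetical acquisition.
#' @return list with `N_highres` (pixels), `t_us`, `t_days`.
#' @export
hypothetical_highres <- function(inventory, P_highres_nm2, t_dwell_us) {
  if (any(inventory$resolution_class != "cellular")) {
    stop("only cellular-resolution tile maps enter the hypothetical ",
         "high-resolution scenario")
  }
  # every slice of each tile map's footprint is imaged at P_highres
  A <- vapply(seq_len(nrow(inventory)),
              function(i) covered_area(inventory[i, ])$A_nm2, 0)
  N <- sum(as.numeric(inventory$nz) * A) / P_highres_nm2
  t_us <- N * t_dwell_us
  list(N_highres = N, t_us = t_us, t_days = t_us / us_per_day)
}

# Display rounding: half away from zero to `digits` decimals (so printed
# gain factors follow the usual reporting convention rather than banker's
# rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Acquisition gain report
#'
#' Computes, from an inventory, the actual multi-resolution acquisition
#' time and size, the hypothetical time and size had the whole cellular
#' footprint been imaged at synaptic resolution, and the resulting gain
#' factor and days saved.
#'
#' @param inventory full inventory (both resolution classes).
#' @param P_highres_nm2 hypothetical pixel area (nm^2); default: the square
#'   of the most common synaptic-class pixel size in the inventory.
#' @param t_dwell_us hypothetical dwell time; default: the most common
#'   synaptic-class dwell time.
#' @return list of class `gain_report`: per-tileset table, `t_total_days`,
#'   `t_highres_days`, `gain_factor` (full precision),
#'   `gain_factor_display` (1 decimal, half away from zero), `days_saved`,
#'   `size_tb`, `size_highres_tb` (TB = 1e12 bytes at 1 byte/pixel).
#' @export
gain_report <- function(inventory, P_highres_nm2 = NULL, t_dwell_us = NULL) {
  if (nrow(inventory) == 0) stop("empty inventory")
  syn <- inventory[inventory$resolution_class == "synaptic", , drop = FALSE]
  if (is.null(P_highres_nm2)) {
    if (nrow(syn) == 0) stop("no synaptic tile sets to infer P_highres from")
    ps <- syn$pixel_size_nm
    P_highres_nm2 <- (as.numeric(names(sort(-table(ps)))[1]))^2
  }
  if (is.null(t_dwell_us)) {
    if (nrow(syn) == 0) stop("no synaptic tile sets to infer dwell from")
    td <- syn$t_dwell_us
    t_dwell_us <- as.numeric(names(sort(-table(td)))[1])
  }
  times <- lapply(seq_len(nrow(inventory)),
                  function(i) tilemap_time(inventory[i, ]))
  per <- data.frame(
    resolution_class = inventory$resolution_class,
    N_tilemap = vapply(times, `[[`, 0, "N_tilemap"),
    t_days = vapply(times, `[[`, 0, "t_days"))
  cell <- inventory[inventory$resolution_class == "cellular", , drop = FALSE]
  hyp <- hypothetical_highres(cell, P_highres_nm2, t_dwell_us)
  t_total <- sum(per$t_days)
  gain <- hyp$t_days / t_total
  structure(list(
    per_tileset = per,
    t_total_days = t_total,
    t_highres_days = hyp$t_days,
    gain_factor = gain,
    gain_factor_display = round_half_up(gain, 1),
    days_saved = hyp$t_days - t_total,
    size_tb = sum(per$N_tilemap) / 1e12,
    size_highres_tb = hyp$N_highres / 1e12,
    P_highres_nm2 = P_highres_nm2,
    t_dwell_us = t_dwell_us),
    class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat("Acquisition gain report\n")
  cat(sprintf("  tile sets:        %d\n", nrow(x$per_tileset)))
  cat(sprintf("  total time:       %.1f d\n", x$t_total_days))
  cat(sprintf("  potential time:   %.1f d (all-synaptic scenario)\n",
              x$t_highres_days))
  cat(sprintf("  time gain factor: %.1f\n", x$gain_factor_display))
  cat(sprintf("  days saved:       %.1f d\n", x$days_saved))
  cat(sprintf("  total size:       %.2f TB (potential %.2f TB)\n",
              x$size_tb, x$size_highres_tb))
  invisible(x)
}

#' Gain factor from published total and potential times
#'
#' For datasets where only the aggregated times are available (in days),
#' computes the displayed gain factor and days saved.
#'
#' @param t_total_days actual multi-resolution acquisition time, days.
#' @param t_highres_days hypothetical all-synaptic time, days.
#' @return list with `gain_factor`, `gain_factor_display`, `days_saved`.
#' @export
gain_from_times <- function(t_total_days, t_highres_days) {
  g <- t_highres_days / t_total_days
  list(gain_factor = g,
       gain_factor_display = round_half_up(g, 1),
       days_saved = t_highres_days - t_total_days)
}
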