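# Internal helpers shared across modules.
#
# Conventions used throughout the package:
#  * volumes are indexed [z, y, x], images [y, x], 1-based as is idiomatic in R;
#  * all geometric transforms are backward maps: a transform evaluated at an
#    output (fixed-frame) coordinate returns the source (moving-frame)
#    coordinate to sample;
#  * 8-bit images are stored as integer matrices with values in 0..255.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

as_uint8 <- function(x) {
  storage.mode(x) <- "integer"
  x[x < 0L] <- 0L
  x[x > 255L] <- 255L
  x
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators are pure functions of the seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Bilinear sampling of a 2-D matrix at fractional (y, x) positions (1-based,
# voxel-centered). Positions outside the image return `fill`.
bilinear_sample <- function(img, y, x, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0;  fx <- x - x0
  out <- rep(as.numeric(fill), length(y))
  ok <- y >= 1 & y <= ny & x >= 1 & x <= nx
  if (!any(ok)) return(out)
  y0k <- clamp(y0[ok], 1, ny); y1k <- clamp(y0[ok] + 1, 1, ny)
  x0k <- clamp(x0[ok], 1, nx); x1k <- clamp(x0[ok] + 1, 1, nx)
  fyk <- fy[ok]; fxk <- fx[ok]
  v00 <- img[cbind(y0k, x0k)]; v01 <- img[cbind(y0k, x1k)]
  v10 <- img[cbind(y1k, x0k)]; v11 <- img[cbind(y1k, x1k)]
  out[ok] <- (1 - fyk) * ((1 - fxk) * v00 + fxk * v01) +
    fyk * ((1 - fxk) * v10 + fxk * v11)
  out
}

# Separable Gaussian kernel of odd length `size`, unit sum.
gaussian_kernel_1d <- function(sigma, size) {
  stopifnot(size >= 1, size %% 2 == 1)
  if (sigma <= 0) {
    k <- numeric(size); k[(size + 1) / 2] <- 1
    return(k)
  }
  r <- (size - 1) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D convolution with replicate (clamp-to-edge) borders.
conv_separable <- function(img, ky, kx = ky) {
  ry <- (length(ky) - 1) / 2
  rx <- (length(kx) - 1) / 2
  ny <- nrow(img); nx <- ncol(img)
  # along y
  tmp <- matrix(0, ny, nx)
  for (i in seq_along(ky)) {
    off <- i - 1 - ry
    rows <- clamp(seq_len(ny) + off, 1, ny)
    tmp <- tmp + ky[i] * img[rows, , drop = FALSE]
  }
  out <- matrix(0, ny, nx)
  for (i in seq_along(kx)) {
    off <- i - 1 - rx
    cols <- clamp(seq_len(nx) + off, 1, nx)
    out <- out + kx[i] * tmp[, cols, drop = FALSE]
  }
  out
}

# Block-mean downsampling by integer factor; partial edge blocks average the
# pixels they do cover, so output dims are ceiling(dim / f).
downsample_mean <- function(img, f) {
  stopifnot(f >= 1, f == round(f))
  if (f == 1) return(img)
  ny <- nrow(img); nx <- ncol(img)
  oy <- ceiling(ny / f); ox <- ceiling(nx / f)
  gy <- (seq_len(ny) - 1) %/% f + 1
  gx <- (seq_len(nx) - 1) %/% f + 1
  sums <- rowsum(img, gy)          # oy x nx
  sums <- t(rowsum(t(sums), gx))   # oy x ox
  cnt <- outer(tabulate(gy, oy), tabulate(gx, ox))
  sums / cnt
}

# Bilinear upsampling of a field sampled at stride `s` (nodes at pixel centers
# 1, 1+s, 1+2s, ...) to a dense ny x nx image.
upsample_field <- function(node_grid, stride, ny, nx, origin = c(1, 1)) {
  if (nrow(node_grid) == 1) {
    node_grid <- node_grid[c(1, 1), , drop = FALSE]
  }
  if (ncol(node_grid) == 1) {
    node_grid <- node_grid[, c(1, 1), drop = FALSE]
  }
  yc <- origin[1] + (seq_len(nrow(node_grid)) - 1) * stride
  xc <- origin[2] + (seq_len(ncol(node_grid)) - 1) * stride
  iy <- approx(yc, seq_along(yc), xout = seq_len(ny), rule = 2)$y
  ix <- approx(xc, seq_along(xc), xout = seq_len(nx), rule = 2)$y
  bil <- function(g) {
    y0 <- clamp(floor(iy), 1, nrow(g)); y1 <- clamp(y0 + 1, 1, nrow(g))
    x0 <- clamp(floor(ix), 1, ncol(g)); x1 <- clamp(x0 + 1, 1, ncol(g))
    fy <- iy - y0; fx <- ix - x0
    (1 - fy) %o% (1 - fx) * g[y0, x0, drop = FALSE] +
      (1 - fy) %o% fx * g[y0, x1, drop = FALSE] +
      fy %o% (1 - fx) * g[y1, x0, drop = FALSE] +
      fy %o% fx * g[y1, x1, drop = FALSE]
  }
  bil(node_grid)
}

#' Read an 8-bit greyscale TIFF image
#'
#' @param path path to a TIFF file.
#' @return integer matrix with values in 0..255.
#' @export
read_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  as_uint8(round(img * 255))
}

#' Write an 8-bit greyscale TIFF image
#'
#' @param img numeric or integer matrix; values are clamped to 0..255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_uint8(round(img))
  tiff::writeTIFF(img / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

rms <- function(x) sqrt(mean(x^2))
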