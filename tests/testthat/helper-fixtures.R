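# Shared fixtures, built in code at test time.

# small textured image with structure at several scales
tiny_image <- function(n = 96, seed = 1) {
  withr::with_seed(seed, {
    img <- conv_separable(matrix(runif(n * n, 0, 255), n, n),
                          gaussian_kernel_1d(1, 5))
    mrvem:::as_uint8(round(img))
  })
}

# small phantom the registration tests share
tiny_phantom <- function(nz = 8, n = 96, seed = 2, noise = 0) {
  make_phantom(phantom_spec(c(nz, n, n), n_neurites = 14,
                            neurite_radius = 6, noise_sigma = noise,
                            seed = seed))
}

# 3-block label toy: three slabs along x
slab_labels <- function() {
  lab <- array(0L, c(2, 2, 6))
  lab[, , 1:2] <- 1L; lab[, , 3:4] <- 2L; lab[, , 5:6] <- 3L
  lab
}

# backward-warp an image by a dense displacement closure d(y, x)
warp_by <- function(img, fy, fx) {
  n1 <- nrow(img); n2 <- ncol(img)
  yy <- rep(seq_len(n1), times = n2)
  xx <- rep(seq_len(n2), each = n1)
  matrix(bilinear_sample(img, yy + fy(yy, xx), xx + fx(yy, xx)), n1, n2)
}

# independent connected-components oracle over an arbitrary edge list,
# using igraph (the implementation uses its own union-find)
igraph_components <- function(n, edges_a, edges_b) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges_a) > 0) {
    g <- igraph::add_edges(g, rbind(edges_a, edges_b))
  }
  igraph::components(g)$membership
}

# partitions equal up to relabeling?
same_partition <- function(a, b) {
  ta <- table(a, b)
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}
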