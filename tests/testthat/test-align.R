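# XY stitching, fusion, root-slice logic, Z alignment, cross-resolution
# registration, rendering and the journal.

test_that("stitching reconstructs a jittered tile map", {
  ph <- make_phantom(phantom_spec(c(8, 160, 160), n_neurites = 40,
                                  neurite_radius = 7, noise_sigma = 0,
                                  seed = 15))
  # integer jitter so the acquired tiles are exact crops: the stitched
  # composite can then be compared pixelwise away from blend seams
  w <- ground_truth_warp(8, c(160, 160), grid = c(2, 2),
                         rigid_amplitude = 0, elastic_amplitude = 0,
                         n_components = 0, jitter_amplitude = 3, seed = 2)
  w$jitter[] <- round(w$jitter)
  d <- withr::local_tempdir()
  man <- tile_and_deform(ph$em, c(2, 2), 0.15, w, dir = d)
  inv <- discover_project(d)[[1]]
  tm <- load_tilemap(inv, 0, 0.15)
  st <- stitch_tilemap(tm)

  # jitter recovered to a fraction of a pixel (up to a global shift)
  errs <- matrix(0, 4, 2)
  for (i in 1:4) {
    r <- (i - 1) %/% 2 + 1; cc <- (i - 1) %% 2 + 1
    errs[i, ] <- st$tile_origins[i, ] -
      c(man$origins_y[r] + w$jitter[1, r, cc, 1],
        man$origins_x[cc] + w$jitter[1, r, cc, 2])
  }
  errs <- sweep(errs, 2, colMeans(errs))
  expect_lt(max(abs(errs)), 0.25)

  # grey-level fidelity against the uncut slice: locate the composite in
  # the phantom slice, then compare pixels away from the blend seams
  loc <- mrvem:::match_template(ph$em[1, , ],
                                st$image[20:140, 20:140], c(20, 20))
  expect_gt(loc$quality, 0.95)
  oy <- round(loc$dy); ox <- round(loc$dx)
  cmp_y <- 15:145; cmp_x <- 15:145
  ref <- ph$em[1, cmp_y + oy, cmp_x + ox]
  got <- st$image[cmp_y, cmp_x]
  expect_lt(sqrt(mean((ref - got)^2)), 3)
})

test_that("a 1x1 tile map stitches to the tile itself", {
  ph <- tiny_phantom(nz = 8, n = 60, seed = 1)
  d <- withr::local_tempdir()
  tile_and_deform(ph$em, c(1, 1), 0, dir = d)
  inv <- discover_project(d)[[1]]
  st <- stitch_tilemap(load_tilemap(inv, 0, 0))
  expect_identical(st$image, mrvem:::as_uint8(ph$em[1, , ]))
})

test_that("a 10-pixel overlap still recovers sub-pixel jitter", {
  ph <- make_phantom(phantom_spec(c(8, 160, 160), n_neurites = 40,
                                  neurite_radius = 7, noise_sigma = 0,
                                  seed = 21))
  ovf <- 10 / 87
  w <- ground_truth_warp(8, c(160, 160), grid = c(2, 2),
                         rigid_amplitude = 0, elastic_amplitude = 0,
                         n_components = 0, jitter_amplitude = 2, seed = 3)
  d <- withr::local_tempdir()
  man <- tile_and_deform(ph$em, c(2, 2), ovf, w, dir = d)
  expect_identical(man$tile_shape[1] -
                     (man$origins_y[2] - man$origins_y[1]), 10)
  st <- stitch_tilemap(load_tilemap(discover_project(d)[[1]], 0, ovf))
  errs <- matrix(0, 4, 2)
  for (i in 1:4) {
    r <- (i - 1) %/% 2 + 1; cc <- (i - 1) %% 2 + 1
    errs[i, ] <- st$tile_origins[i, ] -
      c(man$origins_y[r] + w$jitter[1, r, cc, 1],
        man$origins_x[cc] + w$jitter[1, r, cc, 2])
  }
  errs <- sweep(errs, 2, colMeans(errs))
  expect_lt(max(abs(errs)), 0.5)

  # overlap below the supported floor is rejected outright
  tm <- load_tilemap(discover_project(d)[[1]], 0, ovf)
  tm$origins_x <- tm$origins_x + 3  # pretend declared overlap was 7 px
  tm$origins_x[1] <- 0
  expect_error(stitch_tilemap(tm), "minimum of 10")
})

test_that("fusion merges overlapping members and keeps disjoint ones apart", {
  ph <- make_phantom(phantom_spec(c(8, 110, 150), n_neurites = 34,
                                  neurite_radius = 6, noise_sigma = 1,
                                  seed = 8))
  sl <- ph$em[2, , ]
  # two crops sharing a ~20% band
  A <- sl[, 1:90]; B <- sl[, 61:150]
  fo <- fuse_overlapping_tilemaps(list(
    list(image = A, origin = c(0, 0)),
    list(image = B, origin = c(0, 60))))
  expect_identical(fo$n_members, 1L)
  fused <- fo$members[[1]]
  # the fused mosaic must match the source inside the shared band
  band_x <- 70:80
  got <- fused$image[(10:100) - fused$origin[1],
                     band_x - fused$origin[2]]
  ref <- sl[10:100, band_x]
  expect_lt(sqrt(mean((got - ref)^2)), 3)

  # disjoint crops stay separate
  fd <- fuse_overlapping_tilemaps(list(
    list(image = sl[, 1:60], origin = c(0, 0)),
    list(image = sl[, 90:150], origin = c(0, 89))))
  expect_identical(fd$n_members, 2L)

  # identical duplicates fuse to either input (respect the fused origin)
  fi <- fuse_overlapping_tilemaps(list(
    list(image = A, origin = c(0, 0)),
    list(image = A, origin = c(0, 0))))
  expect_identical(fi$n_members, 1L)
  fim <- fi$members[[1]]
  got <- fim$image[(5:100) - fim$origin[1], (5:80) - fim$origin[2]]
  expect_lt(mean(abs(got - A[5:100, 5:80])), 1)
})

test_that("the root slice is the first contiguous one", {
  expect_identical(find_root_slice(stats::setNames(c(1L, 1L, 1L), 0:2)), 0L)
  expect_identical(find_root_slice(stats::setNames(c(2L, 2L, 1L, 1L), 0:3)), 2L)
  expect_identical(find_root_slice(stats::setNames(c(2L, 2L, 2L, 1L), 6:9)), 9L)
  expect_error(find_root_slice(stats::setNames(c(2L, 3L), 0:1)),
               "no contiguous slice")
})

test_that("Z alignment recovers rigid jitter and bridges a missing slice", {
  ph <- make_phantom(phantom_spec(c(10, 140, 140), n_neurites = 32,
                                  neurite_radius = 7, noise_sigma = 2,
                                  seed = 31))
  w <- ground_truth_warp(10, c(140, 140), grid = c(1, 1),
                         rigid_amplitude = 3, elastic_amplitude = 0,
                         n_components = 0, jitter_amplitude = 0, seed = 5)
  d <- withr::local_tempdir()
  tile_and_deform(ph$em, c(1, 1), 0, w, dir = d)
  inv <- discover_project(d)[[1]]
  slices <- lapply(1:10, function(z) load_tilemap(inv, z - 1, 0)$images[[1]])
  al <- align_z(slices, root = 1)
  expect_identical(al$status[1], "root")
  for (z in c(3, 6, 10)) {
    A <- al$transforms[[z]]$affine
    ideal <- w$rigid[1, ] - w$rigid[z, ]
    expect_lt(max(abs(c(A[1, 3] - ideal[1], A[2, 3] - ideal[2]))), 0.5)
  }

  # idempotence: aligning an already aligned stack finds ~identity
  # (the elastic term still tracks genuine sub-pixel tissue wiggle, so the
  # translation is tight and the mesh small on average)
  al2 <- align_z(al$images, root = 1)
  for (z in c(2, 7)) {
    tf <- al2$transforms[[z]]
    expect_lt(max(abs(c(tf$affine[1, 3], tf$affine[2, 3]))), 0.5)
    expect_lt(mean(abs(c(tf$mesh$dy, tf$mesh$dx))), 0.35)
    expect_lt(max(abs(c(tf$mesh$dy, tf$mesh$dx))), 1)
  }

  # missing slice: black output, neighbor bridged across the gap
  slices5 <- slices
  slices5[5] <- list(NULL)
  al3 <- align_z(slices5, root = 1)
  expect_identical(al3$status[5], "missing")
  expect_true(all(al3$images[[5]] == 0L))
  expect_identical(al3$status[6], "done")
  # slice 6 still lands where the ground truth says (aligned to slice 4)
  A6 <- al3$transforms[[6]]$affine
  ideal6 <- w$rigid[1, ] - w$rigid[6, ]
  expect_lt(max(abs(c(A6[1, 3] - ideal6[1], A6[2, 3] - ideal6[2]))), 0.7)

  # skip slices are warped but never serve as reference
  al4 <- align_z(slices, root = 1, skip_slices = 4)
  expect_identical(al4$status[4], "skip")
  expect_false(all(al4$images[[4]] == 0L))
})

test_that("high-resolution sub-stacks register into the reference frame", {
  ph <- make_phantom(phantom_spec(c(8, 120, 120), n_neurites = 30,
                                  neurite_radius = 6, noise_sigma = 1,
                                  seed = 41))
  # reference stack: already aligned (identity acquisition)
  ref <- structure(list(
    images = lapply(1:8, function(z) mrvem:::as_uint8(ph$em[z, , ])),
    transforms = rep(list(list(affine = mrvem:::identity_affine(),
                               mesh = NULL)), 8),
    status = c("root", rep("done", 7)), root = 1, dims = c(120L, 120L)),
    class = "aligned_stack")

  # high-res slice: 4x upsampled sub-window with a known extra shift
  ratio <- 4; win <- c(y = 30, x = 40); size <- 48; shift <- c(2.3, -1.6)
  mk_hr <- function(z) {
    fy <- win["y"] + shift[1] + (seq_len(size * ratio) - 0.5) / ratio - 0.5
    fx <- win["x"] + shift[2] + (seq_len(size * ratio) - 0.5) / ratio - 0.5
    matrix(bilinear_sample(ph$em[z, , ],
                           rep(fy, times = length(fx)),
                           rep(fx, each = length(fy))),
           length(fy), length(fx))
  }
  reg <- align_highres_to_reference(list(mk_hr(3)), 3, ref, ratio)
  s <- reg$slices[[1]]
  expect_identical(s$status, "done")
  expect_identical(s$ref_slice, 3L)
  # hr pixel (1,1) center corresponds to reference position win + shift + ...
  v <- (size * ratio) / 2
  rc <- highres_to_reference(reg, 1, v, v)
  true_y <- unname(win["y"] + shift[1] + (v - 0.5) / ratio - 0.5)
  true_x <- unname(win["x"] + shift[2] + (v - 0.5) / ratio - 0.5)
  expect_lt(abs(rc$y - true_y), 0.5)
  expect_lt(abs(rc$x - true_x), 0.5)

  # ratio 1, identical image: identity placement
  reg1 <- align_highres_to_reference(list(mrvem:::as_uint8(ph$em[2, , ])),
                                     2, ref, 1)
  s1 <- reg1$slices[[1]]
  expect_lt(max(abs(s1$offset)), 0.1)

  # missing reference at the same z: nearest existing slice, ties toward
  # the lower index
  ref2 <- ref
  ref2$images[[3]] <- matrix(0L, 120, 120)  # black = missing
  reg2 <- align_highres_to_reference(list(mk_hr(3)), 3, ref2, ratio)
  expect_identical(reg2$slices[[1]]$ref_slice, 2L)
})

test_that("rendering, re-rendering and the journal support exact resumability", {
  sim <- simulate_project(withr::local_tempdir(),
                          spec = phantom_spec(c(8, 96, 96), n_neurites = 20,
                                              neurite_radius = 6,
                                              noise_sigma = 2),
                          grid = c(1, 1), overlap_fraction = 0,
                          rigid_amplitude = 2, elastic_amplitude = 2,
                          jitter_amplitude = 0, seed = 3)
  out1 <- withr::local_tempdir()
  res <- run_alignment(sim$paths$cellular, out1, overlap_fraction = 0)

  # re-render from saved transforms is bit-identical
  inv <- discover_project(sim$paths$cellular)[[1]]
  slices <- lapply(seq_along(res$slice_index), function(k) {
    load_tilemap(inv, res$slice_index[k], 0)$images[[1]]
  })
  re <- rerender_stack(slices, file.path(out1, "aligned"))
  for (z in seq_along(re)) {
    expect_identical(re[[z]], res$aligned$images[[z]])
  }

  # downsampled copy has ceiling(dim / 4) extent
  dimg <- read_image(file.path(out1, "aligned", "down", "S0001.tif"))
  expect_identical(dim(dimg), as.integer(ceiling(res$aligned$dims / 4)))

  # an interrupted run resumes to the identical result: simulate the
  # interruption by wiping slices 3..5 of the z step and re-running
  journal_wipe(res$journal, "z", 3:5)
  res2 <- run_alignment(sim$paths$cellular, out1, overlap_fraction = 0)
  for (z in seq_along(res2$aligned$images)) {
    expect_identical(res2$aligned$images[[z]], res$aligned$images[[z]])
  }

  # journal records are append-only and wiping invalidates done units
  j <- journal_read(res$journal)
  expect_true(all(c("xy", "z") %in% j$step))
  journal_wipe(res$journal, "z", 2)
  expect_false(journal_is_done(res$journal, "z", 2))
})
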