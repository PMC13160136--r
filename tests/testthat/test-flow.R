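# Translation estimation, keypoint matching, robust affine fits, and
# patchwise flow fields.

test_that("estimate_translation recovers constructed shifts", {
  img <- tiny_image(128, seed = 1)
  mov <- mrvem:::shift_matrix(img, 3, -2)  # content moves by (3, -2)
  et <- estimate_translation(img, mov, 10)
  expect_true(et$valid)
  expect_equal(c(et$dy, et$dx), c(3, -2), tolerance = 0.05)
  expect_gt(et$peak_quality, 0.95)

  et0 <- estimate_translation(img, img, 10)
  expect_equal(c(et0$dy, et0$dx), c(0, 0), tolerance = 0.01)

  # degenerate constant image: flagged, zero confidence
  flat <- matrix(7, 64, 64)
  etc <- estimate_translation(flat, img[1:64, 1:64], 8)
  expect_false(etc$valid)
  expect_equal(etc$peak_quality, 0)
})

test_that("independent noise pairs fall below the confidence floor", {
  fails <- withr::with_seed(42, {
    vapply(seq_len(100), function(i) {
      a <- matrix(runif(48 * 48), 48, 48)
      b <- matrix(runif(48 * 48), 48, 48)
      et <- estimate_translation(a, b, 8)
      !et$valid
    }, TRUE)
  })
  expect_gte(mean(fails), 0.95)
})

test_that("keypoint matching judges overlap and feeds accurate affine fits", {
  img <- tiny_image(128, seed = 3)
  mk <- match_keypoints(img, img)
  expect_true(mk$overlap)
  expect_gte(nrow(mk$good), 8)
  expect_lt(max(abs(mk$good$fixed_y - mk$good$moving_y)), 0.2)

  # disjoint crops of one phantom share no content
  ph <- tiny_phantom(nz = 8, n = 140, seed = 5)
  a <- ph$em[2, 1:60, 1:60]
  b <- ph$em[2, 71:130, 71:130]
  expect_false(match_keypoints(a, b)$overlap)

  # 5 degree rotation about the center recovered through the affine fit
  th <- 5 * pi / 180
  cy <- 64.5; cx <- 64.5
  rot <- warp_by(img,
                 function(y, x) (cos(th) * (y - cy) - sin(th) * (x - cx)) + cy - y,
                 function(y, x) (sin(th) * (y - cy) + cos(th) * (x - cx)) + cx - x)
  mk2 <- match_keypoints(img, rot)
  expect_true(mk2$overlap)
  # the fitted map sends fixed points to moving points, i.e. the INVERSE
  # rotation of the one used to render the moving image
  af <- fit_affine(mk2$good)
  expect_equal(af$matrix[1, 1], cos(th), tolerance = 1e-2)
  expect_equal(af$matrix[1, 2], sin(th), tolerance = 1e-2)
  expect_equal(af$matrix[2, 1], -sin(th), tolerance = 1e-2)
  expect_equal(af$matrix[2, 2], cos(th), tolerance = 1e-2)
})

test_that("fit_affine is exact on clean data and robust to gross outliers", {
  A <- matrix(c(1.02, -0.05, 3, 0.04, 0.97, -2), 2, 3, byrow = TRUE)
  withr::with_seed(7, {
    fy <- runif(40, 1, 100); fx <- runif(40, 1, 100)
    mv <- apply_affine(A, fy, fx)
    cc <- data.frame(fixed_y = fy, fixed_x = fx,
                     moving_y = mv$y, moving_x = mv$x)
    fit <- fit_affine(cc)
    expect_equal(fit$matrix, A, tolerance = 1e-9)

    # 30% gross outliers
    cc2 <- cc
    out <- sample(40, 12)
    cc2$moving_y[out] <- cc2$moving_y[out] + runif(12, 20, 60)
    cc2$moving_x[out] <- cc2$moving_x[out] - runif(12, 20, 60)
    fit2 <- fit_affine(cc2)
    expect_equal(fit2$matrix, A, tolerance = 1e-3)
  })

  # collinear points are rank-deficient
  col <- data.frame(fixed_y = 1:5, fixed_x = 2 * (1:5),
                    moving_y = 1:5, moving_x = 2 * (1:5))
  expect_error(fit_affine(col), "collinear|degenerate|inlier")
})

test_that("estimate_flow measures synthetic warps and masks bad nodes", {
  ph <- tiny_phantom(nz = 8, n = 120, seed = 6)
  img <- ph$em[3, , ]

  f0 <- estimate_flow(img, img, patch_size = 25, stride = 10,
                      search_radius = 6)
  expect_true(all(abs(f0$dy[f0$valid]) < 0.05))
  expect_true(all(abs(f0$dx[f0$valid]) < 0.05))

  # low-frequency warp recovered below half a pixel RMS
  w <- ground_truth_warp(1, c(120, 120), rigid_amplitude = 0,
                         elastic_amplitude = 4, seed = 8)
  mov <- warp_by(img,
                 function(y, x) warp_displacement(w, 1, y, x)$dy,
                 function(y, x) warp_displacement(w, 1, y, x)$dx)
  fl <- estimate_flow(img, mov, patch_size = 31, stride = 10,
                      search_radius = 8)
  gt <- warp_displacement(w, 1,
                          rep(fl$node_y, times = length(fl$node_x)),
                          rep(fl$node_x, each = length(fl$node_y)))
  v <- as.vector(fl$valid)
  err <- sqrt(mean(((as.vector(fl$dy) + gt$dy)^2 +
                      (as.vector(fl$dx) + gt$dx)^2)[v]))
  expect_lt(err, 0.5)

  # nodes on constant regions are masked invalid
  img2 <- img
  img2[40:80, 40:80] <- 120
  f2 <- estimate_flow(img2, img2, patch_size = 25, stride = 10,
                      search_radius = 5)
  ctr_y <- which(f2$node_y > 52 & f2$node_y < 68)
  ctr_x <- which(f2$node_x > 52 & f2$node_x < 68)
  expect_false(any(f2$valid[ctr_y, ctr_x]))

  expect_error(estimate_flow(img, img, patch_size = 300, stride = 10),
               "patch larger than image")
})

test_that("multiscale flow captures global and local motion together", {
  ph <- tiny_phantom(nz = 8, n = 160, seed = 12)
  img <- ph$em[4, , ]

  # identity: zero field
  m0 <- multiscale_flow(img, img, scales = c(4, 1), patch_size = 31,
                        stride = 12, search_radius = 8)
  expect_lt(max(abs(c(m0$dy[m0$valid], m0$dx[m0$valid]))), 0.1)

  # translation larger than the patch, recovered via the coarse scale;
  # sampling the source 40 px down moves content up, so the flow is -40
  mov <- warp_by(img, function(y, x) 40 + 0 * y, function(y, x) 0 * x)
  mt <- multiscale_flow(img, mov, scales = c(4, 1), patch_size = 31,
                        stride = 12, search_radius = 12)
  mt <- filter_flow(mt)
  v <- mt$valid
  expect_gt(mean(v), 0.2)
  expect_lt(sqrt(mean((mt$dy[v] + 40)^2 + (mt$dx[v])^2)), 0.5)

  # 40 px global shift plus ~2 px low-frequency ripple
  w <- ground_truth_warp(1, c(160, 160), rigid_amplitude = 0,
                         elastic_amplitude = 2, seed = 4)
  mov2 <- warp_by(img,
                  function(y, x) 40 + warp_displacement(w, 1, y, x)$dy,
                  function(y, x) warp_displacement(w, 1, y, x)$dx)
  m2 <- filter_flow(multiscale_flow(img, mov2, scales = c(4, 1),
                                    patch_size = 31, stride = 12,
                                    search_radius = 12))
  gt <- warp_displacement(w, 1,
                          rep(m2$node_y, times = length(m2$node_x)),
                          rep(m2$node_x, each = length(m2$node_y)))
  v2 <- as.vector(m2$valid)
  expect_gt(mean(v2), 0.2)
  err <- sqrt(mean(((as.vector(m2$dy) + 40 + gt$dy)^2 +
                      (as.vector(m2$dx) + gt$dx)^2)[v2]))
  expect_lt(err, 0.5)
})

test_that("flow fields obey antisymmetry and translation equivariance", {
  ph <- tiny_phantom(nz = 8, n = 120, seed = 21)
  img <- ph$em[2, , ]
  w <- ground_truth_warp(1, c(120, 120), rigid_amplitude = 0,
                         elastic_amplitude = 3, seed = 2)
  mov <- warp_by(img,
                 function(y, x) warp_displacement(w, 1, y, x)$dy,
                 function(y, x) warp_displacement(w, 1, y, x)$dx)
  fab <- estimate_flow(img, mov, patch_size = 31, stride = 12,
                       search_radius = 6)
  fba <- estimate_flow(mov, img, patch_size = 31, stride = 12,
                       search_radius = 6)
  both <- fab$valid & fba$valid
  expect_gt(sum(both), 10)
  expect_lt(max(abs(fab$dy[both] + fba$dy[both])), 0.5)
  expect_lt(max(abs(fab$dx[both] + fba$dx[both])), 0.5)

  # shifting BOTH images leaves the field unchanged at shared nodes
  # (shift by exactly one node stride so node grids correspond)
  sh_f <- mrvem:::shift_matrix(img, 12, 12)
  sh_m <- mrvem:::shift_matrix(mov, 12, 12)
  f1 <- estimate_flow(img, mov, patch_size = 31, stride = 12,
                      search_radius = 6)
  f2 <- estimate_flow(sh_f, sh_m, patch_size = 31, stride = 12,
                      search_radius = 6)
  # node (i, j) of f2 sees the content f1 saw one node earlier
  ny <- length(f1$node_y)
  common <- f1$valid[1:(ny - 1), 1:(ny - 1)] & f2$valid[2:ny, 2:ny]
  expect_gte(sum(common), 5)
  dy_a <- f1$dy[1:(ny - 1), 1:(ny - 1)][common]
  dy_b <- f2$dy[2:ny, 2:ny][common]
  expect_lt(stats::median(abs(dy_a - dy_b)), 0.3)
})

test_that("validity calibration separates signal from noise", {
  ph <- tiny_phantom(nz = 8, n = 120, seed = 31)
  img <- ph$em[5, , ]
  f_good <- estimate_flow(img, img, patch_size = 31, stride = 14,
                          search_radius = 6)
  expect_gte(mean(f_good$valid), 0.95)

  withr::with_seed(2, {
    a <- matrix(runif(120^2, 0, 255), 120, 120)
    b <- matrix(runif(120^2, 0, 255), 120, 120)
  })
  f_bad <- estimate_flow(a, b, patch_size = 31, stride = 14,
                         search_radius = 6)
  expect_lte(mean(f_bad$valid), 0.05)
})
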