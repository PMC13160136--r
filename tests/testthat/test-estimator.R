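# Acquisition time, covered-area, hypothetical-scenario and gain-factor
# arithmetic, including brute-force per-pixel enumeration oracles and the
# published per-dataset worked examples.

test_that("tile map pixel counts and times follow the model", {
  unit <- tileset_spec("cellular", gx = 1, gy = 1, nz = 1, nx = 1, ny = 1,
                       t_dwell_us = 1, pixel_size_nm = 10)
  t1 <- tilemap_time(unit)
  expect_identical(t1$N_tilemap, 1)
  expect_identical(t1$t_us, 1)

  s <- tileset_spec("cellular", gx = 2, gy = 3, nz = 10, nx = 1000,
                    ny = 800, t_dwell_us = 2, pixel_size_nm = 10)
  ts <- tilemap_time(s)
  # per-tile summation oracle: every tile contributes nx * ny pixels
  n_oracle <- 0
  for (g in seq_len(2 * 3 * 10)) n_oracle <- n_oracle + 1000 * 800
  expect_identical(ts$N_tilemap, n_oracle)
  expect_identical(ts$N_tilemap, 4.8e7)
  expect_identical(ts$t_us, 9.6e7)
  expect_identical(ts$t_s, 96)

  # doubling nz doubles both outputs
  s2 <- s; s2$nz <- 20
  expect_identical(tilemap_time(s2)$N_tilemap, 2 * ts$N_tilemap)
  expect_identical(tilemap_time(s2)$t_us, 2 * ts$t_us)

  expect_error(tileset_spec("cellular", 1, 1, 1, 1, 1, t_dwell_us = 0,
                            pixel_size_nm = 10), "dwell")
  expect_error(tileset_spec("cellular", 1, 1, 1, 1, 1, t_dwell_us = 1,
                            pixel_size_nm = -1), "pixel size")
})

test_that("covered extents account for overlap geometrically", {
  # single tile: no overlap correction
  s1 <- tileset_spec("cellular", gx = 1, gy = 1, nz = 1, nx = 500, ny = 400,
                     t_dwell_us = 1, pixel_size_nm = 10)
  a1 <- covered_area(s1)
  expect_identical(a1$x_nm, 5000)
  expect_identical(a1$y_nm, 4000)

  # two 1000-px tiles at 15% overlap and 10 nm pixels: first tile 10000 nm,
  # second adds 8500 nm -> 18500 nm
  s2 <- tileset_spec("cellular", gx = 2, gy = 1, nz = 1, nx = 1000,
                     ny = 1000, t_dwell_us = 1, pixel_size_nm = 10,
                     overlap = 0.15)
  expect_identical(covered_area(s2)$x_nm, 18500)

  # zero overlap: plain product
  s3 <- tileset_spec("cellular", gx = 3, gy = 2, nz = 1, nx = 200, ny = 100,
                     t_dwell_us = 1, pixel_size_nm = 5, overlap = 0)
  expect_identical(covered_area(s3)$x_nm, 5 * 3 * 200)
  expect_identical(covered_area(s3)$y_nm, 5 * 2 * 100)

  # monotonicity: more overlap, less area
  areas <- vapply(c(0, 0.1, 0.2, 0.3), function(o) {
    covered_area(tileset_spec("cellular", 3, 3, 1, 100, 100, 1, 10,
                              overlap = o))$A_nm2
  }, 0)
  expect_true(all(diff(areas) < 0))
})

test_that("hypothetical high-resolution counts match enumeration", {
  # 1 um^2 at (10 nm)^2 pixels -> 1e6 pixels
  s <- tileset_spec("cellular", gx = 1, gy = 1, nz = 1, nx = 100, ny = 100,
                    t_dwell_us = 2, pixel_size_nm = 10)
  h <- hypothetical_highres(s, P_highres_nm2 = 100, t_dwell_us = 2)  # nz = 1
  expect_identical(h$N_highres, 1e4)  # (1000 nm)^2 / 100 nm^2

  # additivity over tile maps
  inv2 <- rbind(s, s)
  expect_identical(hypothetical_highres(inv2, 100, 2)$N_highres,
                   2 * h$N_highres)

  # brute-force per-pixel enumeration on an exactly divisible geometry:
  # lay hypothetical pixels over the covered extent and count them
  s4 <- tileset_spec("cellular", gx = 2, gy = 2, nz = 1, nx = 60, ny = 40,
                     t_dwell_us = 1, pixel_size_nm = 12, overlap = 0.25)
  ca <- covered_area(s4)
  hp <- 6  # hypothetical pixel size nm -> P = 36 nm^2
  nx_h <- ca$x_nm / hp
  ny_h <- ca$y_nm / hp
  count <- 0
  for (i in seq_len(ny_h)) count <- count + nx_h
  got <- hypothetical_highres(s4, hp^2, 1)
  expect_equal(got$N_highres, count)

  # the synaptic class is rejected by the guard
  syn <- tileset_spec("synaptic", 1, 1, 1, 10, 10, 1, 10)
  expect_error(hypothetical_highres(syn, 100, 1), "cellular")
})

test_that("gain factors reproduce the published per-dataset examples", {
  pub <- utils::read.csv(system.file("extdata", "sbem_timegain_datasets.csv",
                                     package = "mrvem"))
  expect_identical(nrow(pub), 3L)
  shown <- vapply(seq_len(nrow(pub)), function(i) {
    gain_from_times(pub$total_days[i], pub$potential_days[i])$gain_factor_display
  }, 0)
  expect_identical(shown, c(4.1, 6.8, 2.6))
  expect_identical(mrvem:::round_half_up(mean(shown), 1), 4.5)
  expect_gte(sum(pub$potential_days - pub$total_days), 362)
})

test_that("gain_report composes the full estimate coherently", {
  inv <- make_inventory(list(
    tileset_spec("cellular", gx = 3, gy = 3, nz = 200, nx = 2000, ny = 2000,
                 t_dwell_us = 2, pixel_size_nm = 40, overlap = 0.15),
    tileset_spec("synaptic", gx = 2, gy = 2, nz = 150, nx = 2000, ny = 2000,
                 t_dwell_us = 2, pixel_size_nm = 10, overlap = 0.15)))
  rep <- gain_report(inv)
  # defaults inferred from the synaptic rows
  expect_identical(rep$P_highres_nm2, 100)
  expect_identical(rep$t_dwell_us, 2)
  # total time is the sum over both classes
  t_cell <- tilemap_time(inv[1, ])$t_us
  t_syn <- tilemap_time(inv[2, ])$t_us
  expect_equal(rep$t_total_days, (t_cell + t_syn) / (86400 * 1e6))
  # gain is the ratio to the hypothetical scenario, invariant to units
  hyp <- hypothetical_highres(inv[1, ], 100, 2)
  expect_equal(rep$gain_factor, hyp$t_days / rep$t_total_days)
  expect_equal(rep$gain_factor, hyp$t_us / (t_cell + t_syn))
  expect_equal(rep$days_saved, hyp$t_days - rep$t_total_days)
  # sizes: 1 byte per pixel, TB = 1e12 bytes
  expect_equal(rep$size_tb,
               (tilemap_time(inv[1, ])$N_tilemap +
                  tilemap_time(inv[2, ])$N_tilemap) / 1e12)
  expect_equal(rep$size_highres_tb, hyp$N_highres / 1e12)

  expect_error(gain_report(inv[0, ]), "empty")

  # inventory CSV round trip preserves the report
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(inv, p, row.names = FALSE)
  inv2 <- read_inventory(p)
  rep2 <- gain_report(inv2)
  expect_equal(rep2$gain_factor, rep$gain_factor)
})

test_that("display rounding is half away from zero", {
  expect_identical(mrvem:::round_half_up(4.45, 1), 4.5)
  expect_identical(mrvem:::round_half_up(4.44, 1), 4.4)
  expect_identical(mrvem:::round_half_up(-4.45, 1), -4.5)
  expect_identical(mrvem:::round_half_up(2.0, 1), 2)
})
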