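test_that("line integrals invert Beer-Lambert", {
  flat <- matrix(100, 8, 10)
  st <- array(100, c(8, 10, 2))
  p <- to_line_integrals(st, flat)
  expect_true(all(p == 0))                       # I = I0
  st2 <- array(100 * exp(-2), c(8, 10, 2))
  expect_equal(to_line_integrals(st2, flat)[1, 1, 1], 2, tolerance = 1e-12)
  expect_error(to_line_integrals(st, matrix(0, 8, 10)), "positive")
  # analytic monoenergetic projections give mu * path-length
  g <- desk_geometry()
  sp <- mono60()
  coll <- slit_for_fov(4, g)
  st3 <- project_primary("water_10cm", g, coll, sp, i0 = 1)
  fl3 <- project_primary("air", g, coll, sp, i0 = 1)$total[, , 1]
  p3 <- to_line_integrals(st3, fl3)
  mu <- material_mu("water", 60)$total
  ctr <- p3[dim(p3)[1] %/% 2, dim(p3)[2] %/% 2, 1]
  mu_air <- material_mu("air", 60)$total
  # flat field uses the 20-cm air cylinder; central ray is slightly oblique
  expect_equal(ctr, mu * 10 - mu_air * 20, tolerance = 2e-3)
})

test_that("FDK is linear, zero-preserving and demands angular coverage", {
  g <- desk_geometry(n_views = 24L)
  grid <- recon_grid(64, 64, 8, voxel_mm = 2)
  zero <- array(0, c(g$det_rows, g$det_cols, 24))
  vz <- fdk_reconstruct(zero, g, grid)
  expect_true(all(vz$voxels == 0))
  sp <- mono60()
  coll <- slit_for_fov(4, g)
  st <- project_primary("water_10cm", g, coll, sp, i0 = 1)
  fl <- project_primary("air", g, coll, sp, i0 = 1)$total[, , 1]
  p <- to_line_integrals(st, fl)
  v1 <- fdk_reconstruct(p, g, grid)
  v3 <- fdk_reconstruct(3 * p, g, grid)
  expect_equal(v3$voxels, 3 * v1$voxels, tolerance = 1e-12)
  g_short <- scanner_geometry(det_rows = g$det_rows, det_cols = g$det_cols,
                              det_pitch_mm = g$det_pitch_mm, n_views = 5,
                              angles_deg = seq(0, 120, length.out = 5))
  expect_error(fdk_reconstruct(p[, , 1:5], g_short, grid), "coverage")
})

test_that("FDK recovers the water attenuation coefficient within 5%", {
  g <- desk_geometry(n_views = 64L)
  sp <- mono60()
  coll <- slit_for_fov(4, g)
  st <- project_primary("water_10cm", g, coll, sp, i0 = 1)
  fl <- project_primary("air", g, coll, sp, i0 = 1)$total[, , 1]
  vol <- fdk_reconstruct(to_line_integrals(st, fl), g,
                         recon_grid(128, 128, 8, voxel_mm = 1))
  mu <- material_mu("water", 60)$total
  expect_equal(measure_mu_water(vol), mu, tolerance = 0.05)
  # scatter-free water cylinder shows essentially no cupping
  hu <- hu_calibrate(vol, measure_mu_water(vol))
  expect_lt(abs(cupping_index(hu, build_phantom("water_10cm"))), 15)
  # central ROI of the calibrated volume sits near 0 HU
  sl <- volume_slice(hu)
  ctr <- roi_stats(sl, roi_spec("image", "circle", c(0, 0), diameter_cm = 2))
  expect_lt(abs(ctr$mean), 30)
})

test_that("HU calibration maps water to 0 and vacuum to -1000", {
  g <- desk_geometry(n_views = 24L)
  vol <- structure(list(voxels = array(0.2, c(4, 4, 2)), voxel_mm = 1,
                        center_cm = c(0, 0, 0), units = "1/cm",
                        mu_water = NULL, geometry = g),
                   class = "recon_volume")
  hu <- hu_calibrate(vol, 0.2)
  expect_true(all(hu$voxels == 0))
  vol$voxels[] <- 0
  expect_true(all(hu_calibrate(vol, 0.2)$voxels == -1000))
  expect_error(hu_calibrate(vol, 0), "positive")
  expect_error(hu_calibrate(hu_calibrate(vol, 0.2), 0.2), "already")
})

test_that("reconstruction rotates with the phantom", {
  g <- desk_geometry(n_views = 32L)
  sp <- mono60()
  coll <- slit_for_fov(4, g)
  rod <- function(x, y) phantom_spec(
    10, 10, inserts = tibble::tibble(x_cm = x, y_cm = y, diameter_cm = 3,
                                     height_cm = 10,
                                     material = "dense_bone_800"))
  grid <- recon_grid(64, 64, 4, voxel_mm = 1.5)
  fl <- project_primary("air", g, coll, sp, i0 = 1)$total[, , 1]
  rec <- function(ph) {
    st <- project_primary(ph, g, coll, sp, i0 = 1)
    fdk_reconstruct(to_line_integrals(st, fl), g, grid)$voxels[, , 2]
  }
  v1 <- rec(rod(2, 0))
  v2 <- rec(rod(0, 2))
  # rotating the phantom by 90 deg rotates the reconstruction
  v1r <- t(v1[, rev(seq_len(64))])  # 90 deg rotation of the slice
  expect_gt(cor(as.vector(v2), as.vector(v1r)), 0.98)
})

test_that("cupping appears with scatter and shrinks after correction", {
  g <- desk_geometry(n_views = 48L)
  sp <- mono60()
  c4 <- slit_for_fov(4, g)
  c13 <- slit_for_fov(13, g)
  ph <- build_phantom("water_10cm")
  st4 <- project_primary(ph, g, c4, sp, i0 = 4000)
  st13 <- project_primary(ph, g, c13, sp, i0 = 4000)
  # amplitude chosen for a realistic central scatter-to-primary ratio (~1)
  fld <- analytic_scatter_field(amplitude = 0.04, s0_mm = 0.5)
  t4 <- add_scatter_and_noise(st4, fld, 14, poisson = TRUE, seed = 31)
  t13 <- add_scatter_and_noise(st13, fld, 42, poisson = TRUE, seed = 32)
  flat <- array(4000, dim(st4$total)[1:2])
  res <- correct_fov_scan(t4, t13, 14, 42, flat, flat)
  grid <- recon_grid(96, 96, 8, voxel_mm = 1.5)
  rec <- function(st) {
    p <- to_line_integrals(st, flat)
    fdk_reconstruct(p, g, grid)
  }
  v_raw <- rec(t4)
  v_cor <- rec(res$corrected)
  muw <- measure_mu_water(rec(st4))
  cup_raw <- cupping_index(hu_calibrate(v_raw, muw), ph)
  cup_cor <- cupping_index(hu_calibrate(v_cor, muw), ph)
  expect_gt(cup_raw, 0)        # scatter causes cupping
  expect_lt(cup_cor, cup_raw)  # correction strictly reduces it
})
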