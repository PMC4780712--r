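test_that("ROI statistics match direct formulas", {
  img <- matrix(3, 50, 50)
  rs <- roi_stats(img, roi_spec(side_px = 11))
  expect_equal(rs$mean, 3)
  expect_equal(rs$sd, 0)
  expect_equal(rs$n, 121L)
  chk <- outer(1:11, 1:11, function(i, j) 2 * ((i + j) %% 2))
  img2 <- matrix(0, 11, 11)
  img2[] <- chk
  rs2 <- roi_stats(img2, roi_spec(side_px = 11))
  vals <- as.vector(chk)
  expect_equal(rs2$mean, mean(vals))
  expect_equal(rs2$sd, sqrt(sum((vals - mean(vals))^2) / 120))
  expect_error(roi_stats(matrix(0, 5, 5), roi_spec(side_px = 11)), "outside")
})

test_that("circular image-domain ROIs respect world coordinates", {
  img <- matrix(0, 40, 40)
  attr(img, "pixel_mm") <- 5
  attr(img, "center_cm") <- c(0, 0)
  x <- (seq_len(40) - 0.5 - 20) * 0.5
  img[outer(x^2, x^2, "+") <= 1] <- 9   # 2 cm disc of 9s
  rs <- roi_stats(img, roi_spec("image", "circle", c(0, 0), diameter_cm = 0.9))
  expect_equal(rs$mean, 9)
  expect_error(roi_stats(img, roi_spec("image", "circle", c(11, 0),
                                       diameter_cm = 2)), "outside")
})

test_that("SPR is the ratio of scatter to primary ROI means", {
  g <- desk_geometry(n_views = 1L)
  coll <- collimator_setting("open", g)
  mk <- function(p, s) projection_stack(
    primary = array(p, c(g$det_rows, g$det_cols, 1)),
    scatter = array(s, c(g$det_rows, g$det_cols, 1)),
    geometry = g, collimation = coll)
  expect_equal(compute_spr(mk(10, 0))$spr, 0)
  expect_equal(compute_spr(mk(10, 10))$spr, 1)
  expect_error(compute_spr(mk(0, 1)), "zero")
  no_chan <- projection_stack(total = array(1, c(g$det_rows, g$det_cols, 1)),
                              geometry = g, collimation = coll)
  expect_error(compute_spr(no_chan), "channels")
})

test_that("log-fit diagnostics handle perfect, degenerate and random data", {
  x <- c(0.5, 1, 2, 5, 10, 20, 45)
  y <- 7 + 2.5 * log(x)
  fd <- fit_diagnostics(x, y)
  expect_equal(fd$r2, 1, tolerance = 1e-12)
  expect_equal(fd$a, 2.5, tolerance = 1e-9)
  fc <- fit_diagnostics(x, rep(4, 7))
  expect_equal(fc$a, 0)
  expect_equal(fc$r2, 0)
  expect_true(fc$degenerate)
  expect_error(fit_diagnostics(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_diagnostics(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("CNR follows its definition exactly", {
  # synthetic HU volume over a five-insert phantom
  ph <- build_phantom("mc_10cm_five_tissue")
  nx <- 96
  vox <- 1.5
  x <- (seq_len(nx) - 0.5 - nx / 2) * vox / 10
  base <- matrix(10, nx, nx)
  set.seed(5)
  base <- base + matrix(rnorm(nx * nx, 0, 20), nx, nx)
  for (i in seq_len(nrow(ph$inserts))) {
    ins <- ph$inserts[i, ]
    d2 <- outer((x - ins$x_cm)^2, (x - ins$y_cm)^2, "+")
    base[d2 <= (ins$diameter_cm / 2)^2] <- 150
  }
  vol <- structure(list(voxels = array(base, c(nx, nx, 3)), voxel_mm = vox,
                        center_cm = c(0, 0, 0), units = "HU",
                        mu_water = 0.2, geometry = NULL),
                   class = "recon_volume")
  rep_ <- compute_cnr(vol, ph)
  expect_equal(nrow(rep_), 5)
  # Eq-definition exactness, bit for bit
  expect_identical(rep_$cnr,
                   abs(rep_$ct_mean - rep_$ct_water_mean) / rep_$ct_water_sd)
  # insert at 150 HU over measured water background
  expect_equal(rep_$ct_mean, rep(150, 5))
  expect_equal(attr(rep_, "mean_cnr"), mean(rep_$cnr))
  # contrast of one background SD gives CNR exactly 1
  ws <- rep_$ct_water_sd[1]
  vol2 <- vol
  for (i in seq_len(nrow(ph$inserts))) {
    ins <- ph$inserts[i, ]
    d2 <- outer((x - ins$x_cm)^2, (x - ins$y_cm)^2, "+")
    vol2$voxels[, , 2][d2 <= (ins$diameter_cm / 2)^2] <-
      rep_$ct_water_mean[1] + ws
  }
  rep2 <- compute_cnr(vol2, ph)
  expect_equal(rep2$cnr, rep(1, 5))
  # plain arithmetic example: insert 150, water 10 +/- 20
  expect_equal(abs(150 - 10) / 20, 7)
})

test_that("CNR requires HU calibration and non-degenerate background", {
  ph <- build_phantom("mc_10cm_five_tissue")
  vol <- structure(list(voxels = array(0.2, c(64, 64, 3)), voxel_mm = 2,
                        center_cm = c(0, 0, 0), units = "1/cm",
                        mu_water = NULL, geometry = NULL),
                   class = "recon_volume")
  expect_error(compute_cnr(vol, ph), "HU")
  vol$units <- "HU"
  expect_error(compute_cnr(vol, ph), "zero")
})

test_that("cupping index is zero for uniform and tracks a parabolic dip", {
  ph <- build_phantom("water_10cm")
  nx <- 96
  vox <- 1.5
  mk <- function(img) structure(
    list(voxels = array(img, c(nx, nx, 3)), voxel_mm = vox,
         center_cm = c(0, 0, 0), units = "HU", mu_water = 0.2,
         geometry = NULL), class = "recon_volume")
  expect_equal(cupping_index(mk(matrix(7, nx, nx)), ph), 0)
  # constructed parabolic dip of depth d at the center
  x <- (seq_len(nx) - 0.5 - nx / 2) * vox / 10
  rr2 <- outer(x^2, x^2, "+")
  d <- 80
  dip <- matrix(-d * pmax(0, 1 - rr2 / 25), nx, nx)
  idx <- cupping_index(mk(dip), ph)
  # oracle: mean over the same edge/center regions of the analytic profile
  R <- 5
  keepr <- sqrt(rr2)
  ctr <- keepr <= 0.3 * R
  edge <- keepr >= 0.7 * R & keepr <= 0.9 * R
  oracle <- mean(dip[edge]) - mean(dip[ctr])
  expect_equal(idx, oracle, tolerance = 1e-12)
  expect_gt(idx, 0)
})

test_that("line profiles interpolate, reverse and cross insert plateaus", {
  img <- matrix(4, 30, 30)
  pr <- line_profile(img, c(5, 5), c(25, 25))
  expect_true(all(pr$value == 4))
  img2 <- outer(1:30, 1:30, function(i, j) i + j)
  a <- line_profile(img2, c(3, 7), c(21, 28), n = 50)
  b <- line_profile(img2, c(21, 28), c(3, 7), n = 50)
  expect_equal(a$value, rev(b$value), tolerance = 1e-9)
  # plateau across a rod: synthetic slice with an insert disc
  nx <- 60
  x <- (seq_len(nx) - 0.5 - nx / 2) * 0.2
  sl <- matrix(0, nx, nx)
  sl[outer((x - 3)^2, x^2, "+") <= 1.5^2] <- 500
  prof <- line_profile(sl, c(nx / 2 + 15, 5), c(nx / 2 + 15, 55), n = 120)
  expect_equal(max(prof$value), 500)
  expect_gt(sum(prof$value == 500), 20)
  expect_error(line_profile(img, c(0, 1), c(5, 5)), "leaves")
})
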