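test_that("ray path lengths handle miss, chord and nesting", {
  ph <- build_phantom("water_10cm")
  miss <- ray_path_lengths(ph, c(49.54, 0, 20), c(-21.86, 0, 20))
  expect_true(all(miss$length_cm == 0))
  chord <- ray_path_lengths(ph, c(49.54, 0, 0), c(-21.86, 0, 0))
  expect_equal(chord$length_cm[chord$material == "water"], 10,
               tolerance = 1e-9)
  # nested bone core: innermost wins, sheath loses the core chord
  # the y = 0 ray crosses two cored bone inserts (at +x and -x) and the
  # central rod of the second experimental layout
  ph2 <- build_phantom("exp_10cm_setting2")
  rl <- ray_path_lengths(ph2, c(49.54, 0, 0), c(-21.86, 0, 0))
  g <- function(m) { v <- rl$length_cm[rl$material == m]; if (length(v)) v else 0 }
  expect_equal(g("dense_bone_800"), 1, tolerance = 1e-9)
  expect_equal(g("dense_bone_1750"), 1, tolerance = 1e-9)
  expect_equal(g("soft_tissue"), 4, tolerance = 1e-9)  # two 3-cm sheaths minus cores
  expect_equal(g("lung_exhale"), 3, tolerance = 1e-9)
  expect_equal(g("water"), 1, tolerance = 1e-9)
})

test_that("ray path lengths agree with dense numerical sampling", {
  ph <- build_phantom("mc_10cm_five_tissue")
  pc <- cbctscatter:::phantom_cylinders(ph)
  src <- c(49.54, 0, 0)
  set.seed(42)
  for (k in 1:5) {
    dst <- c(-21.86, runif(1, -8, 8), runif(1, -6, 6))
    rl <- ray_path_lengths(ph, src, dst)
    nstep <- 4e5
    tt <- (seq_len(nstep) - 0.5) / nstep
    pts <- cbind(src[1] + tt * (dst[1] - src[1]),
                 src[2] + tt * (dst[2] - src[2]),
                 src[3] + tt * (dst[3] - src[3]))
    seg <- sqrt(sum((dst - src)^2)) / nstep
    dense <- sum(sqrt(pts[, 1]^2 + pts[, 2]^2) <= 5 & abs(pts[, 3]) <= 5) * seg
    expect_equal(sum(rl$length_cm), dense, tolerance = 1e-3)
  }
})

test_that("primary projection obeys the Beer-Lambert closed form", {
  g <- desk_geometry()
  sp <- mono60()
  coll <- slit_for_fov(4, g)
  vac <- project_primary("air", g, coll, sp, i0 = 7)
  band <- vac$total[, , 1] > 0
  # air is nearly vacuum: every fully illuminated pixel ~ i0
  full <- vac$total[, , 1][vac$total[, , 1] > 0.9 * max(vac$total)]
  expect_equal(mean(full), 7, tolerance = 0.01)
  expect_true(all(vac$total[!band] == 0))
  st <- project_primary("water_10cm", g, coll, sp, i0 = 1)
  mu <- material_mu("water", 60)$total
  ctr <- st$total[nrow(st$total) %/% 2, ncol(st$total) %/% 2, 1]
  ray <- exp(-mu * 10)
  expect_equal(ctr, ray, tolerance = 0.003)
})

test_that("analytic scatter respects channel conservation and slit response", {
  g <- desk_geometry()
  sp <- mono60()
  coll <- slit_for_fov(4, g)
  st <- project_primary("water_10cm", g, coll, sp, i0 = 1000)
  fld <- analytic_scatter_field(amplitude = 0.2, s0_mm = 1)
  s1 <- add_scatter_and_noise(st, fld, slit_mm = 14)
  expect_equal(s1$total, s1$primary + s1$scatter)
  expect_true(all(s1$scatter >= 0))
  # zero amplitude: total = primary
  s0 <- add_scatter_and_noise(st, analytic_scatter_field(amplitude = 0), 14)
  expect_equal(s0$total, st$primary)
  # configured response ratio holds exactly in noiseless mode
  s2 <- add_scatter_and_noise(st, fld, slit_mm = 42)
  r <- scatter_slit_response(fld, 42) / scatter_slit_response(fld, 14)
  in_band <- s1$scatter > 0
  expect_equal(s2$scatter[in_band] / s1$scatter[in_band],
               rep(r, sum(in_band)), tolerance = 1e-12)
  # monotone response with g(0) = 0
  expect_equal(scatter_slit_response(fld, 0), 0)
  expect_true(all(diff(scatter_slit_response(fld, c(0.5, 1, 5, 20, 50))) > 0))
})

test_that("Poisson mode conserves channels in expectation", {
  g <- scanner_geometry(det_rows = 24, det_cols = 30, det_pitch_mm = 8,
                        n_views = 1)
  sp <- mono60()
  coll <- slit_for_fov(4, g)
  st <- project_primary("water_10cm", g, coll, sp, i0 = 50)
  fld <- analytic_scatter_field(amplitude = 0.3, s0_mm = 1)
  noiseless <- add_scatter_and_noise(st, fld, 14)
  tot <- 0
  nseed <- 120
  for (s in seq_len(nseed)) {
    ns <- add_scatter_and_noise(st, fld, 14, poisson = TRUE, seed = s)
    expect_equal(ns$total, ns$primary + ns$scatter)  # exact per draw
    tot <- tot + sum(ns$total)
  }
  mu <- sum(noiseless$total)
  expect_equal(tot / nseed, mu, tolerance = 3 * sqrt(mu / nseed) / mu)
})

test_that("log-shaped slit response yields a near-perfect log fit", {
  g <- scanner_geometry(det_rows = 24, det_cols = 30, det_pitch_mm = 8,
                        n_views = 1)
  sp <- mono60()
  coll <- slit_for_fov(4, g)
  st <- project_primary("water_10cm", g, coll, sp, i0 = 1000)
  fld <- analytic_scatter_field(amplitude = 0.3, s0_mm = 0.05)
  slits <- c(0.5, 1, 2, 5, 10, 20, 45)
  ys <- vapply(slits, function(s) {
    tot <- add_scatter_and_noise(st, fld, s)$total[, , 1]
    mean(tot[10:14, 13:17])
  }, numeric(1))
  expect_gt(fit_diagnostics(slits, ys)$r2, 0.99)
})
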