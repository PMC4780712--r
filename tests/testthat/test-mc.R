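test_that("near-vacuum phantom produces essentially no scatter", {
  g <- desk_geometry()
  coll <- collimator_setting("open", g)
  v <- simulate_view("air", g, coll, mono60(), 5e4, seed = 2,
                     detector = "ideal")
  expect_lt(sum(v$scatter) / sum(v$total), 0.005)
})

test_that("pencil-beam transmission matches the Beer-Lambert oracle", {
  # 1-column detector + narrow axial band = pencil through the cylinder axis
  g <- scanner_geometry(det_rows = 96, det_cols = 1, det_pitch_mm = 2,
                        n_views = 1)
  coll <- collimator_setting(0.12, g)
  n <- 2e5
  v <- simulate_view("water_10cm", g, coll, mono60(), n, seed = 7,
                     detector = "ideal")
  p0 <- exp(-material_mu("water", 60)$total * 10)
  expect_lt(abs(sum(v$primary) / n - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("Compton energies follow the Klein-Nishina law", {
  # oracle: numerical integration of d(sigma)/d(eps) ~ eps + 1/eps - sin^2
  n <- 2e5
  for (E0 in c(60, 100)) {
    es <- sample_compton_energies(E0, n, seed = 3)
    k <- E0 / 510.99895
    eps <- seq(1 / (1 + 2 * k), 1, length.out = 2e5 + 1)
    t <- (1 - eps) / (k * eps)
    w <- eps + 1 / eps - t * (2 - t)
    oracle <- E0 * sum(eps * w) / sum(w)
    expect_lt(abs(mean(es) - oracle), 3 * sd(es) / sqrt(n))
    expect_true(all(es >= E0 / (1 + 2 * k) - 1e-9 & es <= E0 + 1e-9))
  }
})

test_that("channels conserve exactly and honor the counters", {
  g <- desk_geometry()
  coll <- slit_for_fov(4, g)
  v <- simulate_view("mc_10cm_five_tissue", g, coll, mono60(), 5e4, seed = 5,
                     record_photons = TRUE)
  expect_identical(v$total, v$primary + v$scatter)
  expect_equal(sum(v$total), v$n_detected)
  r <- v$records
  expect_true(all(r$n_compton_phantom >= 0 & r$n_rayleigh_phantom >= 0))
  # primary iff no phantom interaction (default classification)
  expect_equal(sum(r$n_compton_phantom + r$n_rayleigh_phantom == 0) / nrow(r),
               sum(v$primary) / sum(v$total), tolerance = 1e-9)
})

test_that("the engine is deterministic and linear in the photon budget", {
  g <- desk_geometry()
  coll <- slit_for_fov(4, g)
  a <- simulate_view("water_10cm", g, coll, mono60(), 2e4, seed = 9)
  b <- simulate_view("water_10cm", g, coll, mono60(), 2e4, seed = 9)
  expect_identical(a$total, b$total)  # bit-identical for a fixed seed
  c2 <- simulate_view("water_10cm", g, coll, mono60(), 4e4, seed = 10)
  r <- sum(c2$total) / sum(a$total)
  expect_lt(abs(r - 2), 3 * 2 * sqrt(1 / sum(a$total) + 1 / sum(c2$total)) * 2)
})

test_that("a single-view scan equals simulate_view and stacks validate", {
  g <- desk_geometry(n_views = 1L)
  coll <- slit_for_fov(4, g)
  sc <- simulate_scan("water_10cm", g, coll, mono60(), 2e4, seed = 11)
  vw <- simulate_view("water_10cm", g, coll, mono60(), 2e4, seed = 11,
                      view_index = 0L)
  expect_identical(sc$total[, , 1], vw$total)
  expect_identical(sc$primary[, , 1], vw$primary)
  expect_s3_class(sc, "projection_stack")
  expect_equal(n_views(sc), 1L)
})

test_that("rotationally symmetric phantoms give view-invariant totals", {
  g <- desk_geometry(n_views = 8L)
  coll <- slit_for_fov(4, g)
  sc <- simulate_scan("water_10cm", g, coll, mono60(), 5e4, seed = 12,
                      detector = "ideal")
  per_view <- apply(sc$total, 3, sum)
  expect_lt(max(abs(per_view - mean(per_view))) / sqrt(mean(per_view)), 4)
})

test_that("primary channel is slit-invariant inside the shared band", {
  g <- desk_geometry()
  sp <- mono60()
  c1 <- slit_for_fov(4, g)
  c2 <- slit_for_fov(13, g)
  ppp <- 400
  v1 <- simulate_view("water_10cm", g, c1, sp, budget_for(g, c1, ppp),
                      seed = 13, detector = "ideal")
  v2 <- simulate_view("water_10cm", g, c2, sp, budget_for(g, c2, ppp),
                      seed = 14, detector = "ideal")
  rows <- (c1$illuminated_rows[1] + 3):(c1$illuminated_rows[2] - 2)
  p1 <- v1$primary[rows, ]
  p2 <- v2$primary[rows, ]
  z <- (sum(p1) - sum(p2)) / sqrt(sum(p1) + sum(p2))
  expect_lt(abs(z), 4)
})

test_that("the detector slab lowers efficiency and labels its interactions", {
  g <- desk_geometry()
  coll <- slit_for_fov(4, g)
  vi <- simulate_view("water_10cm", g, coll, mono60(), 5e4, seed = 15,
                      detector = "ideal")
  vs <- simulate_view("water_10cm", g, coll, mono60(), 5e4, seed = 15,
                      detector = "scintillator", record_photons = TRUE)
  expect_lt(sum(vs$total), sum(vi$total))
  expect_gt(sum(vs$records$n_compton_detector +
                  vs$records$n_rayleigh_detector), 0)
})
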