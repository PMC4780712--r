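test_that("the two-point fit reproduces its knots and the printed ROI model", {
  # flat model from equal observations
  m0 <- fit_log_model(c(14, 42), list(5, 5))
  expect_equal(m0$a[1], 0)
  expect_equal(m0$b[1], 5)
  # closed-form two-point solution on the reported ROI means
  m <- fit_log_model(c(14, 42), list(7095, 8167))
  expect_equal(m$a[1], (8167 - 7095) / log(3), tolerance = 1e-12)
  expect_equal(m$a[1], 975.8, tolerance = 1e-4)
  expect_equal(m$b[1], 7095 - m$a[1] * log(14), tolerance = 1e-9)
  expect_equal(m$b[1], 4519.6, tolerance = 1e-4)
  # extrapolation to a narrow slit
  expect_equal(extrapolate_projection(m, 0.5)[1], 3843.4, tolerance = 1e-4)
  # knot reproduction to round-off
  expect_equal(extrapolate_projection(m, 14)[1], 7095, tolerance = 1e-10)
  expect_equal(extrapolate_projection(m, 42)[1], 8167, tolerance = 1e-10)
})

test_that("two-point exactness holds per pixel on random stacks", {
  set.seed(101)
  for (rep in 1:5) {
    y1 <- array(runif(24 * 30, 10, 100), c(24, 30, 1))
    y2 <- y1 + array(runif(24 * 30, 0.1, 50), c(24, 30, 1))
    m <- fit_log_model(c(14, 42), list(y1, y2))
    expect_lt(max(abs(extrapolate_projection(m, 14) - y1)), 1e-9)
    expect_lt(max(abs(extrapolate_projection(m, 42) - y2)), 1e-9)
    # monotone in the target wherever the slope is positive
    lo <- extrapolate_projection(m, 5)
    hi <- extrapolate_projection(m, 50)
    expect_true(all((hi - lo)[m$a > 0] > 0))
  }
})

test_that("non-positive slopes fall back to the flat model", {
  y1 <- array(c(10, 20), c(2, 1, 1))
  y2 <- array(c(8, 25), c(2, 1, 1))   # first pixel decreases
  m <- fit_log_model(c(14, 42), list(y1, y2))
  expect_true(m$fallback_mask[1, 1, 1])
  expect_false(m$fallback_mask[2, 1, 1])
  expect_equal(m$a[1, 1, 1], 0)
  expect_equal(m$b[1, 1, 1], 9)
  m2 <- fit_log_model(c(14, 42), list(y1, y2), nonneg_slope = FALSE)
  expect_lt(m2$a[1, 1, 1], 0)
})

test_that("multi-observation fits match a brute-force grid search", {
  set.seed(7)
  x <- c(0.5, 1, 2, 5, 10, 20, 45)
  y <- 40 + 9 * log(x) + rnorm(7, 0, 4)
  m <- fit_log_model(x, as.list(y), nonneg_slope = FALSE)
  fd <- fit_diagnostics(x, y)
  # grid-search oracle around the analytic optimum
  avals <- seq(0, 20, by = 0.02)
  bvals <- seq(20, 60, by = 0.05)
  sse <- outer(avals, bvals, function(a, b) {
    vapply(seq_along(a), function(i)
      sum((y - a[i] * log(x) - b[i])^2), numeric(1))
  })
  best <- arrayInd(which.min(sse), dim(sse))
  expect_equal(m$a[1], avals[best[1]], tolerance = 0.03)
  expect_equal(m$b[1], bvals[best[1]], tolerance = 0.06)
  expect_equal(fd$a, m$a[1], tolerance = 1e-9)
  expect_equal(fd$r2, m$r2[1], tolerance = 1e-9)
  expect_true(fd$r2 <= 1 && fd$r2 > 0.5)
})

test_that("fit and extrapolation preconditions are enforced", {
  expect_error(fit_log_model(c(14, 14), list(1, 2)), "distinct")
  expect_error(fit_log_model(c(-1, 42), list(1, 2)), "positive")
  m <- fit_log_model(c(14, 42), list(7095, 8167))
  expect_error(extrapolate_projection(m, 0), "positive slit")
  expect_error(extrapolate_projection(m, -3), "positive slit")
  g1 <- desk_geometry()
  g2 <- downsample_geometry(build_default_geometry(), 2L)
  s1 <- project_primary("water_10cm", g1, slit_for_fov(4, g1), mono60())
  s2 <- project_primary("water_10cm", g2, slit_for_fov(13, g2), mono60())
  expect_error(fit_log_model(c(14, 42), list(s1, s2)), "geometry")
})

test_that("the smoothing kernel is the truncated normalized Gaussian", {
  k <- gaussian_kernel(11, 5)
  expect_equal(dim(k), c(11L, 11L))
  expect_equal(sum(k), 1, tolerance = 1e-12)
  # direct evaluation oracle
  x <- -5:5
  ref <- exp(-outer(x^2, x^2, "+") / 50)
  ref <- ref / sum(ref)
  expect_equal(k, ref)
  expect_error(gaussian_kernel(10, 5), "odd")
  expect_error(gaussian_kernel(11, 0), "sigma")
})

test_that("scatter estimation preserves DC, reproduces impulses, clamps", {
  raw <- array(5, c(31, 31, 1))
  extr <- array(0, c(31, 31, 1))
  est <- estimate_scatter(raw, extr)
  expect_equal(est$scatter, raw, tolerance = 1e-12)  # constant residual kept
  est0 <- estimate_scatter(raw, raw)
  expect_true(all(est0$scatter == 0))                # zero residual
  imp <- array(0, c(31, 31, 1))
  imp[16, 16, 1] <- 1
  esti <- estimate_scatter(imp, extr)
  expect_equal(esti$scatter[11:21, 11:21, 1], gaussian_kernel(11, 5),
               tolerance = 1e-12)                    # kernel image
  # negative residuals are clamped at zero
  estn <- estimate_scatter(extr, raw)
  expect_true(all(estn$scatter == 0))
})

test_that("correction subtracts the estimate and respects the floor", {
  g <- desk_geometry()
  st <- project_primary("water_10cm", g, slit_for_fov(4, g), mono60(),
                        i0 = 100)
  zero <- list(scatter = array(0, dim(st$total)))
  class(zero) <- "scatter_estimate"
  same <- correct_projection(st, zero, floor = 0)
  expect_equal(same$total, st$total)
  big <- list(scatter = array(1e6, dim(st$total)))
  class(big) <- "scatter_estimate"
  floored <- correct_projection(st, big, floor = 1)
  expect_true(all(floored$total == 1))
})

test_that("oracle recovery: log-response fixtures extrapolate to primary", {
  # noiseless fixture whose scatter follows g(s) = log(1 + s/s0) with tiny
  # s0, the estimator's favorable regime; at the target slit the true
  # scatter is below 1% of primary and recovery is within 2% per pixel
  g <- desk_geometry()
  sp <- mono60()
  coll4 <- slit_for_fov(4, g)
  coll13 <- slit_for_fov(13, g)
  st4 <- project_primary("mc_10cm_five_tissue", g, coll4, sp, i0 = 1000)
  st13 <- project_primary("mc_10cm_five_tissue", g, coll13, sp, i0 = 1000)
  fld <- analytic_scatter_field(amplitude = 0.0006, s0_mm = 0.05)
  t4 <- add_scatter_and_noise(st4, fld, 14)
  t13 <- add_scatter_and_noise(st13, fld, 42)
  m <- fit_log_model(c(14, 42), list(t4, t13))
  target <- 0.5
  true_sc <- scatter_slit_response(fld, target) * 0.0006 * 1000
  prim_band <- st4$primary[st4$primary > 0]
  expect_lt(true_sc, 0.01 * stats::median(prim_band))
  yhat <- extrapolate_projection(m, target)
  ok <- m$valid_mask & !m$fallback_mask & st4$primary > 0.2 * max(st4$primary)
  rel <- abs(yhat[ok] - st4$primary[ok]) / st4$primary[ok]
  expect_lt(max(rel), 0.02)
})

test_that("correction reduces the per-view error against the true primary", {
  g <- desk_geometry()
  sp <- mono60()
  coll4 <- slit_for_fov(4, g)
  coll13 <- slit_for_fov(13, g)
  st4 <- project_primary("mc_10cm_five_tissue", g, coll4, sp, i0 = 2000)
  st13 <- project_primary("mc_10cm_five_tissue", g, coll13, sp, i0 = 2000)
  fld <- analytic_scatter_field(amplitude = 0.15, s0_mm = 0.5)
  t4 <- add_scatter_and_noise(st4, fld, 14, poisson = TRUE, seed = 5)
  t13 <- add_scatter_and_noise(st13, fld, 42, poisson = TRUE, seed = 6)
  flat <- array(2000, dim(st4$total)[1:2])
  res <- correct_fov_scan(t4, t13, 14, 42, flat, flat, target_slit_mm = 0.5)
  ok <- res$model$valid_mask[, , 1]
  rmse <- function(a) sqrt(mean((a[, , 1][ok] - st4$primary[, , 1][ok])^2))
  expect_lt(rmse(res$corrected$total), rmse(t4$total))
})

test_that("noise ordering: extrapolated > corrected > raw on Poisson runs", {
  g <- desk_geometry()
  sp <- mono60()
  coll4 <- slit_for_fov(4, g)
  coll13 <- slit_for_fov(13, g)
  st4 <- project_primary("water_10cm", g, coll4, sp, i0 = 2000)
  st13 <- project_primary("water_10cm", g, coll13, sp, i0 = 2000)
  fld <- analytic_scatter_field(amplitude = 0.15, s0_mm = 0.5)
  sds <- matrix(0, 6, 3)
  rows <- 45:51
  cols <- 55:65
  for (s in 1:6) {
    t4 <- add_scatter_and_noise(st4, fld, 14, poisson = TRUE, seed = 100 + s)
    t13 <- add_scatter_and_noise(st13, fld, 42, poisson = TRUE, seed = 200 + s)
    flat <- array(2000, dim(st4$total)[1:2])
    res <- correct_fov_scan(t4, t13, 14, 42, flat, flat)
    extr <- res$extrapolated[, , 1] * 2000
    sds[s, ] <- c(sd(extr[rows, cols]),
                  sd(res$corrected$total[rows, cols, 1]),
                  sd(t4$total[rows, cols, 1]))
  }
  m <- colMeans(sds)
  expect_gt(m[1], m[2])  # extrapolated noisier than corrected
  expect_gt(m[2], m[3])  # corrected slightly noisier than raw
})

test_that("tidy and glance summarize the fit model", {
  m <- fit_log_model(c(14, 42),
                     list(array(1:6, c(2, 3, 1)), array(7:12, c(2, 3, 1))))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  gl <- glance(m)
  expect_equal(gl$n_pixels, 6L)
  expect_equal(gl$n_obs, 2L)
})
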