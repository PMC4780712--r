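# ROI statistics, SPR, CNR, regression diagnostics, cupping index and
# line profiles.

#' Region-of-interest specification
#'
#' @param domain `"projection"` (pixel coordinates) or `"image"` (world
#'   coordinates in cm, requires the image to carry a pixel size).
#' @param shape `"square"` (side in pixels) or `"circle"` (diameter in
#'   cm).
#' @param center ROI center: `(row, col)` pixels for the projection
#'   domain (NULL = image center), `(x, y)` cm for the image domain.
#' @param side_px Square side in pixels (default 11).
#' @param diameter_cm Circle diameter in cm (default 0.9).
#' @return A `roi_spec`.
#' @export
roi_spec <- function(domain = c("projection", "image"),
                     shape = c("square", "circle"), center = NULL,
                     side_px = 11L, diameter_cm = 0.9) {
  domain <- match.arg(domain)
  shape <- match.arg(shape)
  if (shape == "square" && (side_px < 1 || side_px %% 2 == 0)) {
    stop("side_px must be a positive odd integer")
  }
  if (shape == "circle" && diameter_cm <= 0) stop("diameter_cm must be positive")
  structure(list(domain = domain, shape = shape, center = center,
                 side_px = as.integer(side_px), diameter_cm = diameter_cm),
            class = "roi_spec")
}

# logical mask of a ROI on a matrix; errors when the ROI leaves the image
.roi_mask <- function(image, roi) {
  nr <- nrow(image); nc <- ncol(image)
  if (roi$shape == "square") {
    ctr <- roi$center
    if (is.null(ctr)) ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    h <- (roi$side_px - 1) / 2
    rows <- round(ctr[1] - h):round(ctr[1] + h)
    cols <- round(ctr[2] - h):round(ctr[2] + h)
    if (min(rows) < 1 || max(rows) > nr || min(cols) < 1 || max(cols) > nc) {
      stop("ROI extends outside the image")
    }
    m <- matrix(FALSE, nr, nc)
    m[rows, cols] <- TRUE
    return(m)
  }
  pix <- attr(image, "pixel_mm")
  if (is.null(pix)) stop("circular ROIs need an image with a pixel size")
  pix <- pix / 10  # cm
  ctr0 <- attr(image, "center_cm")
  if (is.null(ctr0)) ctr0 <- c(0, 0)
  ctr <- if (is.null(roi$center)) c(0, 0) else roi$center
  x <- (seq_len(nr) - 0.5 - nr / 2) * pix + ctr0[1]
  y <- (seq_len(nc) - 0.5 - nc / 2) * pix + ctr0[2]
  r <- roi$diameter_cm / 2
  if (ctr[1] - r < min(x) - pix / 2 || ctr[1] + r > max(x) + pix / 2 ||
      ctr[2] - r < min(y) - pix / 2 || ctr[2] + r > max(y) + pix / 2) {
    stop("ROI extends outside the image")
  }
  outer(x - ctr[1], y - ctr[2], function(a, b) a^2 + b^2) <= r^2
}

#' Mean and standard deviation within a region of interest
#'
#' Arithmetic mean and sample (n-1) standard deviation of the pixels
#' inside the ROI.
#'
#' @param image A matrix (projection view or volume slice from
#'   [volume_slice()]).
#' @param roi A [roi_spec()].
#' @param mask Optional additional logical mask intersected with the ROI.
#' @return A tibble with `mean`, `sd` and `n`.
#' @export
roi_stats <- function(image, roi = roi_spec(), mask = NULL) {
  m <- .roi_mask(image, roi)
  if (!is.null(mask)) m <- m & mask
  vals <- image[m]
  if (!length(vals)) stop("empty ROI")
  tibble::tibble(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
                 n = length(vals))
}

#' Scatter-to-primary ratio within a region of interest
#'
#' SPR is the ratio of scattered to primary radiation intensities, here
#' the ROI means of the scatter and primary channels of one view.
#'
#' @param stack A `projection_stack` with primary and scatter channels.
#' @param roi A [roi_spec()] (default: central 11 x 11 square).
#' @param view 1-based view index (default: the first view).
#' @return A tibble with channel means and standard deviations, `spr` and
#'   its Monte Carlo standard error.
#' @export
compute_spr <- function(stack, roi = roi_spec(), view = 1L) {
  if (is.null(stack$primary) || is.null(stack$scatter)) {
    stop("stack needs primary and scatter channels")
  }
  pri <- stack$primary[, , view]
  sca <- stack$scatter[, , view]
  tot <- stack$total[, , view]
  m <- .roi_mask(tot, roi)
  mp <- mean(pri[m]); ms <- mean(sca[m]); mt <- mean(tot[m])
  if (mp <= 0) stop("primary ROI mean is zero: SPR undefined")
  sp <- sum(pri[m]); ss <- sum(sca[m])
  tibble::tibble(
    mean_total = mt, sd_total = sd(tot[m]),
    mean_primary = mp, sd_primary = sd(pri[m]),
    mean_scatter = ms, sd_scatter = sd(sca[m]),
    spr = ms / mp,
    se_spr = if (ss > 0) (ms / mp) * sqrt(1 / ss + 1 / sp) else 1 / sp)
}

#' Natural-log regression diagnostics for ROI tallies
#'
#' Least-squares fit of `y = a * ln(x) + b` with the coefficient of
#' determination, as used to summarize ROI intensity versus collimating
#' slit. Constant `y` is reported as `a = 0`, `r2 = 0` with the
#' `degenerate` flag set.
#'
#' @param x Slit sizes (> 0, distinct, at least 3).
#' @param y ROI means at those slit sizes.
#' @return A tibble with `a`, `b`, `r2`, `degenerate`.
#' @export
fit_diagnostics <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x)) {
    stop("need at least 3 matching observations")
  }
  if (any(x <= 0)) stop("x must be positive")
  if (length(unique(x)) < 2) stop("degenerate x: at least two distinct values")
  if (sd(y) == 0) {
    return(tibble::tibble(a = 0, b = y[1], r2 = 0, degenerate = TRUE))
  }
  fit <- lm(y ~ log(x))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble::tibble(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
                 r2 = 1 - ss_res / ss_tot, degenerate = FALSE)
}

# world-coordinate centers of the insert ROIs (cores where present)
.insert_centers <- function(phantom) {
  ins <- phantom$inserts
  if (nrow(ins) == 0) stop("phantom has no inserts")
  mat <- ifelse(is.na(ins$core_material), ins$material, ins$core_material)
  tibble::tibble(material = mat, x_cm = ins$x_cm, y_cm = ins$y_cm,
                 diameter_cm = ifelse(is.na(ins$core_material),
                                      ins$diameter_cm, ins$core_diameter_cm))
}

# water background ROI center: on the insert ring, at an angle clear of
# every insert
.water_roi_center <- function(phantom, roi_r_cm) {
  ins <- phantom$inserts
  R <- 0.6 * phantom$body_diameter_cm / 2
  for (ang in seq(45, 360, by = 5) * pi / 180) {
    p <- R * c(cos(ang), sin(ang))
    ok <- TRUE
    if (nrow(ins) > 0) {
      d <- sqrt((ins$x_cm - p[1])^2 + (ins$y_cm - p[2])^2)
      ok <- all(d >= ins$diameter_cm / 2 + roi_r_cm + 0.1)
    }
    if (ok) return(p)
  }
  stop("no insert-free background location found")
}

# pooled water statistics over the insert-free part of the ring annulus
.water_annulus_stats <- function(phantom, sl, clear_cm) {
  pix <- attr(sl, "pixel_mm") / 10
  nr <- nrow(sl); nc <- ncol(sl)
  x <- (seq_len(nr) - 0.5 - nr / 2) * pix + attr(sl, "center_cm")[1]
  y <- (seq_len(nc) - 0.5 - nc / 2) * pix + attr(sl, "center_cm")[2]
  ring <- 0.6 * phantom$body_diameter_cm / 2
  rr <- sqrt(outer(x^2, y^2, "+"))
  keep <- abs(rr - ring) <= clear_cm
  ins <- phantom$inserts
  for (i in seq_len(nrow(ins))) {
    d <- sqrt(outer((x - ins$x_cm[i])^2, (y - ins$y_cm[i])^2, "+"))
    keep <- keep & (d > ins$diameter_cm[i] / 2 + clear_cm + 0.1)
  }
  vals <- sl[keep]
  if (length(vals) < 8) stop("annulus background has too few voxels")
  tibble::tibble(mean = mean(vals), sd = sd(vals), n = length(vals))
}

#' Contrast-to-noise ratio of rod inserts
#'
#' For each insert, `CNR = |CT# - CT#_water| / SD_water`, where `CT#` is
#' the mean CT number in a circular ROI inside the insert (its core for
#' cored inserts), and the water mean and standard deviation come from an
#' insert-free background ROI at the same ring radius. A CNR of 1.0 means
#' the insert contrast equals the background noise.
#'
#' @param volume An HU-calibrated `recon_volume`.
#' @param phantom The `phantom_spec` that was scanned.
#' @param insert_roi_cm ROI diameter in cm (default 0.9).
#' @param slice 1-based slice (default central).
#' @param background `"roi"` (a single circular water ROI at an
#'   insert-free position on the ring, mirroring the published protocol)
#'   or `"annulus"` (all insert-free water voxels at the ring radius;
#'   a larger sample that stabilizes the SD estimate in low-statistics
#'   reconstructions).
#' @return A tibble of class `cnr_report`: one row per insert with
#'   `material`, `ct_mean`, `ct_water_mean`, `ct_water_sd`, `cnr`; the
#'   mean CNR across inserts is in `attr(, "mean_cnr")`.
#' @export
compute_cnr <- function(volume, phantom, insert_roi_cm = 0.9, slice = NULL,
                        background = c("roi", "annulus")) {
  if (volume$units != "HU") stop("volume must be HU-calibrated first")
  background <- match.arg(background)
  phantom <- build_phantom(phantom)
  sl <- volume_slice(volume, slice)
  if (background == "roi") {
    wc <- .water_roi_center(phantom, insert_roi_cm / 2)
    wroi <- roi_spec("image", "circle", center = wc,
                     diameter_cm = insert_roi_cm)
    ws <- roi_stats(sl, wroi)
  } else {
    ws <- .water_annulus_stats(phantom, sl, insert_roi_cm / 2)
  }
  if (ws$sd == 0) stop("background standard deviation is zero: CNR undefined")
  ctr <- .insert_centers(phantom)
  rows <- lapply(seq_len(nrow(ctr)), function(i) {
    d <- min(insert_roi_cm, 0.9 * ctr$diameter_cm[i])
    iroi <- roi_spec("image", "circle", center = c(ctr$x_cm[i], ctr$y_cm[i]),
                     diameter_cm = d)
    is <- roi_stats(sl, iroi)
    tibble::tibble(material = ctr$material[i], ct_mean = is$mean,
                   ct_sd = is$sd, ct_water_mean = ws$mean,
                   ct_water_sd = ws$sd,
                   cnr = abs(is$mean - ws$mean) / ws$sd)
  })
  rep <- dplyr::bind_rows(rows)
  attr(rep, "mean_cnr") <- mean(rep$cnr)
  class(rep) <- c("cnr_report", class(rep))
  rep
}

#' Cupping index of a cylindrical body
#'
#' Quantifies the central depression of reconstructed values typical of
#' scatter contamination: mean value in an edge band (annulus at 70-90%
#' of the body radius) minus the mean in a central ROI (20% of the body
#' diameter), on the central slice, excluding voxels inside inserts (with
#' a 3 mm margin). About zero for an artifact-free water cylinder,
#' positive under cupping.
#'
#' @param volume A `recon_volume` (any units; the index is in the same
#'   units).
#' @param phantom The scanned `phantom_spec`.
#' @param slice 1-based slice (default central).
#' @return The cupping index (scalar).
#' @export
cupping_index <- function(volume, phantom, slice = NULL) {
  phantom <- build_phantom(phantom)
  sl <- volume_slice(volume, slice)
  pix <- attr(sl, "pixel_mm") / 10
  nr <- nrow(sl); nc <- ncol(sl)
  x <- (seq_len(nr) - 0.5 - nr / 2) * pix + attr(sl, "center_cm")[1]
  y <- (seq_len(nc) - 0.5 - nc / 2) * pix + attr(sl, "center_cm")[2]
  rr <- sqrt(outer(x^2, y^2, "+"))
  R <- phantom$body_diameter_cm / 2
  keep <- matrix(TRUE, nr, nc)
  ins <- phantom$inserts
  if (nrow(ins) > 0) {
    for (i in seq_len(nrow(ins))) {
      di <- outer((x - ins$x_cm[i])^2, (y - ins$y_cm[i])^2, "+")
      keep <- keep & (sqrt(di) > ins$diameter_cm[i] / 2 + 0.3)
    }
  }
  # central disc, grown until it contains insert-free pixels (a central
  # rod insert otherwise empties it)
  ctr_r <- 0.3 * R
  repeat {
    ctr <- rr <= ctr_r & keep
    if (any(ctr) || ctr_r > 0.55 * R) break
    ctr_r <- ctr_r + 0.05 * R
  }
  if (!any(ctr)) stop("no insert-free central pixels for the cupping index")
  edge <- rr >= 0.7 * R & rr <= 0.9 * R & keep
  mean(sl[edge]) - mean(sl[ctr])
}

#' Sample a line profile through an image
#'
#' Bilinearly interpolated samples along the segment between two points
#' given in (row, col) pixel coordinates (fractional coordinates
#' allowed).
#'
#' @param image A matrix.
#' @param from,to Segment end points, `(row, col)`.
#' @param n Number of samples (default: 2 per pixel of segment length).
#' @return A tibble with the distance along the segment `s_px` and the
#'   interpolated `value`.
#' @export
line_profile <- function(image, from, to, n = NULL) {
  len <- sqrt(sum((to - from)^2))
  if (is.null(n)) n <- max(2L, ceiling(2 * len))
  t <- seq(0, 1, length.out = n)
  r <- from[1] + t * (to[1] - from[1])
  c_ <- from[2] + t * (to[2] - from[2])
  if (min(r) < 1 || max(r) > nrow(image) || min(c_) < 1 || max(c_) > ncol(image)) {
    stop("segment leaves the image")
  }
  r0 <- pmin(floor(r), nrow(image) - 1L); c0 <- pmin(floor(c_), ncol(image) - 1L)
  fr <- r - r0; fc <- c_ - c0
  idx <- function(i, j) image[cbind(i, j)]
  val <- (1 - fr) * ((1 - fc) * idx(r0, c0) + fc * idx(r0, c0 + 1)) +
    fr * ((1 - fc) * idx(r0 + 1, c0) + fc * idx(r0 + 1, c0 + 1))
  tibble::tibble(s_px = t * len, value = val)
}
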