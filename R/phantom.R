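#' Cylindrical phantom specification
#'
#' A water-filled cylinder (axis along z, centered on the isocenter) with
#' optional tissue-equivalent rod inserts. Bone-equivalent inserts may
#' carry a denser core inside a soft-tissue-equivalent sheath.
#'
#' @param body_diameter_cm Body cylinder diameter (cm).
#' @param body_height_cm Body cylinder height (cm).
#' @param body_material Body material name (default water).
#' @param inserts A data frame with columns `x_cm`, `y_cm`,
#'   `diameter_cm`, `height_cm`, `material` and optionally
#'   `core_material`, `core_diameter_cm` (NA where absent).
#' @param name Optional label for the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_diameter_cm, body_height_cm = 10,
                         body_material = "water", inserts = NULL,
                         name = "custom") {
  if (body_diameter_cm <= 0 || body_height_cm <= 0) {
    stop("body dimensions must be positive")
  }
  known <- list_materials()
  if (!body_material %in% known) stop("unknown body material: ", body_material)
  if (is.null(inserts)) {
    inserts <- tibble::tibble(x_cm = numeric(), y_cm = numeric(),
                              diameter_cm = numeric(), height_cm = numeric(),
                              material = character(),
                              core_material = character(),
                              core_diameter_cm = numeric())
  }
  inserts <- tibble::as_tibble(inserts)
  if (!"core_material" %in% names(inserts)) inserts$core_material <- NA_character_
  if (!"core_diameter_cm" %in% names(inserts)) inserts$core_diameter_cm <- NA_real_
  if (nrow(inserts) > 0) {
    if (any(inserts$diameter_cm <= 0)) stop("insert diameters must be positive")
    bad <- setdiff(unique(c(inserts$material,
                            inserts$core_material[!is.na(inserts$core_material)])),
                   known)
    if (length(bad)) stop("unknown insert material: ", paste(bad, collapse = ", "))
    R <- body_diameter_cm / 2
    r_out <- sqrt(inserts$x_cm^2 + inserts$y_cm^2) + inserts$diameter_cm / 2
    if (any(r_out > R + 1e-9)) {
      i <- which(r_out > R + 1e-9)[1]
      stop(sprintf("insert %d (%s) extends outside the body cylinder",
                   i, inserts$material[i]))
    }
    if (any(inserts$height_cm > body_height_cm + 1e-9)) {
      stop("insert height exceeds the body height")
    }
    if (nrow(inserts) > 1) {
      for (i in seq_len(nrow(inserts) - 1)) {
        for (j in seq(i + 1, nrow(inserts))) {
          d <- sqrt((inserts$x_cm[i] - inserts$x_cm[j])^2 +
                      (inserts$y_cm[i] - inserts$y_cm[j])^2)
          if (d < (inserts$diameter_cm[i] + inserts$diameter_cm[j]) / 2 - 1e-9) {
            stop(sprintf("inserts %d (%s) and %d (%s) overlap", i,
                         inserts$material[i], j, inserts$material[j]))
          }
        }
      }
    }
    has_core <- !is.na(inserts$core_material)
    if (any(has_core & (is.na(inserts$core_diameter_cm) |
                          inserts$core_diameter_cm <= 0))) {
      stop("cored inserts need a positive core_diameter_cm")
    }
    if (any(has_core & inserts$core_diameter_cm >= inserts$diameter_cm)) {
      stop("core diameter must be smaller than the insert diameter")
    }
  }
  p <- list(body_diameter_cm = body_diameter_cm,
            body_height_cm = body_height_cm, body_material = body_material,
            inserts = inserts, name = name)
  class(p) <- "phantom_spec"
  p
}

# standard five-rod layout: four inserts on a ring at 60% of the body
# radius (90 degrees apart, starting at +x) plus one central rod
.ring_layout <- function(body_d, materials, diameter_cm = 3,
                         height_cm = 10) {
  n <- length(materials)
  stopifnot(n >= 1)
  ring <- 0.6 * body_d / 2
  if (n == 1) {
    x <- 0; y <- 0
  } else {
    k <- seq_len(n - 1) - 1
    ang <- k * 2 * pi / (n - 1)
    x <- c(round(ring * cos(ang), 10), 0)
    y <- c(round(ring * sin(ang), 10), 0)
  }
  tibble::tibble(x_cm = x, y_cm = y, diameter_cm = diameter_cm,
                 height_cm = height_cm, material = materials)
}

#' Names of the packaged phantom presets
#' @return Character vector of preset names accepted by [build_phantom()].
#' @export
phantom_presets <- function() {
  mc <- outer(c(10, 15, 20),
              c("muscle", "dense_bone_800", "adipose", "five_tissue"),
              function(d, l) sprintf("mc_%dcm_%s", d, l))
  c(as.vector(mc), "exp_10cm_setting1", "exp_10cm_setting2", "water_10cm",
    "water_15cm", "water_20cm", "air")
}

#' Build a phantom, from a preset name or an explicit specification
#'
#' Presets cover the twelve simulation layouts (10/15/20-cm water
#' cylinders with a single 3-cm rod of muscle, 800 mg/cc dense bone or
#' adipose, or five rods of different tissues), the two experimental
#' five-insert layouts (bone inserts with a 1-cm core in a
#' soft-tissue-equivalent sheath), water-only calibration cylinders and an
#' air cylinder. Insert positions follow a ring at 60% of the body radius
#' plus one central rod.
#'
#' @param preset A preset name from [phantom_presets()], or a
#'   `phantom_spec` (returned unchanged after validation).
#' @return A `phantom_spec`.
#' @examples
#' build_phantom("mc_10cm_five_tissue")
#' @export
build_phantom <- function(preset) {
  if (inherits(preset, "phantom_spec")) return(preset)
  if (!is.character(preset) || length(preset) != 1) {
    stop("preset must be a name or a phantom_spec")
  }
  if (preset == "air") {
    return(phantom_spec(20, 10, body_material = "air", name = "air"))
  }
  if (grepl("^water_(10|15|20)cm$", preset)) {
    d <- as.numeric(sub("^water_(\\d+)cm$", "\\1", preset))
    return(phantom_spec(d, 10, name = preset))
  }
  m <- regmatches(preset, regexec("^mc_(10|15|20)cm_(.+)$", preset))[[1]]
  if (length(m) == 3) {
    d <- as.numeric(m[2]); layout <- m[3]
    ins <- switch(layout,
      muscle = .ring_layout(d, "muscle"),
      dense_bone_800 = .ring_layout(d, "dense_bone_800"),
      adipose = .ring_layout(d, "adipose"),
      five_tissue = .ring_layout(d, c("muscle", "dense_bone_800", "adipose",
                                      "trabecular_bone", "lung_inhale")),
      stop("unknown phantom preset: ", preset))
    return(phantom_spec(d, 10, inserts = ins, name = preset))
  }
  if (preset == "exp_10cm_setting1") {
    ins <- .ring_layout(10, c("adipose", "breast", "muscle", "liver",
                              "lung_inhale"), height_cm = 5)
    return(phantom_spec(10, 10, inserts = ins, name = preset))
  }
  if (preset == "exp_10cm_setting2") {
    ins <- .ring_layout(10, c("dense_bone_800", "dense_bone_1250",
                              "dense_bone_1750", "trabecular_bone",
                              "lung_exhale"), height_cm = 5)
    bone <- grepl("bone", ins$material)
    ins$core_material <- ifelse(bone, ins$material, NA_character_)
    ins$core_diameter_cm <- ifelse(bone, 1, NA_real_)
    ins$material[bone] <- "soft_tissue"
    return(phantom_spec(10, 10, inserts = ins, name = preset))
  }
  stop("unknown phantom preset: ", preset)
}

# flatten a phantom into the cylinder matrix used by the compiled code:
# columns cx, cy, r, zmin, zmax, mat (0-based), depth, parent (0-based, -1)
phantom_cylinders <- function(phantom, materials = NULL) {
  ins <- phantom$inserts
  mats <- unique(c(phantom$body_material, ins$material,
                   ins$core_material[!is.na(ins$core_material)]))
  if (!is.null(materials)) mats <- materials
  hz <- phantom$body_height_cm / 2
  rows <- list(c(0, 0, phantom$body_diameter_cm / 2, -hz, hz,
                 match(phantom$body_material, mats) - 1, 0, -1))
  if (nrow(ins) > 0) {
    for (i in seq_len(nrow(ins))) {
      ihz <- ins$height_cm[i] / 2
      rows[[length(rows) + 1]] <-
        c(ins$x_cm[i], ins$y_cm[i], ins$diameter_cm[i] / 2, -ihz, ihz,
          match(ins$material[i], mats) - 1, 1, 0)
      if (!is.na(ins$core_material[i])) {
        parent <- length(rows) - 1
        rows[[length(rows) + 1]] <-
          c(ins$x_cm[i], ins$y_cm[i], ins$core_diameter_cm[i] / 2, -ihz, ihz,
            match(ins$core_material[i], mats) - 1, 2, parent)
      }
    }
  }
  list(cyl = do.call(rbind, rows), materials = mats)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> '%s': %s cylinder %g cm diameter x %g cm, %d insert(s)\n",
              x$name, x$body_material, x$body_diameter_cm, x$body_height_cm,
              nrow(x$inserts)))
  if (nrow(x$inserts) > 0) print(x$inserts)
  invisible(x)
}
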