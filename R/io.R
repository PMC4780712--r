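# Readers/writers: MetaImage (MHA, single-file) for stacks and volumes,
# multi-page TIFF as alternate, JSON sidecars for metadata.

#' Write a numeric array as a MetaImage (.mha) file
#'
#' Single-file MetaImage: text header followed by the raw voxel block
#' (64-bit IEEE doubles, little-endian, fastest-varying dimension first).
#'
#' @param arr A 2- or 3-dimensional numeric array.
#' @param path Output path (conventionally `.mha`).
#' @param spacing Element spacing per dimension.
#' @param origin Offset per dimension.
#' @return `path`, invisibly.
#' @export
write_mha <- function(arr, path, spacing = NULL, origin = NULL) {
  dm <- dim(arr)
  if (is.null(dm)) dm <- length(arr)
  nd <- length(dm)
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (is.null(origin)) origin <- rep(0, nd)
  hdr <- c(
    "ObjectType = Image",
    sprintf("NDims = %d", nd),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %s", paste(dm, collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(spacing, scientific = FALSE),
                                         collapse = " ")),
    sprintf("Offset = %s", paste(format(origin, scientific = FALSE),
                                 collapse = " ")),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage (.mha) file written by [write_mha()]
#'
#' Supports uncompressed single-file MetaImages with MET_DOUBLE or
#' MET_FLOAT elements.
#'
#' @param path Path to the `.mha` file.
#' @return A numeric array with attributes `spacing` and `origin`.
#' @export
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL")) {
    stop("only single-file (LOCAL) MetaImages are supported")
  }
  dm <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("unsupported element type: ", type))
  vals <- readBin(con, "numeric", n = prod(dm), size = size,
                  endian = "little")
  arr <- array(vals, dm)
  attr(arr, "spacing") <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  attr(arr, "origin") <- as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  arr
}

#' Persist a projection stack with a JSON sidecar
#'
#' Writes one MHA file per channel (`<prefix>_total.mha`, ...) plus
#' `<prefix>.json` carrying geometry, collimation and acquisition
#' metadata.
#'
#' @param stack A `projection_stack`.
#' @param prefix Output path prefix.
#' @param format `"mha"` or `"tiff"` (multi-page, requires the `tiff`
#'   package).
#' @return The sidecar path, invisibly.
#' @export
write_stack <- function(stack, prefix, format = c("mha", "tiff")) {
  format <- match.arg(format)
  g <- stack$geometry
  sp <- rep(g$det_pitch_mm, 2)
  chans <- c("total", "primary", "scatter")
  files <- list()
  for (ch in chans) {
    if (is.null(stack[[ch]])) next
    f <- sprintf("%s_%s.%s", prefix, ch, if (format == "mha") "mha" else "tif")
    if (format == "mha") {
      write_mha(stack[[ch]], f, spacing = c(sp, 1))
    } else {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the tiff package is needed for TIFF output")
      }
      a <- stack[[ch]]
      pages <- lapply(seq_len(dim(a)[3]), function(v) a[, , v] / max(a, 1))
      tiff::writeTIFF(pages, f, bits.per.sample = 32L, reduce = FALSE)
    }
    files[[ch]] <- basename(f)
  }
  side <- paste0(prefix, ".json")
  meta <- stack$meta
  meta$scatter_field <- NULL  # not serializable
  jsonlite::write_json(list(
    files = files, format = format,
    geometry = unclass(stack$geometry),
    collimation = unclass(stack$collimation),
    meta = meta), side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}

#' Read a projection stack written by [write_stack()]
#' @param prefix The path prefix used when writing.
#' @return A `projection_stack`.
#' @export
read_stack <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "mha")) stop("only MHA stacks can be read back")
  g <- side$geometry
  geometry <- scanner_geometry(g$sad, g$sdd, g$det_rows, g$det_cols,
                               g$det_pitch_mm, g$n_views, g$angles_deg,
                               g$collimator_distance)
  coll <- collimator_setting(
    if (identical(side$collimation$slit_mm, "open")) "open"
    else as.numeric(side$collimation$slit_mm), geometry)
  rd <- function(ch) {
    f <- file.path(dirname(prefix), side$files[[ch]])
    if (is.null(side$files[[ch]]) || !file.exists(f)) return(NULL)
    a <- read_mha(f)
    attributes(a) <- list(dim = dim(a))
    a
  }
  projection_stack(total = rd("total"), primary = rd("primary"),
                   scatter = rd("scatter"), geometry = geometry,
                   collimation = coll, meta = as.list(side$meta))
}

#' Persist a reconstruction volume as MHA with a JSON sidecar
#' @param volume A `recon_volume`.
#' @param prefix Output path prefix.
#' @return The sidecar path, invisibly.
#' @export
write_volume <- function(volume, prefix) {
  f <- paste0(prefix, ".mha")
  write_mha(volume$voxels, f, spacing = rep(volume$voxel_mm, 3),
            origin = volume$center_cm * 10)
  jsonlite::write_json(list(file = basename(f), units = volume$units,
                            voxel_mm = volume$voxel_mm,
                            center_cm = volume$center_cm,
                            mu_water = volume$mu_water),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(prefix, ".json"))
}
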