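#' Projection stack container
#'
#' Per-view detector images with separable channels. `total`, `primary`
#' and `scatter` are arrays of dimension rows x cols x views (photon
#' counts by default, energy-weighted signal optional); `total` must equal
#' `primary + scatter` element-wise when all three are present.
#'
#' @param total Total-channel array (rows x cols x views), or NULL to
#'   derive it as `primary + scatter`.
#' @param primary,scatter Optional channel arrays of matching dimension.
#' @param geometry The `scanner_geometry` used.
#' @param collimation The `collimator_setting` used.
#' @param meta Named list of acquisition metadata (phantom name, photons
#'   per view, seed, ...).
#' @return An object of class `projection_stack`.
#' @export
projection_stack <- function(total = NULL, primary = NULL, scatter = NULL,
                             geometry, collimation, meta = list()) {
  if (is.null(total)) {
    if (is.null(primary) || is.null(scatter)) {
      stop("need total, or both primary and scatter")
    }
    total <- primary + scatter
  }
  if (length(dim(total)) == 2) total <- array(total, c(dim(total), 1))
  dm <- dim(total)
  if (length(dm) != 3) stop("total must be a rows x cols x views array")
  if (dm[1] != geometry$det_rows || dm[2] != geometry$det_cols) {
    stop("array dimensions do not match the detector grid")
  }
  for (ch in list(primary, scatter)) {
    if (!is.null(ch) && !identical(dim(ch)[1:2], dm[1:2])) {
      stop("channel dimensions disagree")
    }
  }
  if (!is.null(primary) && !is.null(scatter)) {
    if (max(abs(total - (primary + scatter))) > 1e-6 * max(1, max(total))) {
      stop("total must equal primary + scatter")
    }
  }
  if (any(total < 0)) stop("negative intensities in total channel")
  s <- list(total = total, primary = primary, scatter = scatter,
            geometry = geometry, collimation = collimation, meta = meta)
  class(s) <- "projection_stack"
  s
}

#' Number of views in a projection stack
#' @param stack A `projection_stack`.
#' @return Integer view count.
#' @export
n_views <- function(stack) dim(stack$total)[3]

#' Extract a channel array from a projection stack
#' @param stack A `projection_stack` (plain arrays pass through).
#' @param channel `"total"`, `"primary"` or `"scatter"`.
#' @return A rows x cols x views array.
#' @export
stack_channel <- function(stack, channel = "total") {
  if (is.array(stack) || is.matrix(stack)) {
    a <- if (length(dim(stack)) == 2) array(stack, c(dim(stack), 1)) else stack
    return(a)
  }
  ch <- stack[[channel]]
  if (is.null(ch)) stop("stack has no '", channel, "' channel")
  ch
}

#' @export
print.projection_stack <- function(x, ...) {
  dm <- dim(x$total)
  chans <- c("total", if (!is.null(x$primary)) "primary",
             if (!is.null(x$scatter)) "scatter")
  cat(sprintf("<projection_stack> %d x %d pixels, %d view(s); channels: %s\n",
              dm[1], dm[2], dm[3], paste(chans, collapse = ", ")))
  if (!is.null(x$meta$phantom)) cat("  phantom:", x$meta$phantom, "\n")
  invisible(x)
}
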