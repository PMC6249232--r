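#' Quality-gate configuration
#'
#' Admission thresholds applied to a query or enrollment image before it may
#' take part in identification: a minimum width and height of 200 px, a
#' minimum of 5 keypoints inside the fin, and an optional sharpness floor
#' `sigma_s` (0 disables it). All thresholds are inclusive (`>=`).
#'
#' @param min_width_px minimum image width in pixels.
#' @param min_height_px minimum image height in pixels.
#' @param min_features minimum number of keypoints inside the fin mask.
#' @param sharpness_threshold minimum sharpness score `sigma_s` (>= 0).
#' @param sharpness_scope compute sharpness over the fin mask only
#'   (`"mask"`, default) or over the whole image (`"image"`).
#' @return An object of class `quality_config`.
#' @export
quality_config <- function(min_width_px = 200L, min_height_px = 200L,
                           min_features = 5L, sharpness_threshold = 0,
                           sharpness_scope = c("mask", "image")) {
  sharpness_scope <- match.arg(sharpness_scope)
  vals <- c(min_width_px, min_height_px, min_features, sharpness_threshold)
  if (any(vals < 0)) stop("quality thresholds must be >= 0", call. = FALSE)
  structure(list(min_width_px = as.integer(min_width_px),
                 min_height_px = as.integer(min_height_px),
                 min_features = as.integer(min_features),
                 sharpness_threshold = as.numeric(sharpness_threshold),
                 sharpness_scope = sharpness_scope),
            class = "quality_config")
}

# 3x3 4-neighbour Laplacian response of a matrix, reflect padding.
laplacian_response <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  up    <- g[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- g[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  left  <- g[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- g[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  up + down + left + right - 4 * g
}

#' Sharpness of a fin image
#'
#' The standard deviation of the image's response to the 3x3 Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]`, computed on the CIE-Lab lightness plane
#' rescaled to `[0, 255]` and evaluated over the fin foreground (or the whole
#' frame, per `scope`). Blur flattens second derivatives, so low values mean
#' a blurred fin; a constant region scores exactly 0.
#'
#' @param image a [fin_image].
#' @param mask a [fin_mask] with non-empty foreground.
#' @param scope `"mask"` (default) or `"image"`.
#' @return Non-negative numeric scalar.
#' @export
sharpness <- function(image, mask, scope = c("mask", "image")) {
  scope <- match.arg(scope)
  stopifnot(inherits(image, "fin_image"), inherits(mask, "fin_mask"))
  if (mask$area_px == 0L) stop("empty mask", call. = FALSE)
  if (!all(dim(mask$mask) == dim(image$pixels)[1:2]))
    stop("mask and image dimensions differ", call. = FALSE)
  resp <- laplacian_response(grey_plane(image))
  vals <- if (scope == "mask") resp[mask$mask] else as.vector(resp)
  if (length(vals) < 2L) return(0)
  stats::sd(vals)
}

#' Admission filter for identification
#'
#' An image takes part in enrollment or identification only if its width and
#' height meet the minima, at least `min_features` keypoints fall inside the
#' fin, and the fin sharpness reaches `sharpness_threshold`. Every violated
#' rule is reported.
#'
#' @param image a [fin_image].
#' @param mask a [fin_mask] for the sharpness rule.
#' @param n_features number of keypoints detected inside the fin (>= 0).
#' @param config a [quality_config()].
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed-rule tags among `"width"`, `"height"`, `"features"`,
#'   `"sharpness"`; empty when `pass` is `TRUE`).
#' @export
passes_filter <- function(image, mask, n_features, config = quality_config()) {
  stopifnot(inherits(config, "quality_config"), n_features >= 0)
  d <- image_size(image)
  reasons <- character()
  if (d[2] < config$min_width_px) reasons <- c(reasons, "width")
  if (d[1] < config$min_height_px) reasons <- c(reasons, "height")
  if (n_features < config$min_features) reasons <- c(reasons, "features")
  if (config$sharpness_threshold > 0) {
    s <- sharpness(image, mask, scope = config$sharpness_scope)
    if (s < config$sharpness_threshold) reasons <- c(reasons, "sharpness")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
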