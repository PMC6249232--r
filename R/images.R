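#' Construct a fin image
#'
#' A `fin_image` holds an 8-bit RGB photograph of a (cropped) dorsal fin as a
#' numeric `H x W x 3` array with values in `[0, 255]`, together with a
#' provenance tag (a file path or a synthetic-generator label).
#'
#' @param pixels numeric `H x W x 3` array, values in `[0, 255]`.
#' @param source character scalar; file path or synthetic tag.
#' @return An object of class `fin_image` with elements `pixels` and `source`.
#' @export
fin_image <- function(pixels, source = "<memory>") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have positive height and width", call. = FALSE)
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(list(pixels = pixels, source = as.character(source)),
            class = "fin_image")
}

#' @export
print.fin_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fin_image %dx%d  source=%s>\n", d[1], d[2], x$source))
  invisible(x)
}

#' Image height and width in pixels
#' @param image a [fin_image].
#' @return Integer vector `c(height, width)`.
#' @export
image_size <- function(image) {
  stopifnot(inherits(image, "fin_image"))
  dim(image$pixels)[1:2]
}

#' Read a fin photograph from disk
#'
#' Reads a JPEG or PNG file into a [fin_image]. Greyscale files are expanded
#' to three identical channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a JPEG or PNG file.
#' @return A [fin_image].
#' @export
read_fin_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)            # x, y[, channel] in [0, 1]
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  px <- aperm(px, c(2L, 1L, 3L)) * 255     # to row(y) x col(x) x channel
  fin_image(pmin(pmax(px, 0), 255), source = path)
}

#' Write a fin image to disk
#' @param image a [fin_image].
#' @param path output path; the extension selects the format (png/jpeg/tiff).
#' @return Invisibly, `path`.
#' @export
write_fin_image <- function(image, path) {
  stopifnot(inherits(image, "fin_image"))
  px <- aperm(image$pixels / 255, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(px, colormode = "Color"), path)
  invisible(path)
}

#' Construct a binary fin mask
#'
#' @param mask logical `H x W` matrix; `TRUE` marks fin (foreground) pixels.
#' @return An object of class `fin_mask` with elements `mask` and `area_px`.
#' @export
fin_mask <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask & !is.na(mask)
  structure(list(mask = mask, area_px = sum(mask)), class = "fin_mask")
}

#' @export
print.fin_mask <- function(x, ...) {
  cat(sprintf("<fin_mask %dx%d  area=%d px>\n",
              nrow(x$mask), ncol(x$mask), x$area_px))
  invisible(x)
}

#' Write a binary mask as a 0/255 PNG for inspection
#' @param mask a [fin_mask].
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
write_fin_mask <- function(mask, path) {
  stopifnot(inherits(mask, "fin_mask"))
  EBImage::writeImage(EBImage::Image(t(mask$mask) * 1), path)
  invisible(path)
}

# Greyscale plane used by the sharpness score and the keypoint detector:
# CIE-Lab lightness L* rescaled from [0, 100] to [0, 255].
grey_plane <- function(image) {
  lab <- rgb_to_lab(image)
  lab$L * 2.55
}
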