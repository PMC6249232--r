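#' Segmentation configuration
#'
#' Controls how the fin mask is extracted from a cropped fin photograph.
#'
#' @param radius structuring-element radius in pixels for the morphological
#'   clean-up, or `NULL` for the size-adaptive default
#'   `max(1, round(0.005 * min(H, W)))`.
#' @param channel which CIE-Lab opponent channel to threshold: `"auto"`
#'   (default) picks, per image, the channel whose Otsu split attains the
#'   larger between-class variance; `"a"` or `"b"` force a channel.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(radius = NULL, channel = c("auto", "a", "b")) {
  channel <- match.arg(channel)
  if (!is.null(radius)) {
    radius <- as.integer(radius)
    if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  }
  structure(list(radius = radius, channel = channel),
            class = "segmentation_config")
}

#' Convert an RGB fin image to CIE-Lab
#'
#' Standard sRGB to CIE-L*a*b* conversion under the D65 white point, delegated
#' to [grDevices::convertColor()]. `L` is lightness in `[0, 100]`; `a` and `b`
#' are the green-red and blue-yellow opponent channels. Greys map to
#' `a = b = 0` and the sea's blue sits well below zero on `b`, which is what
#' makes a grey fin on blue water separable by a single threshold.
#'
#' @param image a [fin_image].
#' @return An object of class `lab_image`: list of `H x W` matrices `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(image) {
  stopifnot(inherits(image, "fin_image"))
  d <- dim(image$pixels)
  flat <- matrix(image$pixels, ncol = 3L) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  structure(list(L = matrix(lab[, 1], d[1], d[2]),
                 a = matrix(lab[, 2], d[1], d[2]),
                 b = matrix(lab[, 3], d[1], d[2])),
            class = "lab_image")
}

#' Otsu threshold of a real-valued channel
#'
#' Builds a 256-bin histogram over the channel's range and picks the cut that
#' maximises the between-class variance (equivalently, minimises the
#' intra-class variance). The binary mask is oriented so that the foreground
#' is the class holding the *minority* of the 1-pixel image border: in a
#' cropped fin photograph the sea touches the border, the fin is interior.
#'
#' @param channel numeric matrix with at least two distinct values.
#' @return List with `threshold` (on the channel's own scale), `mask`
#'   (logical matrix, `TRUE` = foreground) and `between_var` (the attained
#'   between-class variance, useful for comparing candidate channels).
#' @export
otsu_threshold <- function(channel) {
  if (!is.matrix(channel)) stop("`channel` must be a matrix", call. = FALSE)
  lo <- min(channel); hi <- max(channel)
  if (!(hi > lo))
    stop("degenerate input: channel is constant, no threshold exists",
         call. = FALSE)
  nb <- 256L
  # bin index in 1..nb; right edge of bin t is lo + t * w
  w <- (hi - lo) / nb
  idx <- pmin(floor((channel - lo) / w) + 1L, nb)
  h <- tabulate(idx, nbins = nb)
  p <- h / sum(h)
  v <- lo + (seq_len(nb) - 0.5) * w        # bin centres, channel units
  omega <- cumsum(p)                       # P(class 0) for cut after bin t
  mu <- cumsum(p * v)
  mu_t <- mu[nb]
  # between-class variance (channel units^2) for cuts t = 1..nb-1
  t <- seq_len(nb - 1L)
  denom <- omega[t] * (1 - omega[t])
  sigma_b <- ifelse(denom > 0, (mu_t * omega[t] - mu[t])^2 / denom, -Inf)
  t_star <- which.max(sigma_b)
  thr <- lo + t_star * w                   # right edge of the last low bin
  high <- channel > thr
  # orient: majority class on the 1-px border is background
  border <- c(high[1, ], high[nrow(high), ], high[, 1], high[, ncol(high)])
  fg <- if (mean(border) > 0.5) !high else high
  list(threshold = thr, mask = fg, between_var = sigma_b[t_star])
}

#' Morphological clean-up of a binary mask
#'
#' Binary opening followed by binary closing with a disc structuring element,
#' removing speckle noise smaller than the disc and filling comparable holes.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels (>= 1).
#' @return Logical matrix of the same shape.
#' @export
morphological_clean <- function(mask, radius) {
  stopifnot(is.matrix(mask))
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  img <- EBImage::Image(t(mask) * 1)
  out <- EBImage::closing(EBImage::opening(img, brush), brush)
  t(EBImage::imageData(out)) > 0.5
}

#' Extract the fin mask from a cropped fin photograph
#'
#' Pipeline: convert to CIE-Lab, Otsu-threshold the opponent channel (a* or
#' b*) whose split attains the larger between-class variance (or the channel
#' forced by `config`), clean the binary mask morphologically, and keep the
#' largest 8-connected foreground component.
#'
#' @param image a [fin_image] with at least two distinct colours.
#' @param config a [segmentation_config()].
#' @return A [fin_mask] whose foreground is a single 8-connected component.
#' @export
extract_fin_mask <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "fin_image"), inherits(config, "segmentation_config"))
  d <- dim(image$pixels)
  lab <- rgb_to_lab(image)
  cand <- switch(config$channel,
                 auto = list(a = lab$a, b = lab$b),
                 a = list(a = lab$a),
                 b = list(b = lab$b))
  ot <- NULL
  for (ch in cand) {
    if (!(max(ch) > min(ch))) next
    o <- otsu_threshold(ch)
    if (is.null(ot) || o$between_var > ot$between_var) ot <- o
  }
  if (is.null(ot))
    stop("degenerate input: no opponent channel separates the image",
         call. = FALSE)
  radius <- if (is.null(config$radius))
    max(1L, as.integer(round(0.005 * min(d[1], d[2])))) else config$radius
  cleaned <- morphological_clean(ot$mask, radius)
  if (!any(cleaned))
    stop("segmentation failure: empty mask after morphological cleaning",
         call. = FALSE)
  fin_mask(largest_component(cleaned))
}

# Largest 8-connected foreground component; ties broken by the component
# whose smallest (row, col) foreground coordinate comes first.
largest_component <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1))))
  lab <- round(lab)
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # first label encountered scanning rows then columns
    flat <- as.vector(t(lab))              # row-major order
    first_hit <- vapply(best, function(l) match(l, flat), integer(1))
    best <- best[which.min(first_hit)]
  }
  lab == best
}
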