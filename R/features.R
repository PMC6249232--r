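#' Keypoint feature set
#'
#' Scale- and rotation-invariant keypoints with fixed-length descriptors,
#' restricted (by [detect_features()]) to the fin foreground. Coordinates are
#' 0-based with `x` the column (rightward) and `y` the row (downward).
#'
#' @param keypoints data.frame with numeric columns `x`, `y`, `scale`
#'   (> 0), `orientation` (degrees in `[0, 360)`) and optionally `response`.
#' @param descriptors numeric matrix with one row per keypoint; all rows the
#'   same (backend-defined) length.
#' @param image_ref identifier of the source image.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(keypoints, descriptors, image_ref = "<memory>") {
  keypoints <- as.data.frame(keypoints)
  if (!all(c("x", "y", "scale", "orientation") %in% names(keypoints)))
    stop("keypoints need columns x, y, scale, orientation", call. = FALSE)
  descriptors <- as.matrix(descriptors)
  if (nrow(keypoints) != nrow(descriptors))
    stop("one descriptor row per keypoint required", call. = FALSE)
  structure(list(keypoints = keypoints, descriptors = descriptors,
                 image_ref = as.character(image_ref)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set: %d keypoints, %d-d descriptors, ref=%s>\n",
              nrow(x$keypoints), ncol(x$descriptors), x$image_ref))
  invisible(x)
}

#' Number of keypoints in a feature set
#' @param features a [feature_set].
#' @return Integer count.
#' @export
n_features <- function(features) {
  stopifnot(inherits(features, "feature_set"))
  nrow(features$keypoints)
}

#' Keypoint detector backend
#'
#' The identification pipeline is backend-agnostic: any object of class
#' `detector_backend` with a `name` and a `detect(image, mask)` function
#' returning a [feature_set()] can drive it. The built-in `"cdog"` backend is
#' a pose-canonicalising difference-of-Gaussians detector: the fin mask's
#' second moments fix a canonical rotation and scale (major axis horizontal,
#' fixed root-area), the image is warped into that frame, DoG extrema are
#' detected across a Gaussian scale ladder, each keypoint gets a dominant
#' gradient orientation and a 128-dimensional SIFT-style gradient-histogram
#' descriptor. Keypoint positions and scales are mapped back to the original
#' image frame; orientations are reported in the canonical (fin-aligned)
#' frame, which is what makes the equal-orientation match filter tolerant to
#' in-plane rotation of the photograph.
#'
#' @param name backend name; `"cdog"` is the built-in default.
#' @param max_keypoints keep at most this many strongest keypoints.
#' @param contrast_threshold minimum |DoG| response (image scaled to `[0,1]`).
#' @param canvas side, in pixels, of the canonical frame.
#' @param target_sqrt_area canonical fin size: the mask is rescaled so that
#'   the square root of its pixel area equals this value.
#' @param detect for a custom backend, a `function(image, mask)` returning a
#'   [feature_set()]; ignored for `"cdog"`.
#' @return An object of class `detector_backend`.
#' @export
detector_backend <- function(name = "cdog", max_keypoints = 150L,
                             contrast_threshold = 0.01, canvas = 288L,
                             target_sqrt_area = 130, detect = NULL) {
  if (name == "cdog") {
    opts <- list(max_keypoints = as.integer(max_keypoints),
                 contrast_threshold = contrast_threshold,
                 canvas = as.integer(canvas),
                 target_sqrt_area = target_sqrt_area)
    detect <- function(image, mask) cdog_detect(image, mask, opts)
  } else if (is.null(detect)) {
    stop("a custom backend needs a `detect` function", call. = FALSE)
  }
  structure(list(name = name, detect = detect), class = "detector_backend")
}

#' Detect keypoints restricted to the fin
#'
#' Runs the backend's detector and discards every keypoint whose `(x, y)`
#' position falls outside the fin mask (out-of-fin deletion). An empty result
#' is valid; admission is the quality gate's job.
#'
#' @param image a [fin_image].
#' @param mask a [fin_mask] with non-empty foreground.
#' @param backend a [detector_backend()].
#' @return A [feature_set] whose keypoints all lie inside the mask.
#' @export
detect_features <- function(image, mask, backend = detector_backend()) {
  stopifnot(inherits(image, "fin_image"), inherits(mask, "fin_mask"),
            inherits(backend, "detector_backend"))
  if (mask$area_px == 0L) stop("empty mask", call. = FALSE)
  fs <- backend$detect(image, mask)
  kp <- fs$keypoints
  H <- nrow(mask$mask); W <- ncol(mask$mask)
  keep <- rep(FALSE, nrow(kp))
  if (nrow(kp) > 0L) {
    r <- floor(kp$y) + 1L; c <- floor(kp$x) + 1L
    inb <- r >= 1L & r <= H & c >= 1L & c <= W
    keep[inb] <- mask$mask[cbind(r[inb], c[inb])]
  }
  feature_set(kp[keep, , drop = FALSE],
              fs$descriptors[keep, , drop = FALSE],
              image_ref = image$source)
}

# --- canonical-pose DoG backend internals --------------------------------

# Canonical pose of a fin mask: centroid, major-axis angle phi (direction
# disambiguated by the sign of the third moment along the axis) and the
# isotropic scale taking sqrt(area) to the target size.
mask_pose <- function(mask, target_sqrt_area) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 0.5; y <- idx[, 1] - 0.5
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  mxx <- mean(dx * dx); myy <- mean(dy * dy); mxy <- mean(dx * dy)
  phi <- 0.5 * atan2(2 * mxy, mxx - myy)
  su <- dx * cos(phi) + dy * sin(phi)
  if (mean(su^3) < 0) phi <- phi + pi
  list(cx = cx, cy = cy, phi = phi,
       s = target_sqrt_area / sqrt(length(x)))
}

# Bilinear sampling of matrix `g` at 0-based centre coordinates (x, y);
# out-of-range positions return `fill`.
bilinear_sample <- function(g, x, y, fill = 0) {
  nr <- nrow(g); nc <- ncol(g)
  ci <- x + 0.5; ri <- y + 0.5          # continuous 1-based indices
  c0 <- floor(ci); r0 <- floor(ri)
  fc <- ci - c0; fr <- ri - r0
  ok <- c0 >= 1 & c0 + 1 <= nc & r0 >= 1 & r0 + 1 <= nr
  out <- rep(fill, length(x))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    g00 <- g[cbind(r0k, c0k)];       g01 <- g[cbind(r0k, c0k + 1)]
    g10 <- g[cbind(r0k + 1, c0k)];   g11 <- g[cbind(r0k + 1, c0k + 1)]
    out[ok] <- (1 - frk) * ((1 - fck) * g00 + fck * g01) +
      frk * ((1 - fck) * g10 + fck * g11)
  }
  out
}

# 3x3 neighbourhood maximum (8 neighbours, excluding the centre), -Inf edges.
nbr_max8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(-Inf, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 1L && dc == 1L) next
    out <- pmax(out, p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)])
  }
  out
}

cdog_detect <- function(image, mask, opts) {
  g_img <- grey_plane(image) / 255
  m <- mask$mask
  pose <- mask_pose(m, opts$target_sqrt_area)
  C <- opts$canvas
  half <- C / 2

  # inverse map: canonical pixel centres -> image coordinates
  xo <- rep(seq_len(C) - 0.5, each = C) - half   # column-major over rows
  yo <- rep(seq_len(C) - 0.5, times = C) - half
  cphi <- cos(pose$phi); sphi <- sin(pose$phi)
  xi <- pose$cx + (cphi * xo - sphi * yo) / pose$s
  yi <- pose$cy + (sphi * xo + cphi * yo) / pose$s
  bg <- if (any(!m)) stats::median(g_img[!m]) else 0
  gc <- matrix(bilinear_sample(g_img, xi, yi, fill = bg), C, C)
  mc <- matrix(bilinear_sample(m * 1, xi, yi, fill = 0), C, C) > 0.5

  # Gaussian scale ladder and DoG stack in the canonical frame; the ladder
  # starts fine enough to catch few-pixel-wide scar strokes
  sigmas <- 1.2 * 2^((0:8) / 3)
  eb <- EBImage::Image(t(gc))
  levels <- lapply(sigmas, function(s) t(EBImage::imageData(
    EBImage::gblur(eb, sigma = s))))
  dogs <- lapply(seq_len(length(levels) - 1L),
                 function(i) levels[[i + 1L]] - levels[[i]])

  kp <- list()
  for (j in 2:(length(dogs) - 1L)) {
    d <- dogs[[j]]
    up <- dogs[[j + 1L]]; dn <- dogs[[j - 1L]]
    is_max <- d > opts$contrast_threshold & d > nbr_max8(d) &
      d > pmax(nbr_max8(up), up) & d > pmax(nbr_max8(dn), dn)
    is_min <- -d > opts$contrast_threshold & (-d) > nbr_max8(-d) &
      (-d) > pmax(nbr_max8(-up), -up) & (-d) > pmax(nbr_max8(-dn), -dn)
    # keep clear of the silhouette: responses within ~2 sigma of the mask
    # boundary are driven by the fin/sea edge, not by marks on the fin
    margin <- 2L * as.integer(round(2 * sigmas[j + 1L])) + 1L
    mj <- t(EBImage::imageData(EBImage::erode(
      EBImage::Image(t(mc) * 1), EBImage::makeBrush(margin, "disc")))) > 0.5
    hits <- which((is_max | is_min) & mj, arr.ind = TRUE)
    if (nrow(hits) > 0L)
      kp[[length(kp) + 1L]] <- data.frame(
        r = hits[, 1], c = hits[, 2], level = j + 1L,
        sigma = sigmas[j + 1L], response = abs(d[hits]))
  }
  empty <- feature_set(
    data.frame(x = numeric(), y = numeric(), scale = numeric(),
               orientation = numeric(), response = numeric()),
    matrix(numeric(), 0L, 128L), image_ref = image$source)
  if (length(kp) == 0L) return(empty)
  kp <- do.call(rbind, kp)
  ord <- order(-kp$response, kp$r, kp$c)
  kp <- kp[ord[seq_len(min(nrow(kp), opts$max_keypoints))], , drop = FALSE]

  # gradients per used level
  grad <- list()
  for (lv in unique(kp$level)) {
    g <- levels[[lv]]
    nr <- nrow(g); nc <- ncol(g)
    gx <- (g[, c(2:nc, nc)] - g[, c(1, 1:(nc - 1))]) / 2
    gy <- (g[c(2:nr, nr), ] - g[c(1, 1:(nr - 1)), ]) / 2
    grad[[as.character(lv)]] <- list(gx = gx, gy = gy)
  }

  theta <- vapply(seq_len(nrow(kp)), function(i) {
    gr <- grad[[as.character(kp$level[i])]]
    keypoint_orientation(gr$gx, gr$gy, kp$r[i], kp$c[i], kp$sigma[i])
  }, numeric(1))

  desc <- descriptor_block(grad, kp, theta)
  nz <- rowSums(desc^2) > 0
  kp <- kp[nz, , drop = FALSE]; theta <- theta[nz]
  desc <- desc[nz, , drop = FALSE]
  if (nrow(kp) == 0L) return(empty)

  # map back to image frame; orientations stay in the canonical (fin) frame
  xc <- kp$c - 0.5 - half; yc <- kp$r - 0.5 - half
  x_img <- pose$cx + (cphi * xc - sphi * yc) / pose$s
  y_img <- pose$cy + (sphi * xc + cphi * yc) / pose$s
  feature_set(
    data.frame(x = x_img, y = y_img, scale = kp$sigma / pose$s,
               orientation = theta %% 360, response = kp$response),
    desc, image_ref = image$source)
}

# Dominant gradient orientation: 36-bin magnitude histogram in a Gaussian
# window (sd = 1.5 sigma), circular smoothing, parabolic peak interpolation.
keypoint_orientation <- function(gx, gy, r, c, sigma) {
  rad <- min(15L, max(4L, as.integer(round(2.5 * sigma))))
  nr <- nrow(gx); nc <- ncol(gx)
  rs <- max(1L, r - rad):min(nr, r + rad)
  cs <- max(1L, c - rad):min(nc, c + rad)
  wx <- gx[rs, cs]; wy <- gy[rs, cs]
  d2 <- outer((rs - r)^2, (cs - c)^2, `+`)
  w <- exp(-d2 / (2 * (1.5 * sigma)^2)) * sqrt(wx^2 + wy^2)
  ang <- (atan2(wy, wx) * 180 / pi) %% 360
  bin <- pmin(36L, floor(ang / 10) + 1L)
  h <- vapply(1:36, function(b) sum(w[bin == b]), numeric(1))
  for (pass in 1:2)
    h <- (h + h[c(36, 1:35)] + h[c(2:36, 1)]) / 3
  k <- which.max(h)
  hl <- h[if (k == 1L) 36L else k - 1L]
  hr <- h[if (k == 36L) 1L else k + 1L]
  denom <- hl - 2 * h[k] + hr
  off <- if (abs(denom) > 1e-12) 0.5 * (hl - hr) / denom else 0
  ((k - 0.5 + max(-0.5, min(0.5, off))) * 10) %% 360
}

# SIFT-style descriptors for all keypoints: 4x4 spatial cells x 8 orientation
# bins over a rotated patch of half-width 6 sigma, Gaussian-weighted, with
# linear interpolation across orientation bins; L2-normalised, clipped at
# 0.2, renormalised.
descriptor_block <- function(grad, kp, theta) {
  n <- nrow(kp)
  desc <- matrix(0, n, 128L)
  gi <- rep(1:16, times = 16)                                 # u index
  gj <- rep(1:16, each = 16)                                  # v index
  u0 <- (gi - 8.5) * 0.75; v0 <- (gj - 8.5) * 0.75            # units of sigma
  cell <- ((gj - 1) %/% 4) * 4 + ((gi - 1) %/% 4)             # 0..15
  gauss <- exp(-(u0^2 + v0^2) / (2 * 6^2))
  for (lv in unique(kp$level)) {
    sel <- which(kp$level == lv)
    gr <- grad[[as.character(lv)]]
    sig <- kp$sigma[sel][1]
    th <- theta[sel] * pi / 180
    # sample positions: keypoint + R(theta) %*% (u, v) * sigma
    ur <- outer(cos(th), u0 * sig) - outer(sin(th), v0 * sig)  # n_sel x 256
    vr <- outer(sin(th), u0 * sig) + outer(cos(th), v0 * sig)
    xs <- (kp$c[sel] - 0.5) + ur
    ys <- (kp$r[sel] - 0.5) + vr
    sx <- bilinear_sample(gr$gx, as.vector(xs), as.vector(ys))
    sy <- bilinear_sample(gr$gy, as.vector(xs), as.vector(ys))
    mag <- sqrt(sx^2 + sy^2) * rep(gauss, each = length(sel))
    rel <- (atan2(sy, sx) * 180 / pi -
              rep(theta[sel], times = 256)) %% 360
    a <- rel / 45
    b0 <- floor(a); f <- a - b0
    # column-major linear indices into the n x 128 descriptor matrix
    krep <- rep(sel, times = 256)
    cellrep <- rep(cell, each = length(sel))
    i1 <- krep + (cellrep * 8L + (b0 %% 8)) * n
    i2 <- krep + (cellrep * 8L + ((b0 + 1) %% 8)) * n
    acc <- c(mag * (1 - f), mag * f)
    idx <- c(i1, i2)
    sums <- rowsum(acc, idx)
    desc[as.integer(rownames(sums))] <- desc[as.integer(rownames(sums))] + sums
  }
  nrm <- sqrt(rowSums(desc^2))
  pos <- nrm > 0
  desc[pos, ] <- desc[pos, , drop = FALSE] / nrm[pos]
  desc <- pmin(desc, 0.2)
  nrm <- sqrt(rowSums(desc^2))
  pos <- nrm > 0
  desc[pos, ] <- desc[pos, , drop = FALSE] / nrm[pos]
  desc
}
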