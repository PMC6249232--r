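#' Synthetic fin identities and photographs
#'
#' The synthetic generator renders dorsal-fin-like scenes with known ground
#' truth so the whole pipeline can be exercised without field imagery: a grey
#' fin silhouette on blue sea, carrying a per-identity pattern of near-white
#' scar strokes (the marks real Risso's dolphins accumulate with age), with
#' controllable in-plane rotation, scale, Gaussian blur and pixel noise.
#'
#' @param name identity label.
#' @param seed integer seed; the silhouette and scar pattern are a pure
#'   function of it, so an identity is reproducible independently of how its
#'   images are later rendered.
#' @param n_scars number of scar strokes (>= 3).
#' @return An object of class `identity_spec` with the fin polygon (vertices
#'   in the unit square) and the scar strokes.
#' @export
identity_spec <- function(name, seed, n_scars = 8L) {
  if (n_scars < 3L) stop("an identity needs >= 3 scar strokes", call. = FALSE)
  with_seed(as.integer(seed), {
    poly <- fin_polygon_jittered()
    scars <- scar_pattern(poly, n_scars)
  })
  structure(list(name = as.character(name), fin_polygon = poly,
                 scar_pattern = scars, seed = as.integer(seed)),
            class = "identity_spec")
}

#' Rendering parameters for a synthetic fin photograph
#'
#' Defaults render a 400 x 400 scene (comfortably above the 200-px admission
#' gate) with the fin spanning about 70% of the frame, grey fin
#' `(128,128,128)` on blue sea `(20,60,140)` -- colours far apart on the b*
#' axis so a single opponent-channel threshold separates them.
#'
#' @param width,height canvas size in pixels.
#' @param rotation_deg in-plane rotation of the fin, degrees.
#' @param scale fin size multiplier (> 0).
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0; 0 = sharp).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param sea_color,fin_color RGB triples in `[0, 255]`.
#' @param seed integer seed driving the rendering noise.
#' @return An object of class `render_params`.
#' @export
render_params <- function(width = 400L, height = 400L, rotation_deg = 0,
                          scale = 1, blur_sigma = 0, noise_sd = 2,
                          sea_color = c(20, 60, 140),
                          fin_color = c(128, 128, 128), seed = 1L) {
  if (width < 1L || height < 1L) stop("canvas must be >= 1 px", call. = FALSE)
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  if (blur_sigma < 0 || noise_sd < 0)
    stop("`blur_sigma` and `noise_sd` must be >= 0", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 rotation_deg = rotation_deg, scale = scale,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 sea_color = sea_color, fin_color = fin_color,
                 seed = as.integer(seed)),
            class = "render_params")
}

#' Render a synthetic fin photograph with its ground-truth mask
#'
#' The fin polygon is rotated and scaled analytically (in vector space) and
#' rasterised with hard edges, so the returned mask is the exact support of
#' the rendered silhouette; blur and noise are applied to the image only,
#' never to the ground truth. Rendering is bit-reproducible for a fixed seed.
#'
#' @param identity an [identity_spec()].
#' @param params a [render_params()].
#' @return List with `image` (a [fin_image]) and `mask` (the ground-truth
#'   [fin_mask]).
#' @export
generate_fin_image <- function(identity, params = render_params()) {
  stopifnot(inherits(identity, "identity_spec"),
            inherits(params, "render_params"))
  W <- params$width; H <- params$height
  tr <- fin_transform(identity$fin_polygon, params)
  poly <- tr$poly_px
  if (any(poly[, 1] < 1 | poly[, 1] > W - 1 | poly[, 2] < 1 | poly[, 2] > H - 1))
    stop("fin after rotation/scaling exceeds the canvas", call. = FALSE)
  mask <- rasterize_polygon(poly, H, W)

  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(params$sea_color[ch], H, W)
    plane[mask] <- params$fin_color[ch]
    px[, , ch] <- plane
  }
  # scar strokes, clipped to the fin, anti-aliased across their width
  sc <- identity$scar_pattern
  for (k in seq_len(nrow(sc))) {
    p1 <- tr$map(c(sc$x1[k], sc$y1[k]))
    p2 <- tr$map(c(sc$x2[k], sc$y2[k]))
    wpx <- max(1.2, sc$width[k] * tr$size)
    px <- draw_stroke(px, mask, p1, p2, wpx, sc$brightness[k])
  }
  with_seed(params$seed, {
    if (params$blur_sigma > 0) {
      eb <- EBImage::Image(aperm(px / 255, c(2, 1, 3)), colormode = "Color")
      eb <- EBImage::gblur(eb, sigma = params$blur_sigma)
      px <- aperm(EBImage::imageData(eb), c(2, 1, 3)) * 255
    }
    if (params$noise_sd > 0)
      px <- px + array(stats::rnorm(length(px), 0, params$noise_sd), dim = dim(px))
  })
  px <- pmin(pmax(px, 0), 255)
  list(image = fin_image(px, source = sprintf("synthetic:%s", identity$name)),
       mask = fin_mask(mask))
}

#' Generate a synthetic model gallery and labelled query set
#'
#' Emulates the study design in which enrolled model images and test images
#' come from different encounters: one clean model render per identity, plus
#' `q_per_identity` labelled queries per identity rendered under perturbed
#' rotation, scale and blur (models and queries never share parameters).
#'
#' @param n_identities number of distinct identities (>= 2).
#' @param q_per_identity queries per identity.
#' @param params base [render_params()] for the model renders.
#' @param rotation_range,scale_range query perturbation ranges (uniform).
#' @param blur_levels vector of blur sigmas cycled across queries.
#' @param seed master seed for rendering noise and query perturbations.
#' @param identity_seed seed of the identity population: identity specs are a
#'   pure function of it, so changing `seed` re-perturbs the queries while
#'   keeping the same individuals.
#' @return List with `identities`, `models` and `queries`; models and queries
#'   are lists of `list(image, mask, label, rotation, scale, blur)`.
#' @export
generate_gallery <- function(n_identities, q_per_identity = 3L,
                             params = render_params(),
                             rotation_range = c(-15, 15),
                             scale_range = c(0.9, 1.1),
                             blur_levels = 0, seed = 1L,
                             identity_seed = 100L) {
  if (n_identities < 2L) stop("need at least 2 identities", call. = FALSE)
  seed <- as.integer(seed)
  ids <- lapply(seq_len(n_identities), function(i)
    identity_spec(sprintf("SYN-%03d", i),
                  seed = small_seed(identity_seed, 7919L * i)))
  models <- lapply(seq_along(ids), function(i) {
    p <- params; p$seed <- small_seed(seed, 2L * i)
    r <- generate_fin_image(ids[[i]], p)
    list(image = r$image, mask = r$mask, label = ids[[i]]$name,
         rotation = p$rotation_deg, scale = p$scale, blur = p$blur_sigma)
  })
  queries <- list()
  q_idx <- 0L
  for (i in seq_along(ids)) {
    for (q in seq_len(q_per_identity)) {
      q_idx <- q_idx + 1L
      qseed <- small_seed(seed, 1000L + q_idx)
      pert <- with_seed(qseed, list(
        rot = stats::runif(1, rotation_range[1], rotation_range[2]),
        sc = stats::runif(1, scale_range[1], scale_range[2])))
      p <- params
      p$rotation_deg <- params$rotation_deg + pert$rot
      p$scale <- params$scale * pert$sc
      p$blur_sigma <- blur_levels[(q_idx - 1L) %% length(blur_levels) + 1L]
      p$seed <- qseed
      r <- generate_fin_image(ids[[i]], p)
      queries[[q_idx]] <- list(image = r$image, mask = r$mask,
                               label = ids[[i]]$name, rotation = p$rotation_deg,
                               scale = p$scale, blur = p$blur_sigma)
    }
  }
  list(identities = ids, models = models, queries = queries)
}

#' Generate a synthetic catalogue with a sighting schedule
#'
#' Emulates the structure of a multi-year survey: `n_dolphins` individuals
#' over `n_dates` survey dates, each dolphin present on each date with
#' probability `p_resight` (at least one sighting is guaranteed), each date
#' assigned to the deep stratum with probability `depth_mix`, and GPS drawn
#' inside a fixed bounding box in the Gulf of Taranto.
#'
#' @param n_dolphins,n_dates positive integers.
#' @param p_resight per-date presence probability in `[0, 1]`.
#' @param depth_mix probability that a survey date falls in the deep
#'   (>= 800 m) stratum.
#' @param seed integer seed; generation is deterministic per seed.
#' @return A [catalogue] with entries and sightings.
#' @export
generate_catalogue <- function(n_dolphins = 60L, n_dates = 11L,
                               p_resight = 0.25, depth_mix = 0.5, seed = 1L) {
  stopifnot(n_dolphins >= 1L, n_dates >= 1L,
            p_resight >= 0, p_resight <= 1, depth_mix >= 0, depth_mix <= 1)
  with_seed(as.integer(seed), {
    names <- sprintf("SYN-%03d", seq_len(n_dolphins))
    dates <- as.Date("2013-07-01") +
      sort(sample.int(1200L, n_dates, replace = FALSE))
    deep <- stats::runif(n_dates) < depth_mix
    depth <- ifelse(deep, stats::runif(n_dates, 800, 1000),
                    stats::runif(n_dates, 436, 799.9))
    gps_lat <- stats::runif(n_dates, 39.8, 40.3)
    gps_lon <- stats::runif(n_dates, 17.0, 17.6)
    present <- matrix(stats::runif(n_dolphins * n_dates) < p_resight,
                      n_dolphins, n_dates)
    none <- which(rowSums(present) == 0L)
    for (i in none) present[i, sample.int(n_dates, 1L)] <- TRUE
    extra <- sample.int(6L, n_dates, replace = TRUE) - 1L

    idx <- which(present, arr.ind = TRUE)
    d <- idx[, 2]
    entries <- data.frame(
      dolphin_name = names[idx[, 1]],
      input_image = sprintf("images/%s_%s.jpg", names[idx[, 1]], dates[d]),
      cropped_fin = sprintf("fins/%s_%s.png", names[idx[, 1]], dates[d]),
      observation_date = dates[d],
      gps_lat = round(gps_lat[d] + stats::rnorm(nrow(idx), 0, 0.002), 6),
      gps_lon = round(gps_lon[d] + stats::rnorm(nrow(idx), 0, 0.002), 6),
      codename = format(dates[d], "campaign-%Y"),
      side = "left",
      stringsAsFactors = FALSE)
    entries <- entries[order(entries$dolphin_name, entries$observation_date), ]
    rownames(entries) <- NULL
    sightings <- data.frame(
      date = dates, gps_lat = round(gps_lat, 6), gps_lon = round(gps_lon, 6),
      depth_m = round(depth, 1),
      group_size = colSums(present) + extra,
      stringsAsFactors = FALSE)
    sightings$dolphins <- lapply(seq_len(n_dates),
                                 function(j) names[present[, j]])
  })
  catalogue(entries, sightings)
}

# --- internal geometry helpers ------------------------------------------

# Evaluate a local RNG scope: runs `expr` under `seed` and restores the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a distinct sub-seed from a master seed, kept within 32-bit range.
small_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 137 * as.numeric(k)) %% 2147483629)
}

# quadratic Bezier, n samples, endpoints included
qbezier <- function(p0, pc, p1, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * pc[1] + t^2 * p1[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * pc[2] + t^2 * p1[2])
}

# A dorsal-fin-like simple polygon in the unit square (y grows downward):
# steep leading edge up to a backswept tip, concave trailing edge with
# per-identity notches, flat base. Consumes the current RNG stream.
fin_polygon_jittered <- function() {
  j <- function(s) stats::runif(1, -s, s)
  baseL <- c(0.12 + j(0.02), 0.84 + j(0.02))
  baseR <- c(0.88 + j(0.02), 0.80 + j(0.02))
  tip <- c(0.42 + j(0.05), 0.13 + j(0.03))
  lead_ctrl <- c(0.15 + j(0.04), 0.32 + j(0.06))
  trail_ctrl <- c(0.58 + j(0.05), 0.42 + j(0.06))
  lead <- qbezier(baseL, lead_ctrl, tip, 28L)
  trail <- qbezier(tip, trail_ctrl, baseR, 40L)
  # trailing-edge notches: short inward displacements, a classic photo-ID mark
  n_notch <- sample(1:3, 1)
  notch_at <- sort(sample(8:32, n_notch))
  centroid <- colMeans(rbind(lead, trail))
  for (a in notch_at) {
    depth <- stats::runif(1, 0.02, 0.045)
    for (o in 0:1) {
      i <- a + o
      trail[i, ] <- trail[i, ] + depth * (centroid - trail[i, ])
    }
  }
  rbind(lead, trail[-1, , drop = FALSE])   # base closes implicitly
}

# Per-identity scar strokes: both endpoints on the fin surface (as real
# scratch marks are), random heading, widths and brightness in the
# near-white range. Consumes the RNG stream.
scar_pattern <- function(poly, n_scars) {
  bb <- apply(poly, 2, range)
  sample_inside <- function() {
    repeat {
      p <- c(stats::runif(1, bb[1, 1], bb[2, 1]),
             stats::runif(1, bb[1, 2], bb[2, 2]))
      if (point_in_polygon(p[1], p[2], poly)) return(p)
    }
  }
  rows <- vector("list", n_scars)
  for (i in seq_len(n_scars)) {
    p1 <- sample_inside()
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 0.10, 0.30)
    repeat {
      p2 <- p1 + len * c(cos(ang), sin(ang))
      mid <- p1 + 0.5 * len * c(cos(ang), sin(ang))
      if ((point_in_polygon(p2[1], p2[2], poly) &&
           point_in_polygon(mid[1], mid[2], poly)) || len < 0.04) break
      len <- 0.7 * len
    }
    rows[[i]] <- data.frame(x1 = p1[1], y1 = p1[2], x2 = p2[1], y2 = p2[2],
                            width = stats::runif(1, 0.010, 0.020),
                            brightness = stats::runif(1, 215, 255))
  }
  do.call(rbind, rows)
}

point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- poly[c(n, seq_len(n - 1L)), 1]; yj <- poly[c(n, seq_len(n - 1L)), 2]
  cross <- (yi > y) != (yj > y)
  xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
  sum(cross & x < xint) %% 2 == 1
}

# Map the unit-square fin polygon onto the canvas: centre, scale to
# 0.72 * min(W, H) * scale, rotate by rotation_deg about the fin centroid.
fin_transform <- function(poly, params) {
  th <- params$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  size <- 0.72 * min(params$width, params$height) * params$scale
  c0 <- colMeans(poly)
  centre <- c(params$width / 2, params$height / 2)
  map <- function(p) as.vector(R %*% ((p - c0) * size)) + centre
  poly_px <- t(apply(poly, 1, map))
  list(map = map, poly_px = poly_px, size = size)
}

# Even-odd scanline rasterisation; pixel (r, c) centre is (c - 0.5, r - 0.5).
rasterize_polygon <- function(poly_px, H, W) {
  mask <- matrix(FALSE, H, W)
  n <- nrow(poly_px)
  x1 <- poly_px[, 1]; y1 <- poly_px[, 2]
  x2 <- poly_px[c(2:n, 1L), 1]; y2 <- poly_px[c(2:n, 1L), 2]
  for (r in seq_len(H)) {
    y <- r - 0.5
    cross <- (y1 > y) != (y2 > y)
    if (!any(cross)) next
    xc <- sort(x1[cross] + (y - y1[cross]) / (y2[cross] - y1[cross]) *
                 (x2[cross] - x1[cross]))
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      lo <- ceiling(xc[k] + 0.5); hi <- floor(xc[k + 1L] + 0.5)
      if (hi >= lo) mask[r, max(1L, lo):min(W, hi)] <- TRUE
    }
  }
  mask
}

# Blend an anti-aliased stroke of width `wpx` between image points p1, p2
# into `px`, restricted to the fin mask.
draw_stroke <- function(px, mask, p1, p2, wpx, brightness) {
  H <- dim(px)[1]; W <- dim(px)[2]
  pad <- ceiling(wpx / 2 + 1)
  rs <- max(1L, floor(min(p1[2], p2[2]) - pad + 0.5)):
    min(H, ceiling(max(p1[2], p2[2]) + pad + 0.5))
  cs <- max(1L, floor(min(p1[1], p2[1]) - pad + 0.5)):
    min(W, ceiling(max(p1[1], p2[1]) + pad + 0.5))
  if (length(rs) == 0L || length(cs) == 0L) return(px)
  xg <- matrix(rep(cs - 0.5, each = length(rs)), length(rs))
  yg <- matrix(rep(rs - 0.5, times = length(cs)), length(rs))
  v <- p2 - p1
  len2 <- sum(v^2)
  tt <- if (len2 == 0) matrix(0, length(rs), length(cs)) else
    pmin(1, pmax(0, ((xg - p1[1]) * v[1] + (yg - p1[2]) * v[2]) / len2))
  dx <- xg - (p1[1] + tt * v[1]); dy <- yg - (p1[2] + tt * v[2])
  dist <- sqrt(dx^2 + dy^2)
  alpha <- pmin(1, pmax(0, wpx / 2 + 0.5 - dist)) * mask[rs, cs]
  for (ch in 1:3) {
    sub <- px[rs, cs, ch]
    px[rs, cs, ch] <- sub + alpha * (brightness - sub)
  }
  px
}
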