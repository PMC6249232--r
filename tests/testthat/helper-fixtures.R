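# Shared fixtures, memoised so expensive renders/enrollments are built once
# per test run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A mock detector backend that plants a fixed grid of keypoints over the
# whole frame with descriptors derived deterministically from local pixel
# content. Fast; used where matching quality is irrelevant.
grid_backend <- function(step = 25L) {
  detector_backend(name = "grid", detect = function(image, mask) {
    d <- dim(image$pixels)
    ys <- seq(step, d[1] - step, by = step)
    xs <- seq(step, d[2] - step, by = step)
    g <- expand.grid(y = ys, x = xs)
    desc <- cbind(image$pixels[cbind(g$y, g$x, 1)],
                  image$pixels[cbind(g$y, g$x, 2)],
                  image$pixels[cbind(g$y, g$x, 3)],
                  g$x, g$y)
    feature_set(data.frame(x = g$x - 0.5, y = g$y - 0.5, scale = 2,
                           orientation = 0),
                desc, image_ref = image$source)
  })
}

# Brute-force mutual-nearest-neighbour oracle over the full distance matrix.
mutual_nn_oracle <- function(Q, M) {
  nq <- nrow(Q); nm <- nrow(M)
  d <- matrix(0, nq, nm)
  for (i in seq_len(nq)) for (j in seq_len(nm))
    d[i, j] <- sqrt(sum((Q[i, ] - M[j, ])^2))
  pairs <- list()
  for (i in seq_len(nq)) {
    j <- which.min(d[i, ])
    if (which.min(d[, j]) == i) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  do.call(rbind, pairs)
}

# Random feature set with the given descriptor dimension.
random_feature_set <- function(n, dim = 16L, seed = 1L) {
  set.seed(seed)
  feature_set(data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100),
                         scale = runif(n, 1, 4),
                         orientation = runif(n, 0, 360)),
              matrix(rnorm(n * dim), n, dim))
}

test_gallery <- function() {
  memo("gallery20", function() {
    generate_gallery(20, q_per_identity = 2, blur_levels = 0, seed = 42)
  })
}

test_models <- function() {
  memo("models20", function() {
    backend <- detector_backend()
    lapply(test_gallery()$models, function(m) {
      msk <- extract_fin_mask(m$image)
      fin_model(m$label, "left", m$image,
                detect_features(m$image, msk, backend),
                sharpness = sharpness(m$image, msk))
    })
  })
}

# 200-query mixed-blur evaluation shared by evaluation and acceptance tests.
mixed_blur_eval <- function() {
  memo("mixed_eval", function() {
    gal <- generate_gallery(20, q_per_identity = 10,
                            blur_levels = c(0, 1, 2, 4), seed = 42)
    evaluate(test_models(), gal$queries)
  })
}

# Two-row catalogue entries fixture (one dolphin, two dates).
taras_entries <- function() {
  data.frame(
    dolphin_name = c("Taras", "Taras"),
    input_image = c("images/taras1.jpg", "images/taras2.jpg"),
    cropped_fin = c("fins/taras1.png", "fins/taras2.png"),
    observation_date = c("2013-07-01", "2014-08-02"),
    gps_lat = c(40.123456, 40.223456),
    gps_lon = c(17.123456, 17.223456),
    codename = c("campaign-2013", "campaign-2014"),
    side = c("left", "left"),
    stringsAsFactors = FALSE)
}

# Sightings fixture spanning both depth strata.
two_strata_sightings <- function() {
  data.frame(
    date = c("2013-07-01", "2013-08-01", "2014-07-01", "2014-08-01"),
    gps_lat = 40, gps_lon = 17,
    depth_m = c(500, 600, 900, 950),
    group_size = c(3L, 2L, 3L, 2L),
    dolphins = I(list(c("A", "B"), c("A"), c("A", "B", "C"), c("B"))),
    stringsAsFactors = FALSE)
}

two_strata_catalogue <- function() {
  s <- two_strata_sightings()
  entries <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    dd <- s$dolphins[[i]]
    data.frame(dolphin_name = dd,
               input_image = sprintf("img/%s_%d.jpg", dd, i),
               cropped_fin = sprintf("fin/%s_%d.png", dd, i),
               observation_date = s$date[i],
               gps_lat = 40, gps_lon = 17,
               codename = "c1", side = "left", stringsAsFactors = FALSE)
  }))
  catalogue(entries, s)
}
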