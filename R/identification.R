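#' Enrolled fin model
#'
#' One reference image of one side of one dolphin's dorsal fin, with its
#' feature description. The gallery used for identification is a list of
#' these; a dolphin photographed on both sides contributes two models.
#'
#' @param dolphin_name identity label.
#' @param side `"left"` or `"right"`.
#' @param image the enrolled [fin_image] (may be `NULL` for a gallery loaded
#'   without images).
#' @param features a non-empty [feature_set].
#' @param sharpness sharpness score of the enrolled image, if known.
#' @return An object of class `fin_model`.
#' @export
fin_model <- function(dolphin_name, side = c("left", "right"), image,
                      features, sharpness = NA_real_) {
  side <- match.arg(side)
  stopifnot(inherits(features, "feature_set"))
  if (nrow(features$keypoints) == 0L)
    stop("a fin model needs a non-empty feature set", call. = FALSE)
  structure(list(dolphin_name = as.character(dolphin_name), side = side,
                 image = image, features = features,
                 sharpness = as.numeric(sharpness)),
            class = "fin_model")
}

#' @export
print.fin_model <- function(x, ...) {
  cat(sprintf("<fin_model %s/%s: %d keypoints>\n", x$dolphin_name, x$side,
              nrow(x$features$keypoints)))
  invisible(x)
}

#' Match two feature sets
#'
#' Mutual-nearest-neighbour matching in descriptor space under the L2 norm:
#' a pair is kept iff each keypoint is the other's nearest neighbour, so the
#' matching is one-to-one. For every matched pair the query/model
#' coordinates, the descriptor L2 distance and the orientation pair are
#' recorded.
#'
#' @param query,model [feature_set]s with at least one keypoint each.
#' @param lowe_ratio optional ratio test: additionally require the nearest
#'   distance to be at most `lowe_ratio` times the second-nearest (`NULL`,
#'   the default, disables the test).
#' @param distance_space `"descriptor"` (default) stores descriptor-space L2
#'   distances in `D`; `"image"` stores the image-plane distance between the
#'   matched coordinates instead (diagnostic alternative).
#' @return An object of class `match_set`: list with `pairs` (data.frame
#'   `qx, qy, mx, my`), `distances`, `orientations` (data.frame
#'   `o_query, o_model`), `q_idx`, `m_idx` and `k` (the match count).
#' @export
match_features <- function(query, model, lowe_ratio = NULL,
                           distance_space = c("descriptor", "image")) {
  distance_space <- match.arg(distance_space)
  stopifnot(inherits(query, "feature_set"), inherits(model, "feature_set"))
  nq <- nrow(query$keypoints); nm <- nrow(model$keypoints)
  if (nq == 0L || nm == 0L)
    stop("both feature sets must be non-empty", call. = FALSE)
  Q <- query$descriptors; M <- model$descriptors
  d2 <- outer(rowSums(Q^2), rep(1, nm)) + outer(rep(1, nq), rowSums(M^2)) -
    2 * tcrossprod(Q, M)
  d2 <- pmax(d2, 0)
  nn_q <- max.col(-d2, ties.method = "first")        # per query row
  nn_m <- max.col(-t(d2), ties.method = "first")     # per model column
  qi <- which(nn_m[nn_q] == seq_len(nq))
  mi <- nn_q[qi]
  if (!is.null(lowe_ratio) && length(qi) > 0L && nm >= 2L) {
    keep <- vapply(seq_along(qi), function(t) {
      row <- d2[qi[t], ]
      d1 <- sqrt(row[mi[t]])
      d2nd <- sqrt(min(row[-mi[t]]))
      d1 <= lowe_ratio * d2nd
    }, logical(1))
    qi <- qi[keep]; mi <- mi[keep]
  }
  qk <- query$keypoints[qi, , drop = FALSE]
  mk <- model$keypoints[mi, , drop = FALSE]
  # recompute pair distances directly: exact zeros for identical descriptors
  dist <- if (distance_space == "descriptor")
    sqrt(rowSums((Q[qi, , drop = FALSE] - M[mi, , drop = FALSE])^2)) else
      sqrt((qk$x - mk$x)^2 + (qk$y - mk$y)^2)
  structure(list(
    pairs = data.frame(qx = qk$x, qy = qk$y, mx = mk$x, my = mk$y),
    distances = as.numeric(dist),
    orientations = data.frame(o_query = qk$orientation,
                              o_model = mk$orientation),
    q_idx = qi, m_idx = mi, k = length(qi)),
    class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set: k=%d>\n", x$k))
  invisible(x)
}

#' Trimmed median match distance d*
#'
#' The median of the match distances lying inside the closed 25th-75th
#' percentile interval (linear-interpolation percentile convention). Used to
#' break ties between candidate identities; robust against both the best and
#' the worst matches.
#'
#' @param distances non-empty numeric vector of match distances.
#' @return Numeric scalar `d*`.
#' @export
median_distance_iqr <- function(distances) {
  if (length(distances) == 0L)
    stop("no distances: k must be >= 1", call. = FALSE)
  q <- stats::quantile(distances, c(0.25, 0.75), type = 7, names = FALSE)
  stats::median(distances[distances >= q[1] & distances <= q[2]])
}

# wrap an angle difference (degrees) to (-180, 180]
wrap_half_turn <- function(x) x - 360 * ceiling((x - 180) / 360)

#' Keep equally oriented matches
#'
#' Retains exactly the matched pairs whose rounded orientation difference
#' `round(o_query - o_model)` is zero, the difference being wrapped to
#' `(-180, 180]` degrees before rounding (round-half-to-even). Under a
#' consistent relative pose the true correspondences cluster at zero
#' difference while coincidental matches spread over the whole circle.
#'
#' @param matches a [match_set].
#' @return The filtered `match_set`; its `k` is the count `k*`.
#' @export
filter_equal_orientation <- function(matches) {
  stopifnot(inherits(matches, "match_set"))
  omega <- round(wrap_half_turn(matches$orientations$o_query -
                                  matches$orientations$o_model))
  keep <- omega == 0
  structure(list(
    pairs = matches$pairs[keep, , drop = FALSE],
    distances = matches$distances[keep],
    orientations = matches$orientations[keep, , drop = FALSE],
    q_idx = matches$q_idx[keep], m_idx = matches$m_idx[keep],
    k = sum(keep)),
    class = "match_set")
}

#' Score constructor for one query-model comparison
#'
#' @param model the compared [fin_model] (or an identifying label).
#' @param k raw mutual-nearest-neighbour match count.
#' @param k_star match count after the equal-orientation filter.
#' @param d_star trimmed median distance, or `NA` when `k = 0`.
#' @return An object of class `model_score`.
#' @export
model_score <- function(model, k, k_star, d_star) {
  if (k_star > k) stop("k_star cannot exceed k", call. = FALSE)
  structure(list(model = model, k = as.integer(k), k_star = as.integer(k_star),
                 d_star = as.numeric(d_star)),
            class = "model_score")
}

#' Compare a query feature set with every enrolled model
#'
#' For each model: mutual-nearest-neighbour matching, trimmed median distance
#' `d*` over all match distances, then the equal-orientation filter yielding
#' `k*`. Model order is preserved.
#'
#' @param query_features a non-empty [feature_set].
#' @param models non-empty list of [fin_model]s.
#' @param lowe_ratio optional ratio test forwarded to [match_features()].
#' @return List of [model_score]s, one per model, in model order.
#' @export
compare_to_models <- function(query_features, models, lowe_ratio = NULL) {
  if (length(models) == 0L) stop("empty model collection", call. = FALSE)
  lapply(models, function(m) {
    ms <- match_features(query_features, m$features, lowe_ratio = lowe_ratio)
    d_star <- if (ms$k >= 1L) median_distance_iqr(ms$distances) else NA_real_
    k_star <- filter_equal_orientation(ms)$k
    model_score(m, ms$k, k_star, d_star)
  })
}

#' Identity decision from model scores
#'
#' The predicted identity is the model with the highest `k*`; ties are broken
#' by the minimum trimmed median distance `d*`; if that also ties, the first
#' tied model in enrollment order wins and an `ambiguous_tie` warning is
#' attached. A winning `k* <= 4` attaches a `low_support` warning.
#'
#' @param scores non-empty list of [model_score]s in model order.
#' @return An object of class `fin_prediction`: list with `dolphin_name`,
#'   `side`, `winning_score`, `warnings` and `scores`.
#' @export
predict_identity <- function(scores) {
  if (length(scores) == 0L) stop("no scores", call. = FALSE)
  k_star <- vapply(scores, `[[`, integer(1), "k_star")
  d_star <- vapply(scores, `[[`, numeric(1), "d_star")
  warnings <- character()
  cand <- which(k_star == max(k_star))
  if (length(cand) > 1L) {
    d <- d_star[cand]
    d[is.na(d)] <- Inf
    best <- cand[d == min(d)]
    if (length(best) > 1L) warnings <- c(warnings, "ambiguous_tie")
    winner <- best[1]
  } else winner <- cand[1]
  if (k_star[winner] <= 4L) warnings <- c(warnings, "low_support")
  w <- scores[[winner]]
  structure(list(dolphin_name = w$model$dolphin_name, side = w$model$side,
                 winning_score = w, warnings = warnings, scores = scores),
            class = "fin_prediction")
}

#' @export
print.fin_prediction <- function(x, ...) {
  cat(sprintf("<prediction: %s (%s)  k*=%d d*=%.4g%s>\n", x$dolphin_name,
              x$side, x$winning_score$k_star, x$winning_score$d_star,
              if (length(x$warnings)) paste0("  [", paste(x$warnings,
                                                          collapse = ","), "]")
              else ""))
  invisible(x)
}

fin_rejection <- function(reasons, sharpness = NA_real_, n_features = NA_integer_) {
  structure(list(rejected = TRUE, reasons = reasons,
                 sharpness = sharpness, n_features = n_features),
            class = "fin_rejection")
}

#' @export
print.fin_rejection <- function(x, ...) {
  cat(sprintf("<rejected: %s>\n", paste(x$reasons, collapse = ", ")))
  invisible(x)
}

#' Identify the dolphin in a fin photograph
#'
#' Full pipeline: extract the fin mask, score sharpness, detect keypoints
#' inside the fin, apply the admission filter; if the image is admitted,
#' compare it against every enrolled model and decide the identity. Images
#' failing segmentation or the admission filter are returned as a structured
#' rejection naming the failed rules rather than a forced guess; likewise a
#' query that matches no model at all (`k = 0` everywhere) is rejected.
#'
#' @param image the query [fin_image].
#' @param models non-empty list of enrolled [fin_model]s.
#' @param quality a [quality_config()].
#' @param backend a [detector_backend()].
#' @param seg_config a [segmentation_config()].
#' @param lowe_ratio optional ratio test forwarded to matching.
#' @return A `fin_prediction` (with extra fields `sharpness`, `n_features`)
#'   or a `fin_rejection`.
#' @export
identify <- function(image, models, quality = quality_config(),
                     backend = detector_backend(),
                     seg_config = segmentation_config(), lowe_ratio = NULL) {
  if (length(models) == 0L) stop("no enrolled models", call. = FALSE)
  mask <- tryCatch(extract_fin_mask(image, seg_config), error = identity)
  if (inherits(mask, "error"))
    return(fin_rejection(paste0("segmentation: ", conditionMessage(mask))))
  sh <- sharpness(image, mask, scope = quality$sharpness_scope)
  fs <- detect_features(image, mask, backend)
  gate <- passes_filter(image, mask, nrow(fs$keypoints), quality)
  if (!gate$pass)
    return(fin_rejection(gate$reasons, sharpness = sh,
                         n_features = nrow(fs$keypoints)))
  scores <- compare_to_models(fs, models, lowe_ratio = lowe_ratio)
  if (max(vapply(scores, `[[`, integer(1), "k")) == 0L)
    return(fin_rejection("low_support", sharpness = sh,
                         n_features = nrow(fs$keypoints)))
  pred <- predict_identity(scores)
  pred$sharpness <- sh
  pred$n_features <- nrow(fs$keypoints)
  pred
}

#' Persist an enrolled gallery to a directory
#'
#' Writes `models.json` (name, side, backend, descriptor length, sharpness,
#' per-model file names), one keypoint table and one descriptor matrix per
#' model (CSV), and the enrolled images as PNG.
#'
#' @param models list of [fin_model]s.
#' @param dir output directory (created if needed).
#' @param backend_name name recorded in `models.json`.
#' @return Invisibly, `dir`.
#' @export
save_gallery <- function(models, dir, backend_name = "cdog") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    stem <- sprintf("model%03d", i)
    utils::write.csv(m$features$keypoints, file.path(dir, paste0(stem, "_kp.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(m$features$descriptors),
                     file.path(dir, paste0(stem, "_desc.csv")), row.names = FALSE)
    img_file <- NA_character_
    if (!is.null(m$image)) {
      img_file <- paste0(stem, ".png")
      write_fin_image(m$image, file.path(dir, img_file))
    }
    list(dolphin_name = m$dolphin_name, side = m$side, stem = stem,
         image = img_file, sharpness = m$sharpness,
         backend = backend_name, descriptor_length = ncol(m$features$descriptors))
  })
  jsonlite::write_json(meta, file.path(dir, "models.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load an enrolled gallery from a directory
#'
#' @param dir directory written by [save_gallery()].
#' @param load_images also read the enrolled PNGs back (default `FALSE`).
#' @return List of [fin_model]s.
#' @export
load_gallery <- function(dir, load_images = FALSE) {
  meta_path <- file.path(dir, "models.json")
  if (!file.exists(meta_path))
    stop("no gallery found at ", dir, " (missing models.json)", call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path, simplifyDataFrame = FALSE)
  lapply(meta, function(m) {
    kp <- utils::read.csv(file.path(dir, paste0(m$stem, "_kp.csv")))
    desc <- as.matrix(utils::read.csv(file.path(dir, paste0(m$stem, "_desc.csv"))))
    img <- if (load_images && !is.null(m$image) && !is.na(m$image))
      read_fin_image(file.path(dir, m$image)) else NULL
    fin_model(m$dolphin_name, m$side, img,
              feature_set(kp, desc, image_ref = m$stem),
              sharpness = m$sharpness)
  })
}
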