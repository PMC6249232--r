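#' Evaluate identification against labelled queries
#'
#' Runs [identify()] on every labelled query and scores the predictions.
#' Accuracy is the fraction of correct identities among *admitted* queries
#' (those passing segmentation and the admission filter); rejected queries
#' are excluded from the denominator. A penalised accuracy counting
#' rejections as errors is reported alongside for transparency.
#'
#' @param models non-empty list of enrolled [fin_model]s.
#' @param queries list of `list(image = fin_image, label = character)`, as
#'   produced by [generate_gallery()].
#' @param quality a [quality_config()].
#' @param backend a [detector_backend()].
#' @param seg_config a [segmentation_config()].
#' @param lowe_ratio optional ratio test forwarded to matching.
#' @return An object of class `evaluation_result`: list with `per_query`
#'   (data.frame), `accuracy`, `accuracy_penalized`, `n_admitted`, `n_total`.
#' @export
evaluate <- function(models, queries, quality = quality_config(),
                     backend = detector_backend(),
                     seg_config = segmentation_config(), lowe_ratio = NULL) {
  if (length(queries) == 0L) stop("no queries", call. = FALSE)
  rows <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    res <- identify(q$image, models, quality = quality, backend = backend,
                    seg_config = seg_config, lowe_ratio = lowe_ratio)
    if (inherits(res, "fin_rejection")) {
      rows[[i]] <- data.frame(
        query = q$image$source, true_name = q$label,
        predicted_name = NA_character_, side = NA_character_,
        k = NA_integer_, k_star = NA_integer_, d_star = NA_real_,
        sharpness = res$sharpness, warnings = "",
        rejected = TRUE, rejected_reason = paste(res$reasons, collapse = ";"),
        correct = NA, stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        query = q$image$source, true_name = q$label,
        predicted_name = res$dolphin_name, side = res$side,
        k = res$winning_score$k, k_star = res$winning_score$k_star,
        d_star = res$winning_score$d_star, sharpness = res$sharpness,
        warnings = paste(res$warnings, collapse = ";"),
        rejected = FALSE, rejected_reason = "",
        correct = identical(res$dolphin_name, q$label),
        stringsAsFactors = FALSE)
    }
  }
  per_query <- do.call(rbind, rows)
  admitted <- !per_query$rejected
  if (!any(admitted))
    stop("zero admitted queries: every query was rejected", call. = FALSE)
  structure(list(
    per_query = per_query,
    accuracy = mean(per_query$correct[admitted]),
    accuracy_penalized = sum(per_query$correct[admitted]) / nrow(per_query),
    n_admitted = sum(admitted), n_total = nrow(per_query)),
    class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation: accuracy %.1f%% on %d/%d admitted queries>\n",
              100 * x$accuracy, x$n_admitted, x$n_total))
  invisible(x)
}

#' Accuracy as a function of the sharpness threshold
#'
#' For each threshold `sigma_s`, the identification accuracy over admitted
#' queries whose sharpness is strictly greater than `sigma_s`, with the
#' retained count. Default thresholds are the 1, 10, 25, 50, 75 and
#' 90-percentiles of the admitted queries' sharpness values. A threshold
#' retaining zero queries is reported with `NA` accuracy, never dropped.
#'
#' @param result an [evaluate()] result.
#' @param thresholds numeric vector of sharpness thresholds, or `NULL` for
#'   the percentile defaults.
#' @return data.frame with `sigma_s`, `accuracy`, `n_retained`.
#' @export
accuracy_by_sharpness <- function(result, thresholds = NULL) {
  stopifnot(inherits(result, "evaluation_result"))
  pq <- result$per_query[!result$per_query$rejected, , drop = FALSE]
  if (nrow(pq) == 0L) stop("no admitted queries", call. = FALSE)
  if (is.null(thresholds))
    thresholds <- stats::quantile(pq$sharpness,
                                  c(0.01, 0.10, 0.25, 0.50, 0.75, 0.90),
                                  type = 7, names = FALSE)
  out <- lapply(thresholds, function(s) {
    keep <- pq$sharpness > s
    data.frame(sigma_s = s,
               accuracy = if (any(keep)) mean(pq$correct[keep]) else NA_real_,
               n_retained = sum(keep))
  })
  do.call(rbind, out)
}

#' Distribution of query sharpness
#'
#' Five-number summary (minimum, quartiles, maximum; linear-interpolation
#' quantiles) of the admitted queries' sharpness plus the outliers under the
#' standard 1.5 IQR boxplot rule.
#'
#' @param result an [evaluate()] result.
#' @return List with `min`, `q1`, `median`, `q3`, `max` and `outliers`.
#' @export
sharpness_distribution <- function(result) {
  stopifnot(inherits(result, "evaluation_result"))
  v <- result$per_query$sharpness[!result$per_query$rejected]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no admitted queries", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
  list(min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
       outliers = sort(out))
}
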