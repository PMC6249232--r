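test_that("matching an identical feature set is a perfect zero-distance bijection", {
  fs <- random_feature_set(25, seed = 3)
  ms <- match_features(fs, fs)
  expect_equal(ms$k, 25L)
  expect_identical(ms$q_idx, ms$m_idx)
  expect_true(all(ms$distances == 0))
  expect_equal(ms$orientations$o_query, ms$orientations$o_model)
  expect_equal(filter_equal_orientation(ms)$k, 25L)
})

test_that("matching is one-to-one and bounded by the smaller set", {
  q <- random_feature_set(12, seed = 4)
  m <- random_feature_set(30, seed = 5)
  ms <- match_features(q, m)
  expect_lte(ms$k, 12L)
  expect_false(anyDuplicated(ms$q_idx) > 0)
  expect_false(anyDuplicated(ms$m_idx) > 0)
})

test_that("mutual-NN matching agrees with the brute-force oracle and recovers planted pairs", {
  set.seed(6)
  for (trial in 1:10) {
    base <- matrix(rnorm(20 * 16), 20, 16) * 5
    noise <- matrix(rnorm(20 * 16, 0, 0.01), 20, 16)
    Q <- rbind(base + noise, matrix(rnorm(10 * 16, 50, 1), 10, 16))
    M <- rbind(base, matrix(rnorm(10 * 16, -50, 1), 10, 16))
    fq <- feature_set(data.frame(x = seq_len(30), y = 0, scale = 1,
                                 orientation = 0), Q)
    fm <- feature_set(data.frame(x = seq_len(30), y = 0, scale = 1,
                                 orientation = 0), M)
    ms <- match_features(fq, fm)
    oracle <- mutual_nn_oracle(Q, M)
    expect_equal(cbind(ms$q_idx, ms$m_idx)[order(ms$q_idx), , drop = FALSE],
                 oracle[order(oracle[, 1]), , drop = FALSE],
                 ignore_attr = TRUE)
    # the 20 planted correspondences are all recovered
    expect_true(all(vapply(1:20, function(i)
      any(ms$q_idx == i & ms$m_idx == i), logical(1))))
  }
})

test_that("trimmed median distance follows the percentile convention", {
  expect_equal(median_distance_iqr(c(1, 2, 3, 4, 100)), 3)
  expect_equal(median_distance_iqr(rep(7, 4)), 7)
  expect_equal(median_distance_iqr(5), 5)
  expect_error(median_distance_iqr(numeric()), "k must be >= 1")
})

test_that("the equal-orientation filter keeps exactly the zero-rounded pairs", {
  mk_match <- function(dq, dm) {
    n <- length(dq)
    structure(list(pairs = data.frame(qx = 1:n, qy = 1, mx = 1:n, my = 1),
                   distances = rep(1, n),
                   orientations = data.frame(o_query = dq, o_model = dm),
                   q_idx = 1:n, m_idx = 1:n, k = n), class = "match_set")
  }
  expect_equal(filter_equal_orientation(mk_match(30.2, 30.4))$k, 1L)
  expect_equal(filter_equal_orientation(mk_match(30, 45))$k, 0L)
  # differences -0.4, 0.5, 0.6, 180: round-half-to-even keeps the first two
  ms <- mk_match(c(10 - 0.4, 10.5, 10.6, 190) %% 360, rep(10, 4))
  expect_equal(filter_equal_orientation(ms)$k, 2L)
  # wrap-around: 359.8 vs 0.1 is a -0.3 degree difference
  expect_equal(filter_equal_orientation(mk_match(359.8, 0.1))$k, 1L)
})

test_that("comparing to models is order-preserving and batch equals per-model", {
  set.seed(8)
  query <- random_feature_set(15, seed = 9)
  models <- lapply(1:3, function(i)
    fin_model(paste0("M", i), "left", NULL, random_feature_set(10, seed = 20 + i)))
  batch <- compare_to_models(query, models)
  expect_length(batch, 3L)
  for (i in 1:3) {
    single <- compare_to_models(query, models[i])[[1]]
    expect_equal(batch[[i]]$k, single$k)
    expect_equal(batch[[i]]$k_star, single$k_star)
    expect_equal(batch[[i]]$d_star, single$d_star)
    expect_equal(batch[[i]]$model$dolphin_name, paste0("M", i))
  }
  self <- compare_to_models(query, list(fin_model("Q", "left", NULL, query)))[[1]]
  expect_equal(self$k_star, 15L)
  expect_equal(self$d_star, 0)
  expect_error(compare_to_models(query, list()), "empty")
})

test_that("the identity decision follows argmax k*, d* tie-break, and warns", {
  sc <- function(name, k_star, d_star)
    model_score(list(dolphin_name = name, side = "left"),
                k = k_star + 2L, k_star = k_star, d_star = d_star)
  p <- predict_identity(list(sc("A", 10L, 0.2), sc("B", 3L, 0.1)))
  expect_equal(p$dolphin_name, "A")
  expect_length(p$warnings, 0)

  p <- predict_identity(list(sc("A", 5L, 0.3), sc("B", 5L, 0.1)))
  expect_equal(p$dolphin_name, "B")

  p <- predict_identity(list(sc("A", 3L, 0.1), sc("B", 2L, 0.2)))
  expect_equal(p$dolphin_name, "A")
  expect_equal(p$warnings, "low_support")

  p <- predict_identity(list(sc("A", 6L, 0.2), sc("B", 6L, 0.2)))
  expect_equal(p$dolphin_name, "A")
  expect_equal(p$warnings, "ambiguous_tie")
})

test_that("identify returns the enrolled identity on its own model image", {
  models <- test_models()
  r <- identify(models[[3]]$image, models)
  expect_s3_class(r, "fin_prediction")
  expect_equal(r$dolphin_name, models[[3]]$dolphin_name)
  expect_equal(r$winning_score$d_star, 0)
  expect_equal(r$winning_score$k_star, nrow(models[[3]]$features$keypoints))
})

test_that("identify survives a 30-degree in-plane rotation of the query", {
  gal <- test_gallery()
  models <- test_models()
  q <- generate_fin_image(gal$identities[[7]],
                          render_params(rotation_deg = 30, seed = 555))
  r <- identify(q$image, models)
  expect_s3_class(r, "fin_prediction")
  expect_equal(r$dolphin_name, gal$identities[[7]]$name)
})

test_that("undersized queries are rejected with the violated rules named", {
  models <- test_models()
  id <- identity_spec("small", seed = 101)
  q <- generate_fin_image(id, render_params(width = 150L, height = 150L,
                                            seed = 102))
  r <- identify(q$image, models)
  expect_s3_class(r, "fin_rejection")
  expect_true(all(c("width", "height") %in% r$reasons))
})

test_that("galleries persist to disk and load back without changing decisions", {
  models <- test_models()[1:4]
  dir <- withr::local_tempdir()
  save_gallery(models, dir)
  back <- load_gallery(dir)
  expect_length(back, 4L)
  gal <- test_gallery()
  q <- gal$queries[[1]]
  r1 <- identify(q$image, models)
  r2 <- identify(q$image, back)
  expect_equal(r2$dolphin_name, r1$dolphin_name)
  expect_equal(r2$winning_score$k_star, r1$winning_score$k_star)
  expect_equal(r2$winning_score$d_star, r1$winning_score$d_star, tolerance = 1e-6)
  expect_error(load_gallery(file.path(dir, "nope")), "nope")
})
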