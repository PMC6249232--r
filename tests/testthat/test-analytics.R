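# union-find oracle for connected components of a bipartite edge list
components_oracle <- function(dolphins, dates, edges) {
  nodes <- c(paste0("D:", dolphins), paste0("T:", dates))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(edges) > 0L) for (i in seq_len(nrow(edges))) {
    a <- find(paste0("D:", edges$dolphin[i]))
    b <- find(paste0("T:", edges$date[i]))
    if (a != b) parent[[a]] <- b
  }
  length(unique(vapply(nodes, find, character(1))))
}

test_that("the dolphin-date graph structure matches direct counting", {
  cat0 <- two_strata_catalogue()
  g <- build_sighting_graph(cat0)
  pairs <- unique(paste(cat0$entries$dolphin_name,
                        cat0$entries$observation_date))
  expect_equal(nrow(g$edges), length(pairs))
  # a dolphin seen on 2 dates has degree 2
  expect_equal(sum(g$edges$dolphin == "B"), 3L)
  empty <- build_sighting_graph(catalogue(data.frame()))
  expect_equal(nrow(empty$edges), 0L)
  expect_length(connected_components(empty), 0L)
})

test_that("disjoint sighting communities split into complementary sub-graphs", {
  entries <- data.frame(
    dolphin_name = c("A", "A", "B"),
    input_image = paste0("i", 1:3), cropped_fin = paste0("f", 1:3),
    observation_date = c("2015-01-01", "2015-02-01", "2015-03-01"),
    gps_lat = 40, gps_lon = 17, codename = "c", stringsAsFactors = FALSE)
  g <- build_sighting_graph(catalogue(entries))
  comps <- connected_components(g)
  expect_length(comps, 2L)
  sizes <- sort(vapply(comps, function(s)
    length(s$dolphin_nodes) + length(s$date_nodes), numeric(1)))
  expect_equal(sizes, c(2, 3))
})

test_that("components match a union-find oracle on random catalogues", {
  for (seed in 1:8) {
    cat0 <- generate_catalogue(n_dolphins = 12, n_dates = 6,
                               p_resight = 0.18, seed = seed)
    g <- build_sighting_graph(cat0)
    comps <- connected_components(g)
    expect_equal(length(comps),
                 components_oracle(g$dolphin_nodes, g$date_nodes, g$edges))
    # partition property: component sizes sum to the node total
    expect_equal(sum(vapply(comps, function(s)
      length(s$dolphin_nodes) + length(s$date_nodes), numeric(1))),
      length(g$dolphin_nodes) + length(g$date_nodes))
    # edge count equals the number of distinct (dolphin, date) pairs
    expect_equal(nrow(g$edges),
                 nrow(unique(cat0$entries[, c("dolphin_name",
                                              "observation_date")])))
  }
})

test_that("every dolphin on its own date yields one component per dolphin", {
  n <- 7L
  entries <- data.frame(
    dolphin_name = sprintf("D%d", 1:n),
    input_image = sprintf("i%d", 1:n), cropped_fin = sprintf("f%d", 1:n),
    observation_date = as.character(as.Date("2015-01-01") + 1:n),
    gps_lat = 40, gps_lon = 17, codename = "c", stringsAsFactors = FALSE)
  comps <- connected_components(build_sighting_graph(catalogue(entries)))
  expect_length(comps, n)
})

test_that("co-sighting edges carry shared-date weights and the dashed/solid rule", {
  cat0 <- two_strata_catalogue()
  g <- build_co_sighting_graph(cat0)
  ab <- g$edges[g$edges$a == "A" & g$edges$b == "B", ]
  expect_equal(ab$weight, 2L)      # A and B share 2013-07-01 and 2014-07-01
  expect_equal(ab$style, "solid")
  ac <- g$edges[g$edges$a == "A" & g$edges$b == "C", ]
  expect_equal(ac$weight, 1L)
  expect_equal(ac$style, "dashed")
  expect_true(all((g$edges$weight == 1L) == (g$edges$style == "dashed")))
  # A was seen at 500/600/900 m -> both strata; C only at 900 m -> deep only
  cls <- stats::setNames(g$nodes$depth_class, g$nodes$dolphin_name)
  expect_equal(unname(cls["A"]), "both")
  expect_equal(unname(cls["C"]), "deep_only")
  expect_equal(unname(cls["B"]), "both")
})

test_that("sighting frequency is normalised per stratum and excludes singletons", {
  cat0 <- two_strata_catalogue()
  sh <- sighting_frequency(cat0, "shallow")
  # shallow stratum has 2 sightings; A is in both, B in one; C never shallow
  expect_equal(sh$frequency[sh$dolphin_name == "A"], 1.0)
  expect_equal(sh$frequency[sh$dolphin_name == "B"], 0.5)
  expect_false("C" %in% sh$dolphin_name)   # C has 1 total sighting: excluded
  de <- sighting_frequency(cat0, "deep")
  expect_false("C" %in% de$dolphin_name)
  expect_true(all(de$frequency > 0 & de$frequency <= 1))
  s <- cat0$sightings
  shallow_only <- catalogue(cat0$entries[cat0$entries$observation_date <=
                                           as.Date("2013-08-01"), ],
                            s[s$depth_m < 800, ])
  expect_error(sighting_frequency(shallow_only, "deep"), "no sightings")
})

test_that("the right-tailed rank-sum test matches hand-enumerated cases", {
  r <- wilcoxon_rank_sum_right(c(3, 4, 5), c(1, 2))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  r <- wilcoxon_rank_sum_right(1, 1)
  expect_equal(r$p_value, 0.5)
  r <- wilcoxon_rank_sum_right(c(1, 2), c(3, 4, 5))
  expect_gt(r$p_value, 0.5)
  expect_error(wilcoxon_rank_sum_right(numeric(), 1), "non-empty")
  # large-sample branch is a sane approximation of the exact tail
  set.seed(13)
  x <- rnorm(30, 0.8); y <- rnorm(30)
  appr <- wilcoxon_rank_sum_right(x, y)
  expect_equal(appr$method, "normal_approx")
  ref <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)
  expect_equal(appr$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("summary tables tally images, dates and dolphins exactly", {
  cat0 <- catalogue(taras_entries())
  st <- summary_statistics(cat0)
  expect_equal(nrow(st$recap), 2L)
  expect_true(all(st$recap$n_images == 1L))
  expect_equal(st$images_per_dolphin$n_images, 2L)
  expect_equal(st$dates_per_dolphin$n_dates, 2L)

  st0 <- summary_statistics(catalogue(data.frame()))
  expect_equal(nrow(st0$recap), 0L)
  expect_equal(nrow(st0$images_per_dolphin), 0L)

  cat1 <- generate_catalogue(n_dolphins = 15, n_dates = 5, p_resight = 0.4,
                             seed = 2)
  st1 <- summary_statistics(cat1)
  pairs <- nrow(unique(cat1$entries[, c("dolphin_name", "observation_date")]))
  expect_equal(sum(st1$dates_per_dolphin$n_dates), pairs)
  expect_equal(sum(st1$dolphins_per_date$n_dolphins), pairs)
})

test_that("graphs export as edge-list CSV and GraphML", {
  cat0 <- two_strata_catalogue()
  g <- build_sighting_graph(cat0)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(g, p1, "csv")
  expect_equal(nrow(utils::read.csv(p1)), nrow(g$edges))
  write_graph_file(g, p2, "graphml")
  expect_gt(file.size(p2), 0)
  cg <- build_co_sighting_graph(cat0)
  p3 <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(cg, p3, "graphml")
  expect_gt(file.size(p3), 0)
})
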