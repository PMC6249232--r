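#' Bipartite dolphin-date sighting graph
#'
#' One node per identified dolphin, one node per observation date, and an
#' undirected edge whenever at least one catalogue entry links the two. Two
#' dolphins are co-sighted iff they share a date node neighbour; connected
#' components of this graph are closed sighting communities.
#'
#' @param cat a [catalogue].
#' @return An object of class `sighting_graph`: list with `dolphin_nodes`,
#'   `date_nodes` and `edges` (data.frame `dolphin`, `date`).
#' @export
build_sighting_graph <- function(cat) {
  stopifnot(inherits(cat, "catalogue"))
  e <- cat$entries
  edges <- unique(data.frame(dolphin = e$dolphin_name,
                             date = as.character(e$observation_date),
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  structure(list(dolphin_nodes = sort(unique(edges$dolphin)),
                 date_nodes = sort(unique(edges$date)),
                 edges = edges),
            class = "sighting_graph")
}

#' @export
print.sighting_graph <- function(x, ...) {
  cat(sprintf("<sighting_graph: %d dolphins, %d dates, %d edges>\n",
              length(x$dolphin_nodes), length(x$date_nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph_sighting <- function(graph) {
  v <- c(paste0("D:", graph$dolphin_nodes), paste0("T:", graph$date_nodes))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(v), name = v)
  if (nrow(graph$edges) > 0L)
    g <- igraph::add_edges(g, rbind(paste0("D:", graph$edges$dolphin),
                                    paste0("T:", graph$edges$date)))
  g
}

#' Connected components of a sighting graph
#'
#' Partitions dolphins and dates into maximal connected sub-graphs. Disjoint
#' components mean disjoint sighting communities: the dolphins seen on one
#' component's dates are never seen on the other's.
#'
#' @param graph a [build_sighting_graph()] result.
#' @return List of `sighting_graph` objects, largest first.
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "sighting_graph"))
  n_nodes <- length(graph$dolphin_nodes) + length(graph$date_nodes)
  if (n_nodes == 0L) return(list())
  g <- as_igraph_sighting(graph)
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(k) {
    members <- igraph::V(g)$name[comp$membership == k]
    dol <- sub("^D:", "", members[startsWith(members, "D:")])
    dat <- sub("^T:", "", members[startsWith(members, "T:")])
    edges <- graph$edges[graph$edges$dolphin %in% dol |
                           graph$edges$date %in% dat, , drop = FALSE]
    structure(list(dolphin_nodes = sort(dol), date_nodes = sort(dat),
                   edges = edges), class = "sighting_graph")
  })
  sizes <- vapply(out, function(s)
    length(s$dolphin_nodes) + length(s$date_nodes), numeric(1))
  out[order(-sizes)]
}

#' Co-sighting graph with depth preference
#'
#' Nodes are dolphins, classified by the depth stratum of their sightings
#' (`shallow_only`, `deep_only` or `both`, split at `depth_split_m`, with
#' sightings at exactly the split classified deep). Two dolphins are linked
#' iff they share at least one sighting date; the edge weight is the number
#' of shared dates, styled `dashed` for exactly one shared date and `solid`
#' for more.
#'
#' @param cat a [catalogue] whose sightings carry `depth_m`.
#' @param depth_split_m stratum boundary in metres (default 800).
#' @return An object of class `co_sighting_graph`: list with `nodes`
#'   (data.frame `dolphin_name`, `depth_class`) and `edges` (data.frame
#'   `a`, `b`, `weight`, `style`).
#' @export
build_co_sighting_graph <- function(cat, depth_split_m = 800) {
  stopifnot(inherits(cat, "catalogue"))
  s <- cat$sightings
  if (is.null(s)) stop("catalogue has no sightings", call. = FALSE)
  if (any(is.na(s$depth_m)))
    stop("validation error: sighting without depth_m", call. = FALSE)
  deep <- s$depth_m >= depth_split_m
  long <- data.frame(
    dolphin = unlist(s$dolphins),
    date = rep(as.character(s$date), lengths(s$dolphins)),
    deep = rep(deep, lengths(s$dolphins)), stringsAsFactors = FALSE)
  if (nrow(long) == 0L)
    return(structure(list(nodes = data.frame(dolphin_name = character(),
                                             depth_class = character()),
                          edges = data.frame(a = character(), b = character(),
                                             weight = integer(),
                                             style = character())),
                     class = "co_sighting_graph"))
  cls <- vapply(split(long$deep, long$dolphin), function(d) {
    if (all(d)) "deep_only" else if (all(!d)) "shallow_only" else "both"
  }, character(1))
  nodes <- data.frame(dolphin_name = names(cls), depth_class = unname(cls),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$dolphin_name), , drop = FALSE]
  rownames(nodes) <- NULL
  pair_list <- list()
  for (d in unique(long$date)) {
    dd <- sort(unique(long$dolphin[long$date == d]))
    if (length(dd) >= 2L) {
      cmb <- utils::combn(dd, 2L)
      pair_list[[d]] <- data.frame(a = cmb[1, ], b = cmb[2, ],
                                   stringsAsFactors = FALSE)
    }
  }
  if (length(pair_list) == 0L) {
    edges <- data.frame(a = character(), b = character(), weight = integer(),
                        style = character())
  } else {
    pairs <- do.call(rbind, pair_list)
    key <- paste(pairs$a, pairs$b, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(a = vapply(parts, `[`, "", 1L),
                        b = vapply(parts, `[`, "", 2L),
                        weight = as.integer(tab), stringsAsFactors = FALSE)
    edges$style <- ifelse(edges$weight == 1L, "dashed", "solid")
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "co_sighting_graph")
}

#' @export
print.co_sighting_graph <- function(x, ...) {
  cat(sprintf("<co_sighting_graph: %d dolphins, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Sighting frequency per dolphin in a depth stratum
#'
#' The site-fidelity descriptor: for each identified dolphin, the number of
#' its sightings in the stratum divided by the stratum's total number of
#' sightings. Only individuals sighted more than once overall (across both
#' strata) are reported.
#'
#' @param cat a [catalogue] with sightings.
#' @param stratum `"shallow"` (depth < split) or `"deep"` (depth >= split).
#' @param depth_split_m stratum boundary in metres (default 800).
#' @return data.frame with `dolphin_name`, `stratum`, `n_sightings`,
#'   `frequency` (each in `(0, 1]`).
#' @export
sighting_frequency <- function(cat, stratum = c("shallow", "deep"),
                               depth_split_m = 800) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(cat, "catalogue"))
  s <- cat$sightings
  if (is.null(s)) stop("catalogue has no sightings", call. = FALSE)
  deep <- s$depth_m >= depth_split_m
  in_stratum <- if (stratum == "deep") deep else !deep
  total <- sum(in_stratum)
  if (total == 0L) stop("no sightings in stratum ", stratum, call. = FALSE)
  all_counts <- table(unlist(s$dolphins))
  strat_counts <- table(unlist(s$dolphins[in_stratum]))
  keep <- names(strat_counts)[all_counts[names(strat_counts)] > 1L]
  out <- data.frame(dolphin_name = keep, stratum = stratum,
                    n_sightings = as.integer(strat_counts[keep]),
                    stringsAsFactors = FALSE)
  out$frequency <- out$n_sightings / total
  out <- out[order(out$dolphin_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Right-tailed Wilcoxon rank-sum test
#'
#' Tests whether values in `x` tend to be larger than values in `y`
#' (one-sided, H1: x stochastically greater). With no ties and a combined
#' sample size of at most 12 the p-value is exact (the full null distribution
#' of the Mann-Whitney U statistic); otherwise midranks are used with a
#' normal approximation, tie-corrected variance and continuity correction.
#' A degenerate case with zero variance returns p = 0.5.
#'
#' @param x,y non-empty numeric vectors.
#' @return List with `U` (Mann-Whitney statistic of `x`), `p_value` and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_rank_sum_right <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n <= 12L) {
    # exact null distribution of U; right tail P(U >= u)
    p <- stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- nx * ny / 2
  tie_tab <- table(r)
  corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sig2 <- nx * ny / 12 * ((n + 1) - corr)
  if (sig2 <= 0) return(list(U = U, p_value = 0.5, method = "normal_approx"))
  z <- (U - mu - 0.5) / sqrt(sig2)
  list(U = U, p_value = stats::pnorm(z, lower.tail = FALSE),
       method = "normal_approx")
}

#' Catalogue summary tables
#'
#' The engine statistics behind the platform reports: (1) a recap of image
#' counts per dolphin per date, (2) image counts per dolphin, and (3) the
#' date-coverage tables — distinct dates per dolphin and distinct dolphins
#' per date.
#'
#' @param cat a [catalogue].
#' @return List with data.frames `recap` (`dolphin_name`, `date`, `n_images`),
#'   `images_per_dolphin`, `dates_per_dolphin` and `dolphins_per_date`.
#' @export
summary_statistics <- function(cat) {
  stopifnot(inherits(cat, "catalogue"))
  e <- cat$entries
  if (nrow(e) == 0L) {
    empty <- function(...) {
      df <- data.frame(...)
      df[0L, , drop = FALSE]
    }
    return(list(
      recap = empty(dolphin_name = "", date = "", n_images = 0L),
      images_per_dolphin = empty(dolphin_name = "", n_images = 0L),
      dates_per_dolphin = empty(dolphin_name = "", n_dates = 0L),
      dolphins_per_date = empty(date = "", n_dolphins = 0L)))
  }
  dt <- as.character(e$observation_date)
  recap <- as.data.frame(table(dolphin_name = e$dolphin_name, date = dt),
                         stringsAsFactors = FALSE)
  names(recap)[3] <- "n_images"
  recap <- recap[recap$n_images > 0L, , drop = FALSE]
  recap <- recap[order(recap$dolphin_name, recap$date), , drop = FALSE]
  rownames(recap) <- NULL
  ipd <- as.data.frame(table(dolphin_name = e$dolphin_name),
                       stringsAsFactors = FALSE)
  names(ipd)[2] <- "n_images"
  pairs <- unique(data.frame(dolphin_name = e$dolphin_name, date = dt,
                             stringsAsFactors = FALSE))
  dpd <- as.data.frame(table(dolphin_name = pairs$dolphin_name),
                       stringsAsFactors = FALSE)
  names(dpd)[2] <- "n_dates"
  dpdate <- as.data.frame(table(date = pairs$date), stringsAsFactors = FALSE)
  names(dpdate)[2] <- "n_dolphins"
  list(recap = recap, images_per_dolphin = ipd, dates_per_dolphin = dpd,
       dolphins_per_date = dpdate)
}

#' Export a sighting or co-sighting graph
#'
#' @param graph a `sighting_graph` or `co_sighting_graph`.
#' @param path output file.
#' @param format `"csv"` (edge list) or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_graph_file <- function(graph, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (inherits(graph, "sighting_graph")) {
    if (format == "csv") {
      utils::write.csv(graph$edges, path, row.names = FALSE)
    } else {
      igraph::write_graph(as_igraph_sighting(graph), path, format = "graphml")
    }
  } else if (inherits(graph, "co_sighting_graph")) {
    if (format == "csv") {
      utils::write.csv(graph$edges, path, row.names = FALSE)
    } else {
      g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                         vertices = graph$nodes)
      igraph::write_graph(g, path, format = "graphml")
    }
  } else stop("unsupported graph object", call. = FALSE)
  invisible(path)
}
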