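#' Five global graph features of a visibility graph
#'
#' Characterises one region's visibility graph with the five global
#' properties used throughout the package:
#'
#' * `avg_weighted_degree` — arithmetic mean over nodes of the incident
#'   edge-weight sum (node strength);
#' * `avg_path_length` — mean over all unordered node pairs of the
#'   unweighted shortest-path hop count;
#' * `global_clustering` — transitivity, 3 x triangles / connected triples,
#'   on the binary edge set;
#' * `n_communities` — number of groups found by Walktrap (random-walk
#'   length 4) on the weighted graph, taking the partition that maximises
#'   modularity along the merge dendrogram;
#' * `modularity` — Newman–Girvan Q of that partition on the weighted graph.
#'
#' Path length and clustering deliberately use the binary edge set: the
#' hop-count reading of "shortest path" needs no weight-to-distance
#' transform. Set `path_weighted = TRUE` to use `1/weight` edge lengths
#' instead, as a sensitivity analysis.
#'
#' @param x either a numeric series (a weighted visibility graph is built
#'   internally) or an igraph object with edge weights.
#' @param path_weighted if `TRUE`, average path length uses weighted
#'   shortest paths with distance `1/weight`.
#' @param walk_steps Walktrap random-walk length (default 4).
#' @return a one-row tibble with the five feature columns.
#' @examples
#' vg_features(c(2, 3, 1, 4))
#' @export
vg_features <- function(x, path_weighted = FALSE, walk_steps = 4) {
  g <- if (igraph::is_igraph(x)) x else visibility_graph(x, weighted = TRUE)
  if (igraph::vcount(g) < 3) {
    abort("need at least 3 nodes", class = "vgfc_error_validation")
  }
  if (!igraph::is_connected(g)) {
    abort("graph is disconnected; valid visibility graphs are connected",
          class = "vgfc_error_validation")
  }
  w <- igraph::E(g)$weight
  if (is.null(w)) {
    abort("features need a weighted graph; build with weighted = TRUE",
          class = "vgfc_error_validation")
  }
  apl <- if (path_weighted) {
    igraph::mean_distance(g, weights = 1 / w)
  } else {
    igraph::mean_distance(g, weights = NA)
  }
  wt <- igraph::cluster_walktrap(g, weights = w, steps = walk_steps)
  memb <- igraph::membership(wt)
  tibble(avg_weighted_degree = mean(igraph::strength(g)),
         avg_path_length = apl,
         global_clustering = igraph::transitivity(g, type = "global"),
         n_communities = length(unique(memb)),
         modularity = igraph::modularity(g, memb, weights = w))
}

#' Per-region feature table for one scan
#'
#' Builds a weighted visibility graph per region (column) of a parcellated
#' time-series matrix and extracts the five features of [vg_features()].
#'
#' @param ts frames x regions data frame or matrix.
#' @param zscore z-score each region before building the weighted graph
#'   (default `TRUE`; see [zscore_regions()] for why weights need an
#'   amplitude convention).
#' @param path_weighted passed to [vg_features()].
#' @return tibble (`region`, `avg_weighted_degree`, `avg_path_length`,
#'   `global_clustering`, `n_communities`, `modularity`).
#' @export
feature_table <- function(ts, zscore = TRUE, path_weighted = FALSE) {
  m <- ts_matrix(ts)
  if (zscore) m <- as.matrix(zscore_regions(m))
  purrr::map_dfr(colnames(m), function(r) {
    mutate(vg_features(m[, r], path_weighted = path_weighted),
           region = r, .before = 1)
  })
}

#' Feature tables for a whole synthetic cohort
#'
#' Runs [feature_table()] on every (subject, session) scan of a generated
#' cohort.
#'
#' @param cohort a `vg_cohort` from [generate_cohort()].
#' @param zscore,path_weighted passed through to [feature_table()].
#' @param .progress print a dot per scan (default `FALSE`).
#' @return tibble (`subject`, `session`, `region`, five features).
#' @export
cohort_features <- function(cohort, zscore = TRUE, path_weighted = FALSE,
                            .progress = FALSE) {
  grid <- expand.grid(session = 1:2, subject = seq_len(cohort$spec$n_subjects))
  out <- purrr::map2_dfr(grid$subject, grid$session, function(s, ses) {
    if (.progress) cat(".")
    mutate(feature_table(cohort$series[[s]][[ses]], zscore = zscore,
                         path_weighted = path_weighted),
           subject = s, session = ses, .before = 1)
  })
  if (.progress) cat("\n")
  arrange(out, .data$subject, .data$session, .data$region)
}

#' Log-log binned degree distribution
#'
#' Bins positive degrees into logarithmically spaced bins and returns the
#' empirical density on log-log axes, the standard view for eyeballing
#' power-law tails. Zero-count bins are dropped. The density is normalised
#' so that the Riemann sum over bin widths is 1.
#'
#' @param degrees positive numeric degrees (binary counts or weighted
#'   strengths).
#' @param n_bins number of logarithmic bins (default 30).
#' @return tibble (`k`, `p`, `count`, `log_k`, `log_p`) with natural logs.
#' @export
degree_distribution_loglog <- function(degrees, n_bins = 30) {
  degrees <- degrees[is.finite(degrees)]
  if (length(degrees) == 0 || any(degrees <= 0)) {
    abort("degrees must be positive", class = "vgfc_error_validation")
  }
  lo <- min(degrees); hi <- max(degrees)
  if (lo == hi) {
    return(tibble(k = lo, p = NA_real_, count = length(degrees),
                  log_k = log(lo), log_p = NA_real_))
  }
  breaks <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  breaks[1] <- lo; breaks[n_bins + 1] <- hi
  idx <- findInterval(degrees, breaks, rightmost.closed = TRUE)
  idx[idx == n_bins + 1] <- n_bins
  count <- tabulate(idx, nbins = n_bins)
  width <- diff(breaks)
  centre <- sqrt(breaks[-1] * breaks[-(n_bins + 1)])
  keep <- count > 0
  p <- count / (length(degrees) * width)
  tibble(k = centre[keep], p = p[keep], count = count[keep],
         log_k = log(centre[keep]), log_p = log(p[keep]))
}
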