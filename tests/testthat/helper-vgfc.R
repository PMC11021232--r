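# Shared test utilities.

# Random stationary AR(1) series, self-contained so tests do not depend on
# the package's generator internals.
r_ar1 <- function(n, a = 0.4) {
  x <- numeric(n)
  x[1] <- rnorm(1, sd = 1 / sqrt(1 - a^2))
  for (t in 2:n) x[t] <- a * x[t - 1] + rnorm(1)
  x
}

# Sorted 0-based edge pairs of a graph, for exact edge-set comparison.
edge_pairs <- function(g) {
  e <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(e) <- "integer"
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])) - 1L
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# Newman-Girvan modularity recomputed from scratch (independent of igraph):
# Q = sum_c [ m_c/m - (d_c / 2m)^2 ] with edge weights.
modularity_from_scratch <- function(g, membership) {
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  m <- sum(w)
  deg <- numeric(igraph::vcount(g))
  for (k in seq_len(nrow(el))) {
    deg[el[k, 1]] <- deg[el[k, 1]] + w[k]
    deg[el[k, 2]] <- deg[el[k, 2]] + w[k]
  }
  q <- 0
  for (cc in unique(membership)) {
    inside <- membership[el[, 1]] == cc & membership[el[, 2]] == cc
    m_c <- sum(w[inside])
    d_c <- sum(deg[membership == cc])
    q <- q + m_c / m - (d_c / (2 * m))^2
  }
  q
}

# Tiny synthetic feature table (subject x region grid, iid values), for
# exercising the motion/reliability bookkeeping without building graphs.
random_feature_table <- function(n_subjects, n_regions, seed) {
  set.seed(seed)
  grid <- expand.grid(subject = seq_len(n_subjects),
                      region = sprintf("R%02d", seq_len(n_regions)))
  tibble::tibble(subject = grid$subject, region = as.character(grid$region),
                 avg_weighted_degree = rnorm(nrow(grid)),
                 avg_path_length = rnorm(nrow(grid)),
                 global_clustering = rnorm(nrow(grid)),
                 n_communities = rnorm(nrow(grid)),
                 modularity = rnorm(nrow(grid)))
}
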